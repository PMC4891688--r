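# Internal helpers: classed errors and seeded evaluation.

stop_goldrim <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "goldrim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(field, msg, ...) {
  stop_goldrim("goldrim_validation_error",
               paste0("invalid `", field, "`: ", sprintf(msg, ...)))
}

check_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(field, "must be a single finite number")
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_scalar(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Standard normal truncated to |z| <= k, via inverse-CDF so the number of
# RNG draws is fixed (reproducibility).
rnorm_trunc <- function(n, mean = 0, sd = 1, k = 3) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(-k)
  mean + sd * qnorm(runif(n, lo, 1 - lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
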