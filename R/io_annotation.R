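# JSON serialization of ground truth and pore annotations.  All coordinates
# are nm; axes are right-handed with the viewing axis +z and image y
# increasing downward.

vertices_to_list <- function(p) {
  v <- if (inherits(p, "goldrim_roi")) p$boundary$vertices
  else if (inherits(p, "goldrim_polyline")) p$vertices
  else as.matrix(p)
  lapply(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2]))
}

list_to_matrix <- function(x) {
  do.call(rbind, lapply(x, function(v) as.numeric(unlist(v))))
}

#' Write scene ground truth as JSON
#'
#' @param truth a [project_scene()] result.
#' @param path output JSON file.
#' @param offset length-2 nm vector added to the centered lab coordinates
#'   (use the image `offset` to express the truth in the image frame).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, offset = c(0, 0)) {
  stopifnot(inherits(truth, "goldrim_truth"))
  rim <- sweep(truth$projected_rim$vertices, 2L, -offset)
  p <- truth$particles_2d
  obj <- list(
    units = "nm",
    frame = list(viewing_axis = "+z", y_down = TRUE, offset = offset),
    true_circumference = truth$true_circumference,
    pore_diameter = truth$pore_diameter,
    vesicle_radius = truth$vesicle_radius,
    membrane_thickness = truth$membrane_thickness,
    pore_half_angle = truth$pore_half_angle,
    tilt = truth$tilt,
    azimuth = truth$orientation$azimuth,
    rim_semiaxes = truth$rim_semiaxes,
    projected_rim = lapply(seq_len(nrow(rim)), function(i) rim[i, ]),
    particles = if (nrow(p) == 0) list() else lapply(seq_len(nrow(p)), function(i)
      list(x = p$x[i] + offset[1], y = p$y[i] + offset[2],
           class = p$class[i], diameter = p$diameter[i],
           true_distance = p$true_distance[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth JSON
#'
#' @param path JSON written by [write_truth()].
#' @return a `goldrim_truth` object in the frame it was written in (its
#'   `offset` field records the shift that was applied).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path)
  pl <- x$particles
  p <- if (length(pl) == 0) {
    data.frame(x = numeric(), y = numeric(), class = character(),
               diameter = numeric(), true_distance = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      x = vapply(pl, function(q) q$x, numeric(1)),
      y = vapply(pl, function(q) q$y, numeric(1)),
      class = vapply(pl, function(q) q$class, character(1)),
      diameter = vapply(pl, function(q) q$diameter, numeric(1)),
      true_distance = vapply(pl, function(q) q$true_distance, numeric(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(
    true_circumference = x$true_circumference,
    projected_rim = polyline(list_to_matrix(x$projected_rim), closed = TRUE),
    particles_2d = p,
    tilt = x$tilt,
    vesicle_radius = x$vesicle_radius,
    membrane_thickness = x$membrane_thickness,
    pore_half_angle = x$pore_half_angle,
    orientation = orientation(x$tilt, x$azimuth %||% 0),
    pore_diameter = x$pore_diameter,
    rim_semiaxes = as.numeric(unlist(x$rim_semiaxes)),
    offset = as.numeric(unlist(x$frame$offset %||% c(0, 0)))
  ), class = "goldrim_truth")
}

#' Write a pore annotation as JSON
#'
#' Schema: `{"edge": [[x,y],...], "outer": [...], "inner": [...],
#' "regions": [{"label": "pore"|"non_pore", "vertices": [...]}]}`, all
#' coordinates nm in the image frame.
#'
#' @param ann a [pore_annotation()].
#' @param path output JSON file.
#' @param regions optional list of [roi_polygon()]s to embed.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, regions = list()) {
  stopifnot(inherits(ann, "goldrim_annotation"))
  obj <- list(
    units = "nm",
    orientation_class = ann$orientation_class,
    edge = vertices_to_list(ann$edge),
    outer = vertices_to_list(ann$outer),
    inner = vertices_to_list(ann$inner),
    regions = lapply(regions, function(r)
      list(label = r$label, vertices = vertices_to_list(r)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pore annotation JSON
#'
#' @param path JSON in the schema of [write_annotation()].
#' @return list with `annotation` (a [pore_annotation()]) and `regions`
#'   (named-by-label list of [roi_polygon()]s, possibly empty).
#' @export
read_annotation <- function(path) {
  x <- jsonlite::read_json(path)
  ann <- pore_annotation(
    edge = polyline(list_to_matrix(x$edge), closed = TRUE),
    outer = polyline(list_to_matrix(x$outer), closed = TRUE),
    inner = polyline(list_to_matrix(x$inner), closed = TRUE),
    orientation_class = x$orientation_class %||% NULL)
  regions <- lapply(x$regions %||% list(), function(r)
    roi_polygon(list_to_matrix(r$vertices), label = r$label))
  names(regions) <- vapply(regions, function(r) r$label, character(1))
  list(annotation = ann, regions = regions)
}

#' Build a pore annotation from ground truth
#'
#' The traced edge is the projected rim; the outer and inner flanking
#' boundaries are the projections of the sphere circles half a band width
#' away from the rim on either side (default band 5 nm); the pore region is
#' the outer boundary polygon and the non-pore region the projected vesicle
#' outline.
#'
#' @param truth a [project_scene()] result (centered lab frame).
#' @param rim_band full width (nm) of the rim band between the flanking
#'   boundaries.
#' @param offset nm shift into the image frame (the image `offset`).
#' @param en_face_cutoff circularity cutoff for the en-face class.
#' @return list with `annotation` and `regions` as in [read_annotation()].
#' @export
annotation_from_truth <- function(truth, rim_band = 5, offset = c(0, 0),
                                  en_face_cutoff = 0.9) {
  stopifnot(inherits(truth, "goldrim_truth"))
  # truths read back from disk already carry the frame shift they were
  # written with; freshly projected truths are centered
  stored <- truth$offset %||% c(0, 0)
  total <- stored + offset
  flank <- flanking_polylines(truth, band = rim_band,
                              n_vertices = nrow(truth$projected_rim$vertices))
  shift <- function(p, by) polyline(sweep(p$vertices, 2L, -by),
                                    closed = TRUE)
  edge <- shift(truth$projected_rim, offset)
  outer <- shift(flank$outer, total)
  inner <- shift(flank$inner, total)
  ann <- pore_annotation(edge, outer, inner,
                         en_face_cutoff = en_face_cutoff)
  outline <- circle_polyline(total, truth$vesicle_radius,
                             n = nrow(truth$projected_rim$vertices))
  regions <- list(
    pore = roi_polygon(outer, label = "pore"),
    non_pore = roi_polygon(outline, label = "non_pore"))
  list(annotation = ann, regions = regions)
}
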