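#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Path length (nm) of the viewing ray through the membrane shell, per pixel.
// The shell is the spherical layer Ri <= |q| <= R with the pore cap removed
// (vesicle-frame polar angle < alpha about the pore axis, given here as a
// unit vector in lab coordinates).  Midpoint quadrature along z with step
// `zstep`; the ray at projected radius r only meets the sphere for
// |z| <= sqrt(R^2 - r^2), so integration is restricted to that chord.
// Pixel (row i, col j), 0-based, has lab coordinates
// x = (j + 0.5) * px - ox, y = (i + 0.5) * px - oy.
// [[Rcpp::export]]
NumericMatrix shell_path_length_cpp(int nrow, int ncol, double px,
                                    double ox, double oy,
                                    double R, double Ri, double alpha,
                                    double ax, double ay, double az,
                                    double zstep) {
  NumericMatrix L(nrow, ncol);
  const double R2 = R * R, Ri2 = Ri * Ri;
  const double cosal = std::cos(alpha);
  for (int i = 0; i < nrow; ++i) {
    const double y = (i + 0.5) * px - oy;
    for (int j = 0; j < ncol; ++j) {
      const double x = (j + 0.5) * px - ox;
      const double rr = x * x + y * y;
      if (rr >= R2) continue;
      const double zmax = std::sqrt(R2 - rr);
      const int K = (int)std::ceil(2.0 * zmax / zstep);
      if (K <= 0) continue;
      const double h = 2.0 * zmax / K;
      const double dxy = ax * x + ay * y;
      double len = 0.0;
      for (int k = 0; k < K; ++k) {
        const double z = -zmax + (k + 0.5) * h;
        const double q2 = rr + z * z;
        if (q2 < Ri2) continue;               // lumen
        const double dot = dxy + az * z;      // q . axis
        if (dot > cosal * std::sqrt(q2)) continue;  // inside pore cap
        len += h;
      }
      L(i, j) = len;
    }
  }
  return L;
}

// Connected-component labeling of a logical mask (4- or 8-connectivity),
// iterative flood fill.  Returns 0 for background, 1..n for components.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int d4r[] = {-1, 1, 0, 0}, d4c[] = {0, 0, -1, 1};
  const int d8r[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int d8c[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 4) ? d4r : d8r;
  const int *dc = (connectivity == 4) ? d4c : d8c;
  const int nd = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int d = 0; d < nd; ++d) {
          const int qi = pi + dr[d], qj = pj + dc[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (!mask(qi, qj) || lab(qi, qj) != 0) continue;
          lab(qi, qj) = next;
          stack.push_back(qi + qj * nr);
        }
      }
    }
  }
  return lab;
}
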