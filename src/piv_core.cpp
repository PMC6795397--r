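#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One-dimensional three-point subpixel peak offset.
// method: 1 = gaussian3 (falls back to parabolic when a log is undefined),
//         2 = parabolic, 0 = none.
static double peak_offset(double cm, double c0, double cp, int method) {
  if (method == 0) return 0.0;
  if (method == 1 && cm > 0.0 && c0 > 0.0 && cp > 0.0) {
    double lm = std::log(cm), l0 = std::log(c0), lp = std::log(cp);
    double den = lm - 2.0 * l0 + lp;
    if (den < -1e-12) {
      double d = 0.5 * (lm - lp) / den;
      if (std::fabs(d) <= 1.0) return d;
    }
    // fall through to parabolic when the gaussian fit is degenerate
  }
  double den = cm - 2.0 * c0 + cp;
  if (den < -1e-12) {
    double d = 0.5 * (cm - cp) / den;
    if (std::fabs(d) <= 1.0) return d;
  }
  return 0.0;
}

// Windowed normalized cross-correlation displacement search.
//
// For every interrogation window of `ref` (size `window`, spacing
// window - overlap), searches integer shifts within +/- `margin` px in `img`
// for the maximum zero-mean normalized cross-correlation, then refines to
// subpixel precision. Windows whose search region leaves the image, or whose
// reference content is flat (zero variance), are marked invalid.
//
// Returns grid centers (1-based pixel coordinates), displacement components
// u (x, rightward/columns) and v (y, downward/rows), the peak correlation and
// a validity mask. Matrices are indexed [row = y grid, col = x grid].
// [[Rcpp::export]]
List ncc_grid_cpp(const NumericMatrix& ref, const NumericMatrix& img,
                  int window, int overlap, int margin, int subpixel) {
  const int nr = ref.nrow(), nc = ref.ncol();
  if (img.nrow() != nr || img.ncol() != nc)
    stop("reference and frame must have identical dimensions");
  if (window < 8) stop("window_size must be at least 8");
  if (overlap < 0 || overlap >= window) stop("need 0 <= overlap < window_size");
  if (margin < 1) stop("search_margin must be positive");
  if (nr < window || nc < window) stop("image smaller than one window");

  const int step = window - overlap;
  std::vector<int> r0s, c0s;
  for (int r0 = 0; r0 + window <= nr; r0 += step) r0s.push_back(r0);
  for (int c0 = 0; c0 + window <= nc; c0 += step) c0s.push_back(c0);
  const int ny = (int)r0s.size(), nx = (int)c0s.size();

  // integral images of img and img^2 for O(1) patch mean / variance
  NumericMatrix S(nr + 1, nc + 1), S2(nr + 1, nc + 1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      S(i + 1, j + 1)  = v     + S(i, j + 1)  + S(i + 1, j)  - S(i, j);
      S2(i + 1, j + 1) = v * v + S2(i, j + 1) + S2(i + 1, j) - S2(i, j);
    }
  }

  const int N = window * window;
  const int side = 2 * margin + 1;
  std::vector<double> cmap((size_t)side * side);
  std::vector<double> refw((size_t)N);

  NumericMatrix u(ny, nx), v(ny, nx), cmax(ny, nx);
  LogicalMatrix valid(ny, nx);
  NumericVector grid_x(nx), grid_y(ny);
  for (int ix = 0; ix < nx; ++ix) grid_x[ix] = c0s[ix] + 1 + (window - 1) / 2.0;
  for (int iy = 0; iy < ny; ++iy) grid_y[iy] = r0s[iy] + 1 + (window - 1) / 2.0;

  for (int iy = 0; iy < ny; ++iy) {
    const int r0 = r0s[iy];
    for (int ix = 0; ix < nx; ++ix) {
      const int c0 = c0s[ix];
      u(iy, ix) = NA_REAL; v(iy, ix) = NA_REAL; cmax(iy, ix) = NA_REAL;
      valid(iy, ix) = false;

      if (r0 - margin < 0 || c0 - margin < 0 ||
          r0 + window + margin > nr || c0 + window + margin > nc)
        continue;  // no full search margin: border window stays invalid

      // reference window statistics and zero-mean copy
      double sum = 0.0, sum2 = 0.0;
      for (int j = 0; j < window; ++j)
        for (int i = 0; i < window; ++i) {
          double x = ref(r0 + i, c0 + j);
          sum += x; sum2 += x * x;
        }
      double mr = sum / N;
      double var_r = sum2 / N - mr * mr;
      if (var_r <= 1e-12) continue;  // flat window: invalid, not an error
      double sd_r = std::sqrt(var_r);
      {
        int k = 0;
        for (int j = 0; j < window; ++j)
          for (int i = 0; i < window; ++i)
            refw[k++] = ref(r0 + i, c0 + j) - mr;
      }

      double best = -2.0;
      int bdy = 0, bdx = 0;
      for (int dy = -margin; dy <= margin; ++dy) {
        for (int dx = -margin; dx <= margin; ++dx) {
          const int pr = r0 + dy, pc = c0 + dx;
          double sp  = S(pr + window, pc + window) - S(pr, pc + window)
                     - S(pr + window, pc) + S(pr, pc);
          double sp2 = S2(pr + window, pc + window) - S2(pr, pc + window)
                     - S2(pr + window, pc) + S2(pr, pc);
          double mp = sp / N;
          double var_p = sp2 / N - mp * mp;
          double c;
          if (var_p <= 1e-12) {
            c = 0.0;
          } else {
            double dot = 0.0;
            int k = 0;
            for (int j = 0; j < window; ++j)
              for (int i = 0; i < window; ++i)
                dot += refw[k++] * img(pr + i, pc + j);
            // refw is zero-mean, so subtracting mp from the patch is a no-op
            c = dot / (N * sd_r * std::sqrt(var_p));
          }
          cmap[(size_t)(dy + margin) * side + (dx + margin)] = c;
          if (c > best) { best = c; bdy = dy; bdx = dx; }
        }
      }

      double du = bdx, dv = bdy;
      bool on_border = (std::abs(bdx) == margin || std::abs(bdy) == margin);
      // a peak of exactly 1 is a bit-identical match: keep the integer shift
      if (subpixel != 0 && !on_border && best < 1.0 - 1e-9) {
        size_t c0i = (size_t)(bdy + margin) * side + (bdx + margin);
        du += peak_offset(cmap[c0i - 1], best, cmap[c0i + 1], subpixel);
        dv += peak_offset(cmap[c0i - side], best, cmap[c0i + side], subpixel);
      }

      u(iy, ix) = du; v(iy, ix) = dv; cmax(iy, ix) = best;
      valid(iy, ix) = true;
    }
  }

  return List::create(_["grid_x"] = grid_x, _["grid_y"] = grid_y,
                      _["u"] = u, _["v"] = v,
                      _["cmax"] = cmax, _["valid"] = valid);
}
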