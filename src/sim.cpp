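#include <Rcpp.h>
using namespace Rcpp;

static const double TWOPI = 2.0 * M_PI;

static inline double wrap_angle(double th) {
  th -= TWOPI * std::floor(th / TWOPI);
  if (th >= TWOPI) th = 0.0;  // guard round-off at the seam
  return th;
}

// Confined correlated random walk for n squares.
//
// Headings evolve by wrapped-normal increments (SD sigma); each frame every
// square moves `step` px along its heading.  The square's centre is confined
// to [xmin,xmax] x [ymin,ymax]: an exiting step has its increment redrawn up
// to max_redraw times, after which the heading is reflected about the
// violated wall(s), which always resolves for step < arena side.
//
// Returns frame-by-square matrices of x, y and heading; row 1 is the initial
// state (uniform positions, uniform headings), so n_frames rows contain
// n_frames - 1 movement steps.  Uses R's RNG: deterministic under set.seed().
// [[Rcpp::export]]
List sim_motion_cpp(int n, int n_frames, double step, double sigma,
                    double xmin, double xmax, double ymin, double ymax,
                    int max_redraw) {
  NumericMatrix x(n_frames, n), y(n_frames, n), th(n_frames, n);
  for (int j = 0; j < n; ++j) {
    x(0, j) = R::runif(xmin, xmax);
    y(0, j) = R::runif(ymin, ymax);
    th(0, j) = R::runif(0.0, TWOPI);
  }
  for (int f = 1; f < n_frames; ++f) {
    for (int j = 0; j < n; ++j) {
      double th0 = th(f - 1, j), x0 = x(f - 1, j), y0 = y(f - 1, j);
      double th1 = 0, x1 = 0, y1 = 0;
      bool ok = false;
      for (int a = 0; a <= max_redraw; ++a) {
        th1 = wrap_angle(th0 + R::norm_rand() * sigma);
        x1 = x0 + step * std::cos(th1);
        y1 = y0 + step * std::sin(th1);
        if (x1 >= xmin && x1 <= xmax && y1 >= ymin && y1 <= ymax) {
          ok = true;
          break;
        }
      }
      if (!ok) {
        // reflect the last proposal about each violated wall
        if (x1 < xmin || x1 > xmax) th1 = wrap_angle(M_PI - th1);
        if (y1 < ymin || y1 > ymax) th1 = wrap_angle(-th1);
        x1 = x0 + step * std::cos(th1);
        y1 = y0 + step * std::sin(th1);
        // guard against corner round-off
        if (x1 < xmin) x1 = xmin; else if (x1 > xmax) x1 = xmax;
        if (y1 < ymin) y1 = ymin; else if (y1 > ymax) y1 = ymax;
      }
      th(f, j) = th1;
      x(f, j) = x1;
      y(f, j) = y1;
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["heading"] = th);
}

// Synthetic observer: cursor follows a "believed" target with perceptual lag
// and isotropic motor noise; each tracking frame the belief may switch to the
// nearest distractor with probability
//   swap_base * sim_mult * (#distractors within swap_radius of the believed
//   square), clamped to 1.
// x, y: frame-by-square position matrices; target is 1-based; start_frame is
// the first tracking frame (1-based; end of the highlight period).  The
// cursor starts exactly on the true target.  Returns the cursor path (one row
// per tracking frame) and the believed-square index per frame.
// [[Rcpp::export]]
List sim_cursor_cpp(NumericMatrix x, NumericMatrix y, int target,
                    int start_frame, double motor_sd, int lag_frames,
                    double swap_base, double swap_radius, double sim_mult) {
  int n_frames = x.nrow(), n = x.ncol();
  int nt = n_frames - start_frame + 1;
  if (nt < 1) stop("start_frame beyond trajectory length");
  NumericMatrix cursor(nt, 2);
  IntegerVector believed(nt);
  int bel = target - 1;
  double r2 = swap_radius * swap_radius;
  cursor(0, 0) = x(start_frame - 1, bel);
  cursor(0, 1) = y(start_frame - 1, bel);
  believed[0] = bel + 1;
  for (int k = 1; k < nt; ++k) {
    int f = start_frame - 1 + k;  // 0-based frame
    if (n > 1 && swap_base > 0) {
      double bx = x(f, bel), by = y(f, bel);
      int cnt = 0;
      int nearest = -1;
      double best = R_PosInf;
      for (int j = 0; j < n; ++j) {
        if (j == bel) continue;
        double dx = x(f, j) - bx, dy = y(f, j) - by;
        double d2 = dx * dx + dy * dy;
        if (d2 <= r2) ++cnt;
        if (d2 < best) { best = d2; nearest = j; }
      }
      if (cnt > 0) {
        double p = swap_base * sim_mult * cnt;
        if (p > 1.0) p = 1.0;
        if (R::unif_rand() < p) bel = nearest;
      }
    }
    int src = f - lag_frames;
    if (src < 0) src = 0;
    cursor(k, 0) = x(src, bel) + R::norm_rand() * motor_sd;
    cursor(k, 1) = y(src, bel) + R::norm_rand() * motor_sd;
    believed[k] = bel + 1;
  }
  return List::create(_["cursor"] = cursor, _["believed"] = believed);
}
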