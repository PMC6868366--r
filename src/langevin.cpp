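#include <Rcpp.h>
using namespace Rcpp;

// Two-channel double-well surface:
//   V(x,y) = a (x^2 - 1)^2 + b y^4 + G exp(-(x^2+y^2)/(2 sigma^2)) - tilt * x
// Minima near (+-1, 0); the central Gaussian blocks the direct (y ~ 0)
// route so that detours through |y| > 0 carry most of the reactive flux.

static inline double pot(double x, double y, double a, double b, double G,
                         double sigma, double tilt) {
  double q = x * x - 1.0;
  return a * q * q + b * y * y * y * y +
         G * std::exp(-(x * x + y * y) / (2.0 * sigma * sigma)) - tilt * x;
}

static inline void grad(double x, double y, double a, double b, double G,
                        double sigma, double tilt, double *gx, double *gy) {
  double s2 = sigma * sigma;
  double e = G * std::exp(-(x * x + y * y) / (2.0 * s2)) / s2;
  *gx = 4.0 * a * x * (x * x - 1.0) - x * e - tilt;
  *gy = 4.0 * b * y * y * y - y * e;
}

// [[Rcpp::export]]
NumericVector cpp_potential(NumericVector x, NumericVector y, double a,
                            double b, double G, double sigma, double tilt) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = pot(x[i], y[i], a, b, G, sigma, tilt);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_force(NumericVector x, NumericVector y, double a, double b,
                        double G, double sigma, double tilt) {
  R_xlen_t n = x.size();
  NumericMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gx, gy;
    grad(x[i], y[i], a, b, G, sigma, tilt, &gx, &gy);
    out(i, 0) = -gx;
    out(i, 1) = -gy;
  }
  return out;
}

static inline int in_box(double x, double y, const NumericMatrix &stops) {
  // stops rows: xmin xmax ymin ymax; returns 1-based index or 0
  for (int k = 0; k < stops.nrow(); ++k) {
    if (x > stops(k, 0) && x < stops(k, 1) && y > stops(k, 2) &&
        y < stops(k, 3))
      return k + 1;
  }
  return 0;
}

// BAOAB splitting: half kick, half drift, exact Ornstein-Uhlenbeck velocity
// refresh, half drift, half kick. Exact Boltzmann sampling of the velocity
// marginal at any dt; reduces to velocity Verlet when gamma = kBT = 0.
// Frames are recorded (and stop-state membership checked) every
// save_interval integration steps; the initial state is frame 1 and is
// checked before any step is taken.
//
// Returns list(frames = matrix[t x y vx vy], stop = 0 (max_steps) or the
// 1-based stop-box index, steps = integration steps actually taken).
// Uses R's RNG (norm_rand), so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_propagate(NumericVector state0, double t0, double a, double b,
                   double G, double sigma, double tilt, double kBT,
                   double gamma, double dt, double mass, int max_steps,
                   int save_interval, NumericMatrix stops) {
  if (state0.size() != 4) stop("state0 must be (x, y, vx, vy)");
  double x = state0[0], y = state0[1], vx = state0[2], vy = state0[3];
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * kBT / mass);
  int max_frames = max_steps / save_interval + 2;
  NumericMatrix frames(max_frames, 5);
  int nf = 0, steps = 0, stop_idx = 0;

  frames(nf, 0) = t0; frames(nf, 1) = x; frames(nf, 2) = y;
  frames(nf, 3) = vx; frames(nf, 4) = vy; ++nf;
  stop_idx = in_box(x, y, stops);

  double fx, fy;
  grad(x, y, a, b, G, sigma, tilt, &fx, &fy);
  fx = -fx; fy = -fy;

  while (stop_idx == 0 && steps < max_steps) {
    for (int s = 0; s < save_interval && steps < max_steps; ++s) {
      vx += 0.5 * dt * fx / mass;
      vy += 0.5 * dt * fy / mass;
      x += 0.5 * dt * vx;
      y += 0.5 * dt * vy;
      vx = c1 * vx + c2 * norm_rand();
      vy = c1 * vy + c2 * norm_rand();
      x += 0.5 * dt * vx;
      y += 0.5 * dt * vy;
      grad(x, y, a, b, G, sigma, tilt, &fx, &fy);
      fx = -fx; fy = -fy;
      vx += 0.5 * dt * fx / mass;
      vy += 0.5 * dt * fy / mass;
      ++steps;
    }
    if (!R_finite(x) || !R_finite(y) || !R_finite(vx) || !R_finite(vy))
      stop("Langevin integration diverged to a non-finite state");
    frames(nf, 0) = t0 + steps * dt;
    frames(nf, 1) = x; frames(nf, 2) = y;
    frames(nf, 3) = vx; frames(nf, 4) = vy; ++nf;
    stop_idx = in_box(x, y, stops);
  }

  return List::create(_["frames"] = frames(Range(0, nf - 1), Range(0, 4)),
                      _["stop"] = stop_idx, _["steps"] = steps);
}
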