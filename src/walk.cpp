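#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time Ornstein-Uhlenbeck velocity walk with reflecting walls and an
// optional constant-magnitude pull toward a target point (softened within
// `soft_radius` so the walker does not oscillate across the target).
// Noise is pre-drawn in R (one N(0,1) pair per frame) so that all randomness
// flows through R's RNG and seeding stays reproducible.
//
// [[Rcpp::export]]
List ou_walk_cpp(NumericVector start, NumericVector v0,
                 double rho, double sigma,
                 double attr, NumericVector target, double soft_radius,
                 NumericVector lower, NumericVector upper,
                 NumericMatrix noise) {
  const int n = noise.nrow();
  NumericMatrix pos(n, 2);
  double px = start[0], py = start[1];
  double vx = v0[0], vy = v0[1];

  for (int i = 0; i < n; ++i) {
    double ax = 0.0, ay = 0.0;
    if (attr != 0.0) {
      double dx = target[0] - px, dy = target[1] - py;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > 1e-12) {
        double gain = attr * std::min(1.0, d / soft_radius) / d;
        ax = gain * dx;
        ay = gain * dy;
      }
    }
    vx = rho * vx + ax + sigma * noise(i, 0);
    vy = rho * vy + ay + sigma * noise(i, 1);
    px += vx;
    py += vy;

    // reflect into the chamber; a few passes cover pathological jumps
    for (int k = 0; k < 8; ++k) {
      bool moved = false;
      if (px < lower[0]) { px = 2.0 * lower[0] - px; vx = -vx; moved = true; }
      if (px > upper[0]) { px = 2.0 * upper[0] - px; vx = -vx; moved = true; }
      if (py < lower[1]) { py = 2.0 * lower[1] - py; vy = -vy; moved = true; }
      if (py > upper[1]) { py = 2.0 * upper[1] - py; vy = -vy; moved = true; }
      if (!moved) break;
    }
    if (px < lower[0]) px = lower[0]; else if (px > upper[0]) px = upper[0];
    if (py < lower[1]) py = lower[1]; else if (py > upper[1]) py = upper[1];

    pos(i, 0) = px;
    pos(i, 1) = py;
  }
  return List::create(_["pos"] = pos,
                      _["v_end"] = NumericVector::create(vx, vy));
}
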