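#include <Rcpp.h>
using namespace Rcpp;

// Geodesic random walk of a unit vector, reflected at polar angle `theta_c`
// (radians) measured from the +z axis.  Each step displaces the vector along
// a tangential Gaussian with per-axis standard deviation `step_sd` (radians),
// which corresponds to diffusion with D = step_sd^2 / (2 * dt).  Uses R's RNG,
// so results are reproducible under set.seed().
//
// v0 must be a unit vector inside the cone; n rows are returned including the
// initial state.
// [[Rcpp::export(name = ".cone_walk")]]
NumericMatrix cone_walk(int n, double theta_c, double step_sd, NumericVector v0) {
  NumericMatrix out(n, 3);
  double vx = v0[0], vy = v0[1], vz = v0[2];
  for (int i = 0; i < n; i++) {
    if (i > 0) {
      // orthonormal tangent basis at v
      double ax, ay, az;
      if (std::fabs(vz) < 0.9) { ax = 0; ay = 0; az = 1; }
      else                     { ax = 1; ay = 0; az = 0; }
      double t1x = ay * vz - az * vy, t1y = az * vx - ax * vz, t1z = ax * vy - ay * vx;
      double n1 = std::sqrt(t1x * t1x + t1y * t1y + t1z * t1z);
      t1x /= n1; t1y /= n1; t1z /= n1;
      double t2x = vy * t1z - vz * t1y, t2y = vz * t1x - vx * t1z, t2z = vx * t1y - vy * t1x;

      double g1 = R::norm_rand() * step_sd, g2 = R::norm_rand() * step_sd;
      double psi = std::sqrt(g1 * g1 + g2 * g2);
      if (psi > 1e-14) {
        // exponential map: move along the geodesic by angle psi
        double c = std::cos(psi), k = std::sin(psi) / psi;
        double nx = vx * c + (t1x * g1 + t2x * g2) * k;
        double ny = vy * c + (t1y * g1 + t2y * g2) * k;
        double nz = vz * c + (t1z * g1 + t2z * g2) * k;
        double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
        vx = nx / nn; vy = ny / nn; vz = nz / nn;
      }
      double cz = vz; if (cz > 1.0) cz = 1.0; if (cz < -1.0) cz = -1.0;
      double th = std::acos(cz);
      if (th > theta_c) {
        // reflect the polar angle back into [0, theta_c]; repeated reflection
        // handles rare steps beyond 2*theta_c
        double thr = th;
        while (thr > theta_c || thr < 0.0) {
          if (thr > theta_c) thr = 2.0 * theta_c - thr;
          if (thr < 0.0) thr = -thr;
        }
        double sth = std::sin(th);
        if (sth > 1e-12) {
          double px = vx / sth, py = vy / sth;   // unit azimuthal direction
          vx = px * std::sin(thr); vy = py * std::sin(thr); vz = std::cos(thr);
        } else { vx = 0; vy = 0; vz = 1; }
      }
    }
    out(i, 0) = vx; out(i, 1) = vy; out(i, 2) = vz;
  }
  return out;
}
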