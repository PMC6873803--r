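#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Periodic wrap into [0, L)
static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0;  // guard against floating-point edge
  return x;
}

// Minimum-image signed separation on a periodic axis of length L
static inline double mindiff(double dx, double L) {
  dx -= L * std::round(dx / L);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_sim_free(NumericMatrix start, int n_steps, double sigma,
                           double L) {
  const int P = start.nrow();
  NumericVector out(Dimension(n_steps + 1, P, 2));
  std::vector<double> x(P), y(P);
  for (int i = 0; i < P; ++i) {
    x[i] = start(i, 0);
    y[i] = start(i, 1);
    out[i * (n_steps + 1)] = x[i];
    out[(P + i) * (n_steps + 1)] = y[i];
  }
  for (int t = 1; t <= n_steps; ++t) {
    for (int i = 0; i < P; ++i) {
      x[i] = wrap(x[i] + sigma * norm_rand(), L);
      y[i] = wrap(y[i] + sigma * norm_rand(), L);
      out[i * (n_steps + 1) + t] = x[i];
      out[(P + i) * (n_steps + 1) + t] = y[i];
    }
  }
  return out;
}

// Which domain (if any) contains point (x, y)? Cell-list accelerated;
// centers use minimum-image metric so domains wrap with the box.
static inline int domain_at(double x, double y, double L, double radius,
                            const NumericMatrix &centers,
                            const IntegerVector &cell_off,
                            const IntegerVector &cell_ids, int ncell) {
  double cs = L / ncell;
  int cx = (int)std::floor(x / cs);
  int cy = (int)std::floor(y / cs);
  if (cx < 0) cx = 0; if (cx >= ncell) cx = ncell - 1;
  if (cy < 0) cy = 0; if (cy >= ncell) cy = ncell - 1;
  int cell = cy * ncell + cx;
  double r2 = radius * radius;
  for (int k = cell_off[cell]; k < cell_off[cell + 1]; ++k) {
    int j = cell_ids[k];
    double dx = mindiff(x - centers(j, 0), L);
    double dy = mindiff(y - centers(j, 1), L);
    if (dx * dx + dy * dy <= r2) return j;
  }
  return -1;
}

// [[Rcpp::export]]
NumericVector cpp_sim_domain(NumericMatrix start, int n_steps,
                             double sigma_out, double sigma_in, double L,
                             NumericMatrix centers, double radius,
                             double p_enter, double p_exit,
                             IntegerVector cell_off, IntegerVector cell_ids,
                             int ncell) {
  const int P = start.nrow();
  NumericVector out(Dimension(n_steps + 1, P, 2));
  std::vector<double> x(P), y(P);
  std::vector<int> cur(P);
  for (int i = 0; i < P; ++i) {
    x[i] = start(i, 0);
    y[i] = start(i, 1);
    cur[i] = domain_at(x[i], y[i], L, radius, centers, cell_off, cell_ids,
                       ncell);
    out[i * (n_steps + 1)] = x[i];
    out[(P + i) * (n_steps + 1)] = y[i];
  }
  for (int t = 1; t <= n_steps; ++t) {
    for (int i = 0; i < P; ++i) {
      double sigma = (cur[i] >= 0) ? sigma_in : sigma_out;
      double qx = x[i] + sigma * norm_rand();
      double qy = y[i] + sigma * norm_rand();
      double qxw = wrap(qx, L), qyw = wrap(qy, L);
      int tgt = domain_at(qxw, qyw, L, radius, centers, cell_off, cell_ids,
                          ncell);
      bool accept;
      if (tgt == cur[i]) {
        accept = true;
      } else if (cur[i] < 0) {           // outside -> entering tgt
        accept = unif_rand() < p_enter;
      } else if (tgt < 0) {              // inside -> leaving cur
        accept = unif_rand() < p_exit;
      } else {                           // crossing directly between domains
        accept = unif_rand() < p_exit * p_enter;
      }
      if (accept) {
        x[i] = qxw; y[i] = qyw; cur[i] = tgt;
      } else {
        // reflect radially across the boundary of the circle involved
        int j = (cur[i] >= 0) ? cur[i] : tgt;
        double dx = mindiff(qxw - centers(j, 0), L);
        double dy = mindiff(qyw - centers(j, 1), L);
        double d = std::sqrt(dx * dx + dy * dy);
        double dref = 2.0 * radius - d;  // fold back across the circle
        if (d > 1e-12 && dref > 0) {
          double nx = wrap(centers(j, 0) + dx * (dref / d), L);
          double ny = wrap(centers(j, 1) + dy * (dref / d), L);
          int nd = domain_at(nx, ny, L, radius, centers, cell_off, cell_ids,
                             ncell);
          // reflection must keep the particle on its original side
          bool ok = (cur[i] >= 0) ? (nd == cur[i]) : (nd < 0);
          if (ok) { x[i] = nx; y[i] = ny; cur[i] = nd; }
          // else: degenerate geometry, stay put
        }
      }
      out[i * (n_steps + 1) + t] = x[i];
      out[(P + i) * (n_steps + 1) + t] = y[i];
    }
  }
  return out;
}

// Reflect one axis across mesh boundaries crossed with prob. 1 - p_hop
static inline double hop_axis(double x0, double x1, double mesh,
                              double p_hop) {
  long c0 = (long)std::floor(x0 / mesh);
  long c1 = (long)std::floor(x1 / mesh);
  if (c1 == c0) return x1;
  if (unif_rand() < p_hop) return x1;  // hop permitted
  double b = (c1 > c0) ? (c0 + 1) * mesh : c0 * mesh;
  double xr = 2.0 * b - x1;
  // if the step was so large the mirror leaves the compartment, stay put
  if ((long)std::floor(xr / mesh) != c0) return x0;
  return xr;
}

// [[Rcpp::export]]
NumericVector cpp_sim_hop(NumericMatrix start, int n_steps, double sigma,
                          double L, double mesh, double p_hop) {
  const int P = start.nrow();
  NumericVector out(Dimension(n_steps + 1, P, 2));
  std::vector<double> x(P), y(P);
  for (int i = 0; i < P; ++i) {
    x[i] = start(i, 0);
    y[i] = start(i, 1);
    out[i * (n_steps + 1)] = x[i];
    out[(P + i) * (n_steps + 1)] = y[i];
  }
  for (int t = 1; t <= n_steps; ++t) {
    for (int i = 0; i < P; ++i) {
      double qx = hop_axis(x[i], x[i] + sigma * norm_rand(), mesh, p_hop);
      double qy = hop_axis(y[i], y[i] + sigma * norm_rand(), mesh, p_hop);
      x[i] = wrap(qx, L);
      y[i] = wrap(qy, L);
      out[i * (n_steps + 1) + t] = x[i];
      out[(P + i) * (n_steps + 1) + t] = y[i];
    }
  }
  return out;
}

// Expected photon counts per pixel per frame from particle positions.
// pos: array (T, P, 2) of sample positions, T = n_frames * n_substeps;
// each frame averages its n_substeps deposits. Pixel (r, c) covers
// x in [x0 + c*a, x0 + (c+1)*a), y in [y0 + r*a, ...). PSF is a normalized
// 2D Gaussian with 1/e^2 radius omega0 (sd = omega0/2), truncated at
// 4*omega0 from the emitter (mass loss < 1e-12).
// [[Rcpp::export]]
NumericVector cpp_expected_counts(NumericVector pos, int n_frames,
                                  int n_substeps, int H, int W, double x0,
                                  double y0, double a, double omega0,
                                  double cpm) {
  IntegerVector dim = pos.attr("dim");
  const int T = dim[0], P = dim[1];
  if (T < n_frames * n_substeps)
    stop("not enough trajectory samples for the requested frames");
  NumericVector out(Dimension(n_frames, H, W));
  const double inv = 1.0 / (omega0 / std::sqrt(2.0));  // erf argument scale
  const double reach = 4.0 * omega0;
  const double w_per = cpm / n_substeps;
  std::vector<double> ex(W + 2), ey(H + 2);
  for (int f = 0; f < n_frames; ++f) {
    for (int s = 0; s < n_substeps; ++s) {
      int t = f * n_substeps + s;
      for (int i = 0; i < P; ++i) {
        double px = pos[i * T + t];
        double py = pos[(P + i) * T + t];
        int c_lo = (int)std::floor((px - reach - x0) / a);
        int c_hi = (int)std::floor((px + reach - x0) / a);
        int r_lo = (int)std::floor((py - reach - y0) / a);
        int r_hi = (int)std::floor((py + reach - y0) / a);
        if (c_lo < 0) c_lo = 0; if (c_hi > W - 1) c_hi = W - 1;
        if (r_lo < 0) r_lo = 0; if (r_hi > H - 1) r_hi = H - 1;
        if (c_lo > c_hi || r_lo > r_hi) continue;
        for (int c = c_lo; c <= c_hi + 1; ++c)
          ex[c - c_lo] = std::erf((x0 + c * a - px) * inv);
        for (int r = r_lo; r <= r_hi + 1; ++r)
          ey[r - r_lo] = std::erf((y0 + r * a - py) * inv);
        for (int c = c_lo; c <= c_hi; ++c) {
          double fx = 0.5 * (ex[c - c_lo + 1] - ex[c - c_lo]);
          for (int r = r_lo; r <= r_hi; ++r) {
            double fy = 0.5 * (ey[r - r_lo + 1] - ey[r - r_lo]);
            out[(size_t)c * n_frames * H + (size_t)r * n_frames + f] +=
                w_per * fx * fy;
          }
        }
      }
    }
  }
  return out;
}
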