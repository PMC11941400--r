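#include <Rcpp.h>
using namespace Rcpp;

// Nonlinear term base: plain power for integer exponents, |phi|^z otherwise
// (keeps the term real-valued for phi < 0).
static inline double nl_pow(double phi, double z) {
  if (z == std::floor(z)) return std::pow(phi, z);
  return std::pow(std::fabs(phi), z);
}

// One step of the critical (type-I) intermittency map:
//   phi_{n+1} = phi_n + u * phi_n^z + eps_n
static inline double step1(double phi, double u, double z, double eps) {
  return phi + u * nl_pow(phi, z) + eps;
}

// One step of the tricritical intermittency map (phi > 0 required):
//   phi_{n+1} = phi_n - u * phi_n^{-z} + eps_n
static inline double step2(double phi, double u, double z, double eps) {
  return phi - u * nl_pow(phi, -z) + eps;
}

// [[Rcpp::export]]
double step_map1_cpp(double phi, double u, double z, double eps) {
  if (!R_finite(phi)) stop("'phi' must be finite");
  return step1(phi, u, z, eps);
}

// [[Rcpp::export]]
double step_map2_cpp(double phi, double u, double z, double eps) {
  if (!R_finite(phi)) stop("'phi' must be finite");
  if (phi <= 0.0)
    stop("tricritical map evaluated at non-positive state (phi = %g)", phi);
  return step2(phi, u, z, eps);
}

// Coupled spike-train mechanism: iterate map1 in its laminar region; when a
// computed value exceeds th1 it is suppressed (never emitted) and the state
// jumps to the map2 entry value, which is emitted; map2 then falls until a
// computed value drops below th2, which is again suppressed, and map1 resumes
// at its entry value.  Labels: 1 = MAP1, 2 = MAP2, 3 = ENTRY1, 4 = ENTRY2.
// Noise draws come from R's RNG in emission order, so set.seed() in R fixes
// the whole experiment.
// [[Rcpp::export]]
List simulate_coupled_cpp(int n,
                          double u1, double z1, double eps1,
                          double u2, double z2, double eps2,
                          double th1, double th2,
                          double phi_k, double phi_m, double phi_init,
                          bool entry_random,
                          double m1_lo, double m1_hi,
                          double m2_lo, double m2_hi) {
  if (n < 1) stop("'n_samples' must be >= 1");
  NumericVector samples(n);
  IntegerVector labels(n);
  double phi = phi_init;
  int mode = 1;
  samples[0] = phi;
  labels[0] = 1;
  for (int i = 1; i < n; ++i) {
    if (mode == 1) {
      double nxt = step1(phi, u1, z1, R::runif(-eps1, eps1));
      if (nxt > th1) {
        phi = entry_random ? R::runif(m2_lo, m2_hi) : phi_k;
        samples[i] = phi;
        labels[i] = 4;  // ENTRY2
        mode = 2;
      } else {
        phi = nxt;
        samples[i] = phi;
        labels[i] = 1;
      }
    } else {
      if (phi <= 0.0)
        stop("tricritical map asked to step from non-positive state at sample %d",
             i + 1);
      double nxt = step2(phi, u2, z2, R::runif(-eps2, eps2));
      if (nxt < th2) {
        phi = entry_random ? R::runif(m1_lo, m1_hi) : phi_m;
        samples[i] = phi;
        labels[i] = 3;  // ENTRY1
        mode = 1;
      } else {
        phi = nxt;
        samples[i] = phi;
        labels[i] = 2;
      }
    }
  }
  return List::create(_["samples"] = samples, _["labels"] = labels);
}

// Uncoupled intermittent run with burst-end reinjection.  The value that
// crosses the burst-end threshold (upward for map1, downward for map2) is
// suppressed and replaced by a reinjection value inside the laminar region.
// [[Rcpp::export]]
NumericVector run_intermittent_cpp(int map_id, int n,
                                   double u, double z, double eps,
                                   double lam_lo, double lam_hi,
                                   double burst_end,
                                   bool reinject_uniform,
                                   double reinject_value,
                                   double start) {
  if (n < 1) stop("'n_samples' must be >= 1");
  NumericVector out(n);
  double phi = start;
  out[0] = phi;
  for (int i = 1; i < n; ++i) {
    double nxt;
    if (map_id == 1) {
      nxt = step1(phi, u, z, R::runif(-eps, eps));
      if (nxt > burst_end)
        nxt = reinject_uniform ? R::runif(lam_lo, lam_hi) : reinject_value;
    } else {
      if (phi <= 0.0)
        stop("tricritical map asked to step from non-positive state at sample %d",
             i + 1);
      nxt = step2(phi, u, z, R::runif(-eps, eps));
      if (nxt < burst_end)
        nxt = reinject_uniform ? R::runif(lam_lo, lam_hi) : reinject_value;
    }
    phi = nxt;
    out[i] = phi;
  }
  return out;
}
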