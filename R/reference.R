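#' Run the full reference simulate-and-analyse pipeline
#'
#' Generates a spike train with the reference parameterization (critical
#' map \{z = 4, u = 0.011, eps = 0.0175\}, tricritical map \{z = 5,
#' u = 17, eps = 0.07\}, thresholds \{0.31, 0\}, entry values 3 and 0),
#' then (a) runs the method-of-critical-fluctuations scan over
#' `(min(series), th1)` and fits the laminar-length distribution of the
#' selected band, and (b) detects spikes, builds the inter-spike-interval
#' distribution and fits it with the same truncated power law.  At
#' criticality both exponents estimate \eqn{p = 1 + 1/\delta}; with
#' \eqn{z_1 = 4} (\eqn{\delta = 3}, mean-field class) the theoretical value
#' is \eqn{4/3}.
#'
#' @param n_samples Series length (default three million).
#' @param seed Integer seed fixing the whole experiment.
#' @param detection_threshold Spike-detection threshold (default 1.0).
#' @param ... Passed to [mcf_scan()] (e.g. `p3_tol`, `fit_space`).
#' @return An object of class `reference_analysis`: list with the
#'   `spike_train`, the `mcf` result, the `isi_fit` and the theoretical
#'   exponent `p_theory`.
#' @examples
#' \donttest{
#' run_reference_pipeline(n_samples = 5e5, seed = 7)
#' }
#' @export
run_reference_pipeline <- function(n_samples = 3e6, seed = NULL,
                                   detection_threshold = 1.0, ...) {
  m1 <- map1_params()
  m2 <- map2_params()
  cfg <- coupling_config(n_samples = n_samples, seed = seed)
  st <- generate_spike_train(m1, m2, cfg)
  mcf <- mcf_scan(st, upper_limit = cfg$th1, ...)
  intervals <- interspike_intervals(
    detect_spike_onsets(st, detection_threshold))
  isi_fit <- fit_isi_distribution(intervals)
  structure(list(spike_train = st, mcf = mcf, isi_fit = isi_fit,
                 intervals = intervals,
                 p_theory = p_from_z1(m1$z)),
            class = "reference_analysis")
}

#' @export
print.reference_analysis <- function(x, ...) {
  cat("reference spike-train experiment\n")
  cat(sprintf("  %d samples, %d spikes\n",
              length(x$spike_train$samples), length(x$intervals) + 1L))
  cat("\nlaminar-length (MCF) fit:\n")
  print(x$mcf)
  cat("\ninter-spike-interval fit:\n")
  print(x$isi_fit)
  cat(sprintf("\ntheoretical exponent p = z1/(z1-1) = %.4f\n", x$p_theory))
  invisible(x)
}
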