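#' Detect spike onsets by upward threshold crossing
#'
#' A spike onset is the first sample at or above the detection threshold
#' after a sample below it (the first sample of the series is exempt from
#' the predecessor condition).  For spike trains generated with the
#' reference parameterization any threshold strictly between the firing
#' threshold (0.31) and the spike peak (3) detects exactly the entries
#' into the tricritical map; 1.0 is the default.
#'
#' @param series Numeric series (or a `spike_train`).
#' @param threshold Finite detection threshold.
#' @return An object of class `spike_events`: list with `onsets` (1-based
#'   indices, strictly increasing) and `threshold`.
#' @examples
#' detect_spike_onsets(c(0, 0.1, 3.0, 2.9, 0.0), threshold = 1)$onsets  # 3
#' @export
detect_spike_onsets <- function(series, threshold = 1.0) {
  if (inherits(series, "spike_train")) series <- series$samples
  stopifnot(is.numeric(series), is.numeric(threshold),
            length(threshold) == 1L, is.finite(threshold))
  above <- series >= threshold
  prev_below <- c(TRUE, !above[-length(series)])
  structure(list(onsets = which(above & prev_below), threshold = threshold),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("%d spike onsets (threshold %g)\n", length(x$onsets),
              x$threshold))
  invisible(x)
}

#' Inter-spike intervals
#'
#' First differences of the spike-onset indices, measured in algorithmic
#' time steps.  Fewer than two onsets yield an empty result.
#'
#' @param events A `spike_events` object (or an increasing index vector).
#' @return Integer vector of intervals.
#' @examples
#' interspike_intervals(c(10, 25, 100))  # 15 75
#' @export
interspike_intervals <- function(events) {
  onsets <- if (inherits(events, "spike_events")) events$onsets else events
  stopifnot(is.numeric(onsets))
  if (is.unsorted(onsets, strictly = TRUE))
    stop("onset indices must be strictly increasing")
  if (length(onsets) < 2L) return(integer(0))
  as.integer(diff(onsets))
}

#' Fit the inter-spike-interval distribution
#'
#' Tabulates the intervals into a unit-bin relative-frequency distribution
#' and fits the truncated power law \eqn{A\,s^{-p_2}\,e^{-p_3 s}} with
#' [fit_truncated_power_law()]; the fit-space and confidence-interval
#' conventions are identical, so the ISI exponent is directly comparable
#' with the laminar-length exponent.
#'
#' @param intervals Positive integer inter-spike intervals.
#' @param ... Passed to [fit_truncated_power_law()].
#' @return A `tpl_fit` object.
#' @export
fit_isi_distribution <- function(intervals, ...) {
  fit_truncated_power_law(length_distribution(intervals), ...)
}
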