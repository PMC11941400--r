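#' Coupling configuration for the spike-train mechanism
#'
#' Controls the threshold switching between the two maps.  While the
#' critical map runs, a computed value above `th1` (the firing threshold)
#' is suppressed before reaching the output and the state jumps to the
#' tricritical map's entry value `phi_k`; while the tricritical map runs, a
#' computed value below `th2` is suppressed and the state jumps back to the
#' critical map's entry value `phi_m`.  For biological-neuron-type spike
#' trains `th1` is the end of the critical map's laminar region and `th2`
#' its fixed point, so that each spike is followed by hyperpolarization
#' below the firing threshold.
#'
#' Defaults are the package's reference experiment: thresholds
#' \{0.31, 0\}, entry values 3 and 0, three million samples.
#'
#' @param th1 Firing / switch threshold of the critical map.
#' @param th2 Switch-back threshold of the tricritical map; `th2 < th1`.
#' @param phi_k Entry value of the tricritical map (the spike peak);
#'   `phi_k > th1`.
#' @param phi_m Re-entry value of the critical map; `phi_m <= th1`.
#' @param phi_init Initial state (the run starts in the critical map).
#' @param n_samples Number of samples to emit (>= 1).
#' @param seed Optional integer seed; fixes the whole experiment.
#' @param entry_mode `"fixed"` (entry at `phi_k` / `phi_m` exactly, the
#'   reference behaviour) or `"uniform"` (uniform-random entry inside each
#'   map's laminar region; randomizing the entry points does not change the
#'   laminar statistics).
#' @return An object of class `coupling_config`.
#' @seealso [generate_spike_train()]
#' @export
coupling_config <- function(th1 = 0.31, th2 = 0, phi_k = 3, phi_m = 0,
                            phi_init = 0, n_samples = 3e6, seed = NULL,
                            entry_mode = c("fixed", "uniform")) {
  entry_mode <- match.arg(entry_mode)
  stopifnot(is.numeric(th1), is.numeric(th2), is.numeric(phi_k),
            is.numeric(phi_m), is.numeric(phi_init),
            is.numeric(n_samples), length(n_samples) == 1L,
            is.finite(n_samples), n_samples >= 1)
  if (!(th2 < th1 && th1 < phi_k))
    stop("require th2 < th1 < phi_k")
  if (!(phi_m <= th1))
    stop("require phi_m <= th1")
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(th1 = th1, th2 = th2, phi_k = phi_k, phi_m = phi_m,
                 phi_init = phi_init, n_samples = as.integer(n_samples),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 entry_mode = entry_mode),
            class = "coupling_config")
}

#' @export
print.coupling_config <- function(x, ...) {
  cat(sprintf(
    "coupling: th1 = %g, th2 = %g, phi_k = %g, phi_m = %g, phi_init = %g\n",
    x$th1, x$th2, x$phi_k, x$phi_m, x$phi_init))
  cat(sprintf("  n_samples = %d, entry_mode = %s, seed = %s\n",
              x$n_samples, x$entry_mode,
              if (is.null(x$seed)) "<none>" else format(x$seed)))
  invisible(x)
}

st_label_levels <- c("MAP1", "MAP2", "ENTRY1", "ENTRY2")

#' Generate a spike train from the coupled intermittent maps
#'
#' Runs the "map1 <-> map2" threshold-switching mechanism: the critical
#' (type-I) intermittency map produces the relaxation interval and the
#' spike rise; crossing the firing threshold switches the output to the
#' tricritical map, entered at the spike peak, which produces the spike
#' fall; crossing the lower threshold switches back.  Threshold-crossing
#' computed values are suppressed — they never reach the output — and each
#' entry value is emitted as one sample, so exactly `n_samples` values are
#' produced.  There is no external-field / stimulus term anywhere in the
#' update: the spiking is self-organized by the two repellors.
#'
#' Noise draws for both maps come from R's RNG in emission order, so
#' `cfg$seed` fixes the entire series bit-for-bit.
#'
#' @param m1 Critical-map parameters, see [map1_params()].
#' @param m2 Tricritical-map parameters, see [map2_params()].
#' @param cfg Coupling configuration, see [coupling_config()].
#' @return An object of class `spike_train`: a list with `samples`
#'   (numeric), `labels` (factor with levels `MAP1`, `MAP2`, `ENTRY1`,
#'   `ENTRY2`, aligned with `samples`), and the producing `m1`, `m2`,
#'   `config`.
#' @examples
#' st <- generate_spike_train(cfg = coupling_config(n_samples = 5e4, seed = 1))
#' st
#' summarize_segments(st)
#' @export
generate_spike_train <- function(m1 = map1_params(), m2 = map2_params(),
                                 cfg = coupling_config()) {
  stopifnot(inherits(m1, "map1_params"), inherits(m2, "map2_params"),
            inherits(cfg, "coupling_config"))
  if (cfg$entry_mode == "uniform" && !is.finite(m2$phi_L))
    stop("uniform entry mode needs a finite tricritical laminar lower edge")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  raw <- simulate_coupled_cpp(
    cfg$n_samples,
    m1$u, m1$z, m1$eps,
    m2$u, m2$z, m2$eps,
    cfg$th1, cfg$th2, cfg$phi_k, cfg$phi_m, cfg$phi_init,
    cfg$entry_mode == "uniform",
    m1$phi_0, m1$phi_L,
    m2$phi_L, cfg$phi_k)
  structure(list(samples = raw$samples,
                 labels = factor(st_label_levels[raw$labels],
                                 levels = st_label_levels),
                 m1 = m1, m2 = m2, config = cfg),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$samples)
  seg <- summarize_segments(x)
  cat(sprintf("spike train: %d samples, %d spikes\n", n, seg$spike_count))
  cat(sprintf("  range [%.4g, %.4g]; thresholds th1 = %g, th2 = %g\n",
              min(x$samples), max(x$samples), x$config$th1, x$config$th2))
  invisible(x)
}

#' @export
summary.spike_train <- function(object, ...) {
  seg <- summarize_segments(object)
  out <- list(n_samples = length(object$samples),
              range = range(object$samples),
              spike_count = seg$spike_count,
              label_counts = table(object$labels),
              mean_relaxation = if (length(seg$map1_runs))
                mean(seg$map1_runs) else NA_real_,
              mean_fall = if (length(seg$map2_runs))
                mean(seg$map2_runs) else NA_real_)
  class(out) <- "summary.spike_train"
  out
}

#' @export
print.summary.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d samples in [%.4g, %.4g], %d spikes\n",
              x$n_samples, x$range[1], x$range[2], x$spike_count))
  print(x$label_counts)
  cat(sprintf("mean relaxation run: %.1f samples; mean spike fall: %.1f\n",
              x$mean_relaxation, x$mean_fall))
  invisible(x)
}

#' @export
as.data.frame.spike_train <- function(x, ...) {
  data.frame(n = seq_along(x$samples), phi = x$samples, label = x$labels)
}

#' @export
plot.spike_train <- function(x, max_points = 3e5, ...) {
  n <- min(length(x$samples), max_points)
  plot(seq_len(n), x$samples[seq_len(n)], type = "l",
       xlab = "n", ylab = expression(phi[n]), ...)
  abline(h = c(x$config$th1, x$config$th2), lty = 3, col = "grey40")
  invisible(x)
}

#' Segment summary of a spike train
#'
#' Counts the spikes (entries into the tricritical map) and collects the
#' lengths of the maximal runs spent in each map.  Entry samples separate
#' the runs and are not counted in them.
#'
#' @param st A `spike_train` object (or its label factor).
#' @return A list with `spike_count`, `map1_runs`, `map2_runs` (integer run
#'   lengths in order of occurrence) and `n_entry1`.
#' @export
summarize_segments <- function(st) {
  labels <- if (inherits(st, "spike_train")) st$labels else st
  stopifnot(is.factor(labels) || is.character(labels))
  r <- rle(as.character(labels))
  list(spike_count = sum(r$lengths[r$values == "ENTRY2"]),
       map1_runs = r$lengths[r$values == "MAP1"],
       map2_runs = r$lengths[r$values == "MAP2"],
       n_entry1 = sum(r$lengths[r$values == "ENTRY1"]))
}
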