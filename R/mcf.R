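#' Laminar lengths of a series within a value band
#'
#' A laminar episode is a maximal run of consecutive samples strictly
#' inside the band `(phi_red, phi_blue)`.  Episodes truncated by the end of
#' the series are included.
#'
#' @param series Numeric series.
#' @param phi_red Lower band edge (strict).
#' @param phi_blue Upper band edge (strict); must exceed `phi_red`.
#' @return Integer vector of episode lengths, in order of occurrence.
#' @examples
#' extract_laminar_lengths(c(0, 0.05, 0.1, 0.5, 0.02, 0.03, 0.9, 0),
#'                         phi_red = -0.1, phi_blue = 0.2)  # 3 2 1
#' @export
extract_laminar_lengths <- function(series, phi_red, phi_blue) {
  stopifnot(is.numeric(series), is.numeric(phi_red), is.numeric(phi_blue),
            length(phi_red) == 1L, length(phi_blue) == 1L)
  if (!(phi_red < phi_blue)) stop("'phi_red' must be below 'phi_blue'")
  if (length(series) == 0L) return(integer(0))
  r <- rle(series > phi_red & series < phi_blue)
  as.integer(r$lengths[r$values])
}

new_length_distribution <- function(lengths, freq, counts, n_events) {
  structure(list(lengths = as.integer(lengths), freq = as.numeric(freq),
                 counts = counts, n_events = n_events),
            class = "length_distribution")
}

#' Relative-frequency distribution of integer lengths
#'
#' Tabulates laminar lengths (or inter-spike intervals) into unit-width
#' integer bins: distinct observed lengths with relative frequencies
#' `count(L) / n_events`.  No binning or smoothing; zero-count lengths do
#' not appear.
#'
#' @param lengths Positive integer lengths (at least one).
#' @return An object of class `length_distribution` with fields `lengths`
#'   (distinct values, ascending), `freq`, `counts` and `n_events`.
#' @examples
#' length_distribution(c(3, 2, 1))
#' @export
length_distribution <- function(lengths) {
  stopifnot(is.numeric(lengths))
  if (length(lengths) == 0L) stop("no laminar episodes")
  if (any(lengths < 1)) stop("lengths must be positive integers")
  tab <- table(lengths)
  L <- as.integer(names(tab))
  cnt <- as.integer(tab)
  new_length_distribution(L, cnt / length(lengths), cnt, length(lengths))
}

#' Assemble a length distribution from lengths and frequencies
#'
#' Mainly for synthetic distributions given in closed form (an exact power
#' law, say) rather than tabulated from data.  Frequencies are normalized
#' to sum to one.
#'
#' @param lengths Distinct positive integer lengths.
#' @param freq Relative frequencies aligned with `lengths`.
#' @param n_events Nominal number of underlying events (used by fit
#'   preconditions); default `length(lengths)`.
#' @return A `length_distribution` object.
#' @export
as_length_distribution <- function(lengths, freq, n_events = length(lengths)) {
  stopifnot(is.numeric(lengths), is.numeric(freq),
            length(lengths) == length(freq), length(lengths) > 0,
            all(lengths >= 1), all(freq > 0))
  o <- order(lengths)
  new_length_distribution(lengths[o], freq[o] / sum(freq), NULL, n_events)
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("length distribution: %d distinct lengths in [%d, %d], %s events\n",
              length(x$lengths), min(x$lengths), max(x$lengths),
              format(x$n_events)))
  invisible(x)
}

#' @export
as.data.frame.length_distribution <- function(x, ...) {
  d <- data.frame(length = x$lengths, freq = x$freq)
  if (!is.null(x$counts)) d$count <- x$counts
  d
}

#' Fit a truncated power law to a length distribution
#'
#' Fits \eqn{g(L) = A\,L^{-p_2}\,e^{-p_3 L}} to the relative frequencies by
#' nonlinear least squares (Levenberg–Marquardt).  `p2` is the power-law
#' exponent; `p3` is the exponent of the exponential corrective term: when
#' `p3` is close to zero the distribution is scale-free, and if in addition
#' \eqn{p_2 \in [1, 2)} the series carries critical-intermittency dynamics.
#'
#' Two fit spaces are available.  `"linear"` (the default) fits the model
#' to the raw relative frequencies; `"log"` fits
#' \eqn{\log_{10} P = \log_{10} A - p_2 \log_{10} L - p_3 L / \ln 10},
#' weighting all decades of the distribution equally.  `r2` is the
#' coefficient of determination in the chosen fit space.  95% confidence
#' intervals come from the Jacobian covariance with a Student-t quantile at
#' `n_points - 3` degrees of freedom.
#'
#' @param dist A [length_distribution()] object.
#' @param fit_space `"linear"` or `"log"`.
#' @param min_distinct,min_events Fit preconditions: refuse distributions
#'   with fewer distinct lengths / underlying events than this.
#' @param start Named numeric starting values for `p2` and `p3`; the
#'   amplitude start is derived from the first cells of the distribution.
#' @param lower,upper Box constraints for `(p2, p3)`.
#' @return An object of class `tpl_fit` with components `p2`, `p3`,
#'   `amplitude`, `ci95_p2`, `ci95_p3`, `r2`, `fit_space`, `n_points`,
#'   `n_events` and the underlying `nls` model.
#' @examples
#' L <- 1:500
#' d <- as_length_distribution(L, L^-1.5, n_events = 1e4)
#' fit_truncated_power_law(d)
#' @export
fit_truncated_power_law <- function(dist,
                                    fit_space = c("linear", "log"),
                                    min_distinct = 10, min_events = 100,
                                    start = c(p2 = 1.3, p3 = 0.01),
                                    lower = c(p2 = 0, p3 = -1),
                                    upper = c(p2 = 5, p3 = 1)) {
  stopifnot(inherits(dist, "length_distribution"))
  fit_space <- match.arg(fit_space)
  L <- as.numeric(dist$lengths)
  P <- dist$freq
  if (length(L) < min_distinct)
    stop(fit_refused_cnd(sprintf(
      "fit refused: %d distinct lengths (< %d required)",
      length(L), min_distinct)))
  if (dist$n_events < min_events)
    stop(fit_refused_cnd(sprintf(
      "fit refused: %s events (< %d required)",
      format(dist$n_events), min_events)))
  A0 <- P[1] * L[1]^start[["p2"]] * exp(start[["p3"]] * L[1])
  fit <- if (fit_space == "log") {
    y <- log10(P)
    minpack.lm::nlsLM(
      y ~ la - p2 * log10(L) - p3 * L / log(10),
      start = list(la = log10(A0), p2 = start[["p2"]], p3 = start[["p3"]]),
      lower = c(-Inf, lower[["p2"]], lower[["p3"]]),
      upper = c(Inf, upper[["p2"]], upper[["p3"]]),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(
      P ~ A * L^(-p2) * exp(-p3 * L),
      start = list(A = A0, p2 = start[["p2"]], p3 = start[["p3"]]),
      lower = c(1e-300, lower[["p2"]], lower[["p3"]]),
      upper = c(Inf, upper[["p2"]], upper[["p3"]]),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  df <- length(L) - 3L
  tq <- qt(0.975, df)
  res <- stats::resid(fit)
  yobs <- if (fit_space == "log") log10(P) else P
  r2 <- 1 - sum(res^2) / sum((yobs - mean(yobs))^2)
  amplitude <- if (fit_space == "log") 10^cf[["la"]] else cf[["A"]]
  structure(list(
    p2 = cf[["p2"]], p3 = cf[["p3"]], amplitude = amplitude,
    ci95_p2 = cf[["p2"]] + c(-1, 1) * tq * se[["p2"]],
    ci95_p3 = cf[["p3"]] + c(-1, 1) * tq * se[["p3"]],
    se = se, r2 = r2, fit_space = fit_space,
    n_points = length(L), n_events = dist$n_events,
    model = fit, distribution = dist),
    class = "tpl_fit")
}

fit_refused_cnd <- function(msg) {
  structure(class = c("spikemap_fit_refused", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' @export
print.tpl_fit <- function(x, digits = 4, ...) {
  cat(sprintf("truncated power law A * L^-p2 * exp(-p3 L)  [%s-space fit]\n",
              x$fit_space))
  cat(sprintf("  p2 = %.*g  (95%% CI %.4g, %.4g)\n", digits, x$p2,
              x$ci95_p2[1], x$ci95_p2[2]))
  cat(sprintf("  p3 = %.*g  (95%% CI %.4g, %.4g)\n", digits, x$p3,
              x$ci95_p3[1], x$ci95_p3[2]))
  cat(sprintf("  amplitude = %.4g, R^2 = %.4f, %d points / %s events\n",
              x$amplitude, x$r2, x$n_points, format(x$n_events)))
  invisible(x)
}

#' @export
summary.tpl_fit <- function(object, ...) {
  print(object, ...)
  cat("\nunderlying nls fit:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.tpl_fit <- function(object, ...) {
  c(amplitude = object$amplitude, p2 = object$p2, p3 = object$p3)
}

#' @export
confint.tpl_fit <- function(object, ...) {
  m <- rbind(p2 = object$ci95_p2, p3 = object$ci95_p3)
  colnames(m) <- c("2.5 %", "97.5 %")
  m
}

#' @param newdata Optional integer lengths at which to evaluate the fit.
#' @rdname fit_truncated_power_law
#' @export
predict.tpl_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) as.numeric(object$distribution$lengths)
       else as.numeric(newdata)
  object$amplitude * L^(-object$p2) * exp(-object$p3 * L)
}

#' @export
plot.tpl_fit <- function(x, ...) {
  d <- x$distribution
  plot(d$lengths, d$freq, log = "xy", pch = 16, cex = 0.5,
       xlab = "L", ylab = "P(L)", ...)
  Lg <- exp(seq(log(min(d$lengths)), log(max(d$lengths)), length.out = 200))
  lines(Lg, predict(x, Lg), col = "red3", lwd = 2)
  invisible(x)
}

#' Method of critical fluctuations: scan of the upper laminar-band edge
#'
#' Treats the upper band edge `phi_blue` as a free parameter and examines
#' candidate values on progressively denser equally spaced grids over
#' `(phi_red, upper_limit)`.  For each candidate the laminar-length
#' distribution is fitted with [fit_truncated_power_law()]; a candidate
#' qualifies when the exponential correction vanishes (`|p3| <= p3_tol`)
#' while the power-law exponent lies in the critical range
#' \eqn{p_2 \in [1, 2)}.  The scan stops at the first grid density that
#' produces at least one qualifying candidate and returns the qualifier
#' with maximal \eqn{R^2} (ties: smallest `|p3|`, then smallest
#' `phi_blue`).  Different seeds of the underlying simulation may select
#' different `phi_blue` values, but the fitted `p2` is stable.
#'
#' @param series Numeric series (or a `spike_train`).
#' @param phi_red Lower band edge; default the series minimum.
#' @param upper_limit Upper end of the scanned range, exclusive (for spike
#'   trains, the firing threshold).
#' @param p3_tol Qualification tolerance on `|p3|` (default 0.001).
#' @param schedule Integer vector of interior grid sizes tried in order.
#' @param fit_space,min_distinct,min_events Passed to
#'   [fit_truncated_power_law()].
#' @return An object of class `mcf_result`: the selected `phi_blue` /
#'   `phi_red` band, the selected `tpl_fit`, the number of candidates
#'   examined and a data-frame ledger of all candidates.  If no candidate
#'   qualifies at the densest grid, an error of class
#'   `spikemap_no_band` is signalled with the ledger attached.
#' @examples
#' \donttest{
#' st <- generate_spike_train(cfg = coupling_config(n_samples = 5e5, seed = 2))
#' mcf_scan(st, upper_limit = 0.31)
#' }
#' @export
mcf_scan <- function(series, phi_red = NULL, upper_limit,
                     p3_tol = 0.001,
                     schedule = c(20L, 50L, 100L, 200L, 500L),
                     fit_space = c("linear", "log"),
                     min_distinct = 10, min_events = 100) {
  if (inherits(series, "spike_train")) series <- series$samples
  stopifnot(is.numeric(series), length(series) > 0,
            is.numeric(upper_limit), length(upper_limit) == 1L)
  fit_space <- match.arg(fit_space)
  if (is.null(phi_red)) phi_red <- min(series)
  if (!(phi_red < upper_limit))
    stop("'phi_red' must be below 'upper_limit'")
  above_red <- series > phi_red
  ledger <- NULL
  n_examined <- 0L
  for (k in schedule) {
    cand <- phi_red + seq_len(k) * (upper_limit - phi_red) / (k + 1)
    rows <- lapply(cand, function(pb) {
      n_examined <<- n_examined + 1L
      r <- rle(above_red & series < pb)
      lens <- r$lengths[r$values]
      if (length(lens) == 0L)
        return(data.frame(phi_blue = pb, n_episodes = 0L, n_distinct = 0L,
                          p2 = NA_real_, p3 = NA_real_, r2 = NA_real_,
                          qualifies = FALSE))
      fit <- tryCatch(
        fit_truncated_power_law(length_distribution(lens),
                                fit_space = fit_space,
                                min_distinct = min_distinct,
                                min_events = min_events),
        error = function(e) NULL)
      if (is.null(fit))
        return(data.frame(phi_blue = pb, n_episodes = length(lens),
                          n_distinct = length(unique(lens)),
                          p2 = NA_real_, p3 = NA_real_, r2 = NA_real_,
                          qualifies = FALSE))
      data.frame(phi_blue = pb, n_episodes = length(lens),
                 n_distinct = fit$n_points,
                 p2 = fit$p2, p3 = fit$p3, r2 = fit$r2,
                 qualifies = abs(fit$p3) <= p3_tol &&
                   fit$p2 >= 1 && fit$p2 < 2)
    })
    grid_ledger <- do.call(rbind, rows)
    ledger <- rbind(ledger, grid_ledger)
    q <- grid_ledger[grid_ledger$qualifies, , drop = FALSE]
    if (nrow(q) > 0L) {
      q <- q[order(-q$r2, abs(q$p3), q$phi_blue), , drop = FALSE]
      sel <- q[1L, ]
      lens <- extract_laminar_lengths(series, phi_red, sel$phi_blue)
      fit <- fit_truncated_power_law(length_distribution(lens),
                                     fit_space = fit_space,
                                     min_distinct = min_distinct,
                                     min_events = min_events)
      return(structure(list(phi_red = phi_red, phi_blue = sel$phi_blue,
                            fit = fit, p3_tol = p3_tol,
                            candidates_examined = n_examined,
                            qualifying = q, ledger = ledger),
                       class = "mcf_result"))
    }
  }
  stop(structure(class = c("spikemap_no_band", "error", "condition"),
                 list(message = "no critical band found: no phi_blue candidate gave |p3| <= tol with p2 in [1, 2)",
                      call = sys.call(-1), ledger = ledger)))
}

#' @export
print.mcf_result <- function(x, ...) {
  cat(sprintf(
    "MCF scan: selected band (phi_red, phi_blue) = (%.4g, %.4g)\n",
    x$phi_red, x$phi_blue))
  cat(sprintf("  %d candidates examined, %d qualifying (|p3| <= %g, p2 in [1,2))\n",
              x$candidates_examined, nrow(x$qualifying), x$p3_tol))
  print(x$fit)
  invisible(x)
}

#' @export
summary.mcf_result <- function(object, ...) {
  print(object)
  cat("\nqualifying candidates:\n")
  print(object$qualifying, row.names = FALSE)
  invisible(object)
}
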