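#' Parameters of the critical (type-I) intermittency map
#'
#' The map \eqn{\phi_{n+1} = \phi_n + u\,\phi_n^{z} + \epsilon_n} has a
#' marginally unstable fixed point at zero and drives trajectories upward,
#' away from its laminar region \eqn{[\phi_0, \phi_L]}.  \eqn{\epsilon_n}
#' is i.i.d. uniform noise on \eqn{[-\epsilon, +\epsilon]}.  For non-integer
#' \code{z} the nonlinear term uses \eqn{|\phi|^z} so that it stays
#' real-valued for negative states.
#'
#' @param u Positive coefficient of the nonlinear term.
#' @param z Positive exponent of the nonlinear term; \eqn{z = \delta + 1}
#'   where \eqn{\delta} is the isothermal critical exponent.
#' @param eps Non-negative noise half-width.
#' @param phi_0 Fixed point / start of the laminar region (default 0).
#' @param phi_L End of the laminar region; must exceed `phi_0`.
#'
#' @return An object of class `map1_params`.
#' @seealso [map2_params()], [step_map1()]
#' @examples
#' map1_params()                # the reference parameter set
#' map1_params(u = 0.011, z = 4, eps = 0.0175, phi_L = 0.2)
#' @export
map1_params <- function(u = 0.011, z = 4, eps = 0.0175,
                        phi_0 = 0, phi_L = 0.31) {
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u), u > 0,
            is.numeric(z), length(z) == 1L, is.finite(z), z > 0,
            is.numeric(eps), length(eps) == 1L, is.finite(eps), eps >= 0,
            is.numeric(phi_0), length(phi_0) == 1L, is.finite(phi_0),
            is.numeric(phi_L), length(phi_L) == 1L, is.finite(phi_L))
  if (!(phi_0 < phi_L))
    stop("'phi_0' must be below 'phi_L' (laminar region must be non-empty)")
  structure(list(u = u, z = z, eps = eps, phi_0 = phi_0, phi_L = phi_L),
            class = c("map1_params", "map_params"))
}

#' Parameters of the tricritical intermittency map
#'
#' The map \eqn{\phi_{n+1} = \phi_n - u\,\phi_n^{-z} + \epsilon_n} has a
#' marginally unstable fixed point at (theoretically) infinity and drives
#' trajectories downward, away from its laminar region
#' \eqn{[\phi_L, \phi_0)}.  It is only defined for positive states.
#'
#' @param u Positive coefficient of the nonlinear term.
#' @param z Positive exponent; the term is \eqn{u\,\phi^{-z}}.
#' @param eps Non-negative noise half-width.
#' @param phi_L Lower edge of the laminar region (default 1).
#' @param phi_0 Upper edge / fixed point; `Inf` (the default) encodes the
#'   fixed point at infinity.
#'
#' @return An object of class `map2_params`.
#' @seealso [map1_params()], [step_map2()]
#' @examples
#' map2_params()                # the reference parameter set
#' @export
map2_params <- function(u = 17, z = 5, eps = 0.07,
                        phi_L = 1, phi_0 = Inf) {
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u), u > 0,
            is.numeric(z), length(z) == 1L, is.finite(z), z > 0,
            is.numeric(eps), length(eps) == 1L, is.finite(eps), eps >= 0,
            is.numeric(phi_L), length(phi_L) == 1L, is.finite(phi_L),
            is.numeric(phi_0), length(phi_0) == 1L, !is.na(phi_0))
  if (!(phi_L < phi_0))
    stop("'phi_L' must be below 'phi_0'")
  structure(list(u = u, z = z, eps = eps, phi_L = phi_L, phi_0 = phi_0),
            class = c("map2_params", "map_params"))
}

#' @export
print.map_params <- function(x, ...) {
  kind <- if (inherits(x, "map1_params")) "critical (type-I)" else "tricritical"
  cat(sprintf("%s intermittency map: u = %g, z = %g, eps = %g\n",
              kind, x$u, x$z, x$eps))
  if (inherits(x, "map1_params"))
    cat(sprintf("  laminar region [%g, %g]\n", x$phi_0, x$phi_L))
  else
    cat(sprintf("  laminar region [%g, %s)\n", x$phi_L,
                if (is.infinite(x$phi_0)) "Inf" else format(x$phi_0)))
  invisible(x)
}

#' Single steps of the two intermittent maps
#'
#' `step_map1()` evaluates \eqn{\phi + u\,\phi^{z} + \epsilon_n};
#' `step_map2()` evaluates \eqn{\phi - u\,\phi^{-z} + \epsilon_n}.
#' Both are exact arithmetic, no clipping: `step_map2()` may return values
#' far below any switching threshold (the caller handles the overshoot).
#' Vectorized over `phi` and `eps_n`.
#'
#' @param phi Current state (finite; strictly positive for `step_map2`).
#' @param params A [map1_params()] / [map2_params()] object.
#' @param eps_n Noise value(s), `|eps_n| <= params$eps` expected (default 0).
#' @return The next state(s), numeric.
#' @examples
#' step_map1(0.3, map1_params(u = 0.011, z = 4))   # 0.3 + 0.011 * 0.3^4
#' step_map2(3, map2_params(u = 17, z = 5))        # 3 - 17/243
#' @export
step_map1 <- function(phi, params = map1_params(), eps_n = 0) {
  stopifnot(inherits(params, "map1_params"), is.numeric(phi),
            is.numeric(eps_n))
  if (any(!is.finite(phi))) stop("'phi' must be finite")
  n <- max(length(phi), length(eps_n))
  phi <- rep_len(phi, n); eps_n <- rep_len(eps_n, n)
  vapply(seq_len(n), function(i)
    step_map1_cpp(phi[i], params$u, params$z, eps_n[i]), numeric(1))
}

#' @rdname step_map1
#' @export
step_map2 <- function(phi, params = map2_params(), eps_n = 0) {
  stopifnot(inherits(params, "map2_params"), is.numeric(phi),
            is.numeric(eps_n))
  if (any(!is.finite(phi))) stop("'phi' must be finite")
  if (any(phi <= 0))
    stop("tricritical map evaluated at non-positive state")
  n <- max(length(phi), length(eps_n))
  phi <- rep_len(phi, n); eps_n <- rep_len(eps_n, n)
  vapply(seq_len(n), function(i)
    step_map2_cpp(phi[i], params$u, params$z, eps_n[i]), numeric(1))
}

#' Return-plot data for an intermittent map
#'
#' Deterministic (zero-noise) pairs \eqn{(\phi_n, \phi_{n+1})} on a grid,
#' for plotting the return map against the bisector: laminar regions hug
#' the bisector, bursts depart from it.
#'
#' @param params A [map1_params()] or [map2_params()] object.
#' @param phi_grid Numeric grid of states (must be positive for the
#'   tricritical map).  An empty grid yields a zero-row result.
#' @return A data frame with columns `phi` and `phi_next`.
#' @examples
#' return_map_points(map1_params(), seq(0, 0.6, by = 0.01))
#' @export
return_map_points <- function(params, phi_grid) {
  stopifnot(inherits(params, "map_params"), is.numeric(phi_grid))
  if (length(phi_grid) == 0L)
    return(data.frame(phi = numeric(0), phi_next = numeric(0)))
  nxt <- if (inherits(params, "map1_params"))
    step_map1(phi_grid, params) else step_map2(phi_grid, params)
  data.frame(phi = phi_grid, phi_next = nxt)
}

#' Uncoupled intermittent run with burst-end reinjection
#'
#' Iterates a single map from a value inside its laminar region.  A burst
#' ends when the computed next value crosses `burst_end` (upward for the
#' critical map, downward for the tricritical map); the crossing value is
#' suppressed and replaced by a reinjection value inside the laminar region,
#' either uniform-random (the default) or a fixed value.
#'
#' @param params A [map1_params()] or [map2_params()] object.
#' @param n_samples Number of samples to emit (>= 1).
#' @param laminar Length-2 numeric, the laminar region used for start and
#'   reinjection.  Defaults to the map's own laminar bounds (which must be
#'   finite).
#' @param burst_end Burst-end threshold.  Must lie above the laminar region
#'   for the critical map and below it for the tricritical map.
#' @param reinjection `"uniform"` (uniform-random inside `laminar`) or
#'   `"fixed"`.
#' @param reinjection_value Reinjection value when `reinjection = "fixed"`.
#' @param start Starting value; default the midpoint of `laminar`
#'   (`"uniform"`) or `reinjection_value` (`"fixed"`).
#' @param seed Optional integer seed; a fixed seed makes the run
#'   bit-identical across calls.
#' @return Numeric vector of `n_samples` emitted values.
#' @examples
#' x <- run_uncoupled_intermittent(map1_params(phi_L = 0.2),
#'                                 n_samples = 5000, burst_end = 0.65,
#'                                 seed = 1)
#' max(x) <= 0.65
#' @export
run_uncoupled_intermittent <- function(params, n_samples,
                                       laminar = NULL,
                                       burst_end,
                                       reinjection = c("uniform", "fixed"),
                                       reinjection_value = NULL,
                                       start = NULL, seed = NULL) {
  stopifnot(inherits(params, "map_params"),
            is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 1)
  reinjection <- match.arg(reinjection)
  is_map1 <- inherits(params, "map1_params")
  if (is.null(laminar))
    laminar <- if (is_map1) c(params$phi_0, params$phi_L)
               else c(params$phi_L, params$phi_0)
  stopifnot(is.numeric(laminar), length(laminar) == 2L,
            all(is.finite(laminar)), laminar[1] < laminar[2],
            is.numeric(burst_end), length(burst_end) == 1L,
            is.finite(burst_end))
  if (is_map1 && burst_end <= laminar[2])
    stop("'burst_end' must lie above the laminar region for the critical map")
  if (!is_map1 && burst_end >= laminar[1])
    stop("'burst_end' must lie below the laminar region for the tricritical map")
  if (reinjection == "fixed") {
    stopifnot(is.numeric(reinjection_value), length(reinjection_value) == 1L)
    if (reinjection_value < laminar[1] || reinjection_value > laminar[2])
      stop("'reinjection_value' must lie inside the laminar region")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start))
    start <- if (reinjection == "fixed") reinjection_value
             else runif(1, laminar[1], laminar[2])
  run_intermittent_cpp(if (is_map1) 1L else 2L, as.integer(n_samples),
                       params$u, params$z, params$eps,
                       laminar[1], laminar[2], burst_end,
                       reinjection == "uniform",
                       if (reinjection == "fixed") reinjection_value else NA_real_,
                       start)
}

# ---- critical-exponent relations ----------------------------------------

#' Critical-exponent relations between map exponents and laminar-length
#' power laws
#'
#' At criticality the laminar-length distribution is a power law
#' \eqn{P(L) \sim L^{-p}}.  For the critical (type-I) map with exponent
#' \eqn{z_1}, \eqn{p = z_1/(z_1 - 1)}; in terms of the isothermal critical
#' exponent \eqn{\delta} (with \eqn{z_1 = \delta + 1}),
#' \eqn{p = 1 + 1/\delta}, so critical intermittency lives in
#' \eqn{p \in [1, 2)}.  For the tricritical map with exponent \eqn{z_2},
#' \eqn{p = z_2/(z_2 + 1) = (\delta+1)/(\delta+2)}, the tricritical range
#' \eqn{p \in [2/3, 1)}.
#'
#' @param z1,z2 Map exponents (`z1 > 1`, `z2 > 0`).
#' @param delta Isothermal critical exponent (`delta > 1`).
#' @return The laminar-length exponent `p` (or `z1` for [z1_from_delta()]).
#' @examples
#' p_from_delta(3)      # 4/3, the mean-field universality class
#' p_from_z1(4)         # the same via z1 = delta + 1
#' p_from_z2(5)         # 5/6, tricritical
#' z1_from_delta(3)     # 4
#' @export
p_from_z1 <- function(z1) {
  stopifnot(is.numeric(z1))
  if (any(z1 <= 1)) stop("'z1' must exceed 1")
  z1 / (z1 - 1)
}

#' @rdname p_from_z1
#' @export
p_from_delta <- function(delta) {
  stopifnot(is.numeric(delta))
  if (any(delta <= 1)) stop("'delta' must exceed 1")
  1 + 1 / delta
}

#' @rdname p_from_z1
#' @export
p_from_z2 <- function(z2) {
  stopifnot(is.numeric(z2))
  if (any(z2 <= 0)) stop("'z2' must be positive")
  z2 / (z2 + 1)
}

#' @rdname p_from_z1
#' @export
z1_from_delta <- function(delta) {
  stopifnot(is.numeric(delta))
  if (any(delta <= 1)) stop("'delta' must exceed 1")
  delta + 1
}
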