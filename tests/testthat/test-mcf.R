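test_that("laminar-length extraction follows strict band inequalities", {
  s <- c(0.0, 0.05, 0.1, 0.5, 0.02, 0.03, 0.9, 0.0)
  expect_identical(extract_laminar_lengths(s, -0.1, 0.2), c(3L, 2L, 1L))
  expect_identical(extract_laminar_lengths(rep(0.1, 37), -0.1, 0.2), 37L)
  expect_identical(extract_laminar_lengths(c(1, 1, 1), -0.1, 0.2), integer(0))
  expect_identical(extract_laminar_lengths(numeric(0), -0.1, 0.2), integer(0))
  # boundary values are excluded
  expect_identical(extract_laminar_lengths(c(0.2, 0.1, -0.1), -0.1, 0.2), 1L)
  expect_error(extract_laminar_lengths(s, 0.5, 0.1), "phi_red")
})

test_that("laminar-length extraction agrees with a brute-force re-scan", {
  set.seed(314)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    s <- runif(n, -1, 1)
    lo <- runif(1, -1, 0.5)
    hi <- lo + runif(1, 0.01, 1)
    got <- extract_laminar_lengths(s, lo, hi)
    ref <- brute_laminar_lengths(s, lo, hi)
    expect_identical(got, as.integer(ref))
    expect_true(sum(got) <= n)
  }
})

test_that("length distributions are unit-bin relative frequencies", {
  d <- length_distribution(c(3, 2, 1))
  expect_identical(d$lengths, 1:3)
  expect_equal(d$freq, rep(1 / 3, 3))
  d2 <- length_distribution(c(5, 5, 5, 5))
  expect_identical(d2$lengths, 5L)
  expect_equal(d2$freq, 1)
  d3 <- length_distribution(c(1, 1, 2))
  expect_equal(d3$freq, c(2 / 3, 1 / 3))
  expect_equal(sum(length_distribution(rpois(500, 6) + 1L)$freq), 1,
               tolerance = 1e-12)
  expect_error(length_distribution(integer(0)), "no laminar episodes")
})

test_that("the truncated power-law fitter recovers exact distributions", {
  L <- 1:1000
  d <- as_length_distribution(L, L^-1.5, n_events = 1e4)
  f <- fit_truncated_power_law(d)
  expect_equal(f$p2, 1.5, tolerance = 0.01 / 1.5)
  expect_lt(abs(f$p3), 1e-4)
  expect_true(f$ci95_p2[1] <= f$p2 && f$p2 <= f$ci95_p2[2])
  expect_true(f$r2 <= 1)
  # pure exponential limit
  de <- as_length_distribution(1:200, exp(-0.1 * (1:200)), n_events = 1e4)
  fe <- fit_truncated_power_law(de)
  expect_equal(fe$p3, 0.1, tolerance = 0.005 / 0.1)
  expect_lt(abs(fe$p2), 0.05)
  # log-space mode recovers the same exact law
  fl <- fit_truncated_power_law(d, fit_space = "log")
  expect_equal(fl$p2, 1.5, tolerance = 0.01 / 1.5)
  expect_identical(fl$fit_space, "log")
})

test_that("the fitter refuses degenerate distributions", {
  expect_error(fit_truncated_power_law(length_distribution(rep(4L, 500))),
               class = "spikemap_fit_refused")
  expect_error(
    fit_truncated_power_law(length_distribution(c(3L, 2L, 1L))),
    class = "spikemap_fit_refused")
})

test_that("fit accessors are coherent", {
  d <- as_length_distribution(1:300, (1:300)^-1.2, n_events = 1e4)
  f <- fit_truncated_power_law(d)
  expect_named(coef(f), c("amplitude", "p2", "p3"))
  ci <- confint(f)
  expect_identical(rownames(ci), c("p2", "p3"))
  expect_equal(predict(f, 1), unname(coef(f)["amplitude"]),
               tolerance = 1e-8)
  expect_length(predict(f), 300)
})

test_that("the band scan qualifies a critical band on a coupled run and
           reports the candidate ledger", {
  st <- generate_spike_train(cfg = coupling_config(n_samples = 5e5, seed = 2))
  m <- mcf_scan(st, upper_limit = 0.31)
  expect_s3_class(m, "mcf_result")
  expect_true(m$phi_red < m$phi_blue && m$phi_blue < 0.31)
  expect_true(abs(m$fit$p3) <= m$p3_tol)
  expect_true(m$fit$p2 >= 1 && m$fit$p2 < 2)
  expect_true(all(c("phi_blue", "p2", "p3", "r2", "qualifies") %in%
                    names(m$ledger)))
  expect_gte(m$candidates_examined, nrow(m$ledger))
})

test_that("the band scan fails loudly when no critical band exists", {
  err <- tryCatch(mcf_scan(rep(0.5, 1000), phi_red = 0, upper_limit = 1,
                           schedule = c(5L, 10L)),
                  error = function(e) e)
  expect_s3_class(err, "spikemap_no_band")
  expect_match(conditionMessage(err), "no critical band")
  expect_true(is.data.frame(err$ledger))
})

test_that("longer simulations do not widen the exponent confidence interval", {
  width <- function(n, seed) {
    st <- generate_spike_train(cfg = coupling_config(n_samples = n, seed = seed))
    lens <- extract_laminar_lengths(st$samples, -0.64, 0.07)
    f <- fit_truncated_power_law(length_distribution(lens))
    diff(f$ci95_p2)
  }
  w_short <- mean(vapply(21:22, function(s) width(5e5, s), numeric(1)))
  w_long <- mean(vapply(23:24, function(s) width(2e6, s), numeric(1)))
  expect_lt(w_long, w_short)
})
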