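test_that("single map steps match hand-evaluated arithmetic", {
  m1 <- map1_params(u = 0.011, z = 4, eps = 0.0175)
  expect_identical(step_map1(0, m1, 0), 0)                    # fixed point
  expect_equal(step_map1(0.3, m1, 0), 0.3 + 0.011 * 0.3^4)    # 0.3000891
  expect_equal(step_map1(-0.1, m1, 0), -0.1 + 0.011 * 1e-4)   # even exponent
  m2 <- map2_params(u = 17, z = 5, eps = 0.07)
  expect_equal(step_map2(3, m2, 0), 3 - 17 / 243)             # 2.93004115...
  expect_equal(step_map2(100, m2, 0), 100 - 17e-10)           # drift vanishes
  expect_equal(step_map2(0.5, m2, 0), -543.5)                 # overshoot, no clipping
})

test_that("non-integer exponents use the absolute-value base", {
  m <- map1_params(u = 0.2, z = 2.5, eps = 0)
  expect_equal(step_map1(-0.1, m, 0), -0.1 + 0.2 * 0.1^2.5)
  expect_true(is.finite(step_map1(-0.4, m, 0)))
})

test_that("map steps reject invalid states", {
  expect_error(step_map1(Inf, map1_params()), "finite")
  expect_error(step_map1(NaN, map1_params()), "finite")
  expect_error(step_map2(0, map2_params()), "non-positive")
  expect_error(step_map2(-1, map2_params()), "non-positive")
})

test_that("noise-free drift is monotone and marginal at the fixed points", {
  m1 <- map1_params(); m2 <- map2_params()
  phis <- 10^seq(-4, -0.6, length.out = 25)
  expect_true(all(step_map1(phis, m1) > phis))   # upward drift for phi > 0
  phis2 <- 10^seq(0, 2, length.out = 25)         # drift still above one ulp
  expect_true(all(step_map2(phis2, m2) < phis2))
  # numerical derivative of the critical map at its fixed point is 1
  h <- 1e-5
  deriv <- (step_map1(h, m1) - step_map1(-h, m1)) / (2 * h)
  expect_equal(deriv, 1, tolerance = 1e-6)
})

test_that("exponent relations are mutually consistent and land in the
           critical / tricritical ranges", {
  expect_equal(p_from_z1(4), 4 / 3)
  expect_equal(p_from_delta(3), 4 / 3)
  expect_equal(p_from_z1(2), 2)
  expect_equal(p_from_z1(101), 1.01)
  expect_equal(p_from_delta(1.0001), 1 + 1 / 1.0001)
  expect_equal(p_from_z2(5), 5 / 6)
  expect_equal(p_from_z2(2), 2 / 3)
  expect_equal(z1_from_delta(3), 4)
  expect_equal(z1_from_delta(2.5), 3.5)
  deltas <- seq(1.01, 50, length.out = 200)
  expect_equal(p_from_delta(deltas), p_from_z1(z1_from_delta(deltas)))
  z <- seq(2.01, 100, length.out = 200)
  expect_true(all(p_from_z1(z) > 1 & p_from_z1(z) < 2))
  expect_true(all(p_from_z2(z) > 2 / 3 & p_from_z2(z) < 1))
  expect_error(p_from_z1(1), "exceed 1")
  expect_error(p_from_delta(0.5), "exceed 1")
  expect_error(p_from_z2(0), "positive")
  expect_error(z1_from_delta(1), "exceed 1")
})

test_that("return-plot data is the deterministic one-step image of the grid", {
  expect_equal(return_map_points(map1_params(), 0),
               data.frame(phi = 0, phi_next = 0))
  expect_equal(return_map_points(map2_params(), 3)$phi_next, 3 - 17 / 243)
  rp <- return_map_points(map1_params(), c(0.1, 0.2))
  expect_equal(rp$phi_next, c(0.1 + 0.011 * 0.1^4, 0.2 + 0.011 * 0.2^4))
  empty <- return_map_points(map1_params(), numeric(0))
  expect_identical(nrow(empty), 0L)
})

test_that("uncoupled intermittent runs respect reinjection semantics", {
  # noise-free start at the fixed point never leaves it
  m0 <- map1_params(u = 0.011, z = 4, eps = 0, phi_L = 0.2)
  x0 <- run_uncoupled_intermittent(m0, 100, burst_end = 0.65,
                                   reinjection = "fixed",
                                   reinjection_value = 0)
  expect_identical(x0, rep(0, 100))
  # burst-crossing values are suppressed: nothing above the threshold
  m <- map1_params(phi_L = 0.2)
  x <- run_uncoupled_intermittent(m, 5e4, burst_end = 0.65, seed = 5)
  expect_true(max(x) <= 0.65)
  expect_true(any(x > 0.2))          # bursts do occur above the laminar region
  # bit-identical under a fixed seed
  y <- run_uncoupled_intermittent(m, 5e4, burst_end = 0.65, seed = 5)
  expect_identical(x, y)
  # mirrored semantics for the downward map
  m2 <- map2_params(phi_L = 2, phi_0 = 4)
  x2 <- run_uncoupled_intermittent(m2, 2e4, burst_end = 1, seed = 6)
  expect_true(min(x2) >= 1)
  # inconsistent bounds are refused
  expect_error(run_uncoupled_intermittent(m, 100, burst_end = 0.1),
               "burst_end")
  expect_error(run_uncoupled_intermittent(m2, 100, burst_end = 5),
               "burst_end")
})
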