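test_that("power-law rate reduces to known closed forms", {
  # k = 1 is a constant hazard u at any age
  expect_equal(asr_power_law(10, u = 0.5, k = 1), 0.5)
  expect_equal(asr_power_law(0, u = 0.5, k = 1), 0.5)
  # t = 0 with k > 1 gives zero rate
  expect_equal(asr_power_law(0, u = 0.02, k = 6), 0)
  # direct gamma-free arithmetic at integer k: u^6 t^5 / 5!
  expect_equal(asr_power_law(80, u = 0.02, k = 6),
               0.02^6 * 80^5 / 120, tolerance = 1e-12)
  # divergent and malformed inputs are rejected
  expect_error(asr_power_law(0, u = 0.02, k = 0.8), "diverges")
  expect_error(asr_power_law(NaN, u = 0.02, k = 6))
  expect_error(asr_power_law(10, u = -0.1, k = 6))
})

test_that("senescence rate vanishes at support endpoints and reduces to the power law at b = 0", {
  p <- model_params(u = 0.03, k = 7, b = 0.0095)
  expect_equal(asr_senescence(0, p), 0)
  expect_equal(asr_senescence(1 / p$b, p), 0)
  expect_equal(asr_senescence(1 / p$b + 10, p), 0)   # truncated, not negative
  tgrid <- seq(1, 100, by = 7)
  expect_true(all(asr_senescence(tgrid, p) >= 0))
  set.seed(401)
  for (i in 1:20) {
    u <- runif(1, 0.005, 0.05); k <- runif(1, 1.2, 11); tt <- runif(1, 1, 110)
    expect_equal(asr_senescence(tt, model_params(u = u, k = k, b = 0)),
                 asr_power_law(tt, u, k), tolerance = 1e-12)
  }
})

test_that("fitted bladder-cancer parameters reproduce the published peak rate", {
  # male BLCA: u = 0.040, k = 9, b = 0.0098; printed model peak 380 per 1e5
  p <- model_params(u = 0.040, k = 9, b = 0.0098)
  pk <- model_peak(p)
  expect_lt(abs(pk$rate - 380) / 380, 0.15)  # printed u rounding enters as u^9
  expect_lt(abs(pk$age - 91.0), 0.5)
})

test_that("factor decomposition multiplies back to the rate", {
  set.seed(402)
  for (i in 1:10) {
    p <- model_params(u = runif(1, 0.005, 0.05), k = runif(1, 1.5, 11),
                      b = runif(1, 0.006, 0.02))
    tt <- runif(5, 1, 0.95 / p$b)
    f <- asr_factors(tt, p)
    expect_equal(f$A * f$B * f$C, asr_senescence(tt, p), tolerance = 1e-12)
  }
  p <- model_params(u = 0.02, k = 6, b = 0.01)
  f0 <- asr_factors(0, p)
  expect_equal(f0$C, 1)                       # suppression is unity at birth
  expect_equal(f0$A, 0.02^6 / 120, tolerance = 1e-12)
})

test_that("two-variable model is the senescence model with u = c*k - d", {
  tv <- two_variable_constants()
  expect_error(asr_two_variable(50, k = tv$d / tv$c, consts = tv), "undefined")
  expect_error(asr_two_variable(50, k = 1, consts = tv), "undefined")
  set.seed(403)
  for (k in c(2.5, 4, 7, 9)) {
    tt <- runif(4, 1, 100)
    expect_equal(asr_two_variable(tt, k, tv),
                 asr_senescence(tt, model_params(u = tv$c * k - tv$d,
                                                 k = k, b = tv$b)),
                 tolerance = 1e-12)
  }
  # published lifetime probability sequence; k = 2 is skipped because
  # u = 2c - d nearly cancels, so rounding of the printed constants
  # dominates there; k = 8 tolerance reflects rounding propagated via u^k
  pc <- vapply(c(3, 4, 6, 8), function(k)
    cumulative_probability(model_params(u = tv$c * k - tv$d, k = k, b = tv$b)),
    0)
  expect_equal(pc[1], 0.0055, tolerance = 0.05)
  expect_equal(pc[2], 0.0075, tolerance = 0.05)
  expect_equal(pc[3], 0.0094, tolerance = 0.05)
  expect_equal(pc[4], 0.011, tolerance = 0.13)
  # lifetime probability increases with complexity over k in [2, 8]
  kk <- seq(2, 8, by = 0.5)
  pck <- vapply(kk, function(k)
    cumulative_probability(model_params(u = tv$c * k - tv$d, k = k, b = tv$b)),
    0)
  expect_true(all(diff(pck) > 0))
})

test_that("both peak-age expressions match their published uses", {
  # illustrative sequence follows k/(b(k+1))
  expect_equal(round(peak_age_formula(c(2, 3, 4, 6, 8), 0.0099)),
               c(67, 76, 81, 87, 90))
  expect_equal(peak_age_formula(1, 0.01), 50)
  expect_error(peak_age_formula(4, 0), "no finite peak")
  # table-style peak age follows the true argmax (k-1)/(bk)
  p <- model_params(u = 0.040, k = 9, b = 0.0098)
  expect_equal(peak_age_argmax(p), 8 / (0.0098 * 9), tolerance = 1e-12)
  expect_lt(abs(peak_age_argmax(p) - 91.0), 0.5)   # printed male BLCA peak age
  expect_equal(peak_age_argmax(model_params(u = 0.02, k = 2, b = 0.01)), 50)
  expect_error(peak_age_argmax(model_params(u = 0.02, k = 1, b = 0.01)),
               "no interior maximum")
})

test_that("analytic peak age agrees with a dense grid search", {
  set.seed(404)
  for (i in 1:50) {
    k <- runif(1, 1.2, 12); b <- runif(1, 0.005, 0.03)
    p <- model_params(u = 0.02, k = k, b = b)
    grid <- seq(0.01, 1 / b, length.out = 4000)
    t_grid <- grid[which.max(asr_senescence(grid, p))]
    expect_lt(abs(peak_age_argmax(p) - t_grid), diff(grid[1:2]) * 1.5)
  }
})

test_that("closed-form lifetime probability matches adaptive quadrature", {
  set.seed(405)
  for (i in 1:50) {
    p <- model_params(u = runif(1, 0.001, 0.05), k = runif(1, 1.2, 12),
                      b = runif(1, 0.005, 0.03))
    quad <- integrate(asr_senescence, 0, 1 / p$b, params = p,
                      rel.tol = 1e-9)$value
    expect_equal(cumulative_probability(p), quad, tolerance = 1e-6)
  }
  # degenerate senescence slope: undefined, mirrors NaN table entries
  pn <- model_params(u = 7e-06, k = 1.33, b = -0.0168)
  expect_warning(out <- cumulative_probability(pn), "undefined")
  expect_true(is.nan(out))
})

test_that("senescence-induced lifetime-risk reduction equals k/(k+1)", {
  for (k in c(0.7, 2, 3, 4, 6, 8, 11.3))
    expect_equal(senescence_reduction(k), k / (k + 1), tolerance = 1e-10)
  expect_equal(senescence_reduction(4), 0.80, tolerance = 1e-10)
  expect_equal(senescence_reduction(3), 0.75, tolerance = 1e-10)
  expect_gt(senescence_reduction(1e6), 0.999999)
  # independent of the b used for the integration limit
  expect_equal(senescence_reduction(5, b = 0.02), senescence_reduction(5, b = 0.005))
})

test_that("amplitude and transition rate are exact inverses", {
  set.seed(406)
  for (i in 1:100) {
    u <- runif(1, 1e-4, 0.06); k <- runif(1, 0.6, 15)
    expect_equal(u_from_a(a_from_u(u, k), k), u, tolerance = 1e-10)
  }
  expect_equal(u_from_a(0.37, 1), 0.37)   # gamma(1) = 1
  # printed male ACC parameters: amplitude regenerates the curve scale
  a_acc <- a_from_u(0.011, 6.44)
  expect_equal(u_from_a(a_acc, 6.44), 0.011, tolerance = 1e-10)
})

test_that("combined lifetime risk follows the independence complement rule", {
  expect_equal(lifetime_risk_any(numeric(0)), 0)
  expect_equal(lifetime_risk_any(c(0.5, 0.5)), 0.75)
  expect_error(lifetime_risk_any(c(0.2, 1)), "< 1")
  set.seed(407)
  pcs <- runif(8, 0, 0.3)
  r <- lifetime_risk_any(pcs)
  expect_gte(r, max(pcs))
  expect_gt(lifetime_risk_any(pcs + 0.01), r)   # monotone in each argument
})
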