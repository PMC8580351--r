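fx <- paper_fixture_tables()

test_that("parameter summaries reproduce the published mean/SD/n triplets", {
  s <- summarize_parameter(fx$pooled, "b", "non_repro_core")
  expect_equal(s$n, 21)
  expect_equal(s$mean, 0.00991, tolerance = 1e-5 / 0.00991)
  s2 <- summarize_parameter(fx$pooled, "b", "non_repro_core_no_read")
  expect_equal(s2$n, 20)
  expect_equal(s2$mean, 0.0100, tolerance = 5e-5 / 0.0100)
  s3 <- summarize_parameter(fx$female, "b", "reproductive")
  expect_equal(s3$n, 5)
  expect_equal(s3$mean, 0.0117, tolerance = 5e-5 / 0.0117)
  expect_equal(s3$sd, 0.0008, tolerance = 5e-5 / 0.0008)
  s4 <- summarize_parameter(fx$female, "b", "non_repro_core_no_read")
  expect_equal(s4$mean, 0.0098, tolerance = 5e-5 / 0.0098)
  s5 <- summarize_parameter(fx$female, "k", "reproductive")
  expect_equal(s5$mean, 3.7, tolerance = 0.05 / 3.7)
  expect_equal(s5$sd, 1.4, tolerance = 0.05 / 1.4)
  # repeated single value: zero dispersion
  tbl <- data.frame(cancer_code = c("A", "B"), reproductive = FALSE,
                    b = c(0.01, 0.01))
  expect_equal(summarize_parameter(tbl, "b", "all")$sd, 0)
})

test_that("paired tests match the published sex comparisons", {
  res <- paired_parameter_test(fx$male, fx$female, c("u_mu", "k", "b"))
  expect_equal(res$n, rep(20, 3))
  expect_lt(res$p[res$parameter == "u_mu"], 1e-4)          # printed P < 0.0001
  expect_equal(res$p[res$parameter == "k"], 0.0033, tolerance = 0.03)
  # male u is on average about one-third greater than female u
  m <- select_subset(fx$male, "non_repro_core_no_read")
  f <- select_subset(fx$female, "non_repro_core_no_read")
  f <- f[match(m$cancer_code, f$cancer_code), ]
  expect_equal(mean(m$u_mu / f$u_mu), 4 / 3, tolerance = 0.1)
  # Holm adjustment never shrinks a raw P
  expect_true(all(res$p_adj >= res$p))
  # degenerate symmetry cases
  same <- paired_parameter_test(fx$male, fx$male, "u_mu")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ta <- data.frame(cancer_code = c("A", "B"), reproductive = FALSE,
                   x = c(1, 2))
  tb <- data.frame(cancer_code = c("A", "B"), reproductive = FALSE,
                   x = c(1.5, 1.5))                        # differences +/- x
  expect_equal(paired_parameter_test(ta, tb, "x", subset = "all")$t, 0)
})

test_that("Welch test separates reproductive from non-reproductive suppression", {
  w <- welch_t(select_subset(fx$female, "reproductive")$b,
               select_subset(fx$female, "non_repro_core_no_read")$b)
  expect_equal(w$p, 0.002, tolerance = 0.2)                # printed P = 0.002
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # hand-computed Satterthwaite oracle on a textbook two-sample set
  x <- c(19.8, 12.4, 14.9, 16.7, 20.0); y <- c(28.2, 26.0, 20.5, 22.6)
  sx <- var(x) / 5; sy <- var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df_hand <- (sx + sy)^2 / (sx^2 / 4 + sy^2 / 3)
  w2 <- welch_t(x, y)
  expect_equal(w2$t, t_hand, tolerance = 1e-10)
  expect_equal(w2$df, df_hand, tolerance = 1e-10)
})

test_that("rank correlation of peak age with stage number matches the table", {
  core <- select_subset(fx$pooled, "non_repro_core")
  rc <- rank_corr(core$model_peak_age, core$k)
  expect_equal(rc$n, 21)
  expect_equal(rc$estimate, 0.74, tolerance = 0.01)
  expect_lt(rc$p, 0.001)
  seer <- rank_corr(core$seer_peak_age, core$k)
  expect_equal(seer$estimate, 0.62, tolerance = 0.03)      # printed SEER rho
  expect_equal(rank_corr(1:5, 1:5)$estimate, 1)
  expect_equal(linear_corr(1:5, 2 * (1:5) + 3)$estimate, 1)
})

test_that("rank correlation matches the brute-force d-squared formula", {
  x <- c(3, 1, 4, 2)
  perms <- list(c(1,2,3,4), c(2,1,4,3), c(4,3,2,1), c(1,3,2,4), c(3,4,1,2))
  for (y in perms) {
    d <- rank(x) - rank(y)
    rho_hand <- 1 - 6 * sum(d^2) / (4 * (16 - 1))
    expect_equal(rank_corr(x, y)$estimate, rho_hand, tolerance = 1e-12)
  }
})

test_that("correlations are invariant under monotone / affine transforms", {
  set.seed(601)
  x <- rnorm(15); y <- x + rnorm(15)
  expect_equal(rank_corr(x, y)$estimate, rank_corr(exp(x), y^3 + 2 * y)$estimate)
  expect_equal(linear_corr(x, y)$estimate,
               linear_corr(3 * x - 1, -2 * y + 5)$estimate * (-1),
               tolerance = 1e-12)
})

test_that("u~k regression recovers the two-variable constants", {
  reg <- regress_u_on_k(fx$pooled, "non_repro_core")
  expect_equal(reg$n, 21)
  expect_equal(reg$c, 0.0046, tolerance = 0.02)
  expect_equal(reg$d, 0.0087, tolerance = 0.05)   # fixture u rounded to 2 sf
  expect_lt(reg$slope_p, 1e-4)                    # printed P < 0.0001
  # perfectly collinear rows recover the line exactly
  syn <- data.frame(cancer_code = letters[1:5], reproductive = FALSE,
                    k = 2:6, u_mu = 0.005 * (2:6) - 0.009)
  rs <- suppressWarnings(regress_u_on_k(syn, "all"))
  expect_equal(rs$c, 0.005, tolerance = 1e-12)
  expect_equal(rs$d, 0.009, tolerance = 1e-12)
  # slope SE against the closed-form OLS variance on a 5-point set
  xx <- c(1, 2, 3, 4, 5); yy <- c(0.8, 2.3, 2.9, 4.1, 4.6)
  f <- lm(yy ~ xx)
  s2 <- sum(residuals(f)^2) / 3
  se_hand <- sqrt(s2 / sum((xx - mean(xx))^2))
  rg <- regress_u_on_k(data.frame(cancer_code = letters[1:5],
                                  reproductive = FALSE, k = xx, u_mu = yy),
                       "all")
  expect_equal(rg$slope_se, se_hand, tolerance = 1e-12)
})

test_that("ANCOVA finds no sex difference in the u~k trend but detects real ones", {
  m <- select_subset(fx$male, "non_repro_core")
  f <- select_subset(fx$female, "non_repro_core")
  cmp <- compare_slopes(m$k, m$u_mu, f$k, f$u_mu)
  expect_gt(cmp$p_slope, 0.05)
  expect_gt(cmp$p_intercept, 0.05)
  ident <- compare_slopes(1:5, c(1, 2, 3, 4, 5), 1:5, c(1, 2, 3, 4, 5))
  expect_equal(ident$p_slope, 1)
  expect_equal(ident$p_intercept, 1)
  # synthetic pair with a slope difference 5x the noise SE
  set.seed(602)
  x <- rep(1:10, 2); e <- rnorm(20, sd = 0.5)
  y1 <- 1 + 1.0 * (1:10) + e[1:10]
  y2 <- 1 + 3.5 * (1:10) + e[11:20]
  expect_lt(compare_slopes(1:10, y1, 1:10, y2)$p_slope, 0.01)
})

test_that("extrinsic-risk association rank-correlates the ratio columns", {
  rt <- data.frame(cancer_code = letters[1:6],
                   ratio_seer_twovar = c(0.1, 0.5, 1, 2, 5, 40))
  ex_mono <- data.frame(cancer_code = letters[1:6],
                        extrinsic_ratio = c(1, 2, 3, 4, 5, 6))
  expect_equal(extrinsic_association(rt, ex_mono)$estimate, 1)
  ex_anti <- data.frame(cancer_code = letters[1:6],
                        extrinsic_ratio = 6:1)
  expect_equal(extrinsic_association(rt, ex_anti)$estimate, -1)
  # injected rank noise keeps the association strong but below 1
  set.seed(603)
  truth <- rank(rt$ratio_seer_twovar)
  rhos <- replicate(20, {
    noisy <- truth + rnorm(6, sd = 0.8)
    extrinsic_association(rt, data.frame(cancer_code = letters[1:6],
                                         extrinsic_ratio = noisy))$estimate
  })
  expect_gt(median(rhos), 0.5)
  expect_lt(max(rhos), 1 + 1e-12)
})

test_that("lifetime any-cancer risk reproduces the printed 41% / 55%", {
  expect_equal(lifetime_risk_from_table(fx$female, "female"), 0.41,
               tolerance = 0.03 / 0.41)
  expect_equal(lifetime_risk_from_table(fx$male, "male"), 0.55,
               tolerance = 0.03 / 0.55)
})
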