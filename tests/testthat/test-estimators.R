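# Causal estimators: closed-form examples, independent lm() oracles,
# scale equivariance and the robust-method behaviour.

test_that("Wald ratio is beta_y/beta_x with delta-method SE", {
  h <- make_harmonized(bx = 1, by = 0.5, sy = 0.1)
  est <- mr_wald_ratio(h)
  expect_equal(est$theta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$or_per_decrease, exp(-0.5))

  h2 <- make_harmonized(bx = -1, by = 0.5, sy = 0.1)
  est2 <- mr_wald_ratio(h2)
  expect_equal(est2$theta, -0.5)
  expect_equal(est2$se, 0.1)

  expect_error(mr_wald_ratio(make_harmonized(bx = 0, by = 0.5, sy = 0.1)),
               "degenerate", class = "dtmr_validation_error")
})

test_that("IVW matches the hand-computed toy example", {
  h <- make_harmonized(bx = c(1, 1, 1), by = c(0.4, 0.5, 0.6),
                       sy = rep(0.1, 3))
  est <- mr_ivw(h)
  expect_equal(est$theta, 0.5)
  expect_equal(attr(est, "q"), 2.0)
  # Q/(k-1) = 1 so the random-effects inflation is the floor
  expect_equal(est$se, 1 / sqrt(300), tolerance = 1e-12)
  expect_error(mr_ivw(make_harmonized(1, 1, 1)),
               class = "dtmr_not_applicable")
})

test_that("IVW, Egger and Q match the lm() oracles on 200 random instances to 1e-10", {
  set.seed(42)
  for (rep in 1:200) {
    k <- sample(3:10, 1)
    bx <- rnorm(k, 0, 0.1)
    bx[abs(bx) < 1e-3] <- 1e-3
    by <- rnorm(k, 0.4 * bx, 0.05)
    sy <- runif(k, 0.01, 0.2)
    h <- make_harmonized(bx, by, sy)

    ivw <- mr_ivw(h)
    oi <- oracle_ivw(bx, by, sy)
    expect_equal(ivw$theta, oi$theta, tolerance = 1e-10)
    expect_equal(attr(ivw, "se_fixed"), oi$se_fixed, tolerance = 1e-10)
    expect_equal(ivw$se, oi$se_re, tolerance = 1e-10)
    expect_equal(attr(ivw, "q"), oi$q, tolerance = 1e-10)

    q <- cochran_q(h)
    expect_equal(q$q, oi$q, tolerance = 1e-10)

    eg <- mr_egger(h)
    oe <- oracle_egger(bx, by, sy)
    expect_equal(eg$slope$theta, oe$slope, tolerance = 1e-10)
    expect_equal(eg$intercept, oe$intercept, tolerance = 1e-10)
    expect_equal(eg$slope$se, oe$se_slope, tolerance = 1e-10)
    expect_equal(eg$intercept_se, oe$se_intercept, tolerance = 1e-10)
  }
})

test_that("weighted median interpolates correctly and bootstraps an SE", {
  # equal weights, ratios (0.1, 0.2, 0.3): the interpolation formula gives
  # the middle value exactly
  h <- make_harmonized(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3),
                       sy = rep(1, 3))
  est <- mr_weighted_median(h, n_boot = 0)
  expect_equal(est$theta, 0.2)

  # identical ratios collapse to the common value, with a sampling-scale SE
  h2 <- make_harmonized(bx = rep(1, 5), by = rep(0.7, 5), sy = rep(0.1, 5))
  est2 <- mr_weighted_median(h2, n_boot = 500, seed = 1)
  expect_equal(est2$theta, 0.7)
  expect_gt(est2$se, 0)
  expect_lt(abs(est2$se - 0.1 * sqrt(pi / (2 * 5))), 0.05)

  expect_error(mr_weighted_median(make_harmonized(1, 1, 1), n_boot = 0),
               class = "dtmr_not_applicable")
  expect_error(mr_weighted_median(h, n_boot = 100),
               "seed", class = "dtmr_config_error")
})

test_that("weighted median is seed-deterministic", {
  set.seed(9)
  h <- make_harmonized(bx = runif(6, 0.02, 0.1), by = rnorm(6, 0.03, 0.02),
                       sy = runif(6, 0.02, 0.08), sx = rep(0.004, 6))
  a <- mr_weighted_median(h, n_boot = 200, seed = 123)
  b <- mr_weighted_median(h, n_boot = 200, seed = 123)
  expect_identical(a$theta, b$theta)
  expect_identical(a$se, b$se)
})

test_that("weighted mode finds the dominant ratio cluster and resists one outlier", {
  # point mass
  h <- make_harmonized(bx = rep(1, 4), by = rep(0.7, 4), sy = rep(0.1, 4))
  expect_equal(mr_weighted_mode(h, n_boot = 0)$theta, 0.7)

  # 9 ratios near 0.5 plus one down-weighted outlier at 5.0: the KDE argmax
  # stays near 0.5 (dense-grid oracle bound)
  set.seed(21)
  bx <- rep(1, 10)
  by <- c(rnorm(9, 0.5, 0.02), 5.0)
  sy <- c(rep(0.05, 9), 0.5)
  h2 <- make_harmonized(bx, by, sy)
  est <- mr_weighted_mode(h2, n_boot = 0)
  expect_gt(est$theta, 0.4)
  expect_lt(est$theta, 0.6)
})

test_that("Egger recovers an exact line and flags directional pleiotropy", {
  bx <- c(0.02, 0.05, 0.08, 0.11)
  by <- 0.1 + 0.5 * bx
  h <- make_harmonized(bx, by, sy = rep(0.05, 4))
  eg <- mr_egger(h)
  expect_equal(eg$intercept, 0.1, tolerance = 1e-10)
  expect_equal(eg$slope$theta, 0.5, tolerance = 1e-10)
  expect_error(mr_egger(make_harmonized(c(1, 1), c(1, 1), c(1, 1))),
               class = "dtmr_not_applicable")
})

test_that("all estimators are scale-equivariant in the exposure", {
  set.seed(13)
  k <- 9
  bx <- runif(k, 0.02, 0.1)
  by <- rnorm(k, 0.5 * bx, 0.03)
  sy <- runif(k, 0.02, 0.08)
  sx <- rep(0.004, k)
  h1 <- make_harmonized(bx, by, sy, sx)
  c_ <- 3.7
  h2 <- make_harmonized(c_ * bx, by, sy, c_ * sx)
  expect_equal(mr_ivw(h2)$theta, mr_ivw(h1)$theta / c_, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h2, n_boot = 0)$theta,
               mr_weighted_median(h1, n_boot = 0)$theta / c_,
               tolerance = 1e-12)
  expect_equal(mr_egger(h2)$slope$theta, mr_egger(h1)$slope$theta / c_,
               tolerance = 1e-12)
  expect_equal(mr_raps(h2, loss = "l2")$estimate$theta,
               mr_raps(h1, loss = "l2")$estimate$theta / c_,
               tolerance = 1e-8)
})

test_that("single-instrument IVW formula reduces to the Wald ratio", {
  # the IVW closed form with k = 1 collapses to beta_y/beta_x; checked via
  # a duplicated instrument whose weight halves cancel
  h1 <- make_harmonized(bx = 0.05, by = 0.03, sy = 0.04)
  wald <- mr_wald_ratio(h1)
  h2 <- make_harmonized(bx = rep(0.05, 2), by = rep(0.03, 2),
                        sy = rep(0.04, 2))
  ivw <- mr_ivw(h2)
  expect_equal(ivw$theta, wald$theta, tolerance = 1e-12)
})

test_that("mr_all runs the applicable battery and marks the rest", {
  h1 <- make_harmonized(bx = 0.05, by = 0.03, sy = 0.04)
  b1 <- mr_all(h1, n_boot = 50, seed = 1)
  expect_named(b1$estimates, "wald")
  expect_setequal(names(b1$not_applicable),
                  c("ivw_re", "weighted_median", "weighted_mode", "egger",
                    "raps"))

  set.seed(4)
  h3 <- make_harmonized(bx = runif(5, 0.02, 0.1), by = rnorm(5, 0.02, 0.01),
                        sy = runif(5, 0.02, 0.08), sx = rep(0.004, 5))
  b3 <- mr_all(h3, n_boot = 50, seed = 1)
  expect_setequal(names(b3$estimates),
                  c("ivw_re", "weighted_median", "weighted_mode", "egger",
                    "raps"))
  expect_named(b3$not_applicable, "wald")
  tab <- as.data.frame(b3)
  expect_equal(nrow(tab), 6)
  # OR columns are always the exp(-theta) transform
  ok <- !is.na(tab$theta)
  expect_equal(tab$or_per_decrease[ok], exp(-tab$theta[ok]), tolerance = 1e-12)
})
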