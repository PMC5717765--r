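test_that("Wald ratios divide outcome by exposure effects with delta SE", {
  r <- wald_ratio(0.1, 0.01, 0.2, 0.05)
  expect_equal(r$theta, 2.0)
  expect_equal(r$se_theta, 0.5)
  expect_equal(r$weight, r$se_theta^-2)
  expect_equal(wald_ratio(-0.1, 0.01, 0.2, 0.05)$theta, -2.0)
  expect_error(wald_ratio(0, 0.01, 0.2, 0.05), "undefined ratio")

  set.seed(5)
  bx <- runif(10, 0.02, 0.2) * sample(c(-1, 1), 10, TRUE)
  by <- rnorm(10); sy <- runif(10, 0.01, 0.1)
  r10 <- wald_ratio(bx, 0.01, by, sy)
  expect_equal(r10$theta, by / bx)
  expect_equal(r10$se_theta, sy / abs(bx))
})

test_that("IVW pools ratios by inverse variance and handles degeneracy", {
  # two equal-precision ratios 1 and 3 average to 2
  iv <- make_instruments(c(1, 1), c(0.1, 0.1), c(1, 3), c(0.2, 0.2))
  est <- mr_ivw(iv)
  expect_equal(est$beta, 2)
  expect_equal(est$se, sum((0.2)^-2 * c(1, 1))^-0.5)
  expect_equal(est$ci_low, est$beta - qnorm(0.975) * est$se)

  # identical ratios give that constant, any weights
  iv2 <- make_instruments(c(0.5, 1, 2), c(0.1, 0.1, 0.1),
                          c(0.5, 1, 2) * 1.7, c(0.1, 0.3, 0.9))
  expect_equal(mr_ivw(iv2)$beta, 1.7)

  # single variant degenerates to the labelled Wald ratio
  one <- make_instruments(0.1, 0.01, 0.2, 0.05)
  est1 <- mr_ivw(one)
  expect_equal(est1$method, "wald_ratio")
  expect_equal(est1$beta, 2)
  expect_equal(est1$se, 0.5)
})

test_that("IVW equals zero-intercept weighted least squares", {
  set.seed(42)
  for (i in 1:100) {
    iv <- random_instruments(n = sample(3:15, 1))
    wls <- lm(beta_outcome ~ 0 + beta_exposure, data = as.data.frame(iv),
              weights = iv$se_outcome^-2)
    expect_equal(mr_ivw(iv)$beta, unname(coef(wls)), tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the inverse-variance-weighted CDF", {
  # odd n, equal weights: ordinary median
  iv <- make_instruments(c(1, 1, 1), c(0.1, 0.1, 0.1), c(1, 2, 10),
                         c(0.5, 0.5, 0.5))
  expect_equal(mr_weighted_median(iv, n_boot = 50, seed = 1)$beta, 2)

  # even n, equal weights: midpoint by interpolation
  iv4 <- make_instruments(rep(1, 4), rep(0.1, 4), c(1, 2, 3, 4), rep(0.5, 4))
  expect_equal(mr_weighted_median(iv4, n_boot = 50, seed = 1)$beta, 2.5)

  # matches the grid oracle on random weighted fixtures
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    th <- rnorm(n); w <- runif(n, 0.1, 5)
    iv_r <- make_instruments(rep(1, n), rep(0.1, n), th, w^-0.5)
    expect_equal(mr_weighted_median(iv_r, n_boot = 2, seed = 1)$beta,
                 grid_weighted_median(th, w), tolerance = 1e-10)
  }

  # a dominant-weight variant pins the estimate inside its bracket
  th <- c(-3, 0.5, 4)
  w <- c(0.2, 0.7, 0.1)
  ivd <- make_instruments(rep(1, 3), rep(0.1, 3), th, w^-0.5)
  est <- mr_weighted_median(ivd, n_boot = 2, seed = 1)$beta
  expect_gte(est, -3); expect_lte(est, 4)
  expect_lt(abs(est - 0.5), 3.5)  # within the bracket containing theta_2

  expect_error(mr_weighted_median(make_instruments(c(1, 1), c(.1, .1),
                                                   c(1, 2), c(.5, .5))),
               "at least 3")

  # equal weights + odd n equals the sample median on random fixtures
  for (i in 1:10) {
    n <- sample(c(5, 7, 9, 11), 1)
    th <- rnorm(n)
    ive <- make_instruments(rep(1, n), rep(0.1, n), th, rep(0.3, n))
    expect_equal(mr_weighted_median(ive, n_boot = 2, seed = 1)$beta,
                 median(th))
  }
})

test_that("penalisation down-weights outliers and vanishes when homogeneous", {
  # all ratios equal: penalised == unpenalised
  ivh <- make_instruments(rep(1, 5), rep(0.1, 5), rep(1.3, 5),
                          runif(5, 0.1, 0.5))
  expect_equal(mr_penalized_weighted_median(ivh, n_boot = 20, seed = 2)$beta,
               mr_weighted_median(ivh, n_boot = 20, seed = 2)$beta)

  # one gross outlier among 20 concordant variants is crushed
  th <- c(rep(0.3, 20), 25)
  iv <- make_instruments(rep(1, 21), rep(0.05, 21), th, rep(0.1, 21))
  r <- mrkit:::ratios_from_set(iv)
  wstar <- mrkit:::penalized_weights(r$theta, r$weight, 20)
  expect_lt(wstar[21], 0.05 * r$weight[21])
  expect_equal(wstar[1:20], r$weight[1:20])

  # enormous penalty scale recovers the plain weighted median
  ivr <- random_instruments(9)
  expect_equal(mr_penalized_weighted_median(ivr, penalty_scale = 1e12,
                                            n_boot = 2, seed = 3)$beta,
               mr_weighted_median(ivr, n_boot = 2, seed = 3)$beta)
})

test_that("MR-Egger recovers slope and intercept on exact data", {
  set.seed(9)
  bx <- runif(8, 0.05, 0.2) * sample(c(-1, 1), 8, TRUE)
  sy <- runif(8, 0.01, 0.05)

  # noiseless line through origin
  iv <- make_instruments(bx, 0.01, 0.4 * bx, sy)
  eg <- mr_egger(iv)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(eg$overdispersion_factor, 1)

  # noiseless affine relation after orientation
  bxp <- abs(bx)
  iv2 <- make_instruments(bxp, 0.01, 0.02 + 0.4 * bxp, sy)
  eg2 <- mr_egger(iv2)
  expect_equal(eg2$slope$beta, 0.4, tolerance = 1e-10)
  expect_equal(eg2$intercept$estimate, 0.02, tolerance = 1e-10)

  # orientation step is idempotent: pre-flipping some variants changes nothing
  iv3 <- as.data.frame(iv2)
  flip <- c(1, 4, 6)
  iv3$beta_exposure[flip] <- -iv3$beta_exposure[flip]
  iv3$beta_outcome[flip] <- -iv3$beta_outcome[flip]
  eg3 <- mr_egger(instrument_set(iv3))
  expect_equal(eg3$slope$beta, eg2$slope$beta)
  expect_equal(eg3$intercept$estimate, eg2$intercept$estimate)

  expect_error(mr_egger(make_instruments(c(1, 1), c(.1, .1), c(1, 2),
                                         c(.5, .5))), "at least 3")
})

test_that("MR-Egger intercept recovers planted directional pleiotropy", {
  set.seed(123)
  n <- 100
  gamma <- runif(n, 0.05, 0.15)
  alpha <- rnorm(n, 0.02, 0.005)
  sy <- runif(n, 0.01, 0.02)
  by <- rnorm(n, 0.3 * gamma + alpha, sy)
  iv <- make_instruments(gamma, 0.005, by, sy)
  eg <- mr_egger(iv)
  expect_lt(abs(eg$intercept$estimate - 0.02), 3 * eg$intercept$se)
})

test_that("estimators are equivariant under sign and scale changes", {
  set.seed(77)
  seed <- 99
  for (i in 1:10) {
    iv <- random_instruments(n = 9)
    neg <- as.data.frame(iv); neg$beta_outcome <- -neg$beta_outcome
    sc <- as.data.frame(iv)
    sc$beta_exposure <- 4 * sc$beta_exposure
    sc$se_exposure <- 4 * sc$se_exposure
    for (fn in list(mr_ivw,
                    function(x) mr_weighted_median(x, n_boot = 2,
                                                   seed = seed),
                    function(x) mr_penalized_weighted_median(
                      x, n_boot = 2, seed = seed))) {
      b <- fn(iv)$beta
      expect_equal(fn(instrument_set(neg))$beta, -b, tolerance = 1e-12)
      expect_equal(fn(instrument_set(sc))$beta, b / 4, tolerance = 1e-12)
    }
  }
})

test_that("odds-ratio conversion rescales units and preserves the p-value", {
  est <- mr_ivw(random_instruments(6))
  expect_equal(to_odds_ratio(est)$pvalue, est$pvalue)

  null_est <- mrkit:::causal_estimate("ivw", 0, 0.1, 5)
  expect_equal(to_odds_ratio(null_est, unit_scale = 7)$or, 1.0)

  est89 <- mrkit:::causal_estimate("ivw", log(0.89), 0.02, 10)
  expect_equal(to_odds_ratio(est89)$or, 0.89)

  # per-unit to per-10-unit rescaling
  or1 <- to_odds_ratio(est, unit_scale = 1)
  or10 <- to_odds_ratio(est, unit_scale = 10)
  expect_equal(or10$or, or1$or^10)
  expect_equal(or10$pvalue, or1$pvalue)
  expect_error(to_odds_ratio(est, unit_scale = 0))
})
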