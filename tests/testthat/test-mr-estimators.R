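test_that("IVW equals the zero-intercept WLS oracle and handles weights", {
  # equal SEs -> unweighted mean of the ratios
  ins <- make_instruments(bx = c(0.1, 0.1), sx = 0.01,
                          by = c(0.1, 0.3), sy = 0.05)
  expect_equal(mr_ivw(ins)$beta, 2)

  # duplicated instrument: estimate unchanged
  one <- make_instruments(0.1, 0.01, 0.25, 0.05)
  dup <- do.call(rbind, replicate(6, one, simplify = FALSE))
  dup$variant_id <- paste0("v", 1:6)
  expect_equal(mr_ivw(dup)$beta, 2.5)

  # 8 hand-set instruments vs an independent normal-equations WLS solve
  set.seed(8)
  ins8 <- make_instruments(bx = runif(8, 0.03, 0.1), sx = 0.005,
                           by = rnorm(8, 0.02, 0.01),
                           sy = runif(8, 0.004, 0.01))
  w <- 1 / ins8$se_outcome^2
  slope_wls <- sum(w * ins8$beta_exposure * ins8$beta_outcome) /
    sum(w * ins8$beta_exposure^2)
  expect_equal(mr_ivw(ins8)$beta, slope_wls, tolerance = 1e-10)
  expect_equal(mr_ivw(ins8, "fixed")$beta, slope_wls, tolerance = 1e-10)
  # fixed-effect SE is the analytic inverse-variance form
  iw <- 1 / (ins8$se_outcome / ins8$beta_exposure)^2
  expect_equal(mr_ivw(ins8, "fixed")$se, 1 / sqrt(sum(iw)), tolerance = 1e-12)

  expect_error(mr_ivw(one), "insufficient-instruments")
})

test_that("Egger fits exact lines and reduces to IVW without intercept", {
  bx <- c(0.02, 0.05, 0.08, 0.1)
  ins <- make_instruments(bx, 0.005, by = 0.1 + 0.5 * bx, sy = 0.01)
  e <- mr_egger(ins)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)

  # with the intercept constrained to zero the slope is the IVW slope
  w <- 1 / ins$se_outcome^2
  slope0 <- sum(w * ins$beta_exposure * ins$beta_outcome) /
    sum(w * ins$beta_exposure^2)
  expect_equal(mr_ivw(ins)$beta, slope0, tolerance = 1e-12)

  expect_error(mr_egger(ins[1:2, ]), "insufficient-instruments")
  neg <- ins; neg$beta_exposure[1] <- -0.02
  expect_error(mr_egger(neg), "beta_exposure > 0")
})

test_that("Egger intercept test is calibrated and recovers directional bias", {
  # balanced pleiotropy: nominal-level type-I error of the intercept test
  rejections <- 0L
  ints <- c()
  set.seed(314)
  for (i in 1:100) {
    bx <- runif(50, 0.03, 0.12)
    alpha_true <- 0.02
    by_null <- 0.3 * bx + rnorm(50, 0, 0.02)           # balanced
    by_dir <- alpha_true + 0.3 * bx + rnorm(50, 0, 0.02)  # directional
    ins0 <- make_instruments(bx, 0.005, by_null, 0.01)
    ins1 <- make_instruments(bx, 0.005, by_dir, 0.01)
    rejections <- rejections + (mr_egger(ins0)$intercept_pvalue < 0.05)
    ints <- c(ints, mr_egger(ins1)$intercept)
  }
  expect_gte(rejections / 100, 0.01)
  expect_lte(rejections / 100, 0.11)
  # mean recovered intercept within 2 MC-SEs of the truth
  expect_lt(abs(mean(ints) - 0.02), 2 * sd(ints) / sqrt(length(ints)))
})

test_that("weighted median matches the fine-grid interpolation oracle", {
  ins <- make_instruments(bx = rep(0.1, 3), sx = 0.01,
                          by = 0.1 * c(1, 2, 9), sy = 0.05)
  expect_equal(mr_weighted_median(ins, n_boot = 200, seed = 1)$beta, 2)

  # a dominant instrument (> 50% of weight) pins the estimate at its own
  # ratio (up to the interpolation step across its weight interval)
  dom <- make_instruments(bx = rep(0.1, 3), sx = 0.01,
                          by = 0.1 * c(1, 5, 9),
                          sy = c(0.005, 0.2, 0.2))
  expect_equal(mr_weighted_median(dom, n_boot = 200, seed = 1)$beta, 1,
               tolerance = 0.01)

  # 7 unequal-weight instruments vs a dense-grid inversion of the
  # piecewise-linear weighted CDF
  set.seed(77)
  ins7 <- make_instruments(bx = runif(7, 0.05, 0.1), sx = 0.005,
                           by = rnorm(7, 0.03, 0.02),
                           sy = runif(7, 0.005, 0.02))
  theta <- ins7$beta_outcome / ins7$beta_exposure
  w <- (ins7$beta_exposure / ins7$se_outcome)^2
  ord <- order(theta)
  cum <- (cumsum(w[ord]) - w[ord] / 2) / sum(w)
  grid <- seq(min(theta), max(theta), by = 1e-6)
  cdf <- approx(theta[ord], cum, xout = grid)$y
  oracle <- grid[which.min(abs(cdf - 0.5))]
  est <- mr_weighted_median(ins7, n_boot = 200, seed = 1)$beta
  expect_equal(est, oracle, tolerance = 1e-5)

  expect_warning(mr_weighted_median(ins, n_boot = 50, seed = 1), "n_boot")
})

test_that("mode estimators match a brute-force dense-grid argmax", {
  # degenerate: all ratios identical
  same <- make_instruments(bx = rep(0.1, 4), sx = 0.01,
                           by = rep(0.07, 4), sy = 0.01)
  m0 <- mr_mode(same, weighted = FALSE, n_boot = 100, seed = 1)
  expect_equal(m0$beta, 0.7)
  expect_equal(m0$se, 0)

  # symmetric configuration: mode at the centre, within one grid step
  sym <- make_instruments(bx = rep(0.1, 3), sx = 0.01,
                          by = c(-0.1, 0, 0.1), sy = 0.05)
  h_sym <- 0.9 * mad(c(-1, 0, 1)) * 3^(-1 / 5)
  step_sym <- (2 + 6 * h_sym) / 511
  expect_lt(abs(mr_mode(sym, n_boot = 100, seed = 1)$beta), step_sym)

  # 9 hand-set instruments vs a 1e5-point grid oracle
  set.seed(9)
  ins9 <- make_instruments(bx = runif(9, 0.05, 0.12), sx = 0.005,
                           by = rnorm(9, 0.04, 0.02),
                           sy = runif(9, 0.005, 0.02))
  for (weighted in c(FALSE, TRUE)) {
    theta <- ins9$beta_outcome / ins9$beta_exposure
    w <- if (weighted) (ins9$beta_exposure / ins9$se_outcome)^2 else rep(1, 9)
    w <- w / sum(w)
    h <- 0.9 * mad(theta) * 9^(-1 / 5)
    grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 1e5)
    dens <- colSums(outer(theta, grid, function(t, x) dnorm(x, t, h)) * w)
    oracle <- grid[which.max(dens)]
    est <- mr_mode(ins9, weighted = weighted, n_boot = 100, seed = 1)$beta
    step <- diff(range(grid)) / 511  # one grid step of the estimator
    expect_lt(abs(est - oracle), step + 1e-12)
  }
})

test_that("Cochran's Q, I2 and mean F match hand arithmetic", {
  same <- make_instruments(bx = rep(0.1, 4), sx = 0.01,
                           by = rep(0.05, 4), sy = 0.02)
  q0 <- cochrans_q(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$I2, 0)

  two <- make_instruments(bx = c(1, 1), sx = 0.1, by = c(0, 2), sy = 1)
  q2 <- cochrans_q(two, beta_ref = 1)
  expect_equal(q2$Q, 2)
  expect_equal(q2$df, 1)

  one <- make_instruments(0.05, 0.005, 0.01, 0.01)
  expect_equal(mean_f_statistic(one), 100)
  dup <- do.call(rbind, replicate(5, one, simplify = FALSE))
  expect_equal(mean_f_statistic(dup), 100)
  # matches the direct per-variant computation on simulated instruments
  set.seed(10)
  ins <- make_instruments(bx = runif(10, 0.02, 0.1), sx = runif(10, 0.004, 0.01),
                          by = 0, sy = 0.01)
  expect_equal(mean_f_statistic(ins),
               mean((ins$beta_exposure / ins$se_exposure)^2))
})

test_that("Q follows chi-square(J-1) under a single mechanism", {
  set.seed(55)
  qs <- replicate(500, {
    bx <- runif(30, 0.04, 0.12)
    sx <- rep(0.002, 30)
    sy <- rep(0.006, 30)
    ins <- make_instruments(bx + rnorm(30, 0, sx), sx,
                            0.4 * bx + rnorm(30, 0, sy), sy)
    cochrans_q(ins)$Q
  })
  ks <- ks.test(qs, pchisq, df = 29)
  expect_gt(ks$p.value, 0.01)
})

test_that("odds-ratio conversion and estimator-suite invariances", {
  or0 <- to_odds_ratio(0, 0.1)
  expect_equal(or0$or, 1)
  expect_equal(or0$ci_low * or0$ci_high, 1, tolerance = 1e-12)
  or2 <- to_odds_ratio(log(2), 0.1)
  expect_equal(or2$or, 2)
  expect_equal(or2$ci_low, exp(log(2) - 1.96 * 0.1))
  expect_equal(to_odds_ratio(-0.3, 0.1)$or, 1 / to_odds_ratio(0.3, 0.1)$or)

  # all five estimators are invariant to instrument ordering and to a
  # joint sign-flip plus re-harmonization of any subset
  set.seed(12)
  n <- 20
  ins <- make_instruments(bx = runif(n, 0.03, 0.1), sx = 0.005,
                          by = rnorm(n, 0.02, 0.02),
                          sy = runif(n, 0.005, 0.02))
  base <- mr_all(ins, n_boot = 200, seed = 4)
  perm <- ins[sample(n), ]
  expect_equal(mr_all(perm, n_boot = 200, seed = 4)$beta, base$beta,
               tolerance = 1e-9)
  flipped <- ins
  idx <- c(2, 5, 11)
  flipped$beta_exposure[idx] <- -flipped$beta_exposure[idx]
  flipped$beta_outcome[idx] <- -flipped$beta_outcome[idx]
  # re-harmonize: restore the positive-exposure orientation
  reflip <- flipped$beta_exposure < 0
  flipped$beta_exposure[reflip] <- -flipped$beta_exposure[reflip]
  flipped$beta_outcome[reflip] <- -flipped$beta_outcome[reflip]
  expect_equal(mr_all(flipped, n_boot = 200, seed = 4)$beta, base$beta,
               tolerance = 1e-9)
})

test_that("estimators agree with the truth on strong single-mechanism data", {
  cfg <- sim_config(n_variants = 100, cluster_slopes = 0.3,
                    cluster_weights = 1, null_frac = 0, junk_frac = 0,
                    exposure_effect_mean = 0.08, n_exposure = 500000,
                    n_outcome = 250000, flip_frac = 0.5, seed = 31)
  truth <- simulate_truth(cfg)
  sim <- simulate_sumstats(truth, cfg)
  ins <- harmonize_tables(sim$exposure, sim$outcome)$instruments
  res <- mr_all(ins, n_boot = 300, seed = 2)
  for (i in seq_len(nrow(res))) {
    expect_lt(abs(res$beta[i] - 0.3) / res$se[i], 3)
  }
  expect_gt(res$mean_F[1], 50)
})
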