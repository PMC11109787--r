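test_that("wald_ratio matches closed forms and the Monte-Carlo delta oracle", {
  r <- wald_ratio(0.1, 0.01, 0.2, 0.05)
  expect_equal(r$theta, 2.0)
  expect_equal(r$se, 0.5)
  r2 <- wald_ratio(0.1, 0.01, 0.2, 0.05, order = "second")
  expect_equal(r2$se, sqrt(0.25 + 0.04))

  # Monte-Carlo oracle: sd of by*/bx* over 1e6 draws
  set.seed(99)
  bx_s <- rnorm(1e6, 0.1, 0.01)
  by_s <- rnorm(1e6, 0.2, 0.05)
  mc_sd <- sd(by_s / bx_s)
  expect_lt(abs(r2$se - mc_sd) / mc_sd, 0.02)

  expect_error(wald_ratio(0, 0.01, 0.2, 0.05), "undefined-ratio")
})

test_that("mixture_loglik equals a brute-force per-term summation", {
  # standard normal peak
  one <- make_ratios(0.3, 1)
  expect_equal(mixture_loglik(one, mu = 0.3, pi = c(0, 0, 1),
                              junk_scale = 1),
               log(1 / sqrt(2 * pi)), tolerance = 1e-12)

  # 5 hand-set variants, hand-set params, independent direct summation
  ratios <- make_ratios(c(-0.5, 0.1, 0.4, 0.45, 2.0),
                        c(0.1, 0.2, 0.1, 0.15, 0.3))
  mu <- c(-0.5, 0.4)
  piv <- c(0.2, 0.1, 0.3, 0.4)
  js <- 0.8
  direct <- sum(log(
    piv[1] * dnorm(ratios$theta, 0, ratios$se) +
    piv[2] * dnorm(ratios$theta, 0, sqrt(ratios$se^2 + js^2)) +
    piv[3] * dnorm(ratios$theta, mu[1], ratios$se) +
    piv[4] * dnorm(ratios$theta, mu[2], ratios$se)))
  expect_equal(mixture_loglik(ratios, mu, piv, junk_scale = js), direct,
               tolerance = 1e-12)

  expect_error(mixture_loglik(ratios, mu, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("EM recovers degenerate and closed-form cases", {
  # identical ratios, K = 1 and no competing components: the mean is that
  # value and the likelihood is flat after the first update
  same <- make_ratios(rep(0.7, 8), rep(0.1, 8))
  fit <- em_fit(same, K = 1, n_restarts = 1, include_null = FALSE,
                include_junk = FALSE)
  expect_equal(fit$mu, 0.7, tolerance = 1e-10)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2)
  # with null/junk in the model the answer is unchanged
  fit_nj <- em_fit(same, K = 1, n_restarts = 1, junk_scale = 1)
  expect_equal(fit_nj$mu, 0.7, tolerance = 1e-8)

  # K = 1, no null/junk: mean equals the precision-weighted mean (oracle)
  set.seed(5)
  ratios <- make_ratios(rnorm(20, 0.4, 0.1), runif(20, 0.05, 0.3))
  fit1 <- em_fit(ratios, K = 1, include_null = FALSE, include_junk = FALSE,
                 n_restarts = 1)
  w <- 1 / ratios$se^2
  expect_equal(fit1$mu, sum(w * ratios$theta) / sum(w), tolerance = 1e-6)

  expect_error(em_fit(data.frame(theta = numeric(0), se = numeric(0)),
                      K = 1), "empty input")
})

test_that("EM recovers two separated clusters from synthetic truth", {
  cfg <- sim_config(n_variants = 120, cluster_slopes = c(0.4, -0.6),
                    cluster_weights = c(0.5, 0.5), null_frac = 0,
                    junk_frac = 0, n_exposure = 500000, n_outcome = 250000,
                    flip_frac = 0, palindromic_frac = 0, seed = 11)
  truth <- simulate_truth(cfg)
  sim <- simulate_sumstats(truth, cfg)
  r <- ratio_estimates(harmonize_tables(sim$exposure, sim$outcome)$instruments)
  fit <- em_fit(r, K = 2, seed = 11)
  expect_true(fit$monotone)
  expect_equal(fit$mu[1], -0.6, tolerance = 0.05)
  expect_equal(fit$mu[2], 0.4, tolerance = 0.05)
  # >= 95% of confidently assigned cluster variants recover their mechanism
  map <- fitted_to_truth(fit, cfg$cluster_slopes)
  tl <- truth$label[match(r$variant_id, truth$variant_id)]
  conf <- grepl("^cluster_", fit$assignments)
  fitted_k <- as.integer(sub("cluster_", "", fit$assignments[conf]))
  expect_gte(mean(map[fitted_k] == tl[conf]), 0.95)
})

test_that("EM is monotone, scale-equivariant and relabeling-invariant", {
  set.seed(21)
  theta <- c(rnorm(40, 0.5, 0.05), rnorm(40, -0.3, 0.05), rnorm(20, 0, 0.3))
  ratios <- make_ratios(theta, rep(0.05, 100))
  fit <- em_fit(ratios, K = 2, seed = 2)
  expect_true(fit$monotone)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # responsibilities sum to one per variant
  expect_equal(unname(rowSums(fit$responsibilities)), rep(1, 100),
               tolerance = 1e-9)
  # canonical order ascending
  expect_true(all(diff(fit$mu) > 0))

  # scale equivariance: scaling (theta, se) by c scales the fitted means
  c_ <- 3.7
  fit_sc <- em_fit(make_ratios(theta * c_, rep(0.05 * c_, 100)), K = 2,
                   seed = 2)
  expect_equal(fit_sc$mu, fit$mu * c_, tolerance = 1e-4)
  expect_true(fit_sc$monotone)

  # different restart seeds land on the same canonical labels
  fit_b <- em_fit(ratios, K = 2, seed = 77)
  expect_equal(fit_b$mu, fit$mu, tolerance = 1e-4)
})

test_that("BIC model selection finds the true component count", {
  # single slope -> K = 1 selected in >= 95% of replicates
  hits <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    set.seed(1000 + i)
    ratios <- make_ratios(rnorm(80, 0.5, 0.05), rep(0.05, 80))
    sel <- select_model(ratios, K_max = 3, seed = i, n_restarts = 3)
    hits <- hits + (sel$K == 1L)
  }
  expect_gte(hits / n_rep, 0.95)

  # pure-null data -> K = 0 in >= 90% of replicates
  hits0 <- 0L
  for (i in seq_len(n_rep)) {
    set.seed(2000 + i)
    ratios <- make_ratios(rnorm(80, 0, 0.05), rep(0.05, 80))
    sel <- select_model(ratios, K_max = 2, seed = i, n_restarts = 3)
    hits0 <- hits0 + (sel$K == 0L)
  }
  expect_gte(hits0 / n_rep, 0.90)

  # K_max = 0 returns the degenerate null/junk-only model
  set.seed(1)
  deg <- select_model(make_ratios(rnorm(30), rep(1, 30)), K_max = 0)
  expect_identical(deg$K, 0L)
  expect_length(deg$mu, 0)
})

test_that("assignment applies the 80% membership rule", {
  fake <- list(responsibilities = rbind(c(0.85, 0.10, 0.05),
                                        c(0.79, 0.11, 0.10),
                                        c(0.10, 0.85, 0.05)))
  colnames(fake$responsibilities) <- c("cluster_1", "cluster_2", "null")
  expect_identical(assign_clusters(fake, 0.8),
                   c("cluster_1", "unassigned", "cluster_2"))
  # threshold 1 with non-degenerate rows leaves everything unassigned
  expect_identical(assign_clusters(fake, 1.0), rep("unassigned", 3))
})

test_that("parameter recovery error is bounded across replicates", {
  # two clusters separated by >= 6 combined SEs; mean abs error of the
  # recovered means under 1.5x the average se/sqrt(n_per_cluster)
  errs <- c()
  ses <- c()
  for (i in 1:25) {
    set.seed(3000 + i)
    n_half <- 40
    se_j <- runif(2 * n_half, 0.04, 0.08)
    theta <- c(rnorm(n_half, 0.5, se_j[1:n_half]),
               rnorm(n_half, -0.4, se_j[(n_half + 1):(2 * n_half)]))
    fit <- em_fit(make_ratios(theta, se_j), K = 2, seed = i, n_restarts = 3)
    errs <- c(errs, abs(fit$mu - c(-0.4, 0.5)))
    ses <- c(ses, mean(se_j) / sqrt(n_half))
  }
  expect_lt(mean(errs), 1.5 * mean(ses))
})
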