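mr_estimate_row <- function(method, beta, se, ci_low, ci_high, pvalue, n,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_pvalue = NA_real_) {
  data.frame(method = method, beta = beta, se = se, ci_low = ci_low,
             ci_high = ci_high, pvalue = pvalue, n_instruments = n,
             intercept = intercept, intercept_se = intercept_se,
             intercept_pvalue = intercept_pvalue, stringsAsFactors = FALSE)
}

ivw_weights <- function(instr) {
  theta <- instr$beta_outcome / instr$beta_exposure
  se1 <- instr$se_outcome / abs(instr$beta_exposure)
  list(theta = theta, w = 1 / se1^2)
}

#' Inverse-variance-weighted causal estimate
#'
#' Precision-weighted mean of the per-variant Wald ratios with first-order
#' weights `1/se(theta)^2` — algebraically the zero-intercept weighted
#' regression of outcome on exposure effects with weights `1/se_y^2`. The
#' default variance model is multiplicative random effects: the fixed-effect
#' SE is inflated by `max(1, sqrt(Q/(J-1)))`, which is robust when the
#' per-variant estimates are heterogeneous.
#'
#' @param instr harmonized instruments (>= 2 rows) from
#'   [harmonize_tables()].
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return One-row `MREstimate` data.frame.
#' @export
mr_ivw <- function(instr,
                   variance_model = c("multiplicative_random", "fixed")) {
  variance_model <- match.arg(variance_model)
  J <- nrow(instr)
  if (J < 2) stop("insufficient-instruments error: IVW needs >= 2")
  iw <- ivw_weights(instr)
  beta <- sum(iw$w * iw$theta) / sum(iw$w)
  se <- 1 / sqrt(sum(iw$w))
  if (variance_model == "multiplicative_random") {
    Q <- sum(iw$w * (iw$theta - beta)^2)
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate_row("ivw", beta, se, beta - 1.96 * se, beta + 1.96 * se, p, J)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept,
#' weights `1/se_y^2`, requiring the positive-exposure-effect orientation
#' produced by harmonization. The slope is the causal estimate; a nonzero
#' intercept indicates directional horizontal pleiotropy. Inference uses the
#' t distribution with J - 2 df; coefficient SEs are divided by
#' `min(1, sigma)` so they never fall below the fixed-effect ones.
#'
#' @param instr harmonized instruments (>= 3 rows, all `beta_exposure > 0`).
#' @return One-row `MREstimate` data.frame with intercept fields.
#' @export
mr_egger <- function(instr) {
  J <- nrow(instr)
  if (J < 3) stop("insufficient-instruments error: Egger needs >= 3")
  if (any(instr$beta_exposure <= 0)) {
    stop("Egger requires all beta_exposure > 0 (harmonized orientation)")
  }
  fit <- stats::lm(beta_outcome ~ beta_exposure, data = instr,
                   weights = 1 / instr$se_outcome^2)
  sm <- summary(fit)
  co <- sm$coefficients
  adj <- min(1, sm$sigma)
  b <- co["beta_exposure", "Estimate"]
  b_se <- co["beta_exposure", "Std. Error"] / adj
  a <- co["(Intercept)", "Estimate"]
  a_se <- co["(Intercept)", "Std. Error"] / adj
  tq <- stats::qt(0.975, df = J - 2)
  mr_estimate_row("egger", b, b_se, b - tq * b_se, b + tq * b_se,
                  2 * stats::pt(-abs(b / b_se), df = J - 2), J,
                  intercept = a, intercept_se = a_se,
                  intercept_pvalue = 2 * stats::pt(-abs(a / a_se), df = J - 2))
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(theta[1])
  if (cum[length(cum)] <= 0.5) return(theta[length(theta)])
  below <- max(which(cum < 0.5))
  theta[below] + (theta[below + 1] - theta[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted-median causal estimate
#'
#' Orders the Wald ratios and interpolates where the cumulative normalized
#' IVW weights cross 0.5; consistent when at least half the weight comes
#' from valid instruments. The SE is a parametric bootstrap: each ratio is
#' resampled from `N(theta_j, se_j^2)` (weights fixed) and the median
#' recomputed.
#'
#' @param instr harmonized instruments (>= 3 rows).
#' @param n_boot bootstrap resamples (warning below 100).
#' @param seed bootstrap seed.
#' @return One-row `MREstimate` data.frame.
#' @export
mr_weighted_median <- function(instr, n_boot = 1000, seed = 1) {
  J <- nrow(instr)
  if (J < 3) stop("insufficient-instruments error: weighted median needs >= 3")
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable")
  iw <- ivw_weights(instr)
  se1 <- 1 / sqrt(iw$w)
  beta <- weighted_median_point(iw$theta, iw$w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    weighted_median_point(stats::rnorm(J, iw$theta, se1), iw$w)
  }, numeric(1))
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate_row("weighted_median", beta, se, beta - 1.96 * se,
                  beta + 1.96 * se, p, J)
}

mode_point <- function(theta, w, phi, n_grid = 512) {
  h <- phi * 0.9 * stats::mad(theta) * length(theta)^(-1 / 5)
  if (h == 0) return(theta[1])
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  w <- w / sum(w)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, theta, h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based causal estimate (simple or weighted)
#'
#' The argmax of a normal-kernel-smoothed density of the Wald ratios
#' (uniform kernel weights for the simple mode, IVW weights for the
#' weighted mode), on a 512-point grid spanning the ratio range plus three
#' bandwidths. Bandwidth is `phi` times a modified Silverman rule on the
#' median absolute deviation, `0.9 * mad(theta) * J^(-1/5)`. If all ratios
#' coincide the common value is returned with SE 0; otherwise the SE is a
#' parametric bootstrap as in [mr_weighted_median()].
#'
#' @param instr harmonized instruments (>= 3 rows).
#' @param weighted use IVW weights (weighted mode) or uniform (simple mode).
#' @param phi bandwidth multiplier (> 0, default 1).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return One-row `MREstimate` data.frame.
#' @export
mr_mode <- function(instr, weighted = FALSE, phi = 1, n_boot = 1000,
                    seed = 1) {
  J <- nrow(instr)
  if (J < 3) stop("insufficient-instruments error: mode needs >= 3")
  stopifnot(phi > 0)
  iw <- ivw_weights(instr)
  w <- if (weighted) iw$w else rep(1, J)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  if (stats::mad(iw$theta) == 0 && stats::sd(iw$theta) == 0) {
    return(mr_estimate_row(method, iw$theta[1], 0, iw$theta[1], iw$theta[1],
                           NA_real_, J))
  }
  beta <- mode_point(iw$theta, w, phi)
  se1 <- 1 / sqrt(iw$w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    mode_point(stats::rnorm(J, iw$theta, se1), w, phi)
  }, numeric(1))
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate_row(method, beta, se, beta - 1.96 * se, beta + 1.96 * se, p, J)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - beta_ref)^2` with first-order IVW weights,
#' compared to chi-square with J - 1 df;
#' `I^2 = max(0, (Q - df)/Q)`.
#'
#' @param instr harmonized instruments (>= 2 rows).
#' @param beta_ref reference causal effect; defaults to the fixed-effect
#'   IVW estimate.
#' @return list: `Q`, `df`, `pvalue`, `I2`.
#' @export
cochrans_q <- function(instr, beta_ref = NULL) {
  J <- nrow(instr)
  if (J < 2) stop("insufficient-instruments error: Q needs >= 2")
  iw <- ivw_weights(instr)
  beta_ref <- beta_ref %||% (sum(iw$w * iw$theta) / sum(iw$w))
  Q <- sum(iw$w * (iw$theta - beta_ref)^2)
  df <- J - 1
  list(Q = Q, df = df, pvalue = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = max(0, (Q - df) / Q))
}

#' Mean instrument-strength F statistic
#'
#' Mean over instruments of `(beta_exposure / se_exposure)^2`; values above
#' ~10 (and well above 50 in well-powered GWAS) indicate weak-instrument
#' bias is negligible.
#'
#' @param instr harmonized instruments (>= 1 row).
#' @return Scalar mean F.
#' @export
mean_f_statistic <- function(instr) {
  if (nrow(instr) < 1) stop("insufficient-instruments error: F needs >= 1")
  mean((instr$beta_exposure / instr$se_exposure)^2)
}

#' Convert a log-odds causal estimate to an odds ratio with 95% CI
#'
#' @param beta causal effect on the log-odds scale (per exposure SD).
#' @param se its standard error (> 0).
#' @return list: `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0")
  list(or = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se))
}

#' Run the full MR estimator suite on one instrument set
#'
#' IVW (main), MR-Egger, weighted median, simple mode and weighted mode,
#' plus heterogeneity (Cochran's Q, I-squared) and mean instrument-strength
#' F. Methods whose minimum instrument count is not met are skipped.
#'
#' @param instr harmonized instruments.
#' @param variance_model IVW variance model, see [mr_ivw()].
#' @param n_boot bootstrap resamples for median/mode SEs.
#' @param seed bootstrap seed.
#' @param phi mode bandwidth multiplier.
#' @return data.frame of estimates with columns `or`, `or_ci_low`,
#'   `or_ci_high`, `Q`, `Q_pvalue`, `I2`, `mean_F` appended.
#' @export
mr_all <- function(instr, variance_model = "multiplicative_random",
                   n_boot = 1000, seed = 1, phi = 1) {
  J <- nrow(instr)
  rows <- list()
  if (J >= 2) rows$ivw <- mr_ivw(instr, variance_model)
  if (J >= 3) {
    rows$egger <- mr_egger(instr)
    rows$wm <- mr_weighted_median(instr, n_boot, seed)
    rows$sm <- mr_mode(instr, weighted = FALSE, phi, n_boot, seed + 1L)
    rows$wmode <- mr_mode(instr, weighted = TRUE, phi, n_boot, seed + 2L)
  }
  if (!length(rows)) stop("insufficient-instruments error: need >= 2")
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  or <- to_odds_ratio(est$beta, pmax(est$se, .Machine$double.eps))
  est$or <- or$or
  est$or_ci_low <- or$ci_low
  est$or_ci_high <- or$ci_high
  het <- if (J >= 2) cochrans_q(instr) else
    list(Q = NA_real_, df = NA, pvalue = NA_real_, I2 = NA_real_)
  est$Q <- het$Q
  est$Q_pvalue <- het$pvalue
  est$I2 <- het$I2
  est$mean_F <- mean_f_statistic(instr)
  est
}
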