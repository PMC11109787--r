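#' Per-variant Wald ratio estimate
#'
#' The ratio of the variant's outcome association to its exposure
#' association, with a delta-method standard error. First order:
#' `se = se_y / |beta_x|`. Second order adds the exposure uncertainty:
#' `se = sqrt(se_y^2/beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`.
#'
#' @param bx,sx exposure effect and SE (`bx != 0`, `sx > 0`).
#' @param by,sy outcome effect and SE (`sy > 0`).
#' @param order `"first"` (default) or `"second"`.
#' @return data.frame with `theta`, `se`, `order`; vectorized.
#' @export
wald_ratio <- function(bx, sx, by, sy, order = c("first", "second")) {
  order <- match.arg(order)
  if (any(bx == 0)) stop("undefined-ratio error: beta_exposure = 0")
  if (any(sx <= 0) || any(sy <= 0)) stop("standard errors must be > 0")
  theta <- by / bx
  se <- if (order == "first") sy / abs(bx) else
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  data.frame(theta = theta, se = se, order = order, stringsAsFactors = FALSE)
}

#' Build ratio estimates from harmonized instruments
#'
#' @param instruments data.frame from [harmonize_tables()].
#' @param order delta-method order, see [wald_ratio()].
#' @return data.frame: `variant_id`, `theta`, `se`, `order`.
#' @export
ratio_estimates <- function(instruments, order = c("first", "second")) {
  r <- wald_ratio(instruments$beta_exposure, instruments$se_exposure,
                  instruments$beta_outcome, instruments$se_outcome, order)
  cbind(data.frame(variant_id = instruments$variant_id,
                   stringsAsFactors = FALSE), r)
}

# J x C matrix of component log-densities. Component order:
# null (mean 0, var se_j^2), junk (mean 0, var se_j^2 + junk_scale^2),
# cluster_1..K (mean mu_k, var se_j^2).
component_logdens <- function(theta, se, mu, junk_scale,
                              include_null = TRUE, include_junk = TRUE) {
  cols <- list()
  if (include_null) cols$null <- stats::dnorm(theta, 0, se, log = TRUE)
  if (include_junk) {
    cols$junk <- stats::dnorm(theta, 0, sqrt(se^2 + junk_scale^2), log = TRUE)
  }
  for (k in seq_along(mu)) {
    cols[[paste0("cluster_", k)]] <- stats::dnorm(theta, mu[k], se, log = TRUE)
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

default_junk_scale <- function(theta) {
  s <- if (length(theta) > 1) stats::sd(theta) else 0
  if (!is.finite(s) || s == 0) s <- max(abs(theta), 1e-6)
  2 * s
}

#' Log-likelihood of the mixture of normals over ratio estimates
#'
#' Each variant contributes
#' `log(pi_null N(theta; 0, se^2) + pi_junk N(theta; 0, se^2 + s_junk^2) +
#'  sum_k pi_k N(theta; mu_k, se^2))`,
#' evaluated with log-sum-exp to guard against underflow. Variances are the
#' known per-variant squared SEs (heteroscedastic).
#'
#' @param ratios data.frame with `theta` and `se`.
#' @param mu cluster means (length K, may be empty).
#' @param pi named mixture proportions over `(null, junk, cluster_1..K)`
#'   (drop names for positional order null, junk, clusters); must sum to 1.
#' @param junk_scale junk sd beyond the per-variant SE; default twice the
#'   sample sd of `theta`.
#' @param include_null,include_junk include the special components.
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(ratios, mu, pi, junk_scale = NULL,
                           include_null = TRUE, include_junk = TRUE) {
  if (abs(sum(pi) - 1) > 1e-9) stop("mixture proportions must sum to 1")
  junk_scale <- junk_scale %||% default_junk_scale(ratios$theta)
  ld <- component_logdens(ratios$theta, ratios$se, mu, junk_scale,
                          include_null, include_junk)
  if (length(pi) != ncol(ld)) stop("pi has wrong length for the component set")
  a <- sweep(ld, 2L, log(pi), "+")
  sum(row_log_sum_exp(a))
}

run_em_once <- function(theta, se, mu, pi, junk_scale, include_null,
                        include_junk, tol, max_iter) {
  K <- length(mu)
  J <- length(theta)
  ll_prev <- -Inf
  trace <- numeric(max_iter)
  monotone <- TRUE
  converged <- FALSE
  prec <- 1 / se^2
  # null and junk log-densities never change across iterations
  special <- cbind(
    if (include_null) stats::dnorm(theta, 0, se, log = TRUE),
    if (include_junk) stats::dnorm(theta, 0, sqrt(se^2 + junk_scale^2),
                                   log = TRUE))
  n_special <- if (is.null(special)) 0L else ncol(special)
  # log N(theta_j; mu_k, se_j^2) up to the constant per-variant term
  lconst <- -log(se) - 0.918938533204673  # -log(sqrt(2*pi))
  resp <- NULL
  ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ld_clust <- if (K) {
      matrix(lconst - 0.5 * (outer(theta, mu, "-") / se)^2, J, K)
    }
    a <- cbind(special, ld_clust)
    a <- a + rep(log(pi), each = J)
    ll_j <- row_log_sum_exp(a)
    ll <- sum(ll_j)
    resp <- exp(a - ll_j)
    trace[iter] <- ll
    if (ll < ll_prev - 1e-8) monotone <- FALSE
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    # M-step: proportions are mean responsibilities; means are
    # precision-weighted (known variances se_j^2)
    pi <- pmax(colMeans(resp), 1e-12)
    pi <- pi / sum(pi)
    if (K) {
      wr <- resp[, n_special + seq_len(K), drop = FALSE] * prec
      den <- colSums(wr)
      num <- colSums(wr * theta)
      upd <- den > 1e-12
      mu[upd] <- num[upd] / den[upd]
    }
  }
  list(mu = mu, pi = pi, resp = resp, loglik = ll, trace = trace[seq_len(iter)],
       monotone = monotone, converged = converged, n_iter = iter)
}

#' Fit the mixture-of-normals clustering by EM
#'
#' Maximizes the [mixture_loglik()] over cluster means and mixture
#' proportions, with per-variant variances fixed at the squared ratio SEs.
#' The null component's mean is fixed at 0; the junk component is a broad
#' zero-mean normal absorbing idiosyncratic pleiotropy. Initialization uses
#' the K-quantiles of `theta`; `n_restarts` jittered restarts are run and
#' the best final log-likelihood kept. Cluster labels are canonicalized by
#' sorting the fitted means ascending.
#'
#' @param ratios data.frame with `variant_id` (optional), `theta`, `se`.
#' @param K number of substantive clusters (>= 0).
#' @param seed integer seed for the restart jitter.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of jittered initializations.
#' @param include_null,include_junk include the special components.
#' @param junk_scale junk sd; default twice the sample sd of `theta`.
#' @param threshold membership probability required for assignment.
#' @return A `cluster_model`: `K`, `mu`, `pi`, `responsibilities`,
#'   `assignments`, `loglik`, `bic`, `n_iter`, `converged`, `monotone`,
#'   `loglik_trace`, `junk_scale`, `seed`.
#' @export
em_fit <- function(ratios, K, seed = 1, tol = 1e-8, max_iter = 2000,
                   n_restarts = 10, include_null = TRUE, include_junk = TRUE,
                   junk_scale = NULL, threshold = 0.8) {
  theta <- ratios$theta
  se <- ratios$se
  J <- length(theta)
  if (J == 0) stop("empty input: no ratio estimates")
  if (K < 0) stop("K must be >= 0")
  if (J < K + 1) stop("need at least K + 1 variants")
  if (K == 0 && !include_null && !include_junk) {
    stop("K = 0 requires the null or junk component")
  }
  junk_scale <- junk_scale %||% default_junk_scale(theta)

  n_special <- include_null + include_junk
  C <- K + n_special
  base_mu <- if (K) unname(stats::quantile(theta, (seq_len(K) - 0.5) / K)) else
    numeric(0)
  jitter_sd <- if (J > 1 && stats::sd(theta) > 0) 0.25 * stats::sd(theta) else
    0.1

  set.seed(seed)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    mu0 <- if (r == 1L) base_mu else base_mu + stats::rnorm(K, 0, jitter_sd)
    pi0 <- if (K) {
      c(if (include_null) 0.1, if (include_junk) 0.1,
        rep((1 - 0.1 * n_special) / K, K))
    } else {
      rep(1 / n_special, n_special)
    }
    fit <- run_em_once(theta, se, mu0, pi0, junk_scale, include_null,
                       include_junk, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # canonical order: clusters sorted by mean ascending
  if (K > 1) {
    ord <- order(best$mu)
    coff <- n_special
    best$mu <- best$mu[ord]
    best$pi[(coff + 1):(coff + K)] <- best$pi[coff + ord]
    best$resp[, (coff + 1):(coff + K)] <- best$resp[, coff + ord, drop = FALSE]
  }
  comp_names <- c(if (include_null) "null", if (include_junk) "junk",
                  if (K) paste0("cluster_", seq_len(K)))
  colnames(best$resp) <- comp_names
  names(best$pi) <- comp_names
  if (!is.null(ratios$variant_id)) rownames(best$resp) <- ratios$variant_id

  # free parameters: K means + (C - 1) proportions
  p <- K + (C - 1)
  model <- structure(list(
    K = K,
    mu = unname(best$mu),
    pi = best$pi,
    responsibilities = best$resp,
    loglik = best$loglik,
    bic = -2 * best$loglik + p * log(J),
    n_iter = best$n_iter,
    converged = best$converged,
    monotone = best$monotone,
    loglik_trace = best$trace,
    junk_scale = junk_scale,
    threshold = threshold,
    seed = seed,
    variant_id = ratios$variant_id %||% NA_character_,
    theta = theta,
    se = se
  ), class = "cluster_model")
  model$assignments <- assign_clusters(model, threshold)
  model
}

#' Assign variants to clusters at a membership-probability threshold
#'
#' A variant is labelled with its highest-probability component only when
#' that probability reaches the threshold (default 0.8, the conventional
#' 80% membership rule); otherwise it is `"unassigned"`. Null and junk are
#' reported as their own labels, distinct from substantive clusters.
#'
#' @param model a fitted `cluster_model`.
#' @param threshold membership probability required for assignment.
#' @return Character vector of labels, one per variant.
#' @export
assign_clusters <- function(model, threshold = 0.8) {
  resp <- model$responsibilities
  best <- max.col(resp, ties.method = "first")
  pmax_ <- resp[cbind(seq_len(nrow(resp)), best)]
  lab <- colnames(resp)[best]
  lab[pmax_ < threshold] <- "unassigned"
  lab
}

#' Select the number of clusters by BIC
#'
#' Fits `K = 0..K_max` with [em_fit()] and returns the fit minimizing
#' `BIC = -2 loglik + p log(J)` with `p = K + (K + 1)` free parameters
#' (K means plus the free mixture proportions over null, junk and clusters).
#' Ties break toward smaller K.
#'
#' @inheritParams em_fit
#' @param K_max largest number of substantive clusters to consider.
#' @param criterion only `"bic"` is implemented.
#' @return The selected `cluster_model`, with the per-K BIC table in
#'   `$selection`.
#' @export
select_model <- function(ratios, K_max = 5, seed = 1,
                         criterion = c("bic"), ...) {
  criterion <- match.arg(criterion)
  stopifnot(K_max >= 0)
  best <- NULL
  tab <- data.frame(K = integer(), loglik = numeric(), bic = numeric())
  for (K in 0:K_max) {
    if (length(ratios$theta) < K + 1) break
    fit <- em_fit(ratios, K, seed = seed, ...)
    tab <- rbind(tab, data.frame(K = K, loglik = fit$loglik, bic = fit$bic))
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  best$selection <- tab
  best
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> K =", x$K, " J =", length(x$theta),
      " loglik =", format(x$loglik, digits = 6),
      " BIC =", format(x$bic, digits = 6), "\n")
  if (x$K) cat("  cluster means:", paste(format(x$mu, digits = 4),
                                         collapse = ", "), "\n")
  cat("  proportions:", paste(names(x$pi), format(unname(x$pi), digits = 3),
                              sep = "=", collapse = ", "), "\n")
  cat("  assignments:", paste(names(table(x$assignments)),
                              table(x$assignments), sep = ":",
                              collapse = ", "), "\n")
  invisible(x)
}

#' Cluster results as a flat table
#'
#' @param model a `cluster_model`.
#' @return data.frame: variant_id, theta, se, one probability column per
#'   component, assignment.
#' @export
cluster_table <- function(model) {
  out <- data.frame(variant_id = model$variant_id,
                    theta = model$theta,
                    se = model$se,
                    stringsAsFactors = FALSE)
  probs <- as.data.frame(model$responsibilities)
  names(probs) <- paste0("prob_", names(probs))
  out <- cbind(out, probs)
  out$assignment <- model$assignments
  rownames(out) <- NULL
  out
}
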