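#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-variant aligned effects into a genetic-risk-score effect.
#' Fixed weights `w_j = 1/s_j^2` give Cochran's Q about the fixed-effect
#' mean; the moment estimator
#' `tau2 = max(0, (Q - (J-1)) / (sum(w) - sum(w^2)/sum(w)))`
#' feeds random-effects weights `1/(s_j^2 + tau2)`. A single study is
#' returned unchanged with `tau2 = 0`. `method = "REML"` delegates to
#' \pkg{metafor} when available.
#'
#' @param betas,ses equal-length numeric vectors, `ses > 0`.
#' @param method `"DL"` (default, closed form) or `"REML"`.
#' @return list: `beta`, `se`, `zscore`, `pvalue`, `tau2`, `Q`, `df`, `n`.
#' @export
dl_meta <- function(betas, ses, method = c("DL", "REML")) {
  method <- match.arg(method)
  J <- length(betas)
  if (J == 0) stop("empty input: no effects to pool")
  if (length(ses) != J) stop("betas and ses must have equal length")
  if (any(ses <= 0)) stop("ses must be > 0")
  if (J == 1) {
    z <- betas / ses
    return(list(beta = betas, se = ses, zscore = z,
                pvalue = 2 * stats::pnorm(-abs(z)), tau2 = 0, Q = 0,
                df = 0, n = 1L))
  }
  if (method == "REML") {
    if (!requireNamespace("metafor", quietly = TRUE)) {
      stop("method = 'REML' requires the metafor package")
    }
    fit <- metafor::rma(yi = betas, sei = ses, method = "REML")
    return(list(beta = as.numeric(fit$beta), se = fit$se,
                zscore = fit$zval, pvalue = fit$pval, tau2 = fit$tau2,
                Q = fit$QE, df = J - 1L, n = J))
  }
  w <- 1 / ses^2
  mu_fixed <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - mu_fixed)^2)
  tau2 <- max(0, (Q - (J - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  beta <- sum(ws * betas) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- beta / se
  list(beta = beta, se = se, zscore = z, pvalue = 2 * stats::pnorm(-abs(z)),
       tau2 = tau2, Q = Q, df = J - 1L, n = J)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) stop("empty input: no p-values")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("domain error: p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Cluster-size-standardized z-score
#'
#' `z / sqrt(n_variants)`: a display-only transform that removes the
#' mechanical growth of |z| with the number of variants contributing to a
#' cluster's genetic risk score. Inference always uses the raw z.
#'
#' @param z raw z-score(s).
#' @param n_variants number of contributing variants (>= 1).
#' @return Standardized z.
#' @export
standardized_z <- function(z, n_variants) {
  if (any(n_variants < 1)) stop("n_variants must be >= 1")
  z / sqrt(n_variants)
}

# exposure-increasing allele per variant from the exposure table
increasing_allele <- function(exposure) {
  ifelse(exposure$beta >= 0, exposure$effect_allele, exposure$other_allele)
}

# align one trait record's beta to the wanted allele; exact label matches
# take precedence over strand-complement matches (palindromic pairs match
# both ways, and labels are then authoritative); NULL on mismatch
aligned_trait_effect <- function(rec, wanted_allele) {
  if (rec$effect_allele == wanted_allele) {
    list(beta = rec$beta, se = rec$se)
  } else if (rec$other_allele == wanted_allele) {
    list(beta = -rec$beta, se = rec$se)
  } else if (comp_allele(rec$effect_allele) == wanted_allele) {
    list(beta = rec$beta, se = rec$se)
  } else if (comp_allele(rec$other_allele) == wanted_allele) {
    list(beta = -rec$beta, se = rec$se)
  } else {
    NULL
  }
}

#' Genetic-risk-score trait profile of each cluster
#'
#' For every (cluster, trait) cell: each member variant's trait effect is
#' aligned to the exposure-increasing allele, missing variants are replaced
#' by LD proxies at `r2 >= min_r2` (explicit allele correspondence from the
#' proxy table), and the aligned effects are pooled with [dl_meta()].
#' P-values are Benjamini-Hochberg-adjusted within each cluster across
#' traits; `z_std = z / sqrt(n_variants)` is carried for display. Cells
#' with zero resolvable variants are flagged missing (NA estimates), never
#' fabricated.
#'
#' @param assignments data.frame with `variant_id` and `assignment` (e.g.
#'   from [cluster_table()]), or a named character vector.
#' @param trait_tables named list of `sumstats` tables.
#' @param exposure_table the exposure `sumstats` (defines the
#'   exposure-increasing allele per variant).
#' @param proxies optional proxy table.
#' @param min_r2 proxy acceptance threshold.
#' @param clusters labels to profile; default all substantive clusters
#'   (labels starting `cluster_`).
#' @param method meta-analysis flavor passed to [dl_meta()].
#' @return A `profile_matrix` data.frame in long format: cluster, trait,
#'   beta, se, zscore, z_std, pvalue, p_adjusted, tau2, n_variants,
#'   n_proxies, n_dropped.
#' @export
grs_profile <- function(assignments, trait_tables, exposure_table,
                        proxies = NULL, min_r2 = 0.8, clusters = NULL,
                        method = "DL") {
  if (!is.data.frame(assignments)) {
    assignments <- data.frame(variant_id = names(assignments),
                              assignment = unname(assignments),
                              stringsAsFactors = FALSE)
  }
  clusters <- clusters %||%
    sort(unique(grep("^cluster_", assignments$assignment, value = TRUE)))
  inc_allele <- increasing_allele(exposure_table)
  names(inc_allele) <- exposure_table$variant_id

  rows <- list()
  for (cl in clusters) {
    members <- assignments$variant_id[assignments$assignment == cl]
    cl_rows <- list()
    for (tr in names(trait_tables)) {
      tt <- trait_tables[[tr]]
      res <- substitute_proxies(members, tt$variant_id, proxies, min_r2)
      b <- s <- numeric(0)
      n_proxies <- 0L
      n_dropped <- 0L
      for (i in seq_len(nrow(res))) {
        if (res$status[i] == "unresolved") {
          n_dropped <- n_dropped + 1L
          next
        }
        rec <- as.data.frame(tt)[match(res$resolved_id[i], tt$variant_id), ,
                                 drop = FALSE]
        wanted <- inc_allele[[res$target_id[i]]]
        if (res$status[i] == "proxy") {
          map <- proxies[proxies$target_id == res$target_id[i] &
                           proxies$proxy_id == res$resolved_id[i], ,
                         drop = FALSE][1, ]
          texp <- as.data.frame(exposure_table)[
            match(res$target_id[i], exposure_table$variant_id), , drop = FALSE]
          rec <- relabel_proxy_record(rec, texp$effect_allele,
                                      texp$other_allele,
                                      map$target_effect_allele,
                                      map$proxy_effect_allele)
          if (is_drop_signal(rec)) {
            n_dropped <- n_dropped + 1L
            next
          }
          n_proxies <- n_proxies + 1L
        }
        al <- aligned_trait_effect(rec, wanted)
        if (is.null(al)) {
          n_dropped <- n_dropped + 1L
          next
        }
        b <- c(b, al$beta)
        s <- c(s, al$se)
      }
      if (length(b) == 0) {
        cl_rows[[tr]] <- data.frame(
          cluster = cl, trait = tr, beta = NA_real_, se = NA_real_,
          zscore = NA_real_, z_std = NA_real_, pvalue = NA_real_,
          p_adjusted = NA_real_, tau2 = NA_real_, n_variants = 0L,
          n_proxies = n_proxies, n_dropped = n_dropped,
          stringsAsFactors = FALSE)
      } else {
        m <- dl_meta(b, s, method = method)
        cl_rows[[tr]] <- data.frame(
          cluster = cl, trait = tr, beta = m$beta, se = m$se,
          zscore = m$zscore, z_std = standardized_z(m$zscore, m$n),
          pvalue = m$pvalue, p_adjusted = NA_real_, tau2 = m$tau2,
          n_variants = m$n, n_proxies = n_proxies, n_dropped = n_dropped,
          stringsAsFactors = FALSE)
      }
    }
    cl_df <- do.call(rbind, cl_rows)
    # multiple-testing family: traits within one cluster
    ok <- !is.na(cl_df$pvalue)
    if (any(ok)) cl_df$p_adjusted[ok] <- bh_adjust(cl_df$pvalue[ok])
    rows[[cl]] <- cl_df
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(), trait = character())
  rownames(out) <- NULL
  structure(out, class = c("profile_matrix", "data.frame"))
}
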