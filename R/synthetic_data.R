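#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Encodes the multi-mechanism causal model the clustered-MR analysis
#' assumes: variants act on the outcome through one of K mechanisms with
#' distinct causal slopes, are null (no outcome effect), or are "junk"
#' (idiosyncratic pleiotropic effects not tied to the exposure). Sampling
#' noise on every observed effect is governed by allele frequency and GWAS
#' sample size through [se_from_n_eaf()].
#'
#' @param n_variants number of independent variants.
#' @param cluster_slopes true causal effects theta_k, outcome units per
#'   exposure SD.
#' @param cluster_weights proportion of variants per mechanism cluster;
#'   together with `null_frac` and `junk_frac` must sum to 1.
#' @param null_frac proportion of variants with zero outcome effect.
#' @param junk_frac proportion with idiosyncratic pleiotropy.
#' @param pleiotropy_sd sd (outcome units) of the junk pleiotropic offsets.
#' @param pleiotropy_mean mean pleiotropic offset; nonzero gives directional
#'   pleiotropy (for Egger power studies).
#' @param cluster_pleiotropy_sd optional sd of balanced pleiotropic noise
#'   added to cluster variants' outcome effects (default 0: exact slopes).
#' @param exposure_effect_mean mean magnitude of true exposure effects
#'   (per-allele, exposure SD units). Magnitudes are gamma(shape
#'   `exposure_effect_shape`) scaled to this mean and bounded below at
#'   3x the exposure SE, so instruments look genome-wide significant and
#'   the first-order delta method is adequate.
#' @param exposure_effect_shape gamma shape for the magnitudes (default 2).
#' @param eaf_range range of the uniform effect-allele-frequency draw.
#' @param n_exposure,n_outcome GWAS sample sizes of the two samples.
#' @param trait_signatures optional K x T matrix of per-cluster trait slopes
#'   gamma_kt (trait units per exposure SD); column names label the traits.
#' @param trait_n sample size for each secondary-trait GWAS.
#' @param trait_effect_sd sd of variant-level noise around gamma_kt * beta_x.
#' @param palindromic_frac fraction of variants given palindromic (A/T or
#'   C/G) allele pairs, to exercise harmonization.
#' @param flip_frac fraction of outcome/trait records stored on the flipped
#'   allele orientation (the exposure table is stored as-simulated).
#' @param n_validation optional sample size of an independent validation
#'   outcome GWAS drawn from the same truth with fresh noise.
#' @param seed integer seed; all outputs are pure functions of (config, seed).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_variants = 200,
                       cluster_slopes = c(0.4, -0.6),
                       cluster_weights = c(0.35, 0.25),
                       null_frac = 0.3,
                       junk_frac = 0.1,
                       pleiotropy_sd = 0.05,
                       pleiotropy_mean = 0,
                       cluster_pleiotropy_sd = 0,
                       exposure_effect_mean = 0.05,
                       exposure_effect_shape = 2,
                       eaf_range = c(0.05, 0.95),
                       n_exposure = 450000,
                       n_outcome = 250000,
                       trait_signatures = NULL,
                       trait_n = 100000,
                       trait_effect_sd = 0,
                       palindromic_frac = 0.1,
                       flip_frac = 0.5,
                       n_validation = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  K <- length(cfg$cluster_slopes)
  if (length(cfg$cluster_weights) != K) {
    stop("config error: cluster_weights must match cluster_slopes in length")
  }
  tot <- sum(cfg$cluster_weights) + cfg$null_frac + cfg$junk_frac
  if (abs(tot - 1) > 1e-9) {
    stop("config error: cluster_weights + null_frac + junk_frac must sum to 1 (got ",
         format(tot), ")")
  }
  if (any(c(cfg$cluster_weights, cfg$null_frac, cfg$junk_frac) < 0)) {
    stop("config error: negative mixture proportion")
  }
  if (cfg$n_exposure <= 0 || cfg$n_outcome <= 0 || cfg$trait_n <= 0) {
    stop("config error: sample sizes must be positive")
  }
  if (!is.null(cfg$trait_signatures)) {
    cfg$trait_signatures <- as.matrix(cfg$trait_signatures)
    if (nrow(cfg$trait_signatures) != K) {
      stop("config error: trait_signatures must have one row per cluster")
    }
    if (is.null(colnames(cfg$trait_signatures))) {
      colnames(cfg$trait_signatures) <-
        paste0("trait_", seq_len(ncol(cfg$trait_signatures)))
    }
  }
  if (cfg$pleiotropy_sd < 0) stop("config error: pleiotropy_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Large-sample standard error of a per-allele effect on a standardized trait
#'
#' `1 / sqrt(2 * eaf * (1 - eaf) * n)` — the usual approximation for a
#' regression of a standardized phenotype on allele dosage.
#'
#' @param n GWAS sample size (> 0).
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @return Standard error(s); vectorized.
#' @export
se_from_n_eaf <- function(n, eaf) {
  if (any(n <= 0)) stop("domain error: n must be > 0")
  if (any(eaf <= 0 | eaf >= 1)) stop("domain error: eaf must be in (0,1)")
  1 / sqrt(2 * eaf * (1 - eaf) * n)
}

# random allele pair; palindromic pairs are A/T or C/G
draw_alleles <- function(n, palindromic_frac, rng_ok = TRUE) {
  pal <- stats::runif(n) < palindromic_frac
  ea <- oa <- character(n)
  pal_pairs <- rbind(c("A", "T"), c("C", "G"))
  nonpal <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pick_pal <- pal_pairs[sample.int(2, n, replace = TRUE), , drop = FALSE]
  pick_non <- nonpal[sample.int(4, n, replace = TRUE), , drop = FALSE]
  swap <- stats::runif(n) < 0.5
  for (i in seq_len(n)) {
    pair <- if (pal[i]) pick_pal[i, ] else pick_non[i, ]
    if (swap[i]) pair <- rev(pair)
    ea[i] <- pair[1]; oa[i] <- pair[2]
  }
  data.frame(effect_allele = ea, other_allele = oa, stringsAsFactors = FALSE)
}

#' Simulate the ground truth of the multi-mechanism causal model
#'
#' Draws mechanism labels with the configured proportions, true exposure
#' effects (positive, aligned to the exposure-increasing allele), true
#' outcome effects (`theta_k * beta_x` for cluster variants, a pleiotropic
#' offset for junk, 0 for null) and per-trait effects `gamma_kt * beta_x`.
#'
#' @param config a [sim_config()].
#' @return A `truth_table` data.frame: variant_id, chrom, pos, alleles, eaf,
#'   label, beta_x, beta_y, alpha and one `trait_*` column per trait.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_variants
  K <- length(config$cluster_slopes)
  labels_pool <- c(if (K) paste0("cluster_", seq_len(K)), "null", "junk")
  probs <- c(config$cluster_weights, config$null_frac, config$junk_frac)
  label <- sample(labels_pool, n, replace = TRUE, prob = probs)

  eaf <- stats::runif(n, config$eaf_range[1], config$eaf_range[2])
  se_x <- se_from_n_eaf(config$n_exposure, eaf)
  beta_x <- pmax(stats::rgamma(n, shape = config$exposure_effect_shape,
                               rate = config$exposure_effect_shape /
                                 config$exposure_effect_mean),
                 3 * se_x)

  alpha <- rep(0, n)
  beta_y <- rep(0, n)
  is_junk <- label == "junk"
  alpha[is_junk] <- stats::rnorm(sum(is_junk), config$pleiotropy_mean,
                                 config$pleiotropy_sd)
  beta_y[is_junk] <- alpha[is_junk]
  for (k in seq_len(K)) {
    idx <- label == paste0("cluster_", k)
    beta_y[idx] <- config$cluster_slopes[k] * beta_x[idx]
    if (config$cluster_pleiotropy_sd > 0) {
      beta_y[idx] <- beta_y[idx] +
        stats::rnorm(sum(idx), config$pleiotropy_mean,
                     config$cluster_pleiotropy_sd)
    }
  }

  alleles <- draw_alleles(n, config$palindromic_frac)
  truth <- data.frame(
    variant_id = sprintf("var_%04d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1000,
    effect_allele = alleles$effect_allele,
    other_allele = alleles$other_allele,
    eaf = eaf,
    label = label,
    beta_x = beta_x,
    beta_y = beta_y,
    alpha = alpha,
    stringsAsFactors = FALSE
  )
  if (!is.null(config$trait_signatures)) {
    for (t in seq_len(ncol(config$trait_signatures))) {
      eff <- rep(0, n)
      for (k in seq_len(K)) {
        idx <- label == paste0("cluster_", k)
        eff[idx] <- config$trait_signatures[k, t] * beta_x[idx]
      }
      if (config$trait_effect_sd > 0) {
        nz <- eff != 0
        eff[nz] <- eff[nz] + stats::rnorm(sum(nz), 0, config$trait_effect_sd)
      }
      truth[[paste0("trait_", colnames(config$trait_signatures)[t])]] <- eff
    }
  }
  structure(truth, class = c("truth_table", "data.frame"))
}

# observed table = truth + independent sampling noise at the dataset's n,
# with a fraction of records stored on the flipped orientation
observe_table <- function(truth, true_beta, n_sample, trait_label,
                          flip_frac, scramble = TRUE) {
  se <- se_from_n_eaf(n_sample, truth$eaf)
  beta <- true_beta + stats::rnorm(nrow(truth), 0, se)
  p <- pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
  tbl <- data.frame(variant_id = truth$variant_id,
                    chrom = truth$chrom,
                    pos = truth$pos,
                    effect_allele = truth$effect_allele,
                    other_allele = truth$other_allele,
                    eaf = truth$eaf,
                    beta = beta,
                    se = se,
                    pvalue = p,
                    n = n_sample,
                    stringsAsFactors = FALSE)
  if (scramble && flip_frac > 0) {
    fl <- stats::runif(nrow(tbl)) < flip_frac
    tbl[fl, ] <- flip_record(tbl[fl, , drop = FALSE])
  }
  sumstats(tbl, trait_label)
}

#' Simulate two-sample GWAS summary statistics from a truth table
#'
#' Observed effects are the true effects plus independent Gaussian noise
#' with sd given by [se_from_n_eaf()] at each dataset's sample size
#' (two-sample design: exposure and outcome noise are independent).
#' P-values come from the Wald z. Outcome and trait records are stored on a
#' randomly flipped allele orientation for a `flip_frac` fraction of
#' variants, so downstream harmonization is exercised. Deterministic given
#' the config seed.
#'
#' @param truth a `truth_table` from [simulate_truth()].
#' @param config the same [sim_config()].
#' @return list: `exposure`, `outcome` (`sumstats`), `validation`
#'   (`sumstats` or NULL), `traits` (named list of `sumstats`).
#' @export
simulate_sumstats <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  exposure <- observe_table(truth, truth$beta_x, config$n_exposure,
                            "exposure", 0, scramble = FALSE)
  outcome <- observe_table(truth, truth$beta_y, config$n_outcome,
                           "outcome", config$flip_frac)
  validation <- NULL
  if (!is.null(config$n_validation)) {
    validation <- observe_table(truth, truth$beta_y, config$n_validation,
                                "validation", config$flip_frac)
  }
  traits <- list()
  trait_cols <- grep("^trait_", names(truth), value = TRUE)
  for (tc in trait_cols) {
    lab <- sub("^trait_", "", tc)
    traits[[lab]] <- observe_table(truth, truth[[tc]], config$trait_n,
                                   lab, config$flip_frac)
  }
  list(exposure = exposure, outcome = outcome, validation = validation,
       traits = traits)
}

#' Write a truth table as TSV
#' @param truth a `truth_table`.
#' @param path output path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
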