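#' Build a pipeline configuration
#'
#' Either `simulate` (a list of [sim_config()] arguments) or `paths`
#' (exposure / discovery outcome / optional validation outcomes / traits /
#' proxy table) must be supplied. Clustering always runs on the discovery
#' outcome only; validation outcomes are used exclusively by the MR stage.
#'
#' @param simulate list of [sim_config()] arguments, or NULL to read files.
#' @param paths list with `exposure`, `outcome`, optional `validation`
#'   (named character vector of paths), `traits` (named), `proxies`.
#' @param clustering list: `K_max`, `threshold`, `n_restarts`, `junk_scale`,
#'   `ratio_order`.
#' @param mr list: `variance_model`, `n_boot`, `phi`.
#' @param profiling list: `method`, `min_r2`.
#' @param harmonization list: `palindrome_policy`, `eaf_ambiguous`,
#'   `min_r2`.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir output directory, or NULL to skip writing artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            clustering = list(), mr = list(),
                            profiling = list(), harmonization = list(),
                            seed = 1, out_dir = NULL) {
  if (is.null(simulate) && is.null(paths)) {
    stop("config error: supply either simulate or paths")
  }
  cl <- utils::modifyList(list(K_max = 4, threshold = 0.8, n_restarts = 10,
                               junk_scale = NULL, ratio_order = "first"),
                          clustering)
  mr <- utils::modifyList(list(variance_model = "multiplicative_random",
                               n_boot = 1000, phi = 1), mr)
  pr <- utils::modifyList(list(method = "DL", min_r2 = 0.8), profiling)
  hz <- utils::modifyList(list(palindrome_policy = "infer",
                               eaf_ambiguous = 0.42, min_r2 = 0.8),
                          harmonization)
  if (cl$threshold <= 0 || cl$threshold > 1) {
    stop("config error: threshold must be in (0, 1]")
  }
  structure(list(simulate = simulate, paths = paths, clustering = cl,
                 mr = mr, profiling = pr, harmonization = hz,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] fields.
#' @param seed optional master-seed override.
#' @param out_dir optional output-directory override.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL, out_dir = NULL) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate$trait_signatures)) {
    y$simulate$trait_signatures <-
      do.call(rbind, lapply(y$simulate$trait_signatures, unlist))
  }
  pipeline_config(simulate = y$simulate, paths = y$paths,
                  clustering = y$clustering %||% list(),
                  mr = y$mr %||% list(),
                  profiling = y$profiling %||% list(),
                  harmonization = y$harmonization %||% list(),
                  seed = seed %||% y$seed %||% 1,
                  out_dir = out_dir %||% y$out_dir)
}

load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- args$seed %||% derive_seed(config$seed, 0L)
    scfg <- do.call(sim_config, args)
    truth <- simulate_truth(scfg)
    sim <- simulate_sumstats(truth, scfg)
    list(exposure = sim$exposure, outcome = sim$outcome,
         validation = if (!is.null(sim$validation))
           list(validation = sim$validation) else list(),
         traits = sim$traits, proxies = NULL, truth = truth)
  } else {
    p <- config$paths
    validation <- list()
    for (nm in names(p$validation %||% list())) {
      validation[[nm]] <- read_sumstats(p$validation[[nm]], nm)
    }
    traits <- list()
    for (nm in names(p$traits %||% list())) {
      traits[[nm]] <- read_sumstats(p$traits[[nm]], nm)
    }
    list(exposure = read_sumstats(p$exposure, "exposure"),
         outcome = read_sumstats(p$outcome, "outcome"),
         validation = validation, traits = traits,
         proxies = if (!is.null(p$proxies)) read_proxy_table(p$proxies),
         truth = NULL)
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Run the end-to-end clustered-MR analysis
#'
#' Stages, in order: ingest or simulate the summary statistics; harmonize
#' exposure and discovery outcome to the exposure-increasing allele;
#' compute per-variant Wald ratios; fit and select the mixture clustering
#' (discovery outcome only); estimate per-cluster causal effects against
#' every validation outcome (falling back to the discovery outcome when no
#' validation set is configured) with the full estimator suite; profile
#' cluster genetic-risk-score effects on the secondary traits. Record
#' counts reconcile (input = retained + dropped) at every stage and the
#' whole run is a pure function of (config, seed).
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir overrides `config$out_dir`; artifacts (instruments,
#'   cluster table, model summary, MR results, trait profile, run report)
#'   are written there as TSV/YAML when set.
#' @return A `run_report` list: `counts`, `drops`, `model`,
#'   `cluster_summary`, `mr_results`, `profile`, `inputs`, `seeds`,
#'   `version`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  seeds <- list(sim = derive_seed(config$seed, 0L),
                cluster = derive_seed(config$seed, 2L),
                mr = derive_seed(config$seed, 3L))
  counts <- list()
  drops <- list()

  inputs <- load_inputs(config)
  counts$input_variants <- nrow(inputs$exposure)

  hz <- config$harmonization
  harm <- harmonize_tables(inputs$exposure, inputs$outcome,
                           proxies = inputs$proxies, min_r2 = hz$min_r2,
                           palindrome_policy = hz$palindrome_policy,
                           eaf_ambiguous = hz$eaf_ambiguous)
  counts$harmonized <- nrow(harm$instruments)
  counts$harmonization_dropped <- nrow(harm$drops)
  drops$harmonization <- harm$drops
  if (counts$harmonized + counts$harmonization_dropped !=
      counts$input_variants) {
    stop("pipeline error [harmonize]: counts do not reconcile")
  }
  if (counts$harmonized < 2) {
    stop("pipeline error [harmonize]: fewer than 2 instruments retained")
  }

  ratios <- ratio_estimates(harm$instruments,
                            order = config$clustering$ratio_order)
  model <- select_model(ratios, K_max = config$clustering$K_max,
                        seed = seeds$cluster,
                        n_restarts = config$clustering$n_restarts,
                        junk_scale = config$clustering$junk_scale,
                        threshold = config$clustering$threshold)
  ctab <- cluster_table(model)
  counts$clusters <- model$K
  counts$assigned <- sum(ctab$assignment != "unassigned")
  counts$unassigned <- sum(ctab$assignment == "unassigned")

  # MR stage: every substantive cluster plus the full instrument set,
  # against each validation outcome (discovery outcome as fallback)
  val_sets <- inputs$validation
  if (!length(val_sets)) val_sets <- list(discovery = inputs$outcome)
  groups <- c(list(all = harm$instruments$variant_id),
              split(ctab$variant_id, ctab$assignment)[
                grep("^cluster_", unique(ctab$assignment), value = TRUE)])
  mr_rows <- list()
  gi <- 0L
  for (out_name in names(val_sets)) {
    vharm <- harmonize_tables(inputs$exposure, val_sets[[out_name]],
                              proxies = inputs$proxies, min_r2 = hz$min_r2,
                              palindrome_policy = hz$palindrome_policy,
                              eaf_ambiguous = hz$eaf_ambiguous)
    drops[[paste0("mr_", out_name)]] <- vharm$drops
    for (g in names(groups)) {
      gi <- gi + 1L
      gin <- vharm$instruments[vharm$instruments$variant_id %in%
                                 groups[[g]], , drop = FALSE]
      if (nrow(gin) < 2) next
      est <- mr_all(gin, variance_model = config$mr$variance_model,
                    n_boot = config$mr$n_boot,
                    seed = derive_seed(seeds$mr, gi), phi = config$mr$phi)
      est <- cbind(data.frame(outcome = out_name, cluster = g,
                              stringsAsFactors = FALSE), est)
      mr_rows[[paste0(out_name, ".", g)]] <- est
    }
  }
  mr_results <- if (length(mr_rows)) do.call(rbind, mr_rows) else NULL
  if (!is.null(mr_results)) rownames(mr_results) <- NULL

  # trait profiling of substantive clusters
  profile <- NULL
  if (length(inputs$traits)) {
    profile <- grs_profile(ctab[, c("variant_id", "assignment")],
                           inputs$traits, inputs$exposure,
                           proxies = inputs$proxies,
                           min_r2 = config$profiling$min_r2,
                           method = config$profiling$method)
    names(profile)[names(profile) == "assignment"] <- "cluster"
    counts$profiled_cells <- nrow(profile)
  } else {
    counts$profiling <- "skipped (no traits configured)"
  }

  sizes <- table(ctab$assignment)
  cluster_summary <- data.frame(
    cluster = if (model$K) paste0("cluster_", seq_len(model$K)) else
      character(0),
    mean = model$mu,
    proportion = if (model$K)
      unname(model$pi[paste0("cluster_", seq_len(model$K))]) else numeric(0),
    n_assigned = if (model$K)
      as.integer(sizes[paste0("cluster_", seq_len(model$K))]) else integer(0),
    stringsAsFactors = FALSE)
  cluster_summary$n_assigned[is.na(cluster_summary$n_assigned)] <- 0L

  report <- structure(list(counts = counts, drops = drops, model = model,
                           cluster_summary = cluster_summary,
                           mr_results = mr_results, profile = profile,
                           instruments = harm$instruments,
                           cluster_table = ctab, inputs = inputs,
                           seeds = seeds, config = config,
                           version = as.character(
                             utils::packageVersion("clustmr"))),
                      class = "run_report")

  if (!is.null(out_dir)) {
    write_tsv(harm$instruments, file.path(out_dir, "instruments.tsv"))
    write_tsv(ctab, file.path(out_dir, "clusters.tsv"))
    if (!is.null(mr_results)) {
      write_tsv(mr_results, file.path(out_dir, "mr_results.tsv"))
    }
    if (!is.null(profile)) {
      write_tsv(as.data.frame(profile), file.path(out_dir, "profile.tsv"))
    }
    if (!is.null(inputs$truth)) {
      write_truth_table(inputs$truth, file.path(out_dir, "truth.tsv"))
    }
    yaml::write_yaml(list(K = model$K, mu = model$mu,
                          pi = as.list(model$pi), loglik = model$loglik,
                          bic = model$bic, converged = model$converged,
                          junk_scale = model$junk_scale,
                          seeds = seeds, version = report$version),
                     file.path(out_dir, "model.yaml"))
    yaml::write_yaml(c(counts, list(seeds = seeds,
                                    version = report$version)),
                     file.path(out_dir, "report.yaml"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> clustmr", x$version, "\n")
  cat("  variants in:", x$counts$input_variants,
      "| harmonized:", x$counts$harmonized,
      "| dropped:", x$counts$harmonization_dropped, "\n")
  cat("  selected K =", x$model$K, "| assigned:", x$counts$assigned,
      "| unassigned:", x$counts$unassigned, "\n")
  if (nrow(x$cluster_summary)) {
    print(x$cluster_summary, row.names = FALSE)
  }
  invisible(x)
}
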