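#' Scatter of genetic associations colored by cluster assignment
#'
#' Plots the outcome association against the exposure association for every
#' instrument, with one line through the origin per fitted cluster (slope =
#' the cluster's causal-effect estimate). Variants with uncertain
#' membership (below the assignment threshold) are shown as grey points.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_cluster_scatter <- function(report) {
  d <- merge(report$instruments, report$cluster_table[
    , c("variant_id", "assignment")], by = "variant_id")
  d$assignment <- factor(d$assignment)
  sl <- report$cluster_summary
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$beta_exposure, y = .data$beta_outcome,
    colour = .data$assignment)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = assignment_palette(levels(d$assignment))) +
    ggplot2::labs(x = "Genetic association with exposure (SD units)",
                  y = "Genetic association with outcome",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
  if (nrow(sl)) {
    p <- p + ggplot2::geom_abline(
      data = sl, ggplot2::aes(slope = .data$mean, intercept = 0),
      linetype = "dashed", colour = "grey30")
  }
  p
}

assignment_palette <- function(levels) {
  pal <- stats::setNames(rep("grey60", length(levels)), levels)
  subst <- grep("^cluster_", levels, value = TRUE)
  base_cols <- grDevices::hcl.colors(max(3, length(subst)), "Dark 3")
  pal[subst] <- base_cols[seq_along(subst)]
  pal["null"] <- "grey35"
  pal["junk"] <- "tan"
  pal["unassigned"] <- "grey80"
  pal[names(pal) %in% levels]
}

#' Heatmap of cluster trait profiles
#'
#' Tile fill is the cluster-size-standardized z-score; cells significant
#' after Benjamini-Hochberg adjustment within their cluster (p_adj < 0.05)
#' are marked with an asterisk.
#'
#' @param profile a `profile_matrix` from [grs_profile()].
#' @param alpha adjusted-significance mark threshold.
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(profile, alpha = 0.05) {
  d <- as.data.frame(profile)
  d$mark <- ifelse(!is.na(d$p_adjusted) & d$p_adjusted < alpha, "*", "")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$cluster,
                                  fill = .data$z_std)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$mark), size = 6,
                       vjust = 0.75) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z / sqrt(n)") +
    ggplot2::theme_minimal()
}

#' Render a human-readable report with figures
#'
#' Writes a markdown summary plus the cluster scatter and (when trait
#' profiling ran) the profile heatmap as PNG files.
#'
#' @param report a `run_report`.
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)

  sc <- file.path(out_dir, "cluster_scatter.png")
  ggplot2::ggsave(sc, plot_cluster_scatter(report), width = 7, height = 5,
                  dpi = 150)
  paths <- c(paths, sc)

  if (!is.null(report$profile) && nrow(report$profile)) {
    hm <- file.path(out_dir, "profile_heatmap.png")
    ggplot2::ggsave(hm, plot_profile_heatmap(report$profile), width = 7,
                    height = 4, dpi = 150)
    paths <- c(paths, hm)
  }

  md <- file.path(out_dir, "report.md")
  lines <- c(
    paste0("# Clustered MR run report (clustmr ", report$version, ")"),
    "",
    paste0("- Variants in: ", report$counts$input_variants),
    paste0("- Harmonized instruments: ", report$counts$harmonized,
           " (dropped ", report$counts$harmonization_dropped, ")"),
    paste0("- Selected clusters K = ", report$model$K,
           "; BIC = ", format(report$model$bic, digits = 8)),
    paste0("- Assigned at the ", report$model$threshold * 100,
           "% rule: ", report$counts$assigned, "; unassigned: ",
           report$counts$unassigned),
    "",
    "## Cluster summary",
    utils::capture.output(print(report$cluster_summary, row.names = FALSE)),
    "")
  if (!is.null(report$mr_results)) {
    lines <- c(lines, "## MR estimates",
               utils::capture.output(print(
                 report$mr_results[, c("outcome", "cluster", "method",
                                       "beta", "se", "pvalue", "or",
                                       "n_instruments")],
                 row.names = FALSE, digits = 4)), "")
  }
  writeLines(lines, md)
  invisible(c(paths, md))
}
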