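#' Default column dialect for summary-statistics tables
#'
#' Maps the canonical internal field names onto the column headers found in
#' the file. The default follows GWAS-SSF-style headers. Supply a modified
#' copy to [read_sumstats()]/[write_sumstats()] for other layouts.
#'
#' @return Named character vector `canonical = file_column`.
#' @export
default_dialect <- function() {
  c(variant_id    = "variant_id",
    chrom         = "chromosome",
    pos           = "base_pair_location",
    effect_allele = "effect_allele",
    other_allele  = "other_allele",
    eaf           = "effect_allele_frequency",
    beta          = "beta",
    se            = "standard_error",
    pvalue        = "p_value",
    n             = "n")
}

CANONICAL_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pvalue", "n")

#' Construct a summary-statistics table
#'
#' Validates per-variant association records and returns a `sumstats` object
#' (a data.frame with canonical columns). Rows violating the record
#' invariants (alleles must differ and be ACGT, `se > 0`, `eaf` in \[0,1\]
#' or missing, `pvalue` in (0,1\], `n > 0`) are rejected with a message;
#' the count is kept in `attr(x, "n_rejected")`. Duplicate `variant_id`s are
#' an error.
#'
#' @param records data.frame with the canonical columns (`eaf`, `chrom`,
#'   `pos` may be absent; they are filled with `NA`).
#' @param trait_label character scalar naming the trait.
#' @return A `sumstats` data.frame.
#' @export
sumstats <- function(records, trait_label = "trait") {
  stopifnot(is.data.frame(records))
  for (col in c("chrom", "pos", "eaf")) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  missing_cols <- setdiff(CANONICAL_COLS, names(records))
  if (length(missing_cols)) {
    stop("sumstats format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records <- records[CANONICAL_COLS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  ok <- !is.na(records$variant_id) &
    valid_allele(records$effect_allele) &
    valid_allele(records$other_allele) &
    records$effect_allele != records$other_allele &
    !is.na(records$beta) &
    !is.na(records$se) & records$se > 0 &
    (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)) &
    !is.na(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1 &
    !is.na(records$n) & records$n > 0
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message("sumstats [", trait_label, "]: rejected ", n_rejected,
            " record(s) violating field invariants")
  }
  records <- records[ok, , drop = FALSE]
  if (anyDuplicated(records$variant_id)) {
    stop("sumstats integrity error: duplicate variant_id in trait '",
         trait_label, "'")
  }
  rownames(records) <- NULL
  structure(records,
            trait_label = trait_label,
            n_rejected = n_rejected,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat("<sumstats> trait:", attr(x, "trait_label"), "-", nrow(x), "variants\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a summary-statistics table from a delimited file
#'
#' @param path TSV file path.
#' @param trait_label trait name; defaults to the file stem.
#' @param dialect column mapping, see [default_dialect()].
#' @return A `sumstats` object; invalid rows are rejected with a message.
#' @export
read_sumstats <- function(path, trait_label = NULL, dialect = default_dialect()) {
  if (!file.exists(path)) stop("sumstats I/O error: file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
                "pvalue", "n")
  have <- dialect[dialect %in% names(raw)]
  missing_req <- setdiff(required, names(have))
  if (length(missing_req)) {
    stop("sumstats format error: header lacks column(s) for: ",
         paste(dialect[missing_req], collapse = ", "))
  }
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(have)) records[[canon]] <- raw[[have[[canon]]]]
  sumstats(records, trait_label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a summary-statistics table
#'
#' Round-trips with [read_sumstats()]: missing values are written as `NA`.
#'
#' @param table a `sumstats` object.
#' @param path output TSV path.
#' @param dialect column mapping used for the header.
#' @export
write_sumstats <- function(table, path, dialect = default_dialect()) {
  stopifnot(inherits(table, "sumstats") || is.data.frame(table))
  out <- as.data.frame(table)[CANONICAL_COLS]
  names(out) <- unname(dialect[CANONICAL_COLS])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("sumstats I/O error: cannot write ", path)
  invisible(path)
}

#' Flip a variant record to its other allele
#'
#' Swaps effect/other alleles, negates beta, replaces `eaf` by `1 - eaf`;
#' `se`, `pvalue` and `n` are unchanged. Vectorized over rows; applying it
#' twice is the identity.
#'
#' @param rec one or more rows of a `sumstats` table.
#' @return The flipped record(s), same class.
#' @export
flip_record <- function(rec) {
  ea <- rec$effect_allele
  rec$effect_allele <- rec$other_allele
  rec$other_allele <- ea
  rec$beta <- -rec$beta
  rec$eaf <- 1 - rec$eaf
  rec
}

# How do target alleles relate to a query's (effect, other) pair?
#   "same"  query effect allele is the target allele
#   "flip"  query must be flipped
#   strand-complement matches are resolved transparently for
#   non-palindromic pairs; "mismatch" if irreconcilable.
match_alleles <- function(q_ea, q_oa, t_ea, t_oa) {
  if (q_ea == t_ea && q_oa == t_oa) return("same")
  if (q_ea == t_oa && q_oa == t_ea) return("flip")
  if (comp_allele(q_ea) == t_ea && comp_allele(q_oa) == t_oa) return("same")
  if (comp_allele(q_ea) == t_oa && comp_allele(q_oa) == t_ea) return("flip")
  "mismatch"
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns both records to the exposure-increasing allele: the exposure
#' record is flipped if its beta is negative, and the outcome record is
#' flipped to report the same allele. Palindromic variants (A/T, C/G) carry
#' a strand ambiguity; the policy decides their fate:
#'
#' * `"infer"` (default): drop when `min(eaf, 1-eaf) > eaf_ambiguous` in
#'   either dataset or when either eaf is missing; otherwise the minor/major
#'   side of the frequencies is used to detect a strand flip.
#' * `"drop"`: drop all palindromic pairs.
#' * `"keep"`: trust the allele labels as same-strand.
#'
#' @param exp_rec,out_rec single rows of `sumstats` tables for the same
#'   variant (or a proxy relabelled to the target's alleles).
#' @param palindrome_policy `"infer"`, `"drop"` or `"keep"`.
#' @param eaf_ambiguous frequency window treated as strand-ambiguous.
#' @param on_mismatch `"drop"` returns a drop-signal with a reason code;
#'   `"error"` throws on irreconcilable allele sets.
#' @return One-row data.frame (variant_id, aligned_allele, beta_exposure,
#'   se_exposure, eaf_exposure, beta_outcome, se_outcome, proxy_id,
#'   proxy_r2), or a drop-signal object whose `$reason` holds the code.
#' @export
harmonize_pair <- function(exp_rec, out_rec,
                           palindrome_policy = c("infer", "drop", "keep"),
                           eaf_ambiguous = 0.42,
                           on_mismatch = c("drop", "error")) {
  palindrome_policy <- match.arg(palindrome_policy)
  on_mismatch <- match.arg(on_mismatch)
  vid <- exp_rec$variant_id

  fail <- function(reason) {
    if (on_mismatch == "error" && reason == "allele_mismatch") {
      stop("harmonization error: irreconcilable alleles for ", vid)
    }
    drop_signal(reason)
  }

  m <- match_alleles(out_rec$effect_allele, out_rec$other_allele,
                     exp_rec$effect_allele, exp_rec$other_allele)
  if (m == "mismatch") return(fail("allele_mismatch"))
  if (m == "flip") out_rec <- flip_record(out_rec)

  if (is_palindromic(exp_rec$effect_allele, exp_rec$other_allele)) {
    if (palindrome_policy == "drop") return(fail("palindromic"))
    if (palindrome_policy == "infer") {
      if (is.na(exp_rec$eaf) || is.na(out_rec$eaf)) {
        return(fail("palindromic_no_eaf"))
      }
      maf <- pmin(c(exp_rec$eaf, out_rec$eaf), 1 - c(exp_rec$eaf, out_rec$eaf))
      if (any(maf > eaf_ambiguous)) return(fail("palindromic_ambiguous"))
      # discordant frequency sides indicate opposite strands: one extra flip
      if ((exp_rec$eaf - 0.5) * (out_rec$eaf - 0.5) < 0) {
        out_rec <- flip_record(out_rec)
      }
    }
  }

  if (exp_rec$beta == 0) return(fail("zero_exposure_beta"))
  if (exp_rec$beta < 0) {
    exp_rec <- flip_record(exp_rec)
    out_rec <- flip_record(out_rec)
  }

  data.frame(variant_id = vid,
             aligned_allele = exp_rec$effect_allele,
             beta_exposure = exp_rec$beta,
             se_exposure = exp_rec$se,
             eaf_exposure = exp_rec$eaf,
             beta_outcome = out_rec$beta,
             se_outcome = out_rec$se,
             proxy_id = NA_character_,
             proxy_r2 = NA_real_,
             stringsAsFactors = FALSE)
}

#' Resolve missing variants through an LD-proxy table
#'
#' Present ids map to themselves. Each absent id is mapped to the available
#' proxy with the highest r-squared at or above `min_r2` (ties broken by
#' lexicographic proxy id), otherwise left unresolved.
#'
#' @param wanted character vector of target variant ids.
#' @param available character vector of ids present in the other dataset.
#' @param proxies proxy table (data.frame: `target_id`, `proxy_id`, `r2`,
#'   `target_effect_allele`, `proxy_effect_allele`) or NULL.
#' @param min_r2 minimum r-squared for an acceptable proxy (default 0.8).
#' @return data.frame: `target_id`, `resolved_id`, `r2`, `status`
#'   (`present` / `proxy` / `unresolved`).
#' @export
substitute_proxies <- function(wanted, available, proxies = NULL, min_r2 = 0.8) {
  stopifnot(min_r2 > 0, min_r2 <= 1)
  out <- data.frame(target_id = wanted,
                    resolved_id = NA_character_,
                    r2 = NA_real_,
                    status = "unresolved",
                    stringsAsFactors = FALSE)
  present <- wanted %in% available
  out$resolved_id[present] <- wanted[present]
  out$status[present] <- "present"
  if (!is.null(proxies) && any(!present)) {
    cand <- proxies[proxies$target_id %in% wanted[!present] &
                      proxies$proxy_id %in% available &
                      proxies$r2 >= min_r2, , drop = FALSE]
    if (nrow(cand)) {
      cand <- cand[order(cand$target_id, -cand$r2, cand$proxy_id), , drop = FALSE]
      cand <- cand[!duplicated(cand$target_id), , drop = FALSE]
      idx <- match(cand$target_id, out$target_id)
      out$resolved_id[idx] <- cand$proxy_id
      out$r2[idx] <- cand$r2
      out$status[idx] <- "proxy"
    }
  }
  out
}

#' Read an LD-proxy table
#'
#' @param path TSV with columns `target_id`, `proxy_id`, `r2`,
#'   `target_effect_allele`, `proxy_effect_allele`.
#' @return data.frame with validated columns.
#' @export
read_proxy_table <- function(path) {
  px <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("target_id", "proxy_id", "r2", "target_effect_allele",
            "proxy_effect_allele")
  missing_cols <- setdiff(need, names(px))
  if (length(missing_cols)) {
    stop("proxy table format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(px$r2 < 0 | px$r2 > 1, na.rm = TRUE)) {
    stop("proxy table integrity error: r2 outside [0,1]")
  }
  px
}

# Relabel a proxy's record into the target variant's allele frame using the
# explicit correspondence carried by the proxy table (never inferred).
relabel_proxy_record <- function(rec, target_ea, target_oa,
                                 map_target_ea, map_proxy_ea) {
  m <- match_alleles(rec$effect_allele, rec$other_allele,
                     map_proxy_ea, comp_allele(map_proxy_ea))
  # align the proxy record so its effect allele is map_proxy_ea
  if (rec$effect_allele != map_proxy_ea) {
    if (rec$other_allele == map_proxy_ea) {
      rec <- flip_record(rec)
    } else {
      return(drop_signal("proxy_allele_mismatch"))
    }
  }
  # map_proxy_ea corresponds to map_target_ea on the target variant
  rec$effect_allele <- map_target_ea
  rec$other_allele <- if (map_target_ea == target_ea) target_oa else target_ea
  if (!rec$effect_allele %in% c(target_ea, target_oa)) {
    return(drop_signal("proxy_allele_mismatch"))
  }
  rec
}

#' Harmonize an exposure table against an outcome table
#'
#' Pairs every exposure variant with its outcome record (substituting LD
#' proxies for missing variants when a proxy table is supplied), aligns each
#' pair to the exposure-increasing allele via [harmonize_pair()], and logs
#' every drop with a reason code.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param proxies optional proxy table (see [read_proxy_table()]).
#' @param min_r2 proxy acceptance threshold (default 0.8).
#' @inheritParams harmonize_pair
#' @return list with `instruments` (harmonized data.frame, one row per
#'   retained variant) and `drops` (variant_id, reason).
#' @export
harmonize_tables <- function(exposure, outcome, proxies = NULL, min_r2 = 0.8,
                             palindrome_policy = c("infer", "drop", "keep"),
                             eaf_ambiguous = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  res <- substitute_proxies(exposure$variant_id, outcome$variant_id,
                            proxies, min_r2)
  out_idx <- match(res$resolved_id, outcome$variant_id)
  drops <- list()
  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    vid <- exposure$variant_id[i]
    if (res$status[i] == "unresolved") {
      drops[[length(drops) + 1L]] <- drop_record(vid, "missing_in_outcome")
      next
    }
    exp_rec <- exposure[i, , drop = FALSE]
    out_rec <- as.data.frame(outcome)[out_idx[i], , drop = FALSE]
    policy <- palindrome_policy
    if (res$status[i] == "proxy") {
      map <- proxies[proxies$target_id == vid &
                       proxies$proxy_id == res$resolved_id[i], , drop = FALSE][1, ]
      out_rec <- relabel_proxy_record(out_rec, exp_rec$effect_allele,
                                      exp_rec$other_allele,
                                      map$target_effect_allele,
                                      map$proxy_effect_allele)
      if (is_drop_signal(out_rec)) {
        drops[[length(drops) + 1L]] <- drop_record(vid, drop_reason(out_rec))
        next
      }
      # the proxy table's correspondence is explicit; no strand inference
      policy <- "keep"
    }
    h <- harmonize_pair(exp_rec, out_rec, palindrome_policy = policy,
                        eaf_ambiguous = eaf_ambiguous)
    if (is_drop_signal(h)) {
      drops[[length(drops) + 1L]] <- drop_record(vid, drop_reason(h))
    } else {
      if (res$status[i] == "proxy") {
        h$proxy_id <- res$resolved_id[i]
        h$proxy_r2 <- res$r2[i]
      }
      rows[[length(rows) + 1L]] <- h
    }
  }
  instruments <- if (length(rows)) do.call(rbind, rows) else
    harmonize_pair(data.frame(variant_id = "x", effect_allele = "A",
                              other_allele = "C", beta = 1, se = 1, eaf = 0.5),
                   data.frame(variant_id = "x", effect_allele = "A",
                              other_allele = "C", beta = 0, se = 1, eaf = 0.5))[0, ]
  drop_log <- if (length(drops)) do.call(rbind, drops) else empty_drop_log()
  rownames(instruments) <- NULL
  list(instruments = instruments, drops = drop_log)
}
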