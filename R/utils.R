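`%||%` <- function(a, b) if (is.null(a)) b else a

# log(sum(exp(x))) guarded against underflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp for a J x C matrix (vectorized; avoids apply)
row_log_sum_exp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- mx[bad]
  out
}

# sentinel returned in place of a harmonized instrument when a pair is
# dropped; carries the reason code
drop_signal <- function(reason) {
  structure(list(reason = reason), class = "drop_signal")
}

is_drop_signal <- function(x) inherits(x, "drop_signal")

drop_reason <- function(x) if (is_drop_signal(x)) x$reason else NA_character_

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

comp_allele <- function(a) unname(COMPLEMENT[a])

is_palindromic <- function(a1, a2) !is.na(a1) & !is.na(a2) & comp_allele(a1) == a2

valid_allele <- function(a) a %in% names(COMPLEMENT)

drop_record <- function(variant_id, reason) {
  data.frame(variant_id = variant_id, reason = reason, stringsAsFactors = FALSE)
}

empty_drop_log <- function() {
  data.frame(variant_id = character(), reason = character(), stringsAsFactors = FALSE)
}

# deterministic per-stage seeds derived from a master seed, kept under 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7L + offset * 1009) %% 2147483647)
}
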