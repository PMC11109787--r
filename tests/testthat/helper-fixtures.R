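# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk unless a test writes it first.

# minimal well-formed record set
make_records <- function(n = 3, beta = seq_len(n) / 10, se = 0.05,
                         eaf = 0.3, prefix = "rs") {
  data.frame(variant_id = paste0(prefix, seq_len(n)),
             chrom = "1", pos = seq_len(n) * 100,
             effect_allele = "A", other_allele = "C",
             eaf = eaf, beta = beta, se = se,
             pvalue = 0.01, n = 1000, stringsAsFactors = FALSE)
}

make_sumstats <- function(..., trait = "trait") sumstats(make_records(...), trait)

# harmonized instrument set straight from numbers (already aligned)
make_instruments <- function(bx, sx, by, sy) {
  data.frame(variant_id = paste0("v", seq_along(bx)),
             aligned_allele = "A",
             beta_exposure = bx, se_exposure = sx,
             beta_outcome = by, se_outcome = sy,
             proxy_id = NA_character_, proxy_r2 = NA_real_,
             stringsAsFactors = FALSE)
}

# ratio set with known per-variant SEs
make_ratios <- function(theta, se) {
  data.frame(variant_id = paste0("v", seq_along(theta)),
             theta = theta, se = se, stringsAsFactors = FALSE)
}

# map fitted substantive clusters onto the nearest true slope; returns the
# truth label each fitted cluster label corresponds to
fitted_to_truth <- function(model, true_slopes) {
  vapply(seq_len(model$K), function(k) {
    paste0("cluster_", which.min(abs(true_slopes - model$mu[k])))
  }, character(1))
}

# independent brute-force BH step-up (test oracle; mirrors the definition,
# not any library implementation)
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# independent step-by-step DerSimonian-Laird computation (test oracle)
dl_brute_force <- function(b, s) {
  w <- 1 / s^2
  mu_f <- sum(w * b) / sum(w)
  Q <- sum(w * (b - mu_f)^2)
  J <- length(b)
  tau2 <- max(0, (Q - (J - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (s^2 + tau2)
  list(beta = sum(ws * b) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2,
       Q = Q)
}
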