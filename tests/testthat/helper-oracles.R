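# Independent oracles and small fixture builders used across the suite.

# Closed-form OLS via normal equations, reporting coefficient `which`
# with the t-distribution two-sided tail. Kept deliberately naive and
# separate from the package's QR-based fitting path.
oracle_ols <- function(X, y, which = 2L) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * XtXi[which, which])
  tval <- b[which] / se
  list(slope = b[which], se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df))
}

# Two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins: sum of hypergeometric probabilities of tables no more
# probable than the observed one (relative tolerance 1 + 1e-7).
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Random beta matrix with probe/sample names, values away from {0, 1}.
rand_beta <- function(p, n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(p * n, 0.05, 0.95), p, n,
              dimnames = list(sprintf("cg%05d", seq_len(p)),
                              sprintf("S%03d", seq_len(n))))
  m
}

# Minimal annotation table for hand-built fixtures.
tiny_annotation <- function(probe_ids,
                            island = "open_sea", gene = "intergenic",
                            symbols = "") {
  data.frame(probe_id = probe_ids,
             chromosome = "chr1",
             position = seq(100L, by = 1000L,
                            length.out = length(probe_ids)),
             island_context = rep_len(island, length(probe_ids)),
             gene_context = rep_len(gene, length(probe_ids)),
             gene_symbols = rep_len(symbols, length(probe_ids)),
             snp_flag = FALSE, cross_hybridizing_flag = FALSE,
             stringsAsFactors = FALSE)
}

# Small cohort configuration used by fast pipeline-level tests.
small_cohort <- function(seed, n_samples = 60L, n_probes = 300L,
                         effect_fraction = 0, ...) {
  generate_cohort(cohort_config(
    n_samples = n_samples, n_probes = n_probes, chip_size = 6L,
    effect_fraction = effect_fraction, seed = seed, ...))
}
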