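make_qc <- function(beta, detp = 0, beads = 10L) {
  list(detection_p = matrix(detp, nrow(beta), ncol(beta),
                            dimnames = dimnames(beta)),
       min_bead_count = matrix(beads, nrow(beta), ncol(beta),
                               dimnames = dimnames(beta)))
}

test_that("probe QC applies detection, bead and annotation-flag rules", {
  beta <- rand_beta(10, 4)
  ann <- tiny_annotation(rownames(beta))
  qc <- make_qc(beta)

  # boundary: detection p exactly 0.01 in a single sample removes the probe
  qc$detection_p["cg00001", 2] <- 0.01
  out <- apply_probe_qc(beta, qc, ann)
  expect_false("cg00001" %in% rownames(out))

  # boundary: bead count exactly 3 everywhere is retained
  qc2 <- make_qc(beta, beads = 3L)
  out2 <- apply_probe_qc(beta, qc2, ann)
  expect_equal(nrow(out2), 10)

  # hand-enumerated fixture: 2 SNP-flagged + 1 cross-hybridizing + 1 bead
  # failure leave 6 of 10 probes
  ann3 <- ann
  ann3$snp_flag[ann3$probe_id %in% c("cg00002", "cg00003")] <- TRUE
  ann3$cross_hybridizing_flag[ann3$probe_id == "cg00004"] <- TRUE
  qc3 <- make_qc(beta)
  qc3$min_bead_count["cg00005", 1] <- 2L
  out3 <- apply_probe_qc(beta, qc3, ann3)
  expect_equal(nrow(out3), 6)
  expect_identical(rownames(out3),
                   setdiff(rownames(beta), sprintf("cg%05d", 2:5)))
  log <- attr(out3, "removal_log")
  expect_equal(unname(log[c("snp", "cross_hybridizing", "bead_count",
                            "total_removed")]), c(2, 1, 1, 4))

  # probe missing from qc is a data-integrity error
  qc4 <- make_qc(beta)
  qc4$detection_p <- qc4$detection_p[-1, ]
  expect_error(apply_probe_qc(beta, qc4, ann), "absent from qc")
})

test_that("vCpG filter reproduces the range rule with Tukey trimming", {
  vals <- rbind(
    wide = seq(0.40, 0.46, length.out = 12),       # range 0.06 -> retained
    narrow = seq(0.50, 0.54, length.out = 12))     # range 0.04 -> excluded
  colnames(vals) <- sprintf("S%02d", 1:12)
  expect_identical(select_variable_probes(vals, 0.05), "wide")

  # a single extreme outlier is trimmed before the range is measured
  x <- c(seq(0.495, 0.505, length.out = 50), 0.95)
  outl <- matrix(x, 1, dimnames = list("spiky", sprintf("S%02d", 1:51)))
  expect_length(select_variable_probes(outl, 0.05), 0)
  # without trimming it would pass: raw range is 0.455
  expect_identical(select_variable_probes(outl, 0.05, fence = Inf), "spiky")

  expect_error(select_variable_probes(vals[, 1:3, drop = FALSE], 0.05),
               "4 samples")
})

test_that("vCpG filter is sample-order invariant and monotone in threshold", {
  beta <- rand_beta(200, 25, seed = 42)
  beta <- beta * 0.2 + 0.35                         # mixed ranges around 0.05
  sel <- select_variable_probes(beta, 0.05)
  perm <- beta[, sample(ncol(beta))]
  expect_identical(select_variable_probes(perm, 0.05), sel)
  for (thr in c(0.02, 0.05, 0.08, 0.12)) {
    hi <- select_variable_probes(beta, thr + 0.02)
    expect_true(all(hi %in% select_variable_probes(beta, thr)))
  }
})

test_that("chip adjustment removes a planted shift and is idempotent", {
  set.seed(9)
  p <- 150; n <- 60
  m <- matrix(rnorm(p * n, 0, 0.5), p, n,
              dimnames = list(sprintf("cg%03d", 1:p), sprintf("S%02d", 1:n)))
  m <- m + rnorm(p)                               # probe-level means
  batch <- rep(c("b1", "b2"), each = n / 2)
  m[, batch == "b2"] <- m[, batch == "b2"] + 0.8  # planted chip shift

  adj <- combat_adjust(m, batch)
  diffs <- rowMeans(adj[, batch == "b2"]) - rowMeans(adj[, batch == "b1"])
  expect_lt(abs(mean(diffs)), 0.05)
  # direct mean-centering oracle agrees on where the batch means end up
  centred <- m
  for (bt in unique(batch))
    centred[, batch == bt] <- m[, batch == bt] -
      rowMeans(m[, batch == bt]) + rowMeans(m)
  oracle_diffs <- rowMeans(centred[, batch == "b2"]) -
    rowMeans(centred[, batch == "b1"])
  expect_lt(abs(mean(oracle_diffs)), 1e-10)

  # near-idempotence: a second pass has nothing systematic left to remove —
  # residual changes are empirical-Bayes shrinkage of pure estimation noise,
  # far below the planted 0.8 shift, and batch means stay aligned
  adj2 <- combat_adjust(adj, batch)
  expect_lt(max(abs(adj2 - adj)), 0.8 / 4)
  diffs2 <- rowMeans(adj2[, batch == "b2"]) - rowMeans(adj2[, batch == "b1"])
  expect_lt(abs(mean(diffs2)), 0.05)

  # single batch: unchanged with a warning; singleton batch: error names it
  expect_warning(same <- combat_adjust(m, rep("b1", n)), "single batch")
  expect_identical(same, m)
  expect_error(combat_adjust(m, c("solo", rep("b1", n - 1))), "solo")
})

test_that("chip adjustment preserves covariate-associated signal", {
  set.seed(10)
  p <- 120; n <- 200
  epds <- round(pmin(pmax(rnorm(n, 7, 4.4), 0), 30))
  # batch assignment alternates along sorted EPDS: orthogonal by design
  batch <- character(n)
  batch[order(epds)] <- rep(c("b1", "b2"), length.out = n)
  slopes <- runif(p, 0.10, 0.20)
  m <- outer(rnorm(p), rep(1, n)) + slopes %o% (epds - mean(epds)) +
    matrix(rnorm(p * n, 0, 0.25), p, n)
  m[, batch == "b2"] <- m[, batch == "b2"] + 0.8
  dimnames(m) <- list(sprintf("cg%03d", 1:p), sprintf("S%03d", 1:n))

  X <- cbind(1, epds)
  refit <- function(mat) apply(mat, 1, function(y) oracle_ols(X, y)$slope)
  before <- refit(m)
  after <- refit(combat_adjust(m, batch, design = cbind(epds = epds)))
  expect_lt(max(abs(after - before) / abs(before)), 0.10)
})
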