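#' Probe-level quality control
#'
#' Removes probes that fail detection or bead-count criteria in any sample, or
#' that are flagged in the annotation as overlapping a SNP (at the CpG site or
#' its single-base extension) or as cross-hybridizing. A probe is dropped if
#' any sample has detection p >= `detection_p_max` (boundary inclusive), any
#' sample has a minimum bead count (over the methylated/unmethylated channels)
#' below `min_beads`, or either annotation flag is set.
#'
#' @param beta Beta matrix (probes x samples).
#' @param qc List with numeric matrices `detection_p` and `min_bead_count`,
#'   both probes x samples with rownames/colnames matching `beta` probes.
#' @param annotation Probe annotation data frame (see
#'   [generate_probe_annotation()]) with columns `probe_id`, `snp_flag`,
#'   `cross_hybridizing_flag`.
#' @param detection_p_max Detection p-value threshold (inclusive removal).
#'   Default 0.01.
#' @param min_beads Minimum bead count required in every sample. Default 3
#'   ("fewer than 3" removes).
#' @param policy `"probe"` (default): one failing sample removes the probe.
#'   (A per-sample masking alternative is deliberately not implemented; the
#'   strict reading is the package default and only policy.)
#' @return The surviving sub-matrix in original probe order, with attribute
#'   `"removal_log"`: a named integer vector of per-rule removal counts
#'   (a probe failing several rules is counted under each).
#' @export
apply_probe_qc <- function(beta, qc, annotation,
                           detection_p_max = 0.01, min_beads = 3L,
                           policy = "probe") {
  check_beta_matrix(beta)
  policy <- match.arg(policy)
  probes <- rownames(beta)
  for (nm in c("detection_p", "min_bead_count")) {
    if (is.null(qc[[nm]])) stop("qc must contain matrix '", nm, "'")
    missing <- setdiff(probes, rownames(qc[[nm]]))
    if (length(missing))
      stop("probes present in beta but absent from qc$", nm, ": ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  missing <- setdiff(probes, annotation$probe_id)
  if (length(missing))
    stop("probes present in beta but absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))

  dp <- qc$detection_p[probes, colnames(beta), drop = FALSE]
  bc <- qc$min_bead_count[probes, colnames(beta), drop = FALSE]
  if (any(dp < 0 | dp > 1)) stop("detection p-values must lie in [0, 1]")
  ann <- annotation[match(probes, annotation$probe_id), ]

  fail_detp <- apply(dp >= detection_p_max, 1L, any)
  fail_bead <- apply(bc < min_beads, 1L, any)
  fail_snp  <- as.logical(ann$snp_flag)
  fail_xhyb <- as.logical(ann$cross_hybridizing_flag)
  drop <- fail_detp | fail_bead | fail_snp | fail_xhyb

  out <- beta[!drop, , drop = FALSE]
  attr(out, "removal_log") <- c(
    detection_p = sum(fail_detp), bead_count = sum(fail_bead),
    snp = sum(fail_snp), cross_hybridizing = sum(fail_xhyb),
    total_removed = sum(drop), retained = sum(!drop)
  )
  out
}

#' Empirical-Bayes chip (batch) effect adjustment of M-values
#'
#' Removes additive/multiplicative batch effects from an M-value matrix with
#' the parametric empirical-Bayes location/scale model (ComBat), preserving
#' signal associated with covariates supplied in `design`. With a single
#' unique batch the input is returned unchanged with a warning; a batch
#' containing only one sample is an error.
#'
#' @param m M-value matrix (probes x samples).
#' @param batch Per-sample batch labels (e.g. chip ids), length `ncol(m)`.
#' @param design Optional numeric matrix of biological covariates to protect
#'   (samples x covariates, no intercept and no batch indicators).
#' @return Adjusted M-value matrix of the same shape.
#' @export
combat_adjust <- function(m, batch, design = NULL) {
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix")
  if (length(batch) != ncol(m)) stop("batch must have one label per sample")
  batch <- as.character(batch)
  tab <- table(batch)
  if (length(tab) == 1L) {
    warning("single batch: nothing to adjust, returning input unchanged")
    return(m)
  }
  if (any(tab < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  mod <- NULL
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (nrow(design) != ncol(m)) stop("design must have one row per sample")
    mod <- cbind(`(Intercept)` = 1, design)
  }
  out <- suppressMessages(
    sva::ComBat(dat = m, batch = factor(batch), mod = mod,
                par.prior = TRUE, prior.plots = FALSE))
  dimnames(out) <- dimnames(m)
  out
}

#' Select variable CpG probes (vCpGs)
#'
#' A probe is retained when its outlier-trimmed methylation range across
#' samples is at least `min_range`. Outliers are trimmed by Tukey fences:
#' values outside `[Q1 - fence * IQR, Q3 + fence * IQR]` are excluded before
#' the max - min range is computed. The threshold is inclusive (range equal to
#' `min_range` retains the probe).
#'
#' @param beta Beta matrix (probes x samples), at least 4 samples (quartiles
#'   are undefined for the trimming rule below that).
#' @param min_range Minimum trimmed beta range, in (0,1). Default 0.05.
#' @param fence Tukey fence multiplier on the IQR. Default 1.5.
#' @param inclusive Retain probes with range exactly `min_range`? Default TRUE.
#' @return Character vector of retained probe ids, in input order.
#' @export
select_variable_probes <- function(beta, min_range = 0.05, fence = 1.5,
                                   inclusive = TRUE) {
  check_beta_matrix(beta, open_interval = FALSE)
  stopifnot(min_range > 0, min_range < 1, fence >= 0)
  if (ncol(beta) < 4L)
    stop("at least 4 samples are required to trim outliers by quartiles")
  q <- row_quantiles(beta, probs = c(0.25, 0.75))
  iqr <- q[, 2L] - q[, 1L]
  lo <- q[, 1L] - fence * iqr
  hi <- q[, 2L] + fence * iqr
  inside <- beta >= lo & beta <= hi     # recycles per column
  bmax <- beta; bmax[!inside] <- -Inf
  bmin <- beta; bmin[!inside] <- Inf
  rng <- apply(bmax, 1L, max) - apply(bmin, 1L, min)
  keep <- if (inclusive) rng >= min_range else rng > min_range
  rownames(beta)[keep]
}

## internal: row-wise quantiles (type 7)
row_quantiles <- function(x, probs) {
  t(apply(x, 1L, stats::quantile, probs = probs, names = FALSE, type = 7))
}
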