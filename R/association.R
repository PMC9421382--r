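#' Per-CpG linear regression of methylation on EPDS within a fetal-sex stratum
#'
#' Fits, for every probe, the ordinary least-squares model
#' `beta ~ EPDS + covariates` (with intercept) on the samples of the requested
#' fetal-sex stratum, and reports the EPDS coefficient: slope (beta units per
#' EPDS point), standard error, t statistic, residual degrees of freedom and
#' the two-sided p-value of the t-test. Samples with missing EPDS or missing
#' covariates are removed listwise (once, for all probes). Probes with zero
#' variance in the stratum, or any fit under a rank-deficient design, are
#' flagged `degenerate` and carry no p-value. Probes fit perfectly by the
#' model (zero residual variance but nonconstant response) get the p-value
#' floor 1e-300.
#'
#' All fits share one QR decomposition of the design, so the whole matrix is
#' processed in a single pass; results match a per-probe `lm()` call.
#'
#' @param beta Beta matrix (probes x samples); columns must match
#'   `samples$sample_id`.
#' @param samples Sample sheet data frame with columns `sample_id`, `epds`
#'   (integer 0-30, NA allowed) and `fetal_sex` ("female"/"male"), plus any
#'   covariate columns.
#' @param covariates Optional covariates: a character vector of `samples`
#'   column names, and/or a numeric matrix or data frame (samples x
#'   covariates, rows aligned with `samples`) such as Ecc PC scores. Supply
#'   both as a list, e.g. `list("chip_position", ecc$scores)`. Categorical
#'   covariates expand to treatment contrasts (first observed level is the
#'   reference).
#' @param stratum `"female"`, `"male"` or `"both"`.
#' @return Data frame of class `"assoc_table"`: `probe_id`, `slope`, `se`,
#'   `t`, `df`, `p`, `n_used`, `status` (`"ok"`/`"degenerate"`), in input
#'   probe order. Attribute `"n_dropped"` counts listwise-deleted samples.
#' @export
fit_cpg_regressions <- function(beta, samples, covariates = NULL,
                                stratum = c("female", "male", "both")) {
  stratum <- match.arg(stratum)
  check_beta_matrix(beta, open_interval = FALSE)
  if (!all(colnames(beta) %in% samples$sample_id))
    stop("all beta columns must appear in the sample sheet")
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]

  keep <- if (stratum == "both") rep(TRUE, nrow(samples)) else
    samples$fetal_sex == stratum
  if (!any(keep)) stop("empty stratum: ", stratum)
  if (all(is.na(samples$epds[keep]))) stop("all EPDS scores missing in stratum")

  X_cov <- build_covariate_matrix(covariates, samples)
  ok <- keep & !is.na(samples$epds)
  if (!is.null(X_cov)) ok <- ok & stats::complete.cases(X_cov)
  n_dropped <- sum(keep) - sum(ok)

  epds <- samples$epds[ok]
  X <- cbind(`(Intercept)` = 1, epds = as.numeric(epds))
  if (!is.null(X_cov)) {
    Xc <- expand_factors(X_cov[ok, , drop = FALSE])
    X <- cbind(X, Xc)
  }
  n <- nrow(X); q <- ncol(X)
  if (n < q + 2L)
    stop("stratum '", stratum, "' has ", n,
         " usable samples; need at least ", q + 2L)

  Y <- t(beta[, ok, drop = FALSE])        # n x probes
  qrX <- qr(X)
  rank_ok <- qrX$rank == q
  probe_ids <- rownames(beta)
  P <- length(probe_ids)
  res <- data.frame(probe_id = probe_ids, slope = NA_real_, se = NA_real_,
                    t = NA_real_, df = NA_integer_, p = NA_real_,
                    n_used = n, status = "degenerate",
                    stringsAsFactors = FALSE)
  if (rank_ok) {
    coefs <- qr.coef(qrX, Y)              # q x probes
    fitted <- X %*% coefs
    rss <- colSums((Y - fitted)^2)
    df <- n - q
    XtXinv <- chol2inv(chol(crossprod(X)))
    v_epds <- XtXinv[2L, 2L]
    tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
    degen <- tss < 1e-24
    sigma2 <- rss / df
    se <- sqrt(sigma2 * v_epds)
    slope <- coefs[2L, ]
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df)
    perfect <- !degen & sigma2 < 1e-24
    p[perfect] <- 0
    tval[perfect] <- sign(slope[perfect]) * Inf
    se[perfect] <- 0
    p <- pmax(p, 1e-300)                  # keep downstream logs finite
    okrow <- !degen
    res$slope[okrow] <- slope[okrow]
    res$se[okrow] <- se[okrow]
    res$t[okrow] <- tval[okrow]
    res$df <- df
    res$p[okrow] <- p[okrow]
    res$status[okrow] <- "ok"
  }
  attr(res, "n_dropped") <- n_dropped
  attr(res, "stratum") <- stratum
  class(res) <- c("assoc_table", "data.frame")
  res
}

## internal: normalise the covariates argument to one data frame (or NULL)
build_covariate_matrix <- function(covariates, samples) {
  if (is.null(covariates)) return(NULL)
  if (!is.list(covariates) || is.data.frame(covariates))
    covariates <- list(covariates)
  parts <- lapply(covariates, function(cv) {
    if (is.character(cv)) {
      bad <- setdiff(cv, names(samples))
      if (length(bad)) stop("covariate column(s) not in sample sheet: ",
                            paste(bad, collapse = ", "))
      samples[, cv, drop = FALSE]
    } else {
      cv <- as.data.frame(cv)
      if (nrow(cv) != nrow(samples))
        stop("covariate matrix must have one row per sample")
      cv
    }
  })
  do.call(cbind, parts)
}

## internal: expand categorical columns to treatment contrasts
## (reference = first observed level); numeric columns pass through
expand_factors <- function(df) {
  cols <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
      return(m)
    }
    f <- factor(x, levels = unique(as.character(x)))
    lev <- levels(f)
    if (length(lev) < 2L) return(NULL)   # constant factor adds nothing
    m <- sapply(lev[-1L], function(l) as.numeric(f == l))
    colnames(m) <- paste0(nm, lev[-1L])
    m
  })
  do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
}

#' One-sided Kolmogorov-Smirnov test of p-value uniformity
#'
#' Tests whether a collection of p-values shows an excess of small values
#' relative to Uniform(0,1), via the one-sided statistic
#' `D+ = max_i (i/n - p_(i))` (floored at zero). The tail probability is the
#' Birnbaum-Tingey exact formula for `n <= 100` (or when `exact = TRUE`), and
#' the asymptotic form `exp(-2 n D+^2)` otherwise.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\]; nonempty.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact small-sample
#'   tail; default `NULL` chooses exact iff `n <= 100`.
#' @return List of class `"ks_result"`: `d_plus`, `p`, `n`, `method`.
#' @export
ks_uniformity_test <- function(pvalues, exact = NULL) {
  if (length(pvalues) == 0L) stop("pvalues must be nonempty")
  if (anyNA(pvalues)) stop("pvalues must not contain NA")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  n <- length(pvalues)
  d_plus <- max(seq_len(n) / n - sort(pvalues), 0)
  use_exact <- if (is.null(exact)) n <= 100L else isTRUE(exact)
  p <- if (use_exact) ks_dplus_exact_tail(d_plus, n) else
    exp(-2 * n * d_plus^2)
  structure(list(d_plus = d_plus, p = min(p, 1), n = n,
                 method = if (use_exact) "exact" else "asymptotic"),
            class = "ks_result")
}

## internal: exact P(D+ >= d) under uniformity (Birnbaum-Tingey / Smirnov)
ks_dplus_exact_tail <- function(d, n) {
  if (d <= 0) return(1)
  if (d >= 1) return(0)
  j <- 0:floor(n * (1 - d))
  terms <- lchoose(n, j) + (j - 1) * log(j / n + d) +
    (n - j) * log(pmax(1 - d - j / n, 0))
  p <- d * sum(exp(terms))
  min(max(p, 0), 1)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("One-sided KS uniformity test (%s): D+ = %.4g, p = %.4g, n = %d\n",
              x$method, x$d_plus, x$p, x$n))
  invisible(x)
}

#' Select probes associated with EPDS at a nominal threshold
#'
#' Returns the probes whose per-CpG association p-value is strictly below
#' `alpha` (default 0.005, the nominal threshold defining "EPDS-vCpGs";
#' 0.001 is the usual sensitivity threshold). Degenerate fits are never
#' selected.
#'
#' @param results An `assoc_table` from [fit_cpg_regressions()].
#' @param alpha Nominal p-value threshold in (0, 1). Default 0.005.
#' @return Character vector of selected probe ids, in table order.
#' @export
select_epds_vcpgs <- function(results, alpha = 0.005) {
  stopifnot(alpha > 0, alpha < 1)
  sel <- results$status == "ok" & !is.na(results$p) & results$p < alpha
  results$probe_id[sel]
}

#' Intersect two probe-id sets
#'
#' Exact set intersection, returned in deterministic lexicographic order;
#' used e.g. to form the common-vCpG universe of two cohorts.
#'
#' @param set_a,set_b Character vectors of probe ids.
#' @return Sorted character vector.
#' @export
intersect_probe_sets <- function(set_a, set_b) {
  sort(intersect(unique(set_a), unique(set_b)))
}

#' Summarize a selected probe set against its universe
#'
#' Reports the selected count, its percentage of the universe (one decimal)
#' and, when a comparison set is given, the fold-ratio of the two counts
#' (one decimal) — the arithmetic behind statements like "4,716 EPDS-vCpGs
#' (1.1% of total vCpGs), ~2.6 times more than ...".
#'
#' @param selected Probe-id character vector, or a count.
#' @param universe Probe-id character vector (must contain `selected` when
#'   both are vectors), or a count; must be nonempty.
#' @param other_selected Optional comparison set or count.
#' @return List: `n_selected`, `n_universe`, `percent`, and `fold_ratio`
#'   (NA when no/empty comparison set is supplied).
#' @export
summarize_counts <- function(selected, universe, other_selected = NULL) {
  as_count <- function(x) if (is.numeric(x) && length(x) == 1L)
    as.integer(x) else length(unique(x))
  if (is.character(selected) && is.character(universe) &&
      !all(selected %in% universe))
    stop("selected probes must be a subset of the universe")
  n_sel <- as_count(selected)
  n_uni <- as_count(universe)
  if (n_uni == 0L) stop("empty universe")
  n_other <- if (is.null(other_selected)) NA_integer_ else
    as_count(other_selected)
  fold <- if (is.na(n_other) || n_other == 0L) NA_real_ else
    round(n_sel / n_other, 1)
  list(n_selected = n_sel, n_universe = n_uni,
       percent = round(100 * n_sel / n_uni, 1),
       n_other = n_other, fold_ratio = fold)
}
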