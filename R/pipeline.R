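#' Run the full fetal-sex-stratified methylome association pipeline
#'
#' Orchestrates the whole chain on one cohort: optional probe QC, beta-to-M
#' conversion, empirical-Bayes chip adjustment, back-conversion, variable-CpG
#' (vCpG) filtering, reference-based cell-composition estimation and its
#' principal components, then — separately per fetal-sex stratum — per-CpG
#' regression of methylation on EPDS with Ecc-PC and technical covariates,
#' one-sided KS uniformity testing of the p-value distribution, selection of
#' EPDS-associated vCpGs at the nominal and sensitivity thresholds, and
#' genomic-context enrichment of the selected probes against the vCpG
#' reference. Identical inputs and options give identical outputs.
#'
#' @param bundle Either a `cohort_bundle` from [generate_cohort()] or a list
#'   with paths `beta`, `samples`, `annotation`, `reference` (and optionally
#'   `qc`) to be read from disk.
#' @param opts List of options (missing entries take the defaults shown):
#'   `epsilon` (1e-6, M-transform clipping), `vcpg_min_range` (0.05),
#'   `fence` (1.5), `n_ecc_pcs` (5), `covariate_cols`
#'   (`c("chip_position", "extraction_method", "bisulfite_concentration")`),
#'   `alpha` (0.005, EPDS-vCpG threshold), `alpha_sensitivity` (0.001),
#'   `enrichment_alpha` (0.05), `strata` (`c("female", "male")`),
#'   `combat` (TRUE), `exact_ks` (NULL: exact iff n <= 100).
#' @param outdir Optional output directory; when given, association tables,
#'   KS results, probe sets (text and BED), enrichment tables, p-value
#'   histograms and a machine-readable run manifest are written there.
#' @return List of class `"ewastrat_run"`: `vcpg_ids`, per-stratum `assoc`
#'   (tables), `ks`, `epds_vcpgs`, `epds_vcpgs_sensitivity`, `enrichment`,
#'   `summary` (count summaries incl. female/male fold ratio), `ecc`,
#'   `manifest`.
#' @export
run_pipeline <- function(bundle, opts = list(), outdir = NULL) {
  o <- utils::modifyList(list(
    epsilon = 1e-6, vcpg_min_range = 0.05, fence = 1.5, n_ecc_pcs = 5L,
    covariate_cols = c("chip_position", "extraction_method",
                       "bisulfite_concentration"),
    alpha = 0.005, alpha_sensitivity = 0.001, enrichment_alpha = 0.05,
    strata = c("female", "male"), combat = TRUE, exact_ks = NULL
  ), opts)

  if (!inherits(bundle, "cohort_bundle") && !is.null(bundle$beta) &&
      is.character(bundle$beta)) {
    bundle <- list(
      beta = read_beta_tsv(bundle$beta),
      samples = read_sample_sheet_csv(bundle$samples),
      annotation = read_annotation_csv(bundle$annotation),
      reference = read_reference_csv(bundle$reference),
      qc = if (!is.null(bundle$qc)) bundle$qc else NULL)
  }
  beta <- bundle$beta
  samples <- bundle$samples
  annotation <- bundle$annotation
  counts <- list(input_probes = nrow(beta), input_samples = ncol(beta))

  stage <- "probe_qc"
  result <- tryCatch({
    if (!is.null(bundle$qc)) {
      beta <- apply_probe_qc(beta, bundle$qc, annotation)
      counts$qc_retained <- nrow(beta)
    }

    stage <- "chip_adjustment"
    if (isTRUE(o$combat) && length(unique(samples$chip)) > 1L) {
      m <- beta_to_m(beta, o$epsilon)
      m <- combat_adjust(m, samples$chip)
      beta <- m_to_beta(m)
      beta <- pmin(pmax(beta, o$epsilon), 1 - o$epsilon)
    }

    stage <- "vcpg_filter"
    vcpg_ids <- select_variable_probes(beta, o$vcpg_min_range, o$fence)
    counts$vcpgs <- length(vcpg_ids)
    beta_v <- beta[vcpg_ids, , drop = FALSE]

    stage <- "cell_composition"
    comp <- estimate_cell_composition(beta, bundle$reference)
    ecc <- composition_pcs(comp, k = min(o$n_ecc_pcs, ncol(comp) - 1L))

    stage <- "association"
    covars <- list(intersect(o$covariate_cols, names(samples)), ecc$scores)
    covars <- covars[vapply(covars, length, integer(1)) > 0]
    strata_res <- lapply(stats::setNames(o$strata, o$strata), function(s) {
      assoc <- fit_cpg_regressions(beta_v, samples, covars, stratum = s)
      pv <- assoc$p[assoc$status == "ok"]
      ks <- ks_uniformity_test(pv, exact = o$exact_ks)
      list(assoc = assoc, ks = ks,
           epds_vcpgs = select_epds_vcpgs(assoc, o$alpha),
           epds_vcpgs_sensitivity = select_epds_vcpgs(assoc,
                                                      o$alpha_sensitivity))
    })

    stage <- "enrichment"
    enrich <- lapply(strata_res, function(r) {
      if (length(r$epds_vcpgs) == 0L) return(NULL)
      lapply(stats::setNames(c("island_context", "gene_context"),
                             c("island_context", "gene_context")),
             function(sc) feature_enrichment(r$epds_vcpgs, vcpg_ids,
                                             annotation, sc,
                                             o$enrichment_alpha))
    })

    stage <- "summary"
    summaries <- lapply(stats::setNames(o$strata, o$strata), function(s) {
      others <- setdiff(o$strata, s)
      other <- if (length(others)) strata_res[[others[1L]]]$epds_vcpgs else
        NULL
      summarize_counts(strata_res[[s]]$epds_vcpgs, vcpg_ids, other)
    })

    list(vcpg_ids = vcpg_ids,
         strata = strata_res, enrichment = enrich, summary = summaries,
         ecc = ecc, counts = counts, options = o)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  result$manifest <- list(
    package_version = as.character(utils::packageVersion("ewastrat")),
    options = o[setdiff(names(o), "exact_ks")],
    counts = result$counts,
    strata = lapply(result$strata, function(r) list(
      n_ok = sum(r$assoc$status == "ok"),
      ks = unclass(r$ks)[c("d_plus", "p", "n", "method")],
      n_epds_vcpgs = length(r$epds_vcpgs),
      n_epds_vcpgs_sensitivity = length(r$epds_vcpgs_sensitivity))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  class(result) <- "ewastrat_run"

  if (!is.null(outdir)) write_run_outputs(result, annotation, outdir)
  result
}

#' @export
print.ewastrat_run <- function(x, ...) {
  cat("Stratified methylome association run —", x$counts$vcpgs, "vCpGs of",
      x$counts$input_probes, "probes\n")
  for (s in names(x$strata)) {
    r <- x$strata[[s]]
    cat(sprintf("  %-6s: KS D+ = %.4f, p = %.3g; EPDS-vCpGs: %d (%.1f%%)\n",
                s, r$ks$d_plus, r$ks$p, length(r$epds_vcpgs),
                100 * length(r$epds_vcpgs) / max(length(x$vcpg_ids), 1L)))
  }
  invisible(x)
}

## internal: write all per-run artifacts under outdir
write_run_outputs <- function(result, annotation, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(result$vcpg_ids, file.path(outdir, "vcpgs.txt"))
  for (s in names(result$strata)) {
    r <- result$strata[[s]]
    data.table::fwrite(r$assoc, file.path(outdir,
                                          paste0("assoc_", s, ".tsv")),
                       sep = "\t")
    jsonlite::write_json(unclass(r$ks),
                         file.path(outdir, paste0("ks_", s, ".json")),
                         auto_unbox = TRUE, digits = NA)
    writeLines(r$epds_vcpgs,
               file.path(outdir, paste0("epds_vcpgs_", s, ".txt")))
    if (length(r$epds_vcpgs))
      write_probe_bed(r$epds_vcpgs, annotation,
                      file.path(outdir, paste0("epds_vcpgs_", s, ".bed")))
    plot_pvalue_histogram(r$assoc$p[r$assoc$status == "ok"],
                          file.path(outdir, paste0("pvalues_", s, ".png")),
                          main = paste("Per-CpG association p-values,",
                                       s, "stratum"))
    if (!is.null(result$enrichment[[s]]))
      for (sc in names(result$enrichment[[s]]))
        data.table::fwrite(result$enrichment[[s]][[sc]],
                           file.path(outdir, paste0("enrichment_", s, "_",
                                                    sc, ".tsv")),
                           sep = "\t")
  }
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' P-value histogram with the uniform reference line
#'
#' Histogram of association p-values on 20 equal bins of \[0,1\], with the
#' density expected under the uniform distribution drawn as a dashed line —
#' the standard visual check for an excess of small p-values.
#'
#' @param pvalues Numeric vector of p-values.
#' @param path Optional PNG path; when NULL, plots to the active device.
#' @param main Plot title.
#' @export
plot_pvalue_histogram <- function(pvalues, path = NULL,
                                  main = "Association p-values") {
  draw <- function() {
    graphics::hist(pvalues, breaks = seq(0, 1, by = 0.05), freq = FALSE,
                   xlab = "p-value", col = "grey85", border = "white",
                   main = main)
    graphics::abline(h = 1, lty = 2)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 540)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
    invisible(path)
  } else draw()
}
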