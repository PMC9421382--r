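#' Read and write beta-value matrices as TSV
#'
#' The on-disk format is tab-separated with a `probe_id` first column and one
#' column per sample. Values are written with 10 significant digits so that
#' write-then-read round-trips below test tolerances. Gzip is applied
#' automatically for paths ending in `.gz`.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @return `read_beta_tsv`: numeric matrix with probe rownames and sample
#'   colnames.
#' @export
read_beta_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (names(dt)[1L] != "probe_id")
    stop("malformed beta TSV: first column must be 'probe_id' (", path, ")")
  if (anyDuplicated(dt$probe_id)) stop("duplicate probe ids in ", path)
  if (anyDuplicated(names(dt)[-1L])) stop("duplicate sample ids in ", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric values in beta TSV column '", names(dt)[bad + 1L],
         "' (", path, ")")
  }
  rownames(m) <- dt$probe_id
  m
}

#' @rdname read_beta_tsv
#' @param beta Beta (or M-value) matrix with probe rownames / sample colnames.
#' @export
write_beta_tsv <- function(beta, path) {
  check_beta_matrix(beta, open_interval = FALSE)
  dt <- data.frame(probe_id = rownames(beta),
                   signif(beta, 10), check.names = FALSE)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read and write tabular metadata as CSV
#'
#' Plain CSV readers/writers for the probe annotation, sample sheet and
#' cell-type reference panel. `read_annotation_csv` and
#' `read_sample_sheet_csv` validate required columns and id uniqueness;
#' `read_reference_csv` returns a probes x cell-types numeric matrix.
#'
#' @param path File path (`.csv`, optionally `.gz`).
#' @return A data frame (annotation, sample sheet) or matrix (reference).
#' @export
read_annotation_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("probe_id", "chromosome", "position", "island_context",
            "gene_context", "gene_symbols", "snp_flag",
            "cross_hybridizing_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in ", path)
  df$gene_symbols[is.na(df$gene_symbols)] <- ""
  df
}

#' @rdname read_annotation_csv
#' @param annotation,samples,reference Objects to write.
#' @export
write_annotation_csv <- function(annotation, path) {
  data.table::fwrite(annotation, path)
  invisible(path)
}

#' @rdname read_annotation_csv
#' @export
read_sample_sheet_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("sample_id", "epds", "fetal_sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  bad <- !is.na(df$epds) & (df$epds < 0 | df$epds > 30)
  if (any(bad)) stop("EPDS scores outside [0, 30] in ", path)
  df
}

#' @rdname read_annotation_csv
#' @export
write_sample_sheet_csv <- function(samples, path) {
  data.table::fwrite(samples, path)
  invisible(path)
}

#' @rdname read_annotation_csv
#' @export
read_reference_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (names(df)[1L] != "probe_id")
    stop("reference CSV must have a 'probe_id' first column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' @rdname read_annotation_csv
#' @export
write_reference_csv <- function(reference, path) {
  data.table::fwrite(data.frame(probe_id = rownames(reference),
                                signif(reference, 10), check.names = FALSE),
                     path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member gene symbols.
#'
#' @param path File path.
#' @return `read_gmt`: list with `sets` (named list of symbol vectors) and
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], " in ", path,
         ": need name, description and >= 1 gene")
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) stop("duplicate set names in ", path)
  list(sets = stats::setNames(lapply(parts, function(x) x[-(1:2)]), nms),
       descriptions = stats::setNames(vapply(parts, `[[`, character(1), 2L),
                                      nms))
}

#' @rdname read_gmt
#' @param sets Named list of gene-symbol vectors.
#' @param descriptions Optional named descriptions (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets),
                                                             names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export probes as BED4 intervals
#'
#' One record per probe: 0-based half-open interval `[position, position + 2)`
#' covering the CpG dinucleotide, name = probe id.
#'
#' @param probes Character vector of probe ids.
#' @param annotation Probe annotation with `chromosome` and `position`.
#' @param path Output path.
#' @export
write_probe_bed <- function(probes, annotation, path) {
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx)) stop("probes missing from annotation")
  bed <- data.frame(chrom = annotation$chromosome[idx],
                    start = annotation$position[idx],
                    end = annotation$position[idx] + 2L,
                    name = probes)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort bundle to a directory
#'
#' Emits the beta matrix (TSV), sample sheet, annotation and reference panel
#' (CSV), ground-truth tables (CSV) and a YAML echo of the generating
#' configuration.
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the beta matrix? Default FALSE.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(bundle, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_tsv(bundle$beta,
                 file.path(dir, paste0("beta.tsv", if (gzip) ".gz" else "")))
  write_sample_sheet_csv(bundle$samples, file.path(dir, "samples.csv"))
  write_annotation_csv(bundle$annotation, file.path(dir, "annotation.csv"))
  write_reference_csv(bundle$reference, file.path(dir, "reference.csv"))
  data.table::fwrite(bundle$truth$effect_probes,
                     file.path(dir, "truth_effect_probes.csv"))
  data.table::fwrite(
    data.frame(sample_id = rownames(bundle$truth$true_compositions),
               bundle$truth$true_compositions, check.names = FALSE),
    file.path(dir, "truth_compositions.csv"))
  cfg <- bundle$truth$config
  class(cfg) <- NULL
  cfg$category_freqs <- lapply(cfg$category_freqs, as.list)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
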