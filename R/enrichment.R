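#' Genomic-context enrichment of a probe set against a reference set
#'
#' For each level of a genomic-context scheme (CpG-density: island / shore /
#' shelf / open sea; or genic: promoter / 5'UTR / exon / intron / 3'UTR /
#' intergenic), tests whether the query probe set is enriched or depleted in
#' that context relative to a reference probe set, via a two-sided Fisher
#' exact test on the 2x2 table (query in/out of context vs reference in/out).
#' The reference is swappable: e.g. variable CpGs against the full array, or
#' EPDS-associated vCpGs against all vCpGs.
#'
#' @param query,reference Nonempty character vectors of probe ids; the query
#'   need not be a subset of the reference.
#' @param annotation Probe annotation covering all probes in either set.
#' @param scheme `"island_context"` or `"gene_context"`.
#' @param alpha Significance threshold for the `significant` flag.
#'   Default 0.05.
#' @return Data frame with one row per context present in either set:
#'   `feature`, `query_in`, `query_total`, `ref_in`, `ref_total`,
#'   `odds_ratio` (sample odds ratio; may be `Inf` or 0 with empty cells),
#'   `p` (two-sided Fisher), `direction` (`enriched` / `depleted` / `none`),
#'   `significant`.
#' @export
feature_enrichment <- function(query, reference, annotation,
                               scheme = c("island_context", "gene_context"),
                               alpha = 0.05) {
  scheme <- match.arg(scheme)
  if (length(query) == 0L || length(reference) == 0L)
    stop("query and reference probe sets must be nonempty")
  all_probes <- unique(c(query, reference))
  idx <- match(all_probes, annotation$probe_id)
  if (anyNA(idx))
    stop("probes missing from annotation: ",
         paste(utils::head(all_probes[is.na(idx)], 5), collapse = ", "))
  ctx <- stats::setNames(annotation[[scheme]][idx], all_probes)
  levels_all <- if (scheme == "island_context") island_levels() else
    gene_levels()
  q_ctx <- ctx[unique(query)]
  r_ctx <- ctx[unique(reference)]
  qt <- length(q_ctx); rt <- length(r_ctx)

  rows <- lapply(levels_all, function(feat) {
    a <- sum(q_ctx == feat); c_ <- sum(r_ctx == feat)
    if (a + c_ == 0L) return(NULL)       # context absent from both sets
    b <- qt - a; d <- rt - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))
    or <- (a * d) / (b * c_)             # sample odds ratio; Inf/0/NaN allowed
    direction <- if (is.nan(or) || or == 1) "none" else
      if (or > 1) "enriched" else "depleted"
    data.frame(feature = feat, query_in = a, query_total = qt,
               ref_in = c_, ref_total = rt, odds_ratio = or,
               p = ft$p.value, direction = direction,
               significant = ft$p.value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map probes to the unique genes they annotate
#'
#' Union of the gene symbols attached to the probes; intergenic probes
#' contribute nothing. Symbols are harmonized by upper-casing and stripping
#' whitespace, then deduplicated.
#'
#' @param probes Character vector of probe ids.
#' @param annotation Probe annotation with a `gene_symbols` column
#'   (";"-separated symbols, "" for intergenic probes).
#' @return Sorted character vector of unique gene symbols (possibly empty).
#' @export
map_probes_to_genes <- function(probes, annotation) {
  idx <- match(unique(probes), annotation$probe_id)
  if (anyNA(idx)) stop("probes missing from annotation")
  syms <- unlist(strsplit(annotation$gene_symbols[idx], ";", fixed = TRUE))
  syms <- toupper(trimws(syms))
  sort(unique(syms[nzchar(syms)]))
}

#' Hypergeometric gene-set over-representation
#'
#' For every set in a collection, tests whether its overlap with a query gene
#' list is larger than expected by chance: `p = P(X >= overlap)` with `X`
#' hypergeometric on (universe size, set size, query size). P-values are
#' Benjamini-Hochberg adjusted across the collection.
#'
#' @param query_genes Character vector of gene symbols; symbols outside the
#'   universe are dropped with a warning.
#' @param collection List with `sets` (named list of character vectors) and
#'   `universe` (character vector), e.g. from [read_gmt()] plus a universe.
#' @return Data frame sorted by `p` ascending (ties broken by set name):
#'   `set`, `set_size`, `overlap`, `p`, `bh_fdr`.
#' @export
geneset_hypergeometric <- function(query_genes, collection) {
  harmon <- function(x) unique(toupper(trimws(x)))
  universe <- harmon(collection$universe)
  if (length(universe) == 0L) stop("empty gene universe")
  query <- harmon(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  sets <- lapply(collection$sets, function(s) intersect(harmon(s), universe))
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  N <- length(universe); n <- length(query)
  rows <- data.frame(
    set = names(sets),
    set_size = vapply(sets, length, integer(1)),
    overlap = vapply(sets, function(s) length(intersect(s, query)),
                     integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  rows$p <- stats::phyper(rows$overlap - 1L, rows$set_size,
                          N - rows$set_size, n, lower.tail = FALSE)
  rows$bh_fdr <- stats::p.adjust(rows$p, method = "BH")
  rows[order(rows$p, rows$set), , drop = FALSE]
}
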