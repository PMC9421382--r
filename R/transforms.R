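#' Convert beta values to M-values
#'
#' Methylation beta values (fraction methylated, in (0,1)) are mapped to the
#' variance-stabilized M-scale, `M = log2(beta / (1 - beta))`. Values are first
#' clipped to `[epsilon, 1 - epsilon]` so boundary betas give finite M-values;
#' on the clipped domain the transform is exactly inverted by [m_to_beta()].
#'
#' @param beta Numeric matrix (probes x samples) or vector of beta values.
#' @param epsilon Clipping bound in (0, 0.5). Default `1e-6`.
#' @return Object of the same shape on the M-scale.
#' @seealso [m_to_beta()]
#' @export
#' @examples
#' beta_to_m(c(0.5, 0.8))  # 0, 2
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0, epsilon < 0.5)
  v <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(v / (1 - v))
  attributes(m) <- attributes(beta)
  m
}

#' Convert M-values back to beta values
#'
#' Inverse logistic (base 2) map `beta = 2^M / (1 + 2^M)`. Round-trips
#' [beta_to_m()] to within 1e-12 on the clipped domain.
#'
#' @param m Numeric matrix or vector of M-values (finite).
#' @return Object of the same shape on the beta scale, in (0,1).
#' @export
m_to_beta <- function(m) {
  b <- 1 / (1 + 2^(-m))
  attributes(b) <- attributes(m)
  b
}

## internal: validate a beta matrix (probes x samples, rownames/colnames set)
check_beta_matrix <- function(beta, open_interval = TRUE) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta must be a numeric matrix (probes x samples)")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta matrix must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids in beta matrix")
  if (open_interval && (any(beta <= 0) || any(beta >= 1)))
    stop("beta values must lie strictly in (0, 1)")
  invisible(beta)
}

## internal: closed vocabularies for genomic context schemes
island_levels <- function() c("island", "shore", "shelf", "open_sea")
gene_levels <- function() {
  c("promoter", "five_prime_utr", "exon", "intron", "three_prime_utr", "intergenic")
}
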