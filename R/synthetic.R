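#' Configuration for a synthetic methylation cohort
#'
#' Bundles and validates the parameters of the synthetic Infinium-like cohort
#' generator. Defaults emulate the design of a pregnancy cohort profiled on a
#' methylation BeadChip: 491 mothers of whom 47.7% carry female fetuses,
#' depressive-symptom (EPDS) scores with mean 7.0 and SD 4.4 on the 0-30
#' scale, blood-like six-cell-type mixtures, chips of 8 samples, and a small
#' fraction of probes carrying a linear EPDS effect in one fetal-sex stratum.
#'
#' @param n_samples Number of samples. Default 491.
#' @param n_probes Number of probes. Default 20000.
#' @param female_fraction Fraction of samples in the female-fetus stratum.
#'   Default 0.477.
#' @param epds_mean,epds_sd Moments of the EPDS score distribution (normal,
#'   rounded and clipped to \[0, 30\]). Defaults 7.0 and 4.4.
#' @param n_cell_types Number of constituent cell types (>= 2). Default 6.
#' @param chip_size Samples per chip (>= 2). Default 8.
#' @param batch_shift_sd SD of per-probe, per-chip additive shifts on the
#'   M-scale. Default 0.2.
#' @param position_shift_sd SD of per-probe, per-chip-position shifts
#'   (M-scale). Default 0 (off).
#' @param noise_sd SD of per-value measurement noise on the M-scale.
#'   Default 0.15.
#' @param cell_profile_sd SD of per-cell-type deviations around each probe's
#'   baseline, M-scale. Default 0.5.
#' @param dirichlet_alpha Dirichlet concentration for sample compositions;
#'   recycled/truncated to `n_cell_types`. Default `c(12, 6, 3, 2, 2, 2)`
#'   (one dominant cell type, as in whole blood).
#' @param effect_fraction Fraction of probes with a planted EPDS effect.
#'   Default 0.02.
#' @param effect_slope_sd SD of planted slopes (M-value units per EPDS
#'   point); slopes are drawn Normal(0, `effect_slope_sd`). Default 0.0078,
#'   the value of [slope_sd_for_partial_r2()] at a target per-probe partial
#'   R-squared of 0.05 under the default noise and EPDS SDs.
#' @param effect_stratum Stratum carrying the planted effects: `"female"`,
#'   `"male"` or `"both"`. Default `"female"`.
#' @param context_bias Odds multiplier favouring `effect_contexts` when
#'   choosing which probes carry effects (1 = unbiased). Default 1.
#' @param effect_contexts Context labels (island- or gene-scheme) attracting
#'   the bias. Default `c("open_sea", "intergenic")`.
#' @param category_freqs List with named probability vectors
#'   `island_context` and `gene_context`; each must sum to 1. Defaults mirror
#'   an EPIC-like manifest composition.
#' @param seed Integer seed; the bundle is fully reproducible from it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 491L, n_probes = 20000L,
                          female_fraction = 0.477,
                          epds_mean = 7.0, epds_sd = 4.4,
                          n_cell_types = 6L, chip_size = 8L,
                          batch_shift_sd = 0.2, position_shift_sd = 0,
                          noise_sd = 0.15, cell_profile_sd = 0.5,
                          dirichlet_alpha = c(12, 6, 3, 2, 2, 2),
                          effect_fraction = 0.02, effect_slope_sd = 0.0078,
                          effect_stratum = c("female", "male", "both"),
                          context_bias = 1,
                          effect_contexts = c("open_sea", "intergenic"),
                          category_freqs = default_category_freqs(),
                          seed = 1L) {
  effect_stratum <- match.arg(effect_stratum)
  cfg <- list(
    n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
    female_fraction = female_fraction, epds_mean = epds_mean,
    epds_sd = epds_sd, n_cell_types = as.integer(n_cell_types),
    chip_size = as.integer(chip_size), batch_shift_sd = batch_shift_sd,
    position_shift_sd = position_shift_sd, noise_sd = noise_sd,
    cell_profile_sd = cell_profile_sd,
    dirichlet_alpha = rep_len(dirichlet_alpha, as.integer(n_cell_types)),
    effect_fraction = effect_fraction, effect_slope_sd = effect_slope_sd,
    effect_stratum = effect_stratum, context_bias = context_bias,
    effect_contexts = effect_contexts, category_freqs = category_freqs,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  fr <- c(cfg$female_fraction, cfg$effect_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_cell_types < 2L) stop("n_cell_types must be >= 2")
  if (cfg$chip_size < 2L) stop("chip_size must be >= 2")
  if (cfg$chip_size > cfg$n_samples) stop("chip_size exceeds n_samples")
  for (scheme in c("island_context", "gene_context")) {
    f <- cfg$category_freqs[[scheme]]
    if (is.null(f)) stop("category_freqs must contain '", scheme, "'")
    if (any(f < 0)) stop(scheme, " frequencies must be nonnegative")
    if (abs(sum(f) - 1) > 1e-9) stop(scheme, " frequencies must sum to 1")
  }
  invisible(cfg)
}

#' Default genomic-context frequencies for synthetic annotation
#'
#' Island/shore/shelf/open-sea and genic-context proportions resembling the
#' composition of an EPIC-scale manifest.
#' @return List with probability vectors `island_context` and `gene_context`.
#' @export
default_category_freqs <- function() {
  list(
    island_context = c(island = 0.21, shore = 0.18, shelf = 0.06,
                       open_sea = 0.55),
    gene_context = c(promoter = 0.20, five_prime_utr = 0.08, exon = 0.10,
                     intron = 0.37, three_prime_utr = 0.03, intergenic = 0.22)
  )
}

#' Planted slope SD giving a target per-probe partial R-squared
#'
#' Returns the slope SD such that a probe with slope equal to the returned
#' value (the RMS of Normal(0, sd) slopes) has partial R-squared `r2` for the
#' EPDS term against residual M-scale noise of SD `noise_sd`:
#' `sd = sqrt(r2 / (1 - r2)) * noise_sd / epds_sd`.
#'
#' @param r2 Target partial R-squared in (0, 1).
#' @param noise_sd Residual M-scale noise SD.
#' @param epds_sd SD of the EPDS covariate.
#' @return Slope SD in M-value units per EPDS point.
#' @export
slope_sd_for_partial_r2 <- function(r2, noise_sd = 0.15, epds_sd = 4.4) {
  stopifnot(r2 > 0, r2 < 1)
  sqrt(r2 / (1 - r2)) * noise_sd / epds_sd
}

#' Generate synthetic probe annotation
#'
#' Draws, per probe, one CpG-density context (island / shore / shelf /
#' open sea) and one genic context (promoter / 5'UTR / exon / intron / 3'UTR /
#' intergenic) from the supplied frequencies, synthetic coordinates (0-based,
#' strictly increasing within each chromosome) and gene symbols (intergenic
#' probes carry none; all others at least one, with nearby probes sharing
#' symbols).
#'
#' @param n_probes Number of probes.
#' @param category_freqs As in [cohort_config()].
#' @param seed Integer seed (deterministic output for a given seed).
#' @param n_chromosomes Chromosomes to spread probes over. Default 22.
#' @return Data frame with columns `probe_id`, `chromosome`, `position`,
#'   `island_context`, `gene_context`, `gene_symbols` (";"-separated, "" for
#'   intergenic), `snp_flag`, `cross_hybridizing_flag`.
#' @export
generate_probe_annotation <- function(n_probes,
                                      category_freqs = default_category_freqs(),
                                      seed = 1L, n_chromosomes = 22L) {
  for (scheme in c("island_context", "gene_context")) {
    f <- category_freqs[[scheme]]
    if (is.null(f) || any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop(scheme, " frequencies must be nonnegative and sum to 1")
  }
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  probe_id <- sprintf("cg%08d", seq_len(n_probes))
  chromosome <- sort(sample(paste0("chr", seq_len(n_chromosomes)), n_probes,
                            replace = TRUE))
  ## strictly increasing 0-based positions within each chromosome
  position <- integer(n_probes)
  for (ch in unique(chromosome)) {
    i <- which(chromosome == ch)
    position[i] <- cumsum(50L + stats::rpois(length(i), 1500L))
  }
  island_context <- sample(names(category_freqs$island_context), n_probes,
                           replace = TRUE, prob = category_freqs$island_context)
  gene_context <- sample(names(category_freqs$gene_context), n_probes,
                         replace = TRUE, prob = category_freqs$gene_context)
  ## genes tile the genome in ~100 kb blocks so neighbouring probes share them
  block <- position %/% 100000L
  gene_symbols <- ifelse(gene_context == "intergenic", "",
                         toupper(paste0("G", sub("^chr", "", chromosome),
                                        "X", block)))
  data.frame(probe_id = probe_id, chromosome = chromosome,
             position = position, island_context = island_context,
             gene_context = gene_context, gene_symbols = gene_symbols,
             snp_flag = FALSE, cross_hybridizing_flag = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic methylation cohort with known ground truth
#'
#' Builds a full cohort bundle: per-cell-type baseline beta profiles, Dirichlet
#' sample compositions, composition-weighted mixed betas; chip-level batch
#' shifts and measurement noise added on the M-scale; EPDS scores drawn
#' Normal(mean, sd), rounded and clipped to \[0, 30\]; planted linear EPDS
#' effects (M-scale, slope x centred EPDS) in a configurable fraction of
#' probes, restricted to the configured fetal-sex stratum, with optional bias
#' toward chosen genomic contexts. The registry of planted effects, true
#' compositions and batch assignments is returned as ground truth.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"cohort_bundle"` with elements `beta` (probes x
#'   samples matrix in (0,1)), `samples` (sample sheet data frame),
#'   `annotation`, `reference` (cell-type mean beta matrix), and `truth`
#'   (list: `effect_probes` data frame, `true_compositions`,
#'   `batch_assignments`, `config`).
#' @export
generate_cohort <- function(config) {
  cfg <- if (inherits(config, "cohort_config")) config else
    do.call(cohort_config, config)
  validate_cohort_config(cfg)
  n <- cfg$n_samples; p <- cfg$n_probes; k <- cfg$n_cell_types

  annotation <- generate_probe_annotation(p, cfg$category_freqs,
                                          seed = cfg$seed + 1L)
  old <- withr_seed(cfg$seed)
  on.exit(restore_seed(old), add = TRUE)

  probe_ids <- annotation$probe_id
  sample_ids <- sprintf("S%04d", seq_len(n))
  cell_types <- paste0("CT", seq_len(k))

  ## (1) bimodal per-probe baselines, per-cell-type deviations on the M-scale
  state <- sample(3L, p, replace = TRUE, prob = c(0.35, 0.35, 0.30))
  base_beta <- c(stats::rbeta(p, 2, 10), stats::rbeta(p, 10, 2),
                 stats::rbeta(p, 5, 5))[(state - 1L) * p + seq_len(p)]
  base_m <- beta_to_m(base_beta)
  ref_m <- base_m + matrix(stats::rnorm(p * k, 0, cfg$cell_profile_sd), p, k)
  reference <- m_to_beta(ref_m)
  dimnames(reference) <- list(probe_ids, cell_types)

  ## (2) Dirichlet compositions and mixing on the beta scale
  g <- matrix(stats::rgamma(n * k, shape = rep(cfg$dirichlet_alpha,
                                               each = n)), n, k)
  comp <- g / rowSums(g)
  dimnames(comp) <- list(sample_ids, cell_types)
  mixed <- reference %*% t(comp)          # probes x samples

  ## (3) chips, batch shifts and noise on the M-scale
  chip <- paste0("chip", (seq_len(n) - 1L) %/% cfg$chip_size + 1L)
  chip_position <- sprintf("R%02d", (seq_len(n) - 1L) %% cfg$chip_size + 1L)
  m <- beta_to_m(mixed, 1e-6)
  for (ch in unique(chip)) {
    idx <- which(chip == ch)
    m[, idx] <- m[, idx] + stats::rnorm(p, 0, cfg$batch_shift_sd)
  }
  if (cfg$position_shift_sd > 0) {
    for (pos in unique(chip_position)) {
      idx <- which(chip_position == pos)
      m[, idx] <- m[, idx] + stats::rnorm(p, 0, cfg$position_shift_sd)
    }
  }
  m <- m + matrix(stats::rnorm(p * n, 0, cfg$noise_sd), p, n)

  ## (4) covariates
  epds <- pmin(pmax(round(stats::rnorm(n, cfg$epds_mean, cfg$epds_sd)), 0), 30)
  fetal_sex <- ifelse(stats::runif(n) < cfg$female_fraction, "female", "male")
  extraction_method <- sample(c("kitA", "kitB"), n, replace = TRUE)
  bisulfite_concentration <- round(stats::rnorm(n, 50, 5), 1)

  ## (5) planted stratum-specific EPDS effects, context-biased selection
  n_eff <- round(cfg$effect_fraction * p)
  effect_probes <- data.frame(probe_id = character(0), stratum = character(0),
                              slope = numeric(0), island_context = character(0),
                              gene_context = character(0),
                              stringsAsFactors = FALSE)
  if (n_eff > 0) {
    w <- rep(1, p)
    hits <- (annotation$island_context %in% cfg$effect_contexts) +
      (annotation$gene_context %in% cfg$effect_contexts)
    w <- w * cfg$context_bias^hits
    eff_idx <- sample.int(p, n_eff, prob = w)
    slope <- stats::rnorm(n_eff, 0, cfg$effect_slope_sd)
    in_stratum <- if (cfg$effect_stratum == "both") rep(TRUE, n) else
      fetal_sex == cfg$effect_stratum
    centred <- (epds - cfg$epds_mean)[in_stratum]
    m[eff_idx, in_stratum] <- m[eff_idx, in_stratum] +
      outer(slope, centred)
    effect_probes <- data.frame(
      probe_id = probe_ids[eff_idx], stratum = cfg$effect_stratum,
      slope = slope, island_context = annotation$island_context[eff_idx],
      gene_context = annotation$gene_context[eff_idx],
      stringsAsFactors = FALSE)
  }

  beta <- m_to_beta(m)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(probe_ids, sample_ids)

  samples <- data.frame(
    sample_id = sample_ids, epds = as.integer(epds), fetal_sex = fetal_sex,
    chip = chip, chip_position = chip_position,
    extraction_method = extraction_method,
    bisulfite_concentration = bisulfite_concentration,
    group = "A", stringsAsFactors = FALSE)

  structure(list(
    beta = beta, samples = samples, annotation = annotation,
    reference = reference,
    truth = list(effect_probes = effect_probes, true_compositions = comp,
                 batch_assignments = stats::setNames(chip, sample_ids),
                 config = cfg)
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic methylation cohort:",
      nrow(x$beta), "probes x", ncol(x$beta), "samples\n")
  cat("  female fetuses:", sum(x$samples$fetal_sex == "female"),
      " | chips:", length(unique(x$samples$chip)),
      " | planted effect probes:", nrow(x$truth$effect_probes),
      paste0("(", cfg$effect_stratum, " stratum)"), "\n")
  invisible(x)
}

## internal: set the RNG seed, returning the previous state for restoration
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
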