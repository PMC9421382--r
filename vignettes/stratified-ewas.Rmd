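---
title: "Methods: fetal sex-stratified methylome association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal sex-stratified methylome association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewastrat)
```

## The statistical question

`ewastrat` asks whether maternal depressive-symptom scores (EPDS, a 0–30
self-report scale) are associated with the maternal blood methylome in a
way that depends on fetal sex. The unit of inference is deliberately not
the single CpG: with cohort-scale samples and hundreds of thousands of
probes, individual effects are too small for epigenome-wide significance.
Instead, the per-CpG association p-values of an entire stratum are treated
as one sample and tested for departure from uniformity. Under the global
null every p-value is Uniform(0,1); a stratum-wide excess of small
p-values indicates a diffuse association signal even when no single probe
survives multiplicity correction.

## Pipeline and model

For each probe $g$ and each fetal-sex stratum separately, the package fits

$$\beta_g = \alpha_g + \gamma_g \,\mathrm{EPDS} + \sum_k \delta_{gk}
\mathrm{EccPC}_k + \text{technical covariates} + \varepsilon_g$$

by OLS on the methylation fraction (beta) scale, and reports the two-sided
$t$-test of $\gamma_g$. The p-values feed the one-sided
Kolmogorov–Smirnov statistic $D^+ = \max_i\,(i/n - p_{(i)})$, with tail
probability $\exp(-2 n D^+{}^2)$ (Birnbaum–Tingey exact form for
$n \le 100$). Probes with $p < 0.005$ are labelled EPDS-vCpGs
(sensitivity threshold $0.001$); their genomic-context composition is
compared to a reference probe set by two-sided Fisher exact tests, and
their gene mappings can be screened against user-supplied GMT collections
with a hypergeometric over-representation test, BH-adjusted.

Preprocessing before association: probe QC, conversion to M-values
$M = \log_2(\beta/(1-\beta))$, chip-effect removal with parametric
empirical-Bayes location/scale adjustment (ComBat, from the `sva`
package), back-conversion to betas, and the variable-CpG filter. Batch
adjustment happens on the M-scale, association on the beta scale; both
transforms are explicit operations so the choice is auditable.

Key assumptions: linear EPDS effects on methylation within stratum;
cell-mixture confounding captured by the top principal components of
estimated composition; chip effects additive/multiplicative per probe on
the M-scale; p-values across probes treated as independent by the KS test
(co-methylation makes this approximate; see Limitations).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `epsilon` (M-transform clip) | 1e-6 | beta | keeps M finite; round-trip exact on the clipped domain |
| vCpG `min_range` | 0.05 | beta | probes with trimmed range below 5 percentage points carry no usable inter-individual variation |
| vCpG `fence` | 1.5 | IQR multiples | Tukey's standard outlier rule; threshold inclusive (range = 5% retains) |
| detection p threshold | 0.01 | probability | boundary inclusive: p = 0.01 removes the probe |
| minimum bead count | 3 | beads | "fewer than 3" removes; 3 retains |
| `n_ecc_pcs` | 5 | components | five components span nearly all variation of a six-cell-type simplex |
| EPDS-vCpG `alpha` | 0.005 | probability | nominal selection threshold; 0.001 as sensitivity analysis |
| enrichment `alpha` | 0.05 | probability | per-context significance flag |
| deconvolution `tol` | 1e-8 | — | active-set KKT feasibility/convergence tolerance |

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of an
Infinium-style pregnancy cohort so that the full pipeline runs with no
external data and a recoverable truth:

1. **Baselines.** Each probe draws a bimodal baseline methylation level
   (35% low, Beta(2,10); 35% high, Beta(10,2); 30% intermediate,
   Beta(5,5)), mimicking the characteristic two-humped array beta
   distribution. Per-cell-type profiles deviate from the baseline by
   Normal(0, 0.5) on the M-scale, enough divergence for reference-based
   deconvolution to be well-posed.
2. **Mixtures.** Sample compositions are Dirichlet with concentration
   (12, 6, 3, 2, 2, 2) — one dominant cell type with realistic
   person-to-person variability, as in whole blood. Mixed betas are
   composition-weighted averages of the cell profiles.
3. **Technical structure.** Samples fill chips of 8 in order; each
   (probe, chip) pair receives an additive M-scale shift
   Normal(0, 0.2), and every value receives measurement noise
   Normal(0, 0.15) on the M-scale — the scale of replicate variability of
   mid-range array probes once biological cell-mixture variation is
   accounted for separately.
4. **Phenotype.** EPDS is Normal(7.0, 4.4) rounded and clipped to
   [0, 30], matching the published cohort moments without modelling
   zero-inflation; 47.7% of samples are assigned to the female-fetus
   stratum.
5. **Planted effects.** A fraction (default 2%) of probes receives a
   linear EPDS effect on the M-scale, $slope \times (\mathrm{EPDS} -
   \bar{\mathrm{EPDS}})$, applied only to samples of the configured
   stratum. Slopes are Normal(0, `effect_slope_sd`);
   `slope_sd_for_partial_r2(r2)` converts a target per-probe partial
   R² into the slope SD (RMS slope attains the target against the
   generator's residual noise). Probe selection can be biased toward
   chosen contexts (default open sea / intergenic) with odds multiplier
   `context_bias`.

Planting on the M-scale keeps slopes unbounded while betas remain in
(0, 1) after the inverse-logistic transform and clipping at $10^{-6}$.

**What the generator does not emulate:** probe-type chemistry (type I/II
bias), spatial chip-position gradients (available but off by default),
co-methylation correlation between neighbouring probes, genotype-driven
methylation, missing values, and any nonlinear or interaction structure
in the EPDS effect. Tests passing on synthetic cohorts therefore
demonstrate the pipeline's correctness and calibration under the stated
generative model, not the effect sizes or correlation structure of real
cohort data.

## Numerical choices

- **Perfect fits vs constants.** A probe constant within the stratum has
  no testable association and is flagged `degenerate` (no p-value). A
  probe fit perfectly by a nonzero slope gets the p floor $10^{-300}$,
  which also caps all downstream log-scale reporting.
- **Rank deficiency** of the stratum design flags all probes degenerate
  rather than silently dropping columns.
- **Categorical covariates** expand to treatment contrasts with the first
  observed level as reference; any full-rank coding gives identical EPDS
  inference.
- **Listwise deletion** of samples with missing EPDS or covariates, done
  once per stratum and recorded in the result's `n_dropped` attribute.
- **Deconvolution** solves the simplex-constrained least-squares problem
  exactly by an active-set method on the KKT system; returned proportions
  are renormalized so rows sum to one at machine precision.
- **Ecc PC signs** are fixed by making each loading's largest-magnitude
  entry positive, so results are reproducible across platforms.
- **Fisher two-sided p** uses the probability-mass rule (sum of tables no
  more probable than observed, relative tolerance $1 + 10^{-7}$), which
  yields the enrichment/depletion dual reporting with a single test; the
  sample odds ratio (with 0 and $\infty$ admitted) gives the direction.
- **TSV output** uses 10 significant digits so write-then-read round
  trips are exact below test tolerances.

## Decisions where the design was open

- The variable-CpG "excluding outliers" rule is made concrete as Tukey
  fences at 1.5 × IQR with an inclusive 5% threshold; both the fence
  multiplier and inclusivity are arguments.
- Probe QC removes a probe if *any* sample fails detection (the strictest
  reading); no per-value masking is offered, keeping downstream matrices
  complete.
- Per-CpG p-values are two-sided; directionality is assessed only at the
  distributional (KS) stage.
- The KS tail is asymptotic for large collections (the regime of
  $10^4$–$10^5$ vCpGs where the analysis operates) and exact below
  $n = 100$.
- ComBat is used in its full location-and-scale parametric form, the
  default of the cited algorithm. A consequence worth knowing: a second
  adjustment pass is *not* a strict no-op, because the per-batch
  estimates it shrinks on re-run are pure estimation noise; residual
  second-pass changes are of order $\sigma/\sqrt{n_{batch}}$ times the
  shrinkage factor, far below any planted shift but not zero.

## Validation scales

The test suite exercises the chain at sizes chosen to keep the full run
in minutes while leaving the statistical bands meaningful: null
calibration on 200 replicate cohorts of 150 probes × 50 samples
(KS rejection rate at 5% must land in [3%, 7%]); slope-recovery and the
sex-specific KS analogue at 20,000 probes × 200 samples; sex-specificity
and open-sea context recovery across 50 seeds at 6,000 probes × 160
samples with 4% planted probes at partial R² 0.4 and context bias 3.
Detectability of the distribution-level signal scales with the planted
fraction, the per-probe noncentrality
$|slope| \cdot sd(\mathrm{EPDS}) \sqrt{n_{stratum}} / \sigma$, and the
number of probes tested; at weak per-probe effects (partial R² ≈ 0.05)
the female-stratum KS p at this cohort size remains modest even though
the female/male contrast is already visible.

## Limitations

- The KS test treats per-CpG p-values as independent; correlated probes
  (co-methylation, shared cell-mixture residuals) make the reported
  uniformity p approximate. The Ecc-PC covariates remove the dominant
  shared component in both real and synthetic data.
- No raw-intensity processing: Noob/functional normalization, idat
  parsing and genotype-based sample QC belong upstream of this package.
- Gene-set content is user-supplied GMT only; gene symbols are harmonized
  by case and whitespace, without alias resolution.
- The reference-based deconvolution assumes the reference panel's cell
  types span the sample's composition; missing cell types bias the
  estimated proportions toward the available profiles.
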