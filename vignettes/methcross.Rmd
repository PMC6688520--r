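---
title: "Cross-comparative differential methylation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-comparative differential methylation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `methcross`, the
assumptions behind it, the parameters that matter, and the choices we made
where the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The per-site model

Methylation is measured as a beta-value β ∈ [0, 1], the fraction of
methylated alleles at a CpG site in a sample. For a comparison of a case
group against a reference group, each site is fitted by ordinary least
squares on the samples of those two groups only:

β = intercept + γ·case + sex + age + cell proportions + error,

with the two-sided t-test on γ (residual degrees of freedom n − k)
providing the p-value. Assumptions: approximately homoskedastic,
symmetric within-site noise, effects additive on the β scale, and no
unmodelled structure beyond cell composition (batch effects are assumed
removed upstream; see Non-goals below).

**β versus M-values.** We model β directly. Effect sizes are reported and
thresholded as Δβ, and β-scale modelling keeps the coefficient on the same
scale as the threshold; the known heteroskedasticity of β near the
boundaries mainly costs power at extreme sites rather than validity, and
the type-I error of the β-scale model is verified by simulation in the test
suite. A `use_m_values` toggle fits log2(β/(1−β)) instead for users who
prefer the variance-stabilised scale; group means and Δβ stay on the β
scale either way.

**Δβ is deliberately decoupled from γ.** Δβ = mean(case) − mean(reference)
on raw betas, while significance comes from the adjusted model. The two
answer different questions (how large is the raw difference; is there a
difference after covariate adjustment), and the DMC definition combines
them: p < α/m (Bonferroni over the m tested sites, strict) **and**
|Δβ| > 0.05 (strict). Direction (hypo/hyper) is the sign of Δβ, not of γ;
a site with Δβ exactly 0 can never be called, and is excluded from
direction-concordance logic as unclassifiable.

**Degenerate fits.** With exactly zero residual variance, a zero case
coefficient is reported with p = 1 (so constant-β fixtures remain
runnable); a nonzero coefficient with zero residual variance is an error —
it means perfect separation that the t-test cannot describe. Covariates
that are constant in the modelled subset (for instance sex in an
all-female subgroup) are dropped from the design rather than tripping the
rank check; genuinely collinear designs are an error. p-values are clamped
to ≥ 1e-300 to respect the p ∈ (0, 1] contract under extreme separation.

## 2. Cell-composition adjustment

Whole blood is a mixture; diseases shift its composition (toward
granulocytes in active autoimmunity), and composition shifts masquerade as
methylation differences genome-wide. We estimate per-sample proportions by
constrained projection onto reference methylomes of sorted cell types:
minimise ‖β − R·w‖² subject to w ≥ 0, Σw ≤ 1 (solved exactly with a
quadratic-programming solver; the test suite verifies the solution
dominates an exhaustive 0.001-resolution grid).

Design choices:

* **Σw ≤ 1, not = 1, and no renormalisation.** Forcing the sum to one
  would make the proportion covariates exactly collinear with the
  intercept; the inequality keeps the EWAS design full-rank so all
  estimated cell types can enter the regression with no reference-category
  drop. A rank check guards pathological references, naming the collinear
  cell types.
* **Marker panel.** Sites are ranked per cell type by the gap between that
  type's β and the nearest other type; the top `n_per_type` hyper- and
  hypomethylated markers per type are pooled. `n_per_type = 50` is a
  conventional default (there is no canonical value in the literature);
  it is recorded in the run configuration and the sensitivity to it is low
  once the panel spans all types.

## 3. Shared, unique, and indeterminate DMCs

Given the two case-control EWASs over a common site universe:

* A disease's DMC is **shared** if the other disease's EWAS shows
  p < 0.05/n<sub>ref</sub> — where n<sub>ref</sub> is the DMC count of a
  designated reference disease (configurable; conventionally the larger,
  better-powered EWAS) — with the same Δβ sign. The same cutoff is applied
  in both directions, and the two directed lists are merged, duplicates
  removed, into the combined shared set with provenance recorded.
* A DMC is **unique** if the other EWAS shows p > 0.05 (strict).
* DMCs with other-disease p between the sharing cutoff and 0.05 are
  labelled **indeterminate** and retained — forcing them into either set
  would overstate certainty. Sites below the sharing cutoff with opposite
  signs are labelled **discordant** and reported separately; the
  classification scheme itself does not define them, so we surface rather
  than silently drop them.

The direct case-case EWAS (disease A vs disease B, same covariates,
genome-wide Bonferroni, |Δβ| > 0.05) complements the scheme: it finds
quantitative differences at sites that may be qualitatively shared, and
the pipeline reports what fraction of case-case DMCs are DMCs in both
case-control comparisons.

## 4. Signature MDS and enrichment

`mds_embed()` is classical (Torgerson) scaling of pairwise Euclidean
distances over a site panel — by default DMCs at the ten interferon-module
genes of the synthetic cohort. The paper-silent choices: Euclidean on raw
β (the natural metric for bounded fractions at a small panel), the
double-centred Gram matrix's top-2 eigenpairs, and axis signs fixed by
forcing the first sample's coordinate nonnegative, making embeddings
reproducible across runs. Stratified subgroup means (control, disease A,
serology-positive and -negative disease B) quantify the same structure
without ordination.

Regional enrichment is a chi-square goodness-of-fit of the DMC category
distribution (gene regions or CpG-island relation) against the full tested
probe background. Per-category flags come from standardized residuals at a
Bonferroni-corrected level whose divisor is the number of categories in
the run — we never hard-code a published corrected α, since the divisor
follows from the analysis actually performed and is logged. Expected
counts below 5 trigger a warning and a fallback to Monte-Carlo overall and
exact binomial per-category p-values. Chromatin-mark overlap uses the BED
convention exactly: a CpG at 1-based position p overlaps a 0-based
half-open interval [s, e) iff s ≤ p − 1 < e; conversion happens only
inside the overlap routine, and annotation and track must share a genome
assembly (and chromosome naming — verified, with unmatched names listed).

## 5. The classifier and its leakage contract

Random-forest prediction follows the standard protocol for
methylation-based disease classification: three iterations of five-fold
class-stratified cross-validation (the sources are silent on
stratification; we stratify because the smallest class may hold only a few
samples), 1,000 trees, mtry = 300, and per-fold screening to the top
1,000 label-associated sites by per-site simple regression — "approximately
the top 1000" is implemented as exactly k = 1,000 (configurable) for
determinism, with ties broken by |coefficient| then site id. Screening is
computed on training folds only; the test suite enforces this by
corrupting held-out samples and asserting the selection is unchanged, and
quantifies the alternative: on null data, screening once globally before
cross-validation inflates AUC by upwards of 0.15 (the `feature_selection =
"global"` mode exists solely to demonstrate this bias).

AUC is the Mann–Whitney pair-counting statistic (ties count ½), computed
via midranks; a dual-formula test verifies equality with the trapezoidal
ROC integral to 1e-10. The aggregation of AUC across folds/iterations is
not standardised in the sources, so the result object reports per-iteration
AUCs, their mean, and the pooled-over-everything AUC.

## 6. What the synthetic cohort does and does not emulate

`simulation_design()` defaults describe the study conditions at one tenth
scale: 40/35/10 controls/disease-A/disease-B samples, 20,000 autosomal
sites. The generator emulates:

* a majority-hypomethylated shared component (`frac_hypo = 0.72`) with
  intermediate effect sizes in disease B (`delta_B = 0.14 < delta_A =
  0.2`, matching the ~0.6–0.75 effect-size ratio of reported top shared
  sites);
* an interferon-like module (30 sites, always hypomethylated) driven by
  all of disease A but only the serology-positive 75% of disease B;
* cell-composition confounding: per-sample proportions are Dirichlet
  draws (concentration 150, i.e. between-sample SD of a few percent)
  around a realistic blood base composition, shifted toward granulocytes
  in cases by `confound_strength = 0.1`;
* age and sex effects, additive on the logit scale (0.002 per year;
  0.05 male vs female — small, as methylation covariate effects are);
* beta-distributed noise with mean/precision parameterisation
  (`precision = 100`, per-site SD ≈ 0.05 at β = 0.5, heteroskedastic and
  bounded like array betas). There is no published quantitative noise
  model for these data; the default is chosen so planted Δβ ≈ 0.05 sits
  near the detection boundary at the default sample sizes, which is where
  the published thresholds operate.

Mechanics worth knowing: effects are injected on the logit scale and
back-transformed (keeping β bounded), with the per-site logit shift solved
so the β-scale shift equals the nominal delta at that site's baseline;
planted sites are drawn only at baselines with enough headroom for the
full shift, and never at deconvolution marker sites; the ground truth
records the *realized* per-group latent Δβ (mean latent case minus control
level), which is what recovery tests compare against. Non-marker sites
carry small cell-type-specific deviations (≤ 0.15 β) so that composition
confounding has the genome-wide footprint it has in real blood — while the
planted markers remain, by construction, the only sites with between-type
gaps ≥ 0.5.

Not emulated: probe-chemistry artifacts, batch effects, genomic
correlation between neighbouring CpGs, population structure, and realistic
annotation geometry (gene regions and island relations are drawn
independently per site). Passing tests therefore show the *pipeline*
recovers planted structure under realistic noise and confounding — not
that preprocessing of raw array data is handled, nor that effect sizes in
any particular real cohort will match.

## 7. Numerical and reproducibility choices

* Thresholds are exact internally (α/m with no rounding); display
  rounding to 2 significant figures happens only in reports, e.g.
  0.05/385,962 prints as 1.3 × 10⁻⁷.
* p-values are written to results files with 6 significant digits.
* Observed betas are clamped to [1e-6, 1 − 1e-6]; mixture means to
  [1e-4, 1 − 1e-4] before the logit.
* Every stochastic stage takes a seed; the pipeline expands one global
  seed into per-stage seeds by fixed offsets so a single stage can be
  re-run bit-identically, and a full rerun reproduces `summary.json`
  byte for byte. Scientific results should never depend on the seed:
  the acceptance script recomputes all quantities from whatever seed it
  is given.
* Problem sizes in tests and the acceptance script (2,000–20,000 sites,
  cohorts of 40–200 samples, forests of 300–1,000 trees) are chosen so
  each check has clear statistical resolution — binomial 99% bands for
  calibration at 5,000 sites, several-SD-wide AUC bands at 200 samples —
  while a full run remains a desk-scale computation. The permuted-label
  null in particular uses 100 + 100 samples of an exchangeable cohort
  (no planted effects, no covariate effects, tight cell composition):
  at smaller n the null AUC's sampling SD (~0.1) would make any
  two-sided band meaningless, and latent composition axes can correlate
  with a label draw by chance.

## 8. Known limitations

* A single gene symbol per site; multi-gene probe annotations are not
  supported.
* No meta-analytic or heterogeneity treatment of the two EWASs — sharing
  is a threshold rule, faithful to the scheme it implements, not an
  effect-size model.
* No genomic-control/inflation correction or surrogate-variable analysis;
  confounding handling is limited to the modelled covariates.
* The deconvolution reference must be supplied (or simulated); acquiring
  real sorted-cell references is out of scope.
* IDAT parsing, normalisation and probe QC are out of scope; inputs are
  assumed post-QC and complete (missing betas are a load error by design,
  not imputed).
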