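# methcross

Cross-comparative epigenome-wide differential methylation analysis for two
diseases against a shared control group, with a synthetic-cohort generator
that plants ground truth for every stage.

## The problem

Systemic autoimmune diseases such as systemic lupus erythematosus and primary
Sjögren's syndrome show overlapping blood DNA-methylation changes — most
prominently coordinate hypomethylation of type I interferon-regulated genes —
alongside disease-specific alterations. Quantifying which differentially
methylated CpG sites (DMCs) are *shared* between two diseases, which are
*unique* to each, and how well methylation predicts disease status requires a
chain of analyses: covariate-adjusted per-CpG regression, reference-based
cell-composition correction, a sharing/uniqueness classification scheme,
signature ordination, functional-region enrichment, and a leakage-safe
cross-validated classifier. `methcross` implements that chain as a tidyverse
package for epigenomics analysts: every user-facing function takes a data
frame (or a `beta_matrix`) first and returns a tibble, so stages compose with
the pipe; fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## The model

For each CpG site *j* with methylation fraction (beta-value)
β<sub>ij</sub> ∈ [0, 1] in sample *i*, disease status is tested with ordinary
least squares

&nbsp;&nbsp;β<sub>ij</sub> = α<sub>j</sub> + γ<sub>j</sub>·case<sub>i</sub> +
sex<sub>i</sub> + age<sub>i</sub> + **w**<sub>i</sub> + ε<sub>ij</sub>

where **w**<sub>i</sub> are the sample's blood cell-type proportions,
estimated by constrained projection onto flow-sorted reference methylomes
(min<sub>w</sub> ‖β<sub>i</sub> − R·w‖² s.t. w ≥ 0, Σw ≤ 1, the
Houseman approach). A site is a DMC when p < α/m (Bonferroni over the m
tested sites; 0.05/385,962 displays as 1.3 × 10⁻⁷ on a post-QC 450k array
universe) **and** |Δβ| > 0.05, where Δβ is the difference of raw group
means. A DMC of one disease is *shared* when the other disease's EWAS shows
p below a secondary Bonferroni cutoff (0.05 over the reference disease's DMC
count) with the same direction of effect, and *unique* when the other EWAS
shows p > 0.05; the two directed shared lists are merged, deduplicated, into
a combined shared set. Disease status is predicted by a random forest
(1,000 trees, mtry = 300) inside 3 × 5-fold cross-validation, the top 1,000
label-associated sites re-selected within each training fold only, and
performance summarised as the Mann–Whitney pair-counting AUC of pooled
out-of-fold probabilities.

## Worked example

```r
library(methcross)

cfg <- run_config(
  design = simulation_design(n_sites = 5000, n_shared = 150, n_unique_A = 60,
                             n_unique_B = 25, n_module_sites = 15),
  cv = cv_design(n_iterations = 3, n_folds = 5, n_selected_sites = 500,
                 mtry = 150, n_trees = 500),
  seed = 2026)
summary <- run_pipeline(cfg, quiet = TRUE)
summary
#> <run_summary>
#>   5000 sites x 85 samples (seed 2026)
#>   DMCs: A=225 B=145 | shared=155 (155 from A, 122 from B) | unique A=57 B=22
#>   case-case DMCs: 101 (10% also DMC in both case-control EWASs)
#>   AUC A_vs_control: mean 1.000
#>   AUC B_vs_control: mean 1.000
#>   AUC B_seropositive_vs_control: mean 1.000
#>   AUC B_vs_A: mean 1.000

glance(summary$objects$cross$dmcs_A)
#>   case_group reference_group n_dmcs n_tested p_cutoff p_cutoff_display
#> 1  disease_A         control    225     5000    1e-05        1 × 10^-5
#>   delta_cutoff n_hypo n_hyper pct_hypo pct_hyper
#> 1         0.05    169      56       75        25

truth_confusion(summary$objects$cross$shared, summary$objects$truth,
                c("shared", "module"))
#>    tp fp fn sensitivity fdp
#> 1 155  0 10   0.9393939   0
```

The cohort here is a desk-scale synthetic analogue of a two-disease blood
EWAS: 40 controls, 35 disease-A and 10 disease-B samples over 5,000 CpG
sites, with 150 planted shared effects (72% hypomethylated, disease B
intermediate), disease-unique effects, an interferon-like module driven by
the serology-positive disease-B subgroup, granulocyte-shifted cell
composition in cases, and age/sex covariate effects. The `run_summary`
shows the chain recovering that structure: 225 disease-A DMCs at the
Bonferroni cutoff (printed both exactly and display-rounded), a combined
shared set of 155 sites of which none are false discoveries against the
planted truth, and out-of-fold AUC of 1.0 under the strong planted
separation. Individual stages are equally usable on their own —
`run_ewas() |> call_dmcs() |> summarize_directions()`,
`mds_embed() |> autoplot(sheet)`, `crossval_predict()` — and on real data
loaded with `read_beta_matrix()` / `read_sample_sheet()`.

A command-line wrapper (`inst/cli/methcross.R`) exposes the stages as
subcommands (`simulate | deconvolve | ewas | crosscompare | characterize |
predict | run-all`) over the same functions.

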