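---
title: "Methods: pharmacologic profiling of PDX-derived tumor cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacologic profiling of PDX-derived tumor cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, the parameter choices, and the design
decisions behind `pdxscreen`, and is explicit about what the synthetic
validation does and does not establish.

## The screening design

The pipeline targets viability screens of PDX-derived tumor cells (PDTCs)
in 384-well plates read out by ATP bioluminescence: drugs at a fixed
three-dose ladder (10.0, 1.0, 0.1 µM) in 3–4 technical replicates, with
on-plate DMSO vehicle wells and a cytotoxic positive control (anisomycin)
on every plate. Screens of this shape trade dose resolution for library
breadth, which has two consequences that run through the whole package:
potency is only coarsely identified, and per-curve summaries must be robust
to the occasional bad well rather than to systematic lack of fit.

## Normalization

Each drug well is converted to fraction-affected,
`FA = 1 − X_c / X_DMSO`, where `X_DMSO` is the **median** luminescence of
the same plate's DMSO wells (median, not mean, so single bad vehicle wells
cannot shift a whole plate). FA is deliberately **not clipped** at this
stage: `FA < 0` (signal above vehicle) is a real observation — growth
stimulation or a dispensing artifact — and should stay visible in the
normalized table. Clipping to `[0, 1]` happens exactly once, when the
fitted curve is integrated into an AUC, because the 0–1 activity scale is
what makes AUC values comparable across drugs and models.

## The cascade dose–response model

`fit_cascade()` fits the rising four-parameter logistic

FA(x) = bottom + (top − bottom) / (1 + 10^((a − x)·h)),

with `x` = log10 dose, `a` = log10 AC50 and `h` > 0 the Hill slope, by
iteratively reweighted least squares, and falls back to a straight line in
log10 dose when the 4PL cannot be supported. Choices, in order of
consequence:

* **Identifiability on three doses.** A 4PL evaluated at only three
  distinct doses has a column-rank-3 Jacobian — four parameters cannot be
  identified no matter how many replicates are present. When the design has
  exactly three distinct doses the bottom asymptote is therefore **pinned
  at 0**, which is not an approximation but a fact of the normalization: an
  untreated well has FA = 0 by construction. With four or more distinct
  doses all four parameters float.
* **Bounds.** bottom ∈ [−0.5, 0.5], top ∈ [−0.5, 1.5], h ∈ [0.1, 10], and
  `a` within the tested log-dose range ± 1. The box keeps the optimizer out
  of regions where the three-point data carry no information, and is wide
  enough that real curves never sit on a bound.
* **Robust weights.** Tukey bisquare with tuning constant 4.685 on
  residuals scaled by the MAD, updated each iteration. On a 9–12 point
  curve this lets one discordant replicate be down-weighted without
  distorting the asymptotes; it is the reason a single outlier moves the
  fit measurably less than under plain least squares (a property the test
  suite asserts on constructed cases).
* **Optimization.** Levenberg–Marquardt steps on the weighted problem with
  an analytic Jacobian, projected onto the box; the damping makes the
  normal equations solvable even near rank deficiency. Initialization is
  deterministic (top/bottom from the extreme mean FA, `a` at the middle
  dose, `h` = 1) and there are no random restarts, so fits are exactly
  reproducible.
* **Fallback triggers.** Linear least squares replaces the 4PL when the fit
  does not converge in 50 iterations, the Jacobian is numerically
  rank-deficient at the solution, or the Hill slope sits on a bound without
  beating the line's RMSE — the signature of a curve too shallow for a
  three-point design to support. Constant FA short-circuits to a flat
  linear fit. The branch taken is recorded in every fit record.

**AUC** is the mean of the fitted curve clipped to [0, 1] over the tested
log-dose window, computed by a fixed 2001-point composite Simpson rule
(deterministic; the clipping kinks are resolved far below the 10⁻⁶ level at
this grid). The tests check it against adaptive quadrature and against the
closed-form integral of the unclipped 4PL. **IC50** is the dose where the
fitted curve crosses FA = 0.5 inside the window; curves that never reach
0.5 get a flagged `NA` ("no crossing"), not an error, because shallow and
inactive curves legitimately have no IC50.

## Quality control

**Z′** uses the standard definition on raw RLU,
`1 − 3(σ_pos + σ_veh)/|μ_pos − μ_veh|`, with sample standard deviations; it
is invariant to affine rescaling of the reader signal.

**MSR** is `10^(2√2·s)` with `s` the SD of replicate log10 potencies. Two
decisions needed to be made here because a three-point design makes potency
fragile:

* **Which potency.** The potency entering MSR is the log10 of the fitted
  curve's in-window FA = 0.5 crossing (for a full 0-to-1 curve this *is*
  the log10 AC50). The raw `a` parameter of a partial-efficacy curve is the
  worst-identified quantity in the whole fit — its per-replicate scatter
  reflects optimizer geometry, not assay reproducibility — whereas the
  half-effect crossing is pinned by data inside the tested window.
* **Which drugs.** MSR is computed only for qualified drug–model pairs:
  the pooled fit is a converged 4PL with top ≥ 0.8 and an in-window
  crossing, and at least two replicates yield a potency. This mirrors
  standard potency-assay practice (MSR is defined over compounds with
  valid, qualified potency determinations); partial responders simply do
  not have a well-defined potency at three doses, and including them would
  measure fit degeneracy, not the assay.

## Clustering and activity classes

AUC matrices are clustered on both axes with Euclidean distance and Ward
("ward.D2") linkage — a conventional choice for bounded activity profiles,
recorded in the output metadata so external reproductions can sweep
alternatives; leaf order is not a contract. The drug tree is cut at `k = 3`
(exposed as a flag) and the clusters are named by ascending mean AUC:
*inactive*, *selective*, *pan-active*. Drugs missing in more than 20% of
models are dropped before clustering (threshold exposed), then any model
still carrying missing values; both drops are reported. Cluster–subtype
enrichment uses Pearson's chi-squared without continuity correction, with
optional exclusion of named orphan clusters; with 16 models the asymptotic
p is a descriptive index rather than a calibrated test (the suite checks
calibration at larger n).

## Selectivity and pharmacogenomics

Per-drug subtype selectivity is the one-way ANOVA omnibus p at α = 0.05,
after excluding named subtypes (default IM and UNS) and any subtype with
fewer than `min_n = 2` models — a singleton group contributes no
within-group information. Zero within-group variance is handled exactly:
p = 0 when means differ, p = 1 when they do not. Mutation associations are
drug-wise two-group F-tests with Sidak correction
`p_adj = 1 − (1 − p)^m`; the default family is the number of drugs screened
for the gene (the drug-wise screen), with `m` exposed because the choice of
family is a reporting convention, not a statistical necessity.

## ssGSEA

The per-sample enrichment score follows the rank-weighted (Barbie-style)
formulation: genes sorted by expression descending, the gene at position
`i` of `N` carrying rank score `N − i + 1`; ES is the summed difference
between the in-set cumulative distribution weighted by
`(rank score)^alpha` (α = 0.25 by default, exposed) and the uniform
out-of-set cumulative distribution. Two deliberate simplifications:

* **No set-size renormalization of raw ES.** Downstream use z-normalizes
  each pathway across samples (that is what the heatmaps and correlation
  screens consume), so only within-pathway relative values matter.
  Consequently **absolute ES values are not comparable across
  implementations** — only ranks and correlations are — and the package
  makes no claim otherwise.
* **Deterministic ties.** Tied expression is broken by gene-identifier
  order, so scores are reproducible across runs and platforms; an
  all-constant sample falls back to gene order with a warning.

"Consistently active" pathways are ranked by mean raw score with the SD
reported alongside — z-scores cannot serve here since every z row has mean
0 by construction. Correlation screens report Pearson r with its exact
t-distribution p and the dual pass threshold (p < 0.05 and |r| ≥ 0.70);
single-gene screens apply log2(TPM + 1) first, the same variance-taming
transform used for patient–PDX concordance (the transform is a convention
choice; it is recorded here and in the function signatures).

## The synthetic world

`synth_config()` describes the world the generators emit; its defaults are
the stated screening conditions, chosen once:

| parameter | default | why |
|---|---|---|
| models | 16 (2 BL1, 4 BL2, 1 IM, 4 LAR, 4 M, 1 UNS) | the profiled cohort's census |
| doses | 10.0 / 1.0 / 0.1 µM, 3 replicates | the screening design |
| vehicle wells | 16/plate, mean 10,000 RLU, CV 5% | typical CellTiter-Glo vehicle behavior; expected Z′ ≈ 0.83 |
| positive control | 16/plate, 95% kill, CV 10% | anisomycin-like full-kill control |
| replicate potency jitter | 0.05 log10 units | analytic expected MSR `10^(2√2·0.05)` ≈ 1.38, i.e. a reproducible assay |
| drugs | 60 (40% inactive / 35% moderate / 25% pan-active plus planted slots) | desk-scale; library size does not enter per-plate or per-drug QC statistics |
| expression | 1,200 genes, 20 disjoint sets of 25 | desk-scale module structure |

The per-plate control-well counts are not stated anywhere for the original
screens; 16 + 16 is a common 384-well layout and is exposed in the config.
Luminescence noise is multiplicative mean-one log-normal at the stated CV
(plate readers are heteroscedastic; the noise model itself is a design
decision). Each technical replicate perturbs the true log10 AC50 once,
shared across its doses, so replicate potency scatter has a known analytic
size. Planted structure is exact where exactness is checkable: the
mutation–drug pair shifts carrier models' true AUC by exactly its stated
effect (solving for the top asymptote through the closed-form AUC
integral), and the pathway–drug pair drives member genes with a latent
variable constructed by Gram–Schmidt to have *exactly* the target sample
correlation with the drug's true AUC — the realized ssGSEA correlation is
then attenuated only by the rank transform (about 0.78 realized at a
planted 0.8). A trio of drugs shares one activity profile to emulate a
common mechanism of action, and one gene set has a uniformly high baseline
to emulate a constitutively active pathway.

**What the generator does not emulate** — and therefore what a green test
does *not* establish: plate-edge effects, signal drift, dispensing
carryover, growth-rate differences between models (faster-growing cultures
inflate apparent sensitivity of everything), batch effects between screens,
and correlated noise across wells. QC reproduction on synthetic screens
shows the statistics and thresholds behave as specified under the stated
noise model, not that any particular laboratory's plates would pass.

## Validation and known limitations

The acceptance suite reproduces the two printed assay-quality claims on the
default world (mean Z′ ≥ 0.75, mean MSR < 2), checks the numerics against
independent oracles (dense grid search for the 4PL, adaptive quadrature and
the closed form for AUC, a brute-force cumulative-sum oracle for ssGSEA, a
10,000-permutation oracle for ANOVA), verifies parameter recovery (median
log10 AC50 error ≤ 0.2 for strong responders at default noise), and
measures planted-association recovery over 50 seeds. Known limitations:

* With three doses the 4PL is fit under a pinned bottom and box
  constraints; parameters other than the in-window crossing should be read
  as curve descriptors, not physical constants.
* Planted pathway recovery sits essentially at its 90% design point
  (45/50 seeds at the dual threshold with n = 16): a correlation of 0.8
  measured at 16 models against a ≥ 0.70 cutoff leaves little margin, which
  is a property of the screen size, not of the implementation.
* The 50-seed recovery loop runs a 12-drug world rather than the 60-drug
  default to stay inside the desk-time budget; all planted structure is
  retained and the Sidak family is held at 600 (conservative).
* Chi-squared enrichment p-values at 16 models are descriptive; the
  calibration property is established at larger n.
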