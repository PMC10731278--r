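---
title: "Comprehensive evaluation of stress tolerance: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive evaluation of stress tolerance: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotol)
```

## The problem

Screens of stress tolerance — fungal ecotypes on cadmium-amended media,
inoculated seedlings in metal-spiked soil, crop germplasm under drought or
salt — measure many traits per genotype under paired control and stress
treatments. No single trait ranks the genotypes reliably: traits differ in
units, in variance, and in how directly they reflect tolerance. The fuzzy
membership-function comprehensive evaluation condenses such a screen into
one dimensionless score per genotype, the comprehensive D value, and is the
de facto standard in the agronomy and mycorrhiza literature for ranking and
classifying tolerance.

`ecotol` implements the full chain as tested, composable functions:

1. **Resistance coefficients.** For each genotype and indicator (a trait at
   one stress level), CRC = 100 x (mean trait value under stress) / (mean
   control value). Replicates are averaged *before* the ratio — the screen
   reports one coefficient per genotype and indicator, and per-replicate
   ratios would inflate the variance of the ratio estimator. CRC is
   scale-invariant, so traits in any units are comparable.
2. **Membership functions.** Each indicator column is min-max normalized
   across genotypes, U = (X - Xmin) / (Xmax - Xmin), mapping the weakest
   genotype to 0 and the strongest to 1.
3. **Comprehensive indices and weights** (multi-trait evaluations). The CRC
   matrix is column-standardized and decomposed by PCA; the component
   scores are the comprehensive indices F1..Fm, and each component's share
   of total variance (its contribution rate P, in percent) yields its
   weight W = P / sum(P). With g genotypes, at most g - 1 components carry
   variance, so a four-genotype screen is always summarized exhaustively by
   three components.
4. **D scores.** Unweighted: D is the row mean of the membership matrix
   (used when the indicators are one trait at several doses and count
   equally). Weighted: membership is taken over the component scores and
   D = sum(W x U). Either way D is in [0, 1] and larger D means more
   tolerant. With uniform weights the two definitions coincide exactly.
5. **Tolerance classes.** The D values are clustered hierarchically and cut
   into non-/low-/high-tolerant classes.
6. **Cross-level association.** D vectors from two levels of the same
   biology (free-living strains vs the seedlings they mycorrhize) are
   correlated with an exact small-sample Pearson t test.

## Conventions the data do not fix

Several choices are mathematically open; `ecotol` fixes them
deterministically and documents them here.

**Component sign orientation.** PCA scores are defined only up to sign, but
the sign changes the min-max membership and hence D. Each component is
oriented so the sum of its loadings is positive; an exact zero sum is
broken by the sign of the largest-magnitude loading. When scoring a
published index table directly (the `from_indices` pipeline entry or
`membership_values()` on a printed F matrix), the printed signs are taken
as given and no orientation is applied.

**Dendrogram scale and the default cut.** Clustering uses between-groups
average linkage on squared Euclidean distances of D — the default
agglomeration of the major commercial statistics packages. Because D lies
in [0, 1], raw squared merge heights are tiny and no absolute cut such as
"distance 8" is meaningful on them; cuts are therefore defined on the
conventional 0-25 rescaled dendrogram axis. `ecotol` draws that axis on the
*root* (Euclidean) scale of the merge heights, rescaled linearly so the
final merge sits at 25. On the packaged ten-strain worked example this
convention, cut at the default height 8, reproduces the published
three-class partition exactly; rescaling the squared heights directly
would merge the low- and non-tolerant classes at the same cut. Both `k`
and `cut_height` are exposed, so a class count can always be requested
explicitly. Merge-height ties are broken by ordering genotypes by label
before clustering, which also makes the result independent of input order.

**Degenerate columns.** An indicator with identical values in every
genotype has no membership function. The default is an error naming the
column; `degenerate = "drop"` removes it with a warning. Silently mapping
it to 0.5 would shift every D score and is never done. Likewise a zero
control mean leaves the resistance coefficient undefined and is always an
error, and a missing stress cell either errors (default) or drops the
whole indicator (`missing = "drop_indicator"`) — dropping only the
genotype would silently change the PCA weights.

**Lower-is-better indicators.** Damage markers such as malondialdehyde
fall with tolerance, not rise. The screen convention for them is not
standardized; `ecotol` inverts such indicators (100 x control / stress)
when declared with `direction = "lower"`, and treats all indicators as
higher-is-better by default, which is what the packaged worked examples
assume.

**Ranks and ties.** Ranks are assigned by descending D; ties share the
smaller rank and report order is stable in input order.

**Numerical tolerances.** All computation is in double precision.
Comparisons against printed three-decimal tables use an absolute tolerance
of 0.002 to absorb input rounding (0.001 for the published correlation and
its p value, which are printed with the same precision they are computed
at). `comprehensive_indices()` refuses input whose columns are not
standardized (mean within 1e-6 of 0, sd within 1e-4 of 1) rather than
silently re-standardizing, so the preprocessing is always explicit.

## The synthetic generator

Real screens of this kind publish their phenotype data as figures, not
tables, so validation needs data with known truth. `generate_trait_table()`
plants a latent tolerance per genotype on [0, 1] and produces a replicated
control/stress trait table around it:

- expected retention of trait t for genotype g at dose d is
  `exp(-sensitivity_t * d * (1 - tolerance_g))` (default) or the linear
  analogue `max(0, 1 - ...)`, which can reach exact zero growth — the
  fully-inhibited phenotype a screen observes for susceptible isolates;
- control means vary between genotypes with a lognormal CV
  (`control_cv`, default 0.25), as colony areas do even without stress;
- replicates get multiplicative lognormal noise with mean 1 and the
  configured CV (`noise_cv`, default 0.05) — trait values are positive and
  CVs, not additive SDs, are the natural error scale for areas and
  biomass.

The default configuration mirrors a ten-strain screen: one trait (colony
area, control mean 4 cm^2) at doses 2, 4, 6, 8 mg/L with three replicates,
`sensitivity = 0.5` per mg/L so that an intolerant genotype retains about
2% of its growth at the highest dose while a 0.9-tolerance genotype
retains about two thirds. The latent tolerance is attached to the returned
table as an attribute and serves as the recovery oracle: at zero noise the
unweighted D ranking equals the planted ranking exactly, and mean Spearman
recovery over 100 seeds declines monotonically as `noise_cv` rises through
0, 0.05, 0.2, 0.5.

What the generator does *not* emulate: correlated noise between traits,
dose-dependent variance, hormetic (non-monotone) dose responses, or any
mechanistic growth/uptake model. Passing the recovery tests therefore shows
that the evaluation chain inverts the generator's statistical structure,
not that it is robust to every pathology of real phenotype data.

## Problem sizes and runtime

The packaged worked examples are desk-scale (4-10 genotypes, 3-4
components) and evaluate in milliseconds. The property-style tests use
random matrices up to 5 x 5 against brute-force oracles coded directly
from the defining formulas, 25 random 1-D clustering fixtures up to n = 12
against an exhaustive contiguous-partition search, a 100-seed by 4-level
noise sweep for the recovery trend, and 100,000-200,000 draws for the
permutation null of the correlation p value; the full suite runs in a few
seconds on one CPU.

## Known limitations

- The weighted evaluation takes membership over component *scores*, the
  layout of the published four-seedling worked example. Screens that
  instead take membership over raw indicators and then weight would need
  the unweighted path plus external weights.
- Classification assumes 1-D input (D values); clustering genotypes on the
  full CRC profile is out of scope.
- The association test is a single pre-specified correlation; no multiple
  testing correction is applied or needed.
- No dose-response fitting (EC50 and relatives): the evaluation uses only
  per-level ratios, so the dose grid is treated as categorical.
- The published strain-level D values cannot be re-derived here because
  the underlying colony areas were published only as figures; they ship as
  a fixture and enter the pipeline as data.
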