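---
title: "Methods: brain-behavior modes of covariation with permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-behavior modes of covariation with permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccamode)
```

## The problem

`ccamode` implements the statistical machinery for relating structural
brain imaging-derived phenotypes (IDPs) to non-imaging subject measures
(non-IDPs) in a late-midlife cohort assembled by an extreme-groups design
on cognitive change. The pipeline has five analysis stages:

1. **Change scores and selection.** Follow-up IQ is regressed on baseline
   IQ; each subject's standardized residual about the regression line is
   the change measure. Subjects beyond |z| > 3 are excluded as extreme
   test-score artifacts, and the retained subjects split at z = 0 into
   improvers and decliners. Raw-difference change scores (within-wave
   z-scored, later minus earlier) are kept separately as adjustment
   covariates.
2. **Preprocessing.** Every phenotype and confound column is passed
   through a rank-based inverse normal transformation; the four confounds
   (age, absolute motion, relative motion, head size) are regressed out of
   every variable; missing entries are completed by soft-impute for the
   multivariate path only.
3. **Mass-univariate screen.** All IDP-by-non-IDP Pearson correlations on
   pairwise-complete observations, with Bonferroni familywise and
   Benjamini-Hochberg false-discovery control, per-subgroup consistency
   checks against Simpson's paradox, and Manhattan-plot export.
4. **Multivariate mode.** Each set is reduced to its top *d* = 30
   principal components and canonical correlation analysis fits
   `U = X A`, `V = Y B`; significance of each canonical correlation is
   assessed against the permutation null distribution of the *largest*
   canonical correlation, giving familywise-corrected p-values across all
   modes.
5. **Post-hoc summaries.** Structure loadings (correlations of
   polarity-adjusted observed variables with the variates), subdomain
   importance bars split by loading sign, and Tucker congruence of the
   subgroup loading patterns.

Because the motivating cohort data are not publicly deposited, the package
ships a first-class synthetic cohort generator that emulates the data
structure — 193 subjects in two subgroups, 453 IDPs in five modality
blocks, 70 non-IDPs in four subdomains, confound contamination,
block-structured missingness, and a longitudinal IQ panel — with a ground
truth channel for parameter-recovery testing.

## The generator and its calibration

The data model for each variable $j$ of a set is

$$x_j = a_j z + \sum_{k=1}^{4} c_{jk} g_k + \varepsilon_j,$$

with latent mode score $z$, confound cores $g_k$ and noise all standard
normal. A fraction `frac_loaded` (default 0.3) of each set's variables
carries the mode. Loaded variables take the sign of their manifest
polarity, so the planted mode is a "positive-negative" axis: favourable
markers load positively after polarity adjustment.

For a single-factor set with loadings $a$ and unit noise, the best linear
combination of the set correlates with $z$ at
$\rho = \sqrt{a^\top a / (a^\top a + 1)}$, and the population first
canonical correlation between two such sets is $\rho_x \rho_y$. The
default target is 0.75.

**How the strength is split between the sets matters.** The free parameter
is how $\rho_x \rho_y = 0.75$ is divided. Splitting equally
($\rho_x = \rho_y = \sqrt{0.75}$, i.e. $a^\top a = 3$ per set) spreads the
imaging set's signal so thinly over its 453 variables that the planted
covariance spike sits near the Marchenko-Pastur noise bulk of a 193 × 453
matrix and per-variable loadings (~0.15) drown in the sampling noise of a
correlation estimated from 193 subjects (~0.07). The generator instead
uses a **common per-variable loading magnitude** across the two sets —
equal per-variable signal-to-noise — solving
$\sqrt{\tfrac{m_x a^2}{1+m_x a^2}\tfrac{m_y a^2}{1+m_y a^2}} = 0.75$ for
$a$ (about 0.28 at the default layout). The many-variable imaging set then
carries the larger set-level correlation, which is also what one observes
in practice: a wide imaging battery jointly predicts a latent trait far
better than any single scan measure. This choice was made once, on the
above reasoning, and is exposed via `mode_strength_idp` /
`mode_strength_nonidp` for users who want a different split.

Other generator conventions:

* **Ordinal and binary survey items** (civil status, smoking status,
  disease prevalences, exercise frequency) are emulated by thresholding
  the continuous latent at equal-frequency cut points; the analysis treats
  everything as rank data after quantile normalization anyway.
* **Missingness is MCAR only** (defaults: 0 for IDPs — imaging was
  complete; 0.2 for non-IDPs, matching survey "unknown" fractions of up to
  ~30%). A known mechanism is needed to validate the imputer; no
  missingness mechanism beyond that is claimed.
* **Confounds** load on a deterministic anchor subset plus a random 20% of
  variables per confound (scale 0.4), guaranteeing detectable
  contamination before deconfounding. They are emitted on realistic
  measurement scales via monotone transforms, which the rank
  transformation makes immaterial downstream.
* **The IQ panel** uses a first-order (Markov) correlation structure
  across the four waves with adjacent correlations 0.65, 0.71
  (configurable; the wave-20/57 value), and 0.80 — increasing with
  decreasing time gaps between assessments, as longitudinal cognition
  studies consistently find. The panel is an independent channel from the
  phenotype tables: group membership derived from it is exchangeable with
  respect to the planted mode, which is exactly what the subgroup
  congruence checks require.

What the generator does **not** emulate: residual covariance among
variables beyond the factor-plus-confound structure (real imaging blocks
are internally correlated, so a real 30-component reduction captures
~70-75% of variance where the synthetic imaging set concentrates less),
missing-not-at-random mechanisms, site or scanner effects, and any
nonlinearity. Passing tests therefore demonstrate correctness of the
machinery and its calibration under the stated model, not performance on
real cohort data.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `cutoff` | 3 | SD of residualized change | excludes extreme test scores before grouping |
| `q` | none | tail fraction | optional strict extreme-groups selection; default keeps all retained subjects, matching a near-even split |
| `alpha` | 0.05 | level | screen-wide error control |
| `m_eff` | none | count | user-supplied effective number of tests for the Bonferroni threshold |
| `d` | 30 | components | the study's reduction; guarded by `d <= n/6` against rank-deficient overfitting |
| `n_perm` | 10,000 | count | permutation resolution; < 100 warns |
| `lambda` | held-out grid | singular-value units | soft-impute shrinkage; chosen to minimize error on a 5% held-out subset of observed entries |
| `tol`, `max_iter` | 1e-6, 500 | relative Frobenius | imputation convergence contract |
| `report_threshold` | 0.2 | absolute loading | display convention for mode summaries |

## Numerical and procedural choices

* **Rank transform.** Blom offset, $\Phi^{-1}((r - 3/8)/(m + 1/4))$, with
  average ranks for ties; bounded away from 0/1, standard for
  inverse-normal scores. Confounds are themselves rank-transformed before
  the regression, in the same pipeline order as the variables.
* **Deconfounding order.** Variables are deconfounded before imputation.
  The reverse order is defensible; deconfounding first keeps the
  univariate (non-imputed) and multivariate paths on identical residuals.
* **Deconfounding fit.** QR least squares per column on pairwise-complete
  rows; a rank-deficient confound matrix falls back to a minimum-norm
  pseudoinverse fit with a warning rather than failing.
* **Soft-impute.** Fill with column means, iterate SVD with
  soft-thresholded singular values (optionally truncated at `rank_max`),
  restore observed entries, stop on relative Frobenius change < `tol`.
  With rank truncation the step-size sequence can show small transient
  upticks when the active rank changes; without truncation it decreases
  monotonically (up to ~1% numerical slack), and that is the variant the
  convergence property is asserted on.
* **CCA.** Thin QR of each centered matrix, SVD of the Q-factor
  cross-product — the numerically stable route; weights are back-solved
  against the R factors so variates have unit variance. Signs are fixed by
  making the largest-magnitude element of each x-weight column positive;
  the first mode's *global* orientation is then anchored so the cognition
  subdomain's mean loading is positive (the positive-negative framing).
  Rank-deficient inputs are reduced to effective rank with a warning and
  zero weights on dependent columns.
* **Permutation FWE.** Rows of the non-IDP score matrix are permuted
  relative to the IDP matrix; since row permutation leaves column means
  and spans intact, the Q factors are computed once and only the
  cross-product SVD is repeated, making 10,000 permutations cheap. The
  p-value convention is $(1 + \#\{\text{null max} \ge r_i\})/(n_{perm}+1)$,
  avoiding zero p-values; p-values are non-decreasing across modes by
  construction. Exactly *which* matrix is permuted is immaterial by
  symmetry; permutation p-values are row-label equivariant only in
  distribution, not realization-by-realization.
* **Structure loadings** are computed against the deconfounded, pre-PCA
  variables (pairwise-complete), not the PCA scores and not the imputed
  values: imputation is an internal device of the reduction, and loadings
  should reflect observed data. Polarity inversion of "lower is better"
  variables comes from the manifest and is applied before the correlation.
* **Subgroup loadings and congruence.** Loadings per subgroup are
  post-hoc correlations of each subgroup's rows against the *whole-group*
  canonical variates. Refitting a separate CCA inside a ~95-subject
  subgroup is dominated by overfitting noise and would measure the
  instability of a refit, not the similarity of the mode across groups.
  Tucker's congruence coefficient (normalized inner product) compares the
  two patterns.
* **Subdomain importance.** Within each subdomain the positive (grey) bar
  is the sum of squared non-negative loadings divided by the subdomain's
  total member count, and likewise the negative (black) bar — so an
  all-positive subdomain's bar equals its plain mean squared loading, and
  the two bars decompose the subdomain's mean $r^2$ exactly.
* **Split point.** Retained subjects split at z = 0. An invitation /
  response process cannot be recovered from a selection summary; the
  near-even split this produces matches the study design's bookkeeping,
  and a quantile option (`q`) provides strict tail selection when wanted.
* **P-value floor** at the smallest positive double keeps
  $-\log_{10} p$ finite; the FDR threshold line is drawn only when BH adds
  discoveries beyond Bonferroni.
* **Seeds.** Every stochastic step takes an explicit seed; the pipeline
  splits per-stage seeds from a master seed with a counter scheme so
  toggling one stage does not perturb another's stream.

## Problem sizes used by the test suite

Module tests run on reduced layouts (tens of variables, 60-120 subjects)
chosen to exercise every code path quickly; the statistical checks use
the full study-scale layout: the bookkeeping tests build the complete
453 × 70 screen, the calibration test runs 200 null datasets at 500
permutations each, parameter recovery runs 20 full-scale cohorts
(n = 193, d = 30, 999 permutations), detection power runs 50 full
453 × 70 screens, and the large-sample checks use n = 50,000 (closed-form
canonical correlation, IQ regression) and n = 5,000 (consistency of the
first canonical correlation). These sizes were chosen to put Monte-Carlo
error well below the tolerances being asserted.

## Known limitations

* The synthetic covariance is factor-plus-noise; real phenotype blocks
  carry rich internal correlation, so variance-explained figures for a
  30-component reduction differ between synthetic and real data.
* Under the calibrated conditions (population canonical correlation 0.75,
  30% of variables loaded, n = 193), individual structure loadings are
  estimated with sampling error comparable to their true spread; recovery
  of the full loading pattern is informative but bounded — a perfect
  variate would cap the loading-pattern correlation near 0.88 on the
  imaging side.
* Bonferroni is the only familywise control for the univariate screen; no
  permutation-based univariate FWE, no effective-number-of-tests
  estimation (a user-supplied `m_eff` hook exists).
* Two-set CCA only; no sparsity or regularization, no confidence
  intervals on canonical correlations.
* Raw-difference change scores are reported with their known
  regression-to-the-mean artifact (they correlate negatively with baseline
  under imperfect reliability); the residualized score is the selection
  instrument precisely because it is baseline-orthogonal.
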