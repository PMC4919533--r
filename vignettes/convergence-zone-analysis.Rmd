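---
title: "Locating convergence zones: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating convergence zones: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `convzone`, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design decisions taken where the design was genuinely open.

## The two metrics and their assumptions

**Conjunctiveness** is estimated by searchlight representational similarity
analysis. Within a sphere (default radius 4 voxels, at least 30 grey-matter
voxels; reduce both on small synthetic grids), the retrieval-phase instance
patterns are compared with Spearman's rank correlation — rank-based to be
robust to outliers and monotone nonlinearities, at the cost of a little
efficiency. The similarity matrix is regressed on an intercept plus a
contrast that encodes the associative-similarity hypothesis under the
*perception penalty*:

* included **positive** cells: same association, *different* cue–associate
  order (+1/n₊ each);
* included **negative** cells: different associations with *identical* cue
  and associate categories (−1/n₋ each);
* everything else — including between-association cells matching on only one
  category — is excluded.

The weights sum to zero, so the slope is insensitive to the overall
similarity level; the intercept absorbs it. Assumptions: patterns are
exchangeable across instances under the null, and a linear contrast on the
rank-correlation scale is an adequate summary (correlations enter the GLM
untransformed; no Fisher z, since the model fits the observed similarity
space directly and the slope is only used as a relative statistic).

**Hubness** is the participation coefficient of beta-series connectivity
graphs. Edges are Pearson correlations across a phase's instances with
negatives zeroed and positive edges kept when the BH-adjusted two-sided
p-value (from the t transform of r with n−2 df) is below `fdr_alpha` = 0.05.
ê and k in the PC formula use *summed edge weights*: the pipeline keeps
weighted graphs throughout, although a binary mode (`weighted = FALSE`)
matches the edge-count reading of the formula and is used by the oracle
tests. Zero-variance nodes get their edges zeroed with a warning; isolated
nodes get PC 0 by convention.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `radius`, `min_voxels` | 4 voxels, 30 | voxels | standard searchlight settings at 2 mm; use 2/10 on 10–16³ synthetic grids |
| `subsample_factor` | 4 | — | 2 mm → 8 mm connectivity grid; 2 on synthetic grids so enough nodes remain |
| `fdr_alpha` | 0.05 | — | edge retention level |
| `n_perm_group` | 10000 | — | sign-flip permutations; exhaustive when 2ⁿ ≤ n_perm |
| `alpha` | 0.05 | — | uncorrected binarization threshold consumed by the overlap stage |
| `n_perm_overlap`, `n_draw` | 10000, 2 | — | region-resampling null |

## What the synthetic generator emulates

`generate_dataset()` draws, per subject: one standard-normal voxel pattern
per association restricted to the planted region (identical across cue
orders — the conjunctive code); one pattern per stimulus category over the
"visual" regions, entering each retrieval beta as 1.0 × cue pattern + 0.5 ×
associate pattern (order-*dependent*, the confound the perception penalty
must reject); i.i.d. standard-normal module latent series per instance, with
every voxel loading on its own module's series (`module_coupling`, default
1) and planted voxels additionally loading on every other module's
retrieval-phase series (`hub_effect`); and Gaussian noise. Latents are drawn
once per subject because the analysis is within-subject. ITI betas carry
only the own-module loading plus noise.

Defaults (16³ grid, 8 regions, 2 modules, 12 subjects, conjunctive and hub
effects 1.5, perceptual 1.0, noise 1.0) describe a world detectable at
n = 12; the source study reports no effect magnitudes in beta units, so
these are chosen for detectability, not to match it. What the generator does
**not** emulate: hemodynamics, autocorrelated noise, spatial noise
smoothness, motion, between-subject anatomical variability, or behavioural
errors. A green planted-effect test therefore establishes the *statistical
machinery* (contrast, graphs, permutation inference, overlap), not
robustness to realistic fMRI artefacts.

One consequence of the module-based connectivity model is worth knowing:
the hub term couples the planted region to every voxel of the other modules,
so retrieval-phase PC rises not only inside the planted region but, more
weakly, wherever those cross-module edges land. Hubness extent is therefore
expected to exceed the planted region even in a perfectly clean run; peak
location and ROI-level overlap, not extent, are the recovery criteria.

## Numerical and design decisions

* **Degenerate model vs. global null.** `module_coupling` exists so that the
  fully degenerate model (all four multipliers 0, noise → 0 gives all-zero
  betas) is distinct from the *global null* of the pipeline (three effects 0,
  coupling 1): baseline connectivity exists but no retrieval-vs-ITI
  difference and no mnemonic code.
* **Uniform cell weights.** The balance requirement constrains only the mean
  of included weights; uniform ±1/n weighting within each cell class is used
  as the simplest scheme satisfying it.
* **Shared subnetwork partition.** By default a Louvain partition is
  computed per phase from that phase's region graph. With
  `share_partition = TRUE` the partition is derived once from the baseline
  (ITI) graph and used for both phases — the usual practice of defining
  canonical modules from task-free data. On coarse atlases (few regions)
  this is strongly recommended: a strongly hub-coupled region can otherwise
  be reassigned wholesale by the retrieval-phase partition, which re-labels
  its home module's internal edges as cross-module and spreads the PC
  increase over the entire module, destroying voxel specificity. The
  acceptance pipeline uses the shared partition for exactly this reason.
* **Overlap null semantics.** `spatial_resampling_test()` draws `n_draw`
  regions uniformly *without replacement within a draw*; by default target
  regions may be redrawn (label-shuffling semantics). Ties between null and
  observed count against the hypothesis, and the add-one estimator keeps
  p > 0. Note that Dice is extent-invariant: a null draw pairing the target
  with a region where both masks are empty reproduces the observed Dice
  exactly, so on coarse atlases the no-exclusion Dice p is floored at
  roughly (number of such pairs)/C(R, 2). `exclude_targets = TRUE` removes
  target redraws and is what the packaged acceptance pipeline uses on its
  8-region atlas; with ~100+ regions the distinction is negligible.
* **Sign-flip p-values.** Exhaustive enumeration (p = count/2ⁿ, identity
  included) when 2ⁿ ≤ n_perm, Monte-Carlo with the add-one estimator
  otherwise. Zero-variance/zero-mean voxels are flagged and given p = 1;
  zero-variance/nonzero-mean voxels keep t = ±Inf, which behaves correctly
  under flips. Null-vs-observed comparisons use a 1e-9 relative tolerance so
  the identity flip always counts against itself regardless of BLAS
  summation order.
* **Exact Wilcoxon.** The signed-rank test is exact for n < 50 without ties
  or zeros and falls back to the normal approximation otherwise.
* **Searchlight kernel.** The per-sphere rank/correlate/fit loop is
  implemented in C++ (ties get average ranks; zero-variance patterns drop
  their cells; cells are recentred over the valid subset). The R functions
  `pattern_similarity()` + `fit_contrast()` compute the same quantity and
  the suite asserts agreement, so the fast path is never the only route.
* **Calibration scaling.** The packaged calibration test evaluates the group
  test at searchlight centres spaced farther apart than the sphere diameter,
  with `module_coupling = 0`, so its pooled false-positive draws are
  genuinely independent and the exact binomial interval applies; the
  perception-penalty test summarises visual regions by a 120-centre ROI mean
  per subject. Both are time-budget scalings, not changes to the stated
  effect sizes.

## Known limitations

* The mixture-model T-map correction, TFCE, variance smoothing and
  anatomical normalisation of the original processing chain are out of
  scope; group inference is voxel-wise sign-flip permutation only.
* Eigenvector centrality runs on the same beta-series graphs as the PC
  path (no raw time-series preprocessing exists in this package).
* NIfTI support is deliberately minimal (little-endian NIfTI-1, 3-D/4-D,
  common datatypes, slope/intercept scaling on read).
* On atlases with very few regions the overlap null is coarse
  (C(R, 2) distinct draws); p-values are then floor-limited accordingly.
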