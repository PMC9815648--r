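---
title: "Methods: block-wise CPM, behavioral PLS, and the synthetic study generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-wise CPM, behavioral PLS, and the synthetic study generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockcpm)
```

This vignette documents the statistical model implemented by `blockcpm`, the
calibration of the synthetic generator, and the design decisions a user
should know before interpreting results.

## 1. Connectome representation

With `P` parcels the connectome has `E = P(P-1)/2` unique edges
(`total_edges(268)` = 35,778). All edge vectors use the column-major upper
triangle order of `m[upper.tri(m)]`; `edge_table(p)` maps vector positions
to 0-based parcel pairs, and `ut_vec()` / `vec_ut()` round-trip exactly.
Block-wise functional connectivity (`block_fc`) Pearson-correlates parcel
time series over a half-open, 0-based TR window `[onset_tr, offset_tr)`
(minimum 3 TRs) and Fisher-z transforms the result, clipping `|r|` at
`1 - 1e-6` so degenerate blocks stay finite. Denoising (`denoise`) regresses
out confounds (plus an intercept) and zeroes FFT bins outside a
0.008–0.12 Hz pass band, applied per run before block extraction. Motion
exclusion (`motion_filter`) uses strict thresholds: the stringent profile
retains blocks with `fd_mean < 0.2` mm and `fd_max < 2` mm; the liberal
profile uses 0.5 / 5 mm.

## 2. CPM with leave-one-site-out cross-validation

`select_edges()` correlates every edge with behavior across training
subjects and keeps edges with two-tailed `p < alpha` (t transform of r,
`n - 2` df; `alpha = 0.01`; deliberately not multiplicity-corrected), signed
by the correlation. **Network strength** is the signed sum of Fisher-z
values over the *unique* (upper-triangle) mask edges; summing both triangles
would merely double the scale and change no correlation-based result.

`cpm()` folds by acquisition site: each fold's mask is trained on all other
sites and scores the held-out site's subjects. The consensus mask keeps
edges whose mean signed site vote reaches the binarization threshold **in
absolute value, inclusively** (default 0.5, so an exact half of consistent
votes counts); signed voting means an edge selected positively by half the
sites and negatively by the other half cancels to zero.

## 3. Hypergeometric overlap tests

Whether two edge sets of sizes `K` and `N` share more than chance of the `M`
total edges is tested against the hypergeometric null. The default
convention is the literal upper tail of the cumulative distribution,
`1 - F(x) = P(X > x)`, which reproduces the canonical printed values
(e.g. `hypergeom_p(37, 757, 1674, 35778)` = 0.351); `P(X >= x)` is
available as `convention = "greater_equal"` and both are reported by
`network_overlap()`. Overlap percentages are expressed relative to the
**union** of the two sets. The computation runs in log space
(`lchoose` + log-sum-exp) so connectome-scale `M` cannot overflow, and is
unit-tested against exhaustive enumeration for all parameter sets with
`M <= 12`.

## 4. Two-group behavioral PLS

Edges and behavior are z-scored within group; row `g` of the cross-block
matrix `R` holds the within-group edge-behavior correlations. The SVD of
`t(R)` yields latent variables; with two groups and one behavior, LV1 is the
group-common and LV2 the group-differential brain-behavior pattern. The
covariance fraction of LV `l` is `s_l^2 / sum(s^2)`.

- **Permutation test**: subject rows of the edge matrix are shuffled against
  the behavior/group labels; each LV's singular value is compared to its
  permuted distribution with an add-one p-value.
- **Bootstrap ratios**: subjects are resampled with replacement within
  group; each bootstrap solution is aligned to the original by Procrustes
  rotation, and the bootstrap distribution is accumulated on
  **singular-value-scaled saliences** `U diag(s)`. The bootstrap ratio is
  the scaled original salience divided by its bootstrap SD, with
  `|Z_BR| >= 3` marking reliable edges. Scaling by the singular values
  matters: the unit-norm constraint on `U` alone understates per-edge
  sampling variability and inflates the ratios (measured ~3.5% of null edges
  beyond `|Z| = 3` instead of the nominal ~0.3%); with the scaled
  convention the null tail rate is correct, which the test suite asserts.
- **Balanced subsampling**: with unequal groups, `balanced_bpls()` repeats
  the fit on size-matched subsamples (default 200) and averages sign-aligned
  saliences.

## 5. Computational lesioning

`lesion_mask()` removes every mask edge touching a macroscale region
(20 regions, 10 per hemisphere; `make_region_labels`). The cost of a lesion
is `delta R^2 = R^2(full strength) - R^2(lesioned strength)` from OLS of
behavior on strength (plus optional covariates). Group differences in
`delta R^2` are tested by within-group bootstrap with a two-sided add-one p
(`compare_lesion_groups`); `lesion_profile()` sweeps all regions.

## 6. Dependent-correlation tests

`williams_t()` implements Williams' t2 (as codified by Steiger 1980) for
comparing two correlations sharing one variable, with `n - 3` df;
`steiger_z()` is the Fisher-z pooled-r variant. Both are exactly zero at
equality, antisymmetric, and hold their nominal type-I error (asserted by
Monte Carlo at `n = 100`). `weighted_correlation()` uses weighted moments
and equals the replicated-data Pearson for integer weights; `dprime()`
applies the log-linear (+0.5 counts / +1 totals) correction by default.

## 7. The synthetic generator and its calibration

`simulate_study()` fans a single seed into per-stage sub-seeds
(`derive_seed`) for ground truth, subjects, behavior and connectomes, so any
stage can be regenerated independently and reruns are bit-reproducible.

**Ground truth** (`make_ground_truth`) plants four predictive masks with
*exact* sizes and *exact* pairwise overlaps (defaults rescale the canonical
757/630/1674/1203 sizes and 37/33 overlaps to the chosen parcel count), plus
disjoint group-common and group-differential edge sets. A configurable
fraction of the SA mask edges is forced to touch one hub region so that
lesioning has a localized ground truth.

**Connectomes** (direct-edges mode): the Fisher-z value of edge `e` for
subject `s` in block `b` is

```
z = mu_e + w_sa(e) beta (a_sa + eta_sb) + w_wm(e) beta (a_wm + eta_sb)
      + c_e beta a_sa + g_s d_e beta a_sa + noise,   noise ~ N(0, sigma_e^2)
```

where `w_.(e)` are the signed mask indicators, `c_e`/`d_e` the signed
common/differential indicators, `g_s = +1` for youth and `-1` for adults,
`eta_sb` the latent per-block attentional state, `beta = 0.02` z-units per
ability SD and `sigma_e = 0.1`. **Behavior**: block accuracy is linear in
ability (`lambda = 0.03` per SD), group, stimulus type, run, motion and
state, with noise SD 0.17, clipped to [0, 1].

Calibration (done analytically, before any acceptance check): averaging over
16 blocks, the SA-mask strength has signal SD
`beta * n_mask_edges * sd(a_sa)` against residual SD
`sigma_e * sqrt(n_mask_edges / 16)`, giving a strength-ability correlation
of ~0.9 at the 100-parcel scale; accuracy averaged over 8 condition blocks
correlates ~0.45 with ability; their product plants a population
strength-accuracy correlation of ~0.4.

In `timeseries` mode, the implied correlation matrix `tanh(z)` is projected
to the nearest positive-semidefinite correlation matrix by eigenvalue
clipping with unit-diagonal rescaling (`nearest_psd_corr`) and multivariate
normal TR samples are drawn, so estimated FC carries realistic
finite-length noise.

## 8. Pipeline

`run_pipeline()` orchestrates simulate → strength → CPM → overlap → lesion →
PLS from one validated config (unknown keys rejected), writes TSV/JSON
outputs plus an exclusion log, and records per-file MD5 checksums in
`manifest.json`. Wall-clock timing goes to an unchecksummed `timing.log`, so
the manifest is byte-identical across reruns with the same config and seed.
`validate_inputs()` checks a dataset directory (shapes, vocabularies,
0-based parcel ranges, FD presence) and always returns a diagnostic report
rather than throwing.

## 9. Conventions worth restating

- Edge order: `m[upper.tri(m)]`, 0-based parcel ids in all tables.
- All empirical p-values use the add-one convention
  `(1 + #{extreme}) / (n + 1)`; two-sided bootstrap p-values double the
  crossing fraction, capped at 1.
- Consensus binarization is inclusive at the threshold.
- Overlap tests default to `P(X > x)`; percentages use the union
  denominator.
- Strength sums unique edges once.
- Problem sizes used in validation: null calibrations at the full 35,778-edge
  scale (selection) and reduced scale (PLS permutations); parameter recovery
  at `P = 100`, `n = 400` per group.

## 10. Limitations

The generator's direct-edges mode skips the hemodynamic level entirely;
timeseries mode draws i.i.d. TRs (no autocorrelation). Mixed-effects
regressions and mediation analyses are out of scope; the package exposes the
OLS/correlation layer those analyses build on. The Steiger variant
implemented is the shared-variable case; other dependent-correlation cases
are not covered.
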