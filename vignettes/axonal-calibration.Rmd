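---
title: "Calibrating DWI axonal water fractions against EM volume fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating DWI axonal water fractions against EM volume fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axocal)
```

## The problem

Biophysical DWI models of white matter (SMI, BAYDIFF, WMTI, WMTI-W, NODDI,
NODDI-DTI and relatives) estimate an axonal *water* fraction
$f_{AW} = f_A/(f_A+f_E)$: myelin water relaxes too quickly to contribute to
the diffusion-weighted signal, so the denominator contains only the axonal
and extracellular water. Histology by electron microscopy, on the other
hand, measures volume fractions, and in many datasets only those of
*myelinated* axons ($f_{A,M}$) and myelin ($f_M$); unmyelinated axons
($f_{A,U}$, with $f_A = f_{A,M} + f_{A,U}$) are hard to segment reliably
and are often not part of the reference. Comparing the two modalities
therefore needs more than the obvious rescaling
$f_A^{(DWI)} = (1-f_M^{(EM)}) f_{AW}^{(DWI)}$: it needs calibration for

1. the unmyelinated axons that DWI sees and EM does not — modelled as a
   subtractive **offset** $U$, estimated per statistically homogeneous
   group of animals, and
2. the echo-time dependence of the fitted signal fraction when
   compartmental T2 values differ — modelled as a multiplicative
   **scaling** $s(TE)$.

Both corrections enter linearly,
$$f_A^{(DWI)} = (1-f_M^{(EM)})\, s\, f_{AW}^{(DWI)} - U_j,$$
and the package's job is to decide, by fitting and information-criterion
comparison, which of the parameters $\{U_1, U_2, s\}$ the data actually
support, and to quantify the agreement that results.

## The scaling model

At $b = 0$ the four-compartment ex vivo signal model with compartmental
relaxation gives a normalized signal
$$\hat S_0(TE) = (1-\nu_{dot})\Big[(1-\nu_{iso})\big(\nu e^{-TE/T_{2,a}} +
(1-\nu)e^{-TE/T_{2,e}}\big) + \nu_{iso}e^{-TE/T_{2,iso}}\Big] +
\nu_{dot}e^{-TE/T_{2,dot}},$$
so a relaxation-blind model reports
$f_{AW}(TE) = (1-\nu_{dot})(1-\nu_{iso})\nu\, e^{-TE/T_{2,a}}/\hat S_0(TE)$
instead of the TE = 0 value $(1-\nu_{dot})(1-\nu_{iso})\nu$. The ratio is
the predicted scaling
$$s_{pred} = \frac{\hat S_0(TE)}{e^{-TE/T_{2,a}}} =
(1-\nu_{dot})\Big[(1-\nu_{iso})\big(\nu + (1-\nu)e^{-TE/\Delta_e}\big) +
\nu_{iso}e^{-TE/\Delta_{iso}}\Big] + \nu_{dot}e^{-TE/\Delta_{dot}},$$
with $\Delta_x = (1/T_{2,x} - 1/T_{2,a})^{-1}$. We write the time constants
in this reciprocal-difference form on dimensional grounds (a difference of
rates, inverted); compartments with equal T2 have $\Delta_x \to \infty$ and
contribute a factor of 1 rather than a division by zero. The defining
identity $s_{pred}\cdot f_{AW}(TE) = (1-\nu_{dot})(1-\nu_{iso})\nu$ holds
to machine precision for every parameter set and is enforced by a
1000-draw property test.

```{r}
sf <- signal_fractions(nu = 0.475)
t2 <- t2_profile(T2_a = 50, T2_e = 30)   # Delta_e = 75 ms
c(s_pred = predicted_scaling(sf, t2, TE = 19),
  identity = predicted_scaling(sf, t2, 19) * fAW_at_TE(sf, t2, 19) / 0.475)
```

Compartmental T2 values are configuration inputs, never constants baked
into the math: they vary with field strength, fixation and tissue state.
When only a scaling value is known (not the T2 values behind it),
`solve_delta_e()` / `synthetic_t2_profile()` invert the two-compartment
formula to build an internally consistent — and explicitly *synthetic* —
profile; the anchor `T2_a = 50` ms in that helper is arbitrary because the
two-compartment $s_{pred}$ depends on the profile only through $\Delta_e$.

## Group selection

Offsets are fitted per group, not per genotype, to avoid fitting noise:
a one-way ANOVA on the EM axonal volume fraction across genotypes is
followed by all-pairs testing, and genotypes that are *not* significantly
different are merged by graph connectivity. Exactly two components are
expected on this design (Controls/Pten/Rictor vs the severely
hypomyelinated Tsc2); anything else is surfaced as an explicit ambiguity
error carrying the component structure, with a user-supplied mapping as
the escape hatch. Because the original analysis does not name its post-hoc
procedure, the default here is Tukey's HSD at $\alpha = 0.05$ — the
standard companion of a one-way ANOVA, and multiplicity-safe — with
unadjusted pooled-SD t-tests behind `method = "t"`. The 60 mouse-by-ROI
values are treated as independent replicates (the pooling stage has no
mixed-effects structure); this matches how the groups were derived in the
study design the package emulates, and is a known simplification.

## Fitting and model selection

Each combination of free parameters (the baseline `{}` plus the seven
non-trivial subsets of $\{U_1, U_2, s\}$) is fitted by minimising
$\mathrm{RSS} = \lVert f_A^{(EM)} - f_A^{(DWI)} \rVert^2$ subject to
$U_j \in [0,1]$, $s \in [0,2]$, and the physical volume constraint
$f_A^{(DWI)} + f_M^{(EM)} \le 1$. Two details are deliberate:

- **Constraint form.** The volume constraint is enforced elementwise, for
  every observation; a literal scalar `min` form (binding only the single
  smallest value) is available via `constraint_form = "min"`, but the
  elementwise form is the one that actually guarantees physically
  reasonable estimates everywhere.
- **Optimizer.** The objective is a convex quadratic in $(U_1, U_2, s)$,
  so the box-constrained optimum is found *exactly* by enumerating the at
  most $3^k$ bound-activity patterns and solving each reduced
  least-squares problem — no tolerance, no starting-point sensitivity, and
  trivially reproducible. Only if the winning candidate violates the
  volume constraint (rare: it requires calibrated fractions pushing past
  $1-f_M$) does the fit fall back to log-barrier optimisation
  (`constrOptim`, analytic gradient, barrier $\mu = 10^{-8}$, objective
  tolerance $10^{-14}$) from a deterministic feasible multi-start grid.
  Every fit is checked against an exhaustive-grid oracle in the test
  suite (201 points per free dimension, 41 for the three-parameter
  combination).

Selection uses $\mathrm{BIC} = k\ln n + n\ln(\mathrm{RSS}/n)$ and
$\Delta\mathrm{BIC}$ against the baseline, computed on all data; ranking
is ascending with ties broken by fewer parameters and then name. A perfect
fit (RSS = 0, possible on noiseless synthetic data) has no finite BIC and
is reported as $-\infty$ with a `perfect_fit` flag — it ranks first by
construction. Parameters not freed stay at $U = 0$, $s = 1$, so the
baseline is exactly the uncalibrated rescaling. Stability is assessed by
leave-one-out over *mice* (all four ROIs of an animal leave together,
respecting the clustering) and reported as the sample SD of the fold
estimates.

The **hybrid** mode fixes $s = s_{pred}$ and fits only the offsets; `k`
counts only the free offsets, so hybrid calibration is cheaper in BIC
terms whenever the prediction is adequate — the regime intended for human
applications where histological references are scarce.

## Agreement metrics

Accuracy is summarised Bland–Altman style: per-point differences
$\delta = f_A^{(DWI)} - f_A^{(EM)}$ against means, bias
$\langle\delta\rangle$, and error
$\epsilon = 1.96\sqrt{\langle\delta^2\rangle - \langle\delta\rangle^2}$.
The moments are *population* moments (divide by $n$) because the
definition is written with plain averages; the sample-SD variant sits
behind `population = FALSE`. Relative bias and error divide by the EM
dynamic range $\max f_A^{(EM)} - \min f_A^{(EM)}$ computed over all
observations entering the comparison, and are reported in percent; tables
render as "bias (rel%)" with fractions to two decimals and percentages to
whole numbers.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the analysis assumes — it
is the package's test bed, not a tissue simulator. Per mouse and ROI it
draws latent tissue fractions (Gaussian around genotype means, clamped,
closing $f_A + f_M + f_E = 1$ exactly), forms the true
$f_{AW} = (f_{A,M} + w\,f_{A,U})/(f_A + f_E)$ with a sensitivity weight
$w$ (default 1: impermeable-stick assumption, unmyelinated axons fully
visible to DWI), and emits voxelwise observations
$f_{AW}/s_{true} + \mathcal N(0, \sigma_{vox})$ with invalid voxels
injected at configured rates — exercising the strict $<0$ / $>1$ / NaN
discard rule and the 6–12 voxel-per-ROI regime — before ROI averaging.
EM observations add Gaussian noise to the latent $f_{A,M}$ and $f_M$.
Because $(1-f_M) f_{AW} = f_{A,M} + w f_{A,U}$ identically, calibrating
with $s = s_{true}$, $U_j = w f_{A,U,j}$ recovers the latent myelinated
fraction exactly in the noiseless regime — the generator realises the
offset-as-unmyelinated-fraction and scaling-as-T2-weighting
interpretations by construction.

Default choices, made once:

- **Cohort**: 6 Controls + 3 Pten + 3 Rictor + 3 Tsc2, four ROIs (genu,
  midbody, splenium, fornix) — 60 observations, a 48/12 group split.
- **Means**: $f_{A,M} \approx 0.35$ for Control/Pten/Rictor and 0.10 for
  Tsc2 (the feature that drives pooling); myelin means 0.30 / 0.37 / 0.24
  / 0.10 encode the hyper-/hypomyelinated phenotypes but do not affect
  grouping. Between-ROI SD 0.03 for both.
- **Effects**: the group-wise unmyelinated fraction visible to the fit is
  0 in group 1 and 0.20 in group 2, and $s_{true} = 0.75$ — within the
  0.18–0.24 offset and 0.52–1.11 scaling ranges a data-driven calibration
  of this kind plausibly produces. Note the group-1 value emulates the
  *fitted* finding (negligible group-1 offset), not a biological claim
  that control tissue lacks unmyelinated axons; the constant-total
  alternative (`fA_U_mode = "derived-from-total"`, total 0.5) is available
  and gives group-1 offsets near 0.15, in which case `{U1,U2,s}` becomes
  the expected winner.
- **Noise**: voxel SD 0.03, EM SD 0.02, outlier rates 2% negative, 2%
  above one, 1% NaN — enough to make selection non-trivial while keeping
  parameter recovery well inside ±0.05.

What the generator does *not* emulate: spatial voxel structure, b-value
dependence and model-fitting error of the DWI models themselves,
between-ROI correlation within a mouse beyond the shared genotype mean,
EM segmentation bias, or tissue deformation between modalities. Passing
tests on synthetic cohorts therefore demonstrate the *pipeline's*
correctness and identifiability under its stated assumptions — not the
accuracy of any DWI model on real tissue.

## Numerical choices and degenerate inputs

- Fractions are stored as unitless decimals; renderers multiply by 100.
- CSV round-trips serialise doubles at 17 significant digits
  (`read_cohort(write_cohort(x))` is the identity).
- Voxel filtering keeps the boundary values 0 and 1 (the discard rule is
  strict); an ROI below `min_valid = 3` valid voxels is kept but flagged,
  mirroring the smallest ROI retained in the emulated study; an empty ROI
  is an error.
- `bic()` refuses nothing but RSS = 0, which becomes the $-\infty$
  sentinel; `delta_bic()` of two perfect fits is defined as 0.
- Leave-one-out folds whose fit fails are dropped from the SD with a
  warning, never silently.
- The generator restores the caller's RNG state; cohorts are pure
  functions of (config, seed).

## Problem sizes

The test suite runs entirely on synthetic data at the native problem size
(60 observations). Property suites use 1000 draws for the scaling
identity, 500 random instances against the brute-force ANOVA oracle,
exhaustive 201-per-dimension grids on 20 cohorts for the fit oracle, 120
stochastic-recovery fits, and 50 seeds per preset for the model-selection
behaviour — sizes chosen so the whole suite completes in about a minute
while keeping every check at full strength.

## Limitations

The calibration is linear and global: a single scaling for all ROIs and
two offsets tied to a data-derived grouping. Relative accuracy metrics
depend on the EM dynamic range, so they are only comparable across
analyses sharing a cohort design. The predicted scaling is a first-order,
$b = 0$ approximation — it ignores diffusion-weighting of the compartment
signals and any T2 variation across tracts — and the package deliberately
does not fit DWI models or T2 profiles from raw signals: its inputs begin
at ROI-level scalar metrics.
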