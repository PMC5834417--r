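---
title: "Reference-tissue quantification of dynamic PET: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-tissue quantification of dynamic PET: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refkin)
```

## The problem

Quantifying amyloid and tau burden with dynamic brain PET, without
arterial sampling, rests on reference-tissue methods: a region assumed
devoid of specific binding (cerebellum grey matter for the tracers
emulated here) stands in for the arterial input function. The package
implements the three standard outcome measures —

* **SRTM** (simplified reference tissue model). The target-region
  time-activity curve (TAC) is expressed through the reference TAC as

  $$C_T(t) = R_1\,C_R(t) + \Big(k_2 - \frac{R_1 k_2}{1+\mathrm{BP_{ND}}}\Big)\,
  C_R(t) \otimes e^{-\frac{k_2}{1+\mathrm{BP_{ND}}}t},$$

  with delivery ratio $R_1$, target efflux rate $k_2$ (1/min) and
  non-displaceable binding potential $\mathrm{BP_{ND}}$.

* **Reference Logan** graphical analysis. For frame midpoints beyond an
  equilibrium time $t^*$,
  $\int_0^t C_T / C_T$ is linear in $\int_0^t C_R / C_T$ with slope
  $1+\mathrm{BP_{ND}}$ and intercept `int`.

* **SUVR**, the ratio of duration-weighted mean target to reference
  activity over a static window, which approximates
  $1+\mathrm{BP_{ND}}$ at equilibrium.

On top of the fitters sit the acquisition-design analyses: how short a
dynamic scan, how late a $t^*$, and which static window give stable
outcomes; how well static SUVR agrees with dynamic
$\mathrm{BP_{ND}}$; and how regional signals of two tracers correlate
across subjects (the signed-$R^2$ matrix).

Because no clinical scans ship with the package, a synthetic-data
module generates everything the analyses consume, with known ground
truth. All tests and the validation script run on synthetic cohorts;
what they demonstrate is internal consistency and the qualitative
behaviours expected of the methods, not agreement with any particular
clinical dataset.

## The simulator

**Input function.** Reference-tissue methods never see plasma, but the
simulator needs an input to drive a realistic reference TAC. The
default is a gamma-variate first pass (peak at 0.8 min) plus a
two-exponential recirculation tail rising smoothly from zero. The tail
(rates 0.2 and 0.015 /min, amplitudes 15% and 8% of peak) was set once
so that the fast tracer's late SUVR windows flatten out from roughly
30 min post-injection, the stabilisation pattern reported for
fast-kinetics amyloid tracers; with a much slower tail the simulated
SUVR never settles, which would misrepresent the acquisition-design
questions the package exists to ask. A `constant_infusion` form (a
saturating ramp) is provided for equilibrium experiments, and
`custom` accepts any vectorised function of time.

**Forward model.** The reference region is a one-tissue compartment,
$C_R = K_1^{ref}\, \mathrm{IF} \otimes e^{-k_2^{ref} t}$; targets
follow the SRTM convolution form above. Convolutions run on an
internal 0.01-min grid using an exact-per-step recursion for piecewise
linear inputs (evaluated with a C-level recursive filter, so cost is
linear in grid length). Frame values are **time-averages** over each
frame, not midpoint samples — that is how scanners bin counts — via
trapezoidal cumulative integration interpolated at frame boundaries.
Simulated TACs carry their fine-grid curve alongside the frame values;
fitters use it when present and otherwise reconstruct a fine reference
by linear interpolation through the frame midpoints anchored at
$(0,0)$.

**Default protocols.** The fast (amyloid-like, `av45`) protocol is 60
min in 27 frames (6×10 s, 3×20 s, 3×30 s, 4×60 s, 1×150 s, 10×300 s);
the slow (tau-like, `av1451`) protocol extends the same early framing
to 120 min (39 frames). Framing is configuration, not a constant; any
`frame_schedule()` is accepted. Region means put the fast tracer's
efflux near 0.15/min and the slow tracer's near 0.045/min with
$\mathrm{BP_{ND}}$ between 0.3 and 1.8 across six regions, so the
apparent clearance $\theta = k_2/(1+\mathrm{BP_{ND}})$ equilibrates on
a ~15 min timescale for the fast tracer and several-fold later for the
slow one — the kinetics contrast that drives every fast-versus-slow
ordering result.

**Cohorts.** Subject-level parameters are log-normal around the means
(so positivity is automatic) with default coefficients of variation of
8% ($R_1$), 10% ($k_2$) and 20% ($\mathrm{BP_{ND}}$, sampled as
$1+\mathrm{BP_{ND}}$ so the $>-1$ constraint is respected). A Gaussian
copula over the latent normals of $1+\mathrm{BP_{ND}}$ induces any
requested correlation of binding across regions and tracers; the
correlation matrix is validated for symmetry, unit diagonal and
positive semidefiniteness before sampling. The default cohort size is
12 subjects, a typical pilot-study cohort.

**Noise.** Frames receive zero-mean Gaussian noise with the standard
count-statistics surrogate
$\sigma_i = s\sqrt{\max(C_i,\varepsilon)\,e^{\lambda t_i}/\Delta t_i}$
($\lambda$ fixed to fluorine-18, half-life 109.77 min): variance grows
with activity and decay, shrinks with frame length. The default scale
$s = 0.05$ yields regional TACs of the visual quality typical of
moderately sized cortical regions. The model has no spatial
correlation, no scatter/randoms structure, no motion and no
partial-volume effects — so passing tests say nothing about those
failure modes of real data.

**Phantoms.** `generate_phantom()` paints regional TACs into a
labelled 3-D array (plus independent voxel noise) to exercise
`extract_tacs()` and `fit_parametric()` end to end; with zero noise
the extraction roundtrip is exact by construction, which is the point
— it isolates bookkeeping errors from statistical ones.

## Fitting choices

**SRTM** uses the basis-function solution: for each apparent rate
$\theta$ on a 100-point log-spaced grid from 1/600 to 1 /min
(clearance half-times ~0.7 to ~7000 min), the basis
$C_R \otimes e^{-\theta t}$ is built on the fine grid and
frame-averaged, and the two linear parameters are solved by weighted
least squares. The grid minimum of the weighted residual sum of
squares is then polished by a bounded 1-D optimisation between its
neighbouring grid points; without this refinement the ~6.5% grid
spacing caps parameter accuracy at the percent level, with it the
noiseless inverse is exact to numerical precision. Ties prefer the
smaller $\theta$ (smoother kinetics). Fits whose optimum sits at a
grid end are flagged `boundary`; a flat objective across the grid
(e.g. target identical to reference, where $k_2$ is unidentifiable)
is flagged `degenerate`. Weights default to uniform — frame weighting
is a protocol decision, and `count_weights()` provides the
decay/duration-based alternative. Negative $\mathrm{BP_{ND}}$ is
reported, never clipped: clipping would bias stability curves in noisy
low-binding regions.

**Reference Logan** integrates frame values trapezoidally over frame
midpoints with an implicit $(0,0)$ anchor (activity is zero at
injection), regresses by ordinary least squares over midpoints beyond
$t^*$, and reports slope$-1$. At least three late frames are required;
frames where the target activity is numerically zero are reported by
index rather than silently propagated. Noiseless estimates approach
truth from below as $t^*$ grows (transient equilibrium), with a small
(<1%) late-$t^*$ overshoot attributable to trapezoid error on 5-min
frames — visible in sweep tails and tolerated by the stability
analyses rather than hidden.

**SUVR** weights frames by their overlap with the window, so windows
need not align with frame boundaries; the reference region's SUVR is
identically 1 by construction.

**Parametric maps** apply the chosen method voxelwise inside a mask
(default: voxels with any signal). The reference basis set is built
once per image and shared across voxels. A failing voxel (e.g. all
zero) becomes a missing value and a line in a failure log; it never
aborts the image.

## Stability and correlation analyses

Scan-duration sweeps truncate TACs to frames wholly inside each
duration (straddling frames are dropped — conservative), refit, and
aggregate mean ± between-subject SD per region. "Stable" is
operationalised as entering and remaining within ±5% of the
full-information estimate (`stability_onset()`, band configurable):
published stability onsets are by-eye judgments of such plots, so the
band is a parameter rather than a claim. Noiseless duration sweeps are
nearly flat — with exact data the model inverts at any identifiable
duration — so duration-stability experiments are run at the default
noise level, where short scans genuinely destabilise the fit;
$t^*$ and window sweeps show their kinetics-driven ordering even
noiselessly.

Static-versus-dynamic agreement pools all region×subject pairs into
one ordinary least-squares regression of SUVR on $\mathrm{BP_{ND}}$.
Under constant infusion at secular equilibrium the relation is exactly
$\mathrm{SUVR} = 1 + \mathrm{BP_{ND}}$, so slope 1 / intercept 1 /
$R^2 \approx 1$ is a sharp correctness check of the whole pipeline;
the equilibrium experiment uses efflux rates near 0.2/min and a 1-min
infusion ramp so that the slowest region is equilibrated to better
than 1% by the 100–120 min window.

The signed-$R^2$ matrix computes, per region pair, the Pearson
correlation across subjects of one measure against another and
reports $\mathrm{sign}(r)\,r^2$, with cells below the ±0.3 display
threshold masked to `NA` — the raw values and per-cell correlation
p-values are always kept alongside, so masking is presentational, not
destructive. Pearson (not Spearman) matches the linear-regression
framing of the agreement analyses and is switchable. No
multiple-testing correction is applied by default, matching per-cell
reporting conventions; Benjamini–Hochberg is available via
`p_adjust = "BH"`.

## Validation experiments and their sizes

The test suite and `scripts/acceptance.R` run, at these sizes:

* SRTM forward-inverse recovery and the independent
  nonlinear-least-squares cross-check: 50 random draws over
  $R_1 \in [0.6, 1.4]$, $k_2 \in [0.03, 0.3]$/min,
  $\mathrm{BP_{ND}} \in [0, 3]$, noiseless.
* Logan accuracy at $t^* = 20$ min on a fast-kinetics curve
  ($k_2 = 0.2$/min, $\mathrm{BP_{ND}} = 2$ — a parameter pair whose
  30-min stabilisation matches fast-tracer behaviour), plus a
  monotone $t^*$ sweep.
* Logan-below-SRTM noise bias: 200 noisy replicates at noise scale
  0.05.
* Equilibrium identity: 8 subjects × 4 regions under constant
  infusion.
* Fast-versus-slow stabilisation onsets: two 12-subject cohorts at
  default noise.
* Copula recovery: 200 low-noise subjects, latent correlation 0.92
  between one fast-tracer and one slow-tracer region
  ($r^2 = 0.846$).
* Phantom roundtrip: 72 voxels, 3 regions, noiseless.

## Known limitations

* The simulator's subject variability is purely parametric; real
  cohorts add registration error, partial-volume effects, off-target
  binding and motion, none of which are modelled. Conclusions about
  *which* scan window or $t^*$ is optimal therefore transfer only
  qualitatively.
* The reference TAC is itself noisy in noisy cohorts, and the SRTM
  basis is then built from an interpolated reference — adequate for
  the frame schedules shipped, but very sparse early framing would
  degrade it.
* Logan estimates inherit the classic noise-induced negative bias;
  the package reports it rather than correcting it (no likelihood
  or total-least-squares variants are implemented).
* `extract_tacs()` uses unweighted voxel means within a label;
  grey-matter probability weighting would require the MRI processing
  chain that is deliberately out of scope.
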