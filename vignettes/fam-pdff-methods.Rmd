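---
title: "Methods: flip-angle-modulated CSE-MRI simulation and PDFF fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flip-angle-modulated CSE-MRI simulation and PDFF fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famfat)
```

This vignette is the package's own account of its science: the signal model
and its assumptions, the flip-angle-modulation (FAM) design machinery, the
forward simulator, the fitting algorithms, the statistical conventions, and
the design choices made where the design was genuinely open.

## Signal model

A voxel containing water and fat proton densities $W$ and $F$ produces, at
echo time $TE_n$ of a spoiled gradient-echo train,

$$s(TE_n) = (W + F\,c_n)\,e^{-R_2^* TE_n}\,e^{i 2\pi \psi TE_n},
\qquad c_n = \sum_p a_p e^{i 2\pi f_p TE_n},$$

with a **six-peak fat spectrum** at offsets $-3.80, -3.40, -2.60, -1.94,
-0.39, +0.60$ ppm and relative amplitudes $0.087, 0.693, 0.128, 0.004,
0.039, 0.048$ — the widely used triglyceride model. The nominal amplitudes
sum to 0.999; the constructor normalizes them to sum exactly to one so that
$c(0) = 1$ holds identically. Frequencies are
$f_p = \bar\gamma B_0 (\delta_p + \Delta\delta)$ with
$\bar\gamma = 42.5775$ MHz/T; for room-temperature phantoms the conventional
$\Delta\delta = +0.11$ ppm temperature correction is applied
(`default_fat_spectrum(phantom = TRUE)`), and in vivo mode uses 0.

Sign conventions: positive $\psi$ produces phase $+2\pi\psi TE$; fat offsets
are negative (fat precesses more slowly than water). Data acquired under the
conjugate convention can be conjugated before fitting.

Assumptions inherited from standard confounder-corrected CSE fitting: a
single $R_2^*$ shared by water and fat, no $T_2$ as distinct from $R_2^*$,
no multi-compartment water. `PDFF = F/(W+F)` is reported in percent.

## Why steady-state acquisitions are T1-biased, and how FAM avoids it

A constant-flip acquisition converges to the SPGR steady state
$S/M_0 = \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$, $E_1 = e^{-TR/T_1}$, which
suppresses long-$T_1$ water more than short-$T_1$ fat. The resulting
apparent fat fraction $F g_f / (F g_f + W g_w)$ is computed by
`apparent_pdff_steady_state()`; the bias vanishes as $\alpha \to 0$ and is
nonnegative whenever $T_{1,fat} < T_{1,water}$.

FAM acquires each 2D slice with **centric phase-encode ordering starting
from equilibrium**. The first excitation contributes the DC line of k-space
with signal $M_0 \sin\alpha_1$ — independent of $T_1$ — and the flip angles
of later excitations are modulated as the acquisition walks outward in
k-space. Image contrast in flat regions is set by the DC weight, so ROI
means in vial interiors are essentially free of $T_1$ bias; $T_1$ enters
only through the shape of the k-space apodization, i.e. through edge
responses.

The transient recursion (perfect spoiling assumed, no RF-phase schedule
simulated) is

$$S_j = M_z(j)\sin\alpha_j,\qquad
M_z(j{+}1) = M_z(j)\cos\alpha_j\,E_1 + M_0(1-E_1),\qquad M_z(1)=M_0 .$$

## Schedule solving as target tracking

The published numerical optimization behind FAM schedules is not tabulated
anywhere we could build from, so the package poses schedule design as a
deterministic, fully testable inversion: given a per-excitation **target
signal profile** $t_j$, solve $\alpha_j = \arcsin(t_j / M_z(j))$ exactly at
a reference $T_1$, capping at `cap_deg` when infeasible. The default target
(`fam_target()`) is

* a **flat top** at $\sin\alpha_1$ for the first 15% of the train
  (preserves resolution near the k-space center),
* an **exponential decay** over 35% of the train down to the **Ernst-level
  floor** $\sqrt{(1-E_1)/(1+E_1)}$ — the largest signal sustainable
  indefinitely at the reference $T_1$ — and constant thereafter.

Defaults $\alpha_1 = 6°$, flat fraction 0.15, decay fraction 0.35 and
reference $T_1$s $(300, 1400)$ ms were chosen once, by the design criterion
that **no excitation reaches the flip cap** at any preset (once $M_z$ is
fully consumed by a 90° pulse the recursion can never recover, and the
remainder of k-space collapses to $M_0(1-E_1)$), while keeping the
point-spread-function broadening modest. At the 3T preset this yields a
FWHM broadening of about 1.12 relative to uniform weighting, a maximum
sidelobe of about 0.15, and a maximum DC-normalized weighting discrepancy of
about 0.15 between $T_1 = 300$ and $1400$ ms. These figures are recomputed
by `fam_design_report()`; they are properties of the solved schedule, not
assumptions.

`psf_metrics()` evaluates the phase-encode PSF by densely zero-padded DFT of
the per-line weights; broadening is quoted relative to the uniform (box)
window of the same length, and a weighting with fewer than two nonzero lines
is rejected as degenerate.

Echo-time noise performance is assessed by the Cramér–Rao lower bound on the
PDFF variance of the three-parameter magnitude model
(`crlb_pdff_variance()`), via the Fisher information of $(W, F, R_2^*)$ and
the delta method. A bound of this kind applies to unbiased estimators, so
tests compare it to Monte-Carlo variance at high SNR (agreement within 15%
at SNR 50) rather than asserting an inequality.

## Protocol presets and timing

Presets `"0.55T"`, `"1.5T"`, `"3T"` carry the variable-flip 2D protocols
(TR 15.8/12.6/9.3 ms, TE$_1$ 2.38/1.67/1.21 ms, $\Delta$TE 2.22/1.82/1.22 ms,
matrices 108²/144²/144², 6 monopolar echoes, 32 slices), and `"3T-3D-CSE"`
the constant-3° steady-state comparator (TR 6.4 ms). The per-slice temporal
footprint of a sequential 2D acquisition is $TR \times N_y$; totals multiply
the one-decimal-rounded per-slice value by the slice count, matching the
rounding convention of protocol tables (1.7/1.8/1.3 s per slice and
54.4/57.6/41.6 s totals at the three field strengths). A 2.89 T system
declared "3T" keeps its true $B_0$ in `b0_t` and its label in `b0_label`.

## Digital phantom

`make_pdff_t1_phantom()` renders the 4×4 grid of cylindrical vials covering
all 16 combinations of PDFF (0, 10, 20, 30%) and $T_{1w}$ (200, 600, 1000,
1400 ms), with $T_{1f} = 300$ ms everywhere. Choices the physical phantom
does not dictate:

* $R_2^* = 40\ \mathrm{s^{-1}}$ inside vials (typical agar-emulsion value),
  configurable;
* vial radius 2.5 cm in a 44 cm FOV (the physical vial diameter is not
  public; the constraint is that vials span ≥ 8 voxels and the 1.4 cm ROI
  fits well inside);
* vial edges taper over a 2-voxel band on the proton-density map only, so
  parameter maps are constant inside vials and centered ROIs never see the
  edge model;
* background is empty (air): background voxels are flagged invalid by the
  fitters rather than fitted.

`make_synthetic_liver()` provides a schematic elliptical liver partitioned
into nine angular sectors standing in for the Couinaud segments — only the
nine-label bookkeeping matters for whole-liver averaging — with smooth,
deterministic PDFF and $R_2^*$ fields that can straddle the exclusion
thresholds.

## Forward simulation

`simulate_echoes()` applies the schedule-induced k-space weighting
separately per species and $T_1$ class: each species sub-image (water; fat
carrying its phasor) is Fourier transformed along the phase-encode
dimension, each PE line scaled by the transient signal of that class's
$T_1$, transformed back and summed. This is exact for the phantom's
piecewise-constant $T_1$ maps; continuously varying maps are quantized to at
most 32 classes (documented approximation). Constant-flip steady-state mode
applies the converged flat weighting. $R_2^*$ decay is evaluated at the echo
time only (echo-centered approximation, consistent with standard CSE
fitting); readout sampling is ideal.

Noise is complex Gaussian added in the image domain, which under the unitary
Fourier transform is equivalent to white k-space noise; `noise_sd` is the
per-channel SD in image units, and repetitions (`repeat_acquisitions()`)
differ only in their seeds.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: respiratory motion (the motion robustness of 2D
FAM in vivo is outside desk scale), multi-channel coils and adaptive
combination, $B_1^+$ inhomogeneity and slice-profile effects, RF-spoiling
imperfections, gradient timing errors, and vendor reconstruction pipelines.
Conclusions from this package concern the encoding/fitting mathematics, not
scanner engineering.

## Fitting

**Magnitude fitting** (`magnitude_fit()`) solves, per voxel, bounded
nonlinear least squares of $|W + F c_n| e^{-R_2^* TE_n}$ against the echo
magnitudes over $(W, F, R_2^*)$ with $W, F \ge 0$ and
$R_2^* \in [0, 1000]\ \mathrm{s^{-1}}$ (Levenberg–Marquardt with analytic
Jacobian, cost tolerance $10^{-12}$). Magnitude fitting is invariant to any
voxelwise phase but dominance-ambiguous around PDFF 50%; both water- and
fat-dominant initializations are run and the lower-residual solution kept,
with ties resolved to the water-dominant branch. A Rician noise-floor
correction is **not** applied; at the simulated SNRs (≥ 20) the resulting
bias stays below test tolerances.

**Field mapping** (`estimate_field_map()`) discretizes $\psi$ over the full
fat–water ambiguity period $\pm 1/(2\Delta TE)$ (81 points by default; the
step must stay below 5% of the period) and minimizes
$\sum_v D_v(\psi_v) + \lambda \sum_{(v,u)} |\psi_v - \psi_u|$. The data term
is the variable-projection residual of the complex two-species model,
marginalized over an $R_2^*$ grid (0–200 s⁻¹ step 25) and normalized by the
mean voxel power so $\lambda$ is comparable across datasets. The discrete
optimizer is **iterated conditional modes** with checkerboard sweeps (energy
non-increasing by construction; the trace is returned), plus one global
constant-relabel move: the $L_1$ penalty is flat on monotone ramps, which
local sweeps cannot cross, so the best constant map is also offered and
accepted when it lowers the energy. ICM was chosen over a min-cut solver
because the energy above is the specification; the optimizer is an exchange-
able component and its convergence is tested, not assumed.

**Complex fitting** (`complex_fit()`) demodulates a given field map and
solves the complex linear problem for $(W, F)$ at each $R_2^*$ of a coarse
bracket, refined by a 1-D bounded search (tolerance $10^{-10}$); magnitudes
of the complex amplitudes populate the maps. A field map wrong by exactly
the fat–water ambiguity frequency swaps water and fat — the inherited,
documented failure mode.

**Hybrid fitting** (`hybrid_fit()`) minimizes
$w\,\|\text{complex residual}\|^2 + (1-w)\,\|\text{magnitude residual}\|^2$
over $(W, F, R_2^*, \phi_0)$, initialized from the complex fit. The default
$w = 0.5$ is a declared convention (no published value exists for the
weighting); $w = 1$ and $w = 0$ reduce exactly to the complex and magnitude
paths.

For matched-model experiments on steady-state data,
`correct_steady_state_t1()` divides the fitted amplitudes by the per-species
SPGR factors and recomputes PDFF; this is how the T1-bias mechanism is
verified quantitatively (fitted apparent PDFF equals the closed-form
prediction to numerical precision, and correction restores the truth).

PDFF maps retain raw values; only display (`autoplot()`) clips to
$[-5, 105]$% so statistics are never silently distorted.

## Analysis conventions

* ROI summaries average voxels within each ROI; SDs use the $n-1$
  denominator throughout.
* Bias is measured against the **low-flip-angle reference convention**: for
  each nominal-PDFF vial group, the $T_{1w} = 200$ ms vial (closest to the
  ~300 ms fat $T_1$) measured with a 1° constant-flip steady-state
  acquisition defines the group reference (`vial_reference_table()`).
* Agreement statistics are $1.96 \times$ SD of paired differences:
  limits of agreement between methods (LoA), test–retest repeatability (RC),
  between-condition reproducibility (RDC). On synthetic test–retest data
  with independent $N(0,\sigma^2)$ errors, RC recovers
  $1.96\sqrt{2}\,\sigma$.
* Voxel-wise SD across repetitions is the noise surrogate; per-system
  normalization divides ROI SDs by the median ROI SD of the reference
  method on the same system.
* ROIs with summary $R_2^*$ **strictly greater than** 276 s⁻¹ (1.5T) or
  397 s⁻¹ (3T) are excluded (values exactly at the threshold are retained;
  the rule is idempotent). Whole-liver PDFF is the unweighted mean of the
  surviving segment means — partial exclusion renormalizes over the
  remainder.
* In vivo LoA/RC/RDC magnitudes are **not** reproducible at desk scale
  (they require patients); the package verifies the estimators'
  parameter-recovery properties instead.

## Problem sizes and numerical tolerances

The shipped tests exercise full-resolution presets (144² and 108² matrices)
for the end-to-end bias and T1-bias-mechanism checks, and reduced grids
(48² with a 14.4 cm FOV, 24² single-vial phantoms) for per-operation
oracles, keeping vials above 8 voxels across and ROIs inside vials.
Monte-Carlo checks use $10^4$ draws (CRLB comparison, RC recovery). Key
tolerances: transient-vs-closed-form steady state $10^{-10}$ (with the train
length extended until the geometric convergence factor is below
$10^{-13}$); target-tracking round trip $10^{-8}$ on uncapped excitations;
noiseless end-to-end PDFF recovery 0.1%; field-map recovery within one grid
step; CRLB-vs-Monte-Carlo 15% at SNR 50.

## Known limitations

Perfect spoiling and ideal slice profiles; single coil; no motion model; no
bipolar readouts, parallel imaging or simultaneous multi-slice; hybrid
weighting and graph-cut staging are surrogates specified by their cost
functions; the Pulseq `.seq` export is a best-effort text rendering of the
block structure, timing-consistent but not vendor-certified.
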