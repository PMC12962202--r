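# famfat

Desk-scale toolkit for **flip-angle-modulated (FAM) 2D chemical-shift-encoded
MRI** of proton-density fat fraction (PDFF), the quantitative imaging
biomarker of hepatic steatosis. It is aimed at quantitative-MRI researchers
who want to study, on a digital phantom, why a centric-encoded variable-flip
2D acquisition escapes the T1-related PDFF bias of conventional steady-state
3D protocols — and at what cost in k-space filtering and SNR.

## The problem and the method

Multi-echo chemical-shift-encoded (CSE) MRI separates water and fat through
their resonance-frequency difference. The voxel signal at echo time `TE_n` is

    s(TE_n) = (W + F * c_n) * exp(-R2* TE_n) * exp(i 2π ψ TE_n),
    c_n = Σ_p a_p exp(i 2π f_p TE_n),       PDFF = F / (W + F),

with `W`, `F` the water/fat proton densities, `c_n` the multi-peak fat
phasor, `R2*` the shared transverse decay and `ψ` the B0 field offset.
Conventional 3D protocols acquire in the spoiled-gradient-echo steady state

    S/M0 = sin α (1 − E1) / (1 − E1 cos α),    E1 = exp(−TR/T1),

which saturates long-T1 water more than short-T1 fat and biases PDFF upward:
at 3T with TR = 6.4 ms and α = 3°, a true 30% fat fraction reads as 31.7%.
FAM instead acquires each 2D slice centrically from equilibrium — the k-space
center is sampled on the very first excitations, where the signal
`M0 sin α_1` is independent of T1 — and modulates the flip angle across the
phase-encode train to balance k-space filtering, quantitative accuracy and
SNR at the k-space periphery.

The package implements the whole desk-scale loop:

* **Sequence design** — centric orderings, the transient flip-angle
  recursion, exact target-tracking schedule solving, k-space weighting and
  PSF metrics, Cramér–Rao echo-time evaluation, protocol timing
  (`solve_fam_schedule()`, `psf_metrics()`, `crlb_pdff_variance()`,
  `sequence_timing()`).
* **Digital phantom** — the 16-vial PDFF (0/10/20/30%) × T1water
  (200/600/1000/1400 ms) grid, 1.4 cm vial ROIs, and a schematic nine-segment
  liver slice (`make_pdff_t1_phantom()`, `vial_rois()`,
  `make_synthetic_liver()`).
* **Acquisition simulation** — species- and T1-class-resolved k-space
  weighting under FAM or constant-flip steady state, complex Gaussian noise,
  seeded repetitions (`simulate_echoes()`, `repeat_acquisitions()`).
* **Fitting** — magnitude, complex and hybrid confounder-corrected
  PDFF/R2*/field-map estimation, with a regularized discrete field-map
  estimator (`magnitude_fit()`, `complex_fit()`, `hybrid_fit()`,
  `estimate_field_map()`).
* **Analysis** — ROI summaries, bias against the low-flip T1w = 200 ms
  reference convention, Bland–Altman LoA/RC/RDC (each 1.96 × SD of the paired
  differences), voxel-wise SD noise surrogates, and the R2* exclusion rule
  (276 s⁻¹ at 1.5T, 397 s⁻¹ at 3T) (`roi_summary()`, `bias_vs_reference()`,
  `bland_altman()`, `r2star_exclude()`, `whole_liver_pdff()`).

Results are tibbles throughout; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

```r
library(famfat)

# T1 bias of a conventional steady-state acquisition (3 deg, TR 6.4 ms):
100 * apparent_pdff_steady_state(0.30, 3, 6.4, t1_water_ms = 809, t1_fat_ms = 382)
#> [1] 31.73211       # true 30% reads as 31.7%

# Design the 3T FAM protocol and inspect timing / filtering / noise:
rep <- fam_design_report("3T")
rep$timing
#> # A tibble: 1 × 3
#>   per_slice_s per_slice_rounded_s total_s
#> 1       1.339                 1.3    41.6
rep$psf$t1_long$fwhm_broadening   #> 1.12408
rep$crlb_pdff_sd_pct              #> 1.257498  (PDFF SD at SNR 50)

# Noiseless end-to-end phantom run at 3T: simulate, fit, summarize, bias
run <- fam_run_pipeline(list(preset = "3T", mode = "fam", noise_sd = 0, seed = 1))
dplyr::select(run$bias, roi, pdff, t1w_ms, mean, ref_mean, bias)
#> # A tibble: 16 × 6     (first rows)
#>    roi  pdff t1w_ms   mean ref_mean    bias
#>      1   0      200  0.000    0      0.0000
#>      2   0.1    200  9.998    9.985  0.0127
#>      3   0.2    200 20.00    19.97   0.0225
#>      4   0.3    200 30.00    29.97   0.0295
run$max_abs_bias_pdff
#> [1] 0.03427624
```

`run$bias$mean` is the ROI-mean fitted PDFF (%) per vial, `ref_mean` the
group reference from the 1°-flip T1w = 200 ms convention, and `bias` their
difference; the maximum absolute bias across all 16 vials is ~0.03% PDFF —
the centric equilibrium start makes the DC k-space weight `sin α_1` for every
T1, so the fitted fat fraction is essentially T1-independent.

A thin command-line wrapper is installed at
`system.file("cli", "famfat.R", package = "famfat")` with `design` and
`pipeline` subcommands.

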