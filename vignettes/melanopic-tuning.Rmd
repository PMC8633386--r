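---
title: "Mapping the melanopic tuning range of metameric LED spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the melanopic tuning range of metameric LED spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamel)
```

## The problem

White light of a given chromaticity and illuminance is not unique: a
multi-channel LED luminaire can realise the same visual stimulus with many
different spectral power distributions.  Those *metamers* can differ
considerably in melanopic irradiance — the quantity that drives the
melanopsin-based, non-visual responses of the circadian system.  `metamel`
quantifies, for synthetic 6-, 8- and 11-channel luminaires, how far the
melanopic stimulus can be tuned at *fixed* chromaticity and illuminance,
and maps that tuning range over white points along the Planckian locus.

This vignette documents the model, every tunable parameter that matters,
the numerical choices, and what the synthetic setup can and cannot say
about physical luminaires.

## Spectra and the melanopic quantities

All spectra live on a fixed 380–780 nm grid with 1 nm spacing
(401 samples), in W·m⁻²·nm⁻¹.  Integrals use the rectangle rule at 1 nm;
on this grid the difference to the trapezoid rule is far below every
tolerance used here, and the test suite checks integration against an
independent trapezoid oracle to < 0.2 %.

Photopic illuminance is `E_v = 683 · Σ V(λ) X(λ)` lx.  The melanopic
equivalent daylight illuminance divides the melanopic irradiance
`Σ s_mel(λ) X(λ)` by the melanopic irradiance per lux of standard daylight
D65.  Two points deserve emphasis:

* **The melanopic action spectrum is constructed, not tabulated.**
  `melanopic_sensitivity()` builds `s_mel` from the Govardovskii vitamin-A1
  opsin nomogram with peak absorbance at 480 nm (a quantal sensitivity,
  converted to an energy basis by multiplying with λ), filtered by the
  ocular-media transmittance of a 32-year-old standard observer (van de
  Kraats & van Norren 2007 model), then peak-normalised.  The resulting
  curve peaks near 490 nm.

* **The D65 conversion constant is derived from the bundled tables.**
  The constant is *defined* as the melanopic irradiance of D65 per lux of
  D65, so deriving it from the package's own D65, V(λ) and `s_mel` tables
  makes the melanopic DER of D65 exactly 1 — the anchor every melanopic
  metric hangs on.  The derivation reproduces the published value
  1.3262 · 10⁻³ W·m⁻²·lx⁻¹ to better than 1 % (asserted in the tests);
  hard-coding the published constant instead would have broken the D65
  anchor by exactly the small residual error of the constructed action
  spectrum, which is the wrong trade.

Chromaticity uses the bundled CIE 1931 2° colour-matching functions
(5 nm source table, linearly interpolated).  CCT and Duv follow the
table-search approach: the Planckian locus is tabulated densely
(1000–25000 K, ~0.05 % geometric steps) in the CIE 1960 (u, v) space, and
a parabolic fit through the three nearest entries refines both values.
Duv is signed (positive above the locus) and, following the conventional
definition, is always *measured and stepped in the 1960 uv space*, while
targets and maps are reported in u′v′ and xy.  Round trips through
`planck_point()` → `duv_offset()` → `cct_duv()` close to |ΔCCT|/CCT < 0.1 %
and |ΔDuv| < 10⁻⁴.  Degenerate spectra are legal inputs to the integrals
(an all-zero spectrum has zero illuminance) but are rejected by
`chromaticity()` and by CCT/Duv (points with |Duv| > 0.05 are considered
CCT-undefinable).

## The synthetic luminaires

The measured primaries of the physical 11-channel luminaire that motivated
the three presets are not publicly tabulated, so the package generates
stand-ins:

* narrowband channels are Gaussians with a default FWHM of 20 nm (a
  typical royal-blue/cyan/red LED linewidth; configurable per call),
  normalised to unit radiometric power;
* the two phosphor-converted whites (4655 K and 2740 K, shared by all
  presets) are modelled as a 450 nm pump Gaussian plus one broad phosphor
  Gaussian (FWHM 110 nm) whose centre and power ratio are solved
  deterministically so the chromaticity lands on the locus at the target
  CCT (achieved: |ΔCCT| < 1 K, |Duv| < 10⁻⁵, checked against the ±50 K /
  ±0.005 contract in the tests);
* the 11-channel preset adds a lime phosphor channel, modelled as a broad
  Gaussian centred at 550 nm with FWHM 100 nm.

Channel rosters: 6-channel = {475, 504, 521, 662 nm} + whites; 8-channel =
{450, 465, 504, 521, 638, 662 nm} + whites; 11-channel = {419, 450, 457,
504, 521, 597, 638, 662 nm} + lime + whites.  Mixing is exactly linear in
the weights (`mix()`), i.e. the duty-cycle nonlinearity of a real driver is
idealised away — a stated limitation, not an oversight: it preserves the
additivity that all downstream invariants (illuminance and melanopic
linearity, rescaling) rely on.

What this emulation does *not* reproduce: the true linewidths, phosphor
shapes and relative powers of any physical device.  Consequently the
absolute tuning-range maxima of the atlas are properties of the synthetic
primaries, and only the qualitative structure — which the acceptance tests
assert — transfers: the tuning range grows with CCT and saturates around
~4500 K, adding channels never shrinks the achievable range, and the
colour-fidelity gate is the binding constraint.

## The target grid

`build_grid()` places 17 CCT levels between 2700 K and 7443 K, each with
33 Duv offsets {0, ±0.003, …, ±0.048} — 561 targets.  The CCT-level count
follows from the published grid size (561 / 33); the exact CCT ladder was
an open choice because only its endpoints and a few interior values are
published.  The default spaces levels uniformly in u′v′ arc position along
the locus (the geometric reading of a "uniform grid" in that diagram);
uniform spacing in reciprocal CCT is available as `spacing = "recip_cct"`.
Neither option is asserted to be the original ladder.  Likewise, whether
the Duv ladder was stepped in u′v′ or uv(1960) units was unstated; the
package steps in uv(1960), the space in which Duv is defined, and keeps
that convention everywhere.

Targets outside a luminaire's gamut are not errors: they produce empty
metamer sets, flagged infeasible, and show as gaps in the maps.

## The metamer harvest

The original optimisation engine behind the published dataset is
unpublished, so the package specifies its own: a differential-evolution
style population search (population 60, 400 generations per repetition by
default, F = 0.7, CR = 0.9) over channel weights in [0, 1]ⁿ, with the
objective `‖(u′, v′) − target‖ + 10⁻³ · max(0, |E_v − 220| − 2)`.  The key
contract is *harvesting*: every weight vector visited anywhere in the
search whose mixture satisfies the per-axis chromaticity tolerance
(|Δu′|, |Δv′| ≤ 0.001) **and** the 220 ± 2 lx working window is archived,
not just the best individual.  Eight repetitions with derived seeds
(`derive_seed()`, a counter-based fan-out) per target make the harvest
reproducible and monotone in the number of repetitions.

Numerical choices:

* spectra are optimised at 220 ± 2 lx and then rescaled linearly to the
  250 lx reporting level, in that order; because dimming is linear the
  chromaticity tolerance is unaffected by the rescale;
* duplicate solutions are collapsed by rounding weight vectors to a
  10⁻³ box (max-norm) — metamer "distinctness" has no published
  definition, and this resolution is far below any photometrically
  meaningful weight change;
* the archive is capped (`max_archive`, default 4000 per repetition) as a
  memory safety valve; mid-gamut targets can otherwise archive tens of
  thousands of members without changing the extremes;
* a target is declared infeasible only after *all* repetitions return
  empty archives;
* an optional `max_active` limit zeroes the smallest weights of every
  candidate so that no solution drives more channels than allowed.

## Colour fidelity gating

Fidelity scoring follows the TM-30 method structure: reference illuminant
of the same CCT (Planckian below 4000 K, the CIE daylight series above
5000 K — reconstructed from the daylight characteristic vectors with the
mean vector anchored to the bundled D65 so that the 6504 K phase *is* D65 —
and a proportional blend between), colour shifts of an evaluation-sample
set in CAM02-UCS (L_A = 100 cd·m⁻², Y_b = 20, average surround), the 6.73
scaling with the logarithmic soft floor, and 16 reference hue bins with
bin 1 (reds) reported as `rf_h1`.

Two deliberate substitutions, both visible in the API and the tests:

* **The evaluation samples are synthetic.**  The standard's 99 sample
  reflectances are not redistributable data, and no vetted implementation
  of the index exists in this package's dependency set.
  `fidelity_samples()` therefore generates 99 deterministic, closed-form
  reflectances (band-pass and band-stop Gaussians of varied width plus
  sigmoidal edge spectra) that cover all 16 hue bins under every relevant
  reference (asserted in the tests).  Scores behave like the real index —
  100 for reference-equal spectra, high for smooth broadband spectra, low
  for spiky mixtures — but are an *analogue*, and the package never claims
  certified TM-30 values.  The cross-check oracle in the test suite is an
  independent scalar re-implementation of the scoring chain (own constants,
  plain loops), agreeing to ±0.5.
* **The 2° observer is used throughout**, including fidelity, for internal
  consistency; the letter of the standard uses the 10° observer for sample
  colour shifts.  With synthetic samples this is a second-order detail.

Gating keeps members with `rf ≥ 85 & rf_h1 ≥ 85` ("p3"), `≥ 90/≥ 90`
("p2"), or all members ("none").  Tightening the criterion can only shrink
a metamer set, so per-target tuning ranges are ordered
`Δγ(p2) ≤ Δγ(p3) ≤ Δγ(none)` — an invariant the acceptance tests verify on
re-gated cached harvests.  A CRI R_a diagnostic field exists in the score
frame but is reported as `NA`: the CRI test-colour reflectances are not
bundled, and R_a is never used as a gate.

## Reduction and the atlas

`summarize_target()` scans a gated set for its melanopic EDI extremes
(ties broken by first occurrence) and derives `Δγ`, `ΔE_mel = E_v · Δγ`
and the Michelson contrast `C_M = (max − min)/(max + min)`.
`summarize_cct()` reduces across the Duv ladder of each CCT: the per-CCT
DER extremes (γ̂ values, a *non-metameric* comparison across
chromaticities) and the largest within-target tuning range (Δγ̃, the truly
metameric quantity), each with its arg-max Duv.  DER and contrast are kept
at full precision internally and printed to 2 decimals in reports.

`build_atlas()` interpolates `delta_gamma` and `c_m` onto a regular CIExy
raster by barycentric interpolation over the structured
(CCT level, Duv level) lattice — each complete cell split into two
triangles — with no extrapolation: raster cells outside optimised targets
stay `NA`, so gamut holes remain visible.  Linear interpolation cannot
exceed the data extremes, and global maxima are located by brute force over
the raw per-target values, ties broken by the lowest
(CCT level, Duv level) index (no ordering was published for this case).

## Problem sizes used by the test and acceptance suites

The full 561-target, three-luminaire study is deliberately not what the
automated checks run; the package's properties are scale-free and are
asserted on reduced sizes chosen to exercise every code path:

* qualitative atlas properties: 5 CCT levels × 7 Duv offsets
  (Duv ≤ 0.009), all three luminaires, 8 repetitions per target,
  150 generations, archive capped at 150 per repetition;
* optimiser recovery: 100 feasible-by-construction targets (11-channel),
  2 repetitions of 150 generations each, ≥ 95 % required to archive at
  least one in-tolerance solution;
* the rich-yield check (≥ 50 distinct metamers at a mid-gamut target) runs
  at the default search size.

A full-scale run is a `pipeline_config()` call away and writes per-target
caches, so it can be resumed and re-gated under a different fidelity
criterion without re-optimising.

## Known limitations

* Synthetic primaries: absolute tuning-range values and the exact
  locations of the atlas maxima depend on the Gaussian/phosphor stand-ins.
* Fidelity is a TM-30 *analogue* (synthetic samples, 2° observer); gate
  thresholds of 85/90 act on that analogue's scale.
* Linear dimming; no thermal droop, driver quantisation or measured-SPD
  ingestion (a CSV loader exists for external spectra, but no measured
  channel data ships with the package).
* Melanopic only: other alpha-opic channels would need their own action
  spectra; the container and constants make that extension mechanical.
* No melatonin-suppression or other dose–response modelling: the package
  stops at the melanopic stimulus, which is the quantity a luminaire
  actually controls.
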