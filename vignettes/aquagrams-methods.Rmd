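---
title: "Aquagrams for water NIR spectra: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aquagrams for water NIR spectra: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquagrams)
```

## The problem

Water dominates the near-infrared spectrum of any aqueous or biological
system. In the first overtone region of the O–H stretch (1300–1600 nm) the
broad band around 1450 nm is a superposition of bands of distinct water
molecular species — free OH, small clusters, and water engaged in one to
four hydrogen bonds. Aquaphotomics reads a system through this water
matrix: the absorbance pattern at 12 experimentally established water
matrix coordinates (WAMACs, `C01`–`C12`, each a 6–12 nm range between 1336
and 1518 nm) forms a water spectral pattern that acts as an integrated
fingerprint of how a perturbation (temperature, solutes, biological state)
restructures the hydrogen-bond network. The pattern is drawn as a radar
chart, the *aquagram*.

This package implements two aquagram calculations plus everything needed
to validate them end to end without instrument data.

## The classic aquagram and why it is unstable

`classic_aquagram()` computes, for each group $g$ and coordinate center
wavelength $\lambda$,

$$A'_\lambda = \frac{A_\lambda - \mu_\lambda}{\sigma_\lambda},$$

averaged over the group's spectra, where $A_\lambda$ is the
multiplicative-scatter-corrected absorbance and $\mu_\lambda$,
$\sigma_\lambda$ are the mean and sample SD at $\lambda$ over **all**
spectra in the call. Values are dimensionless z-scores, and their
group-size-weighted mean is identically zero at every coordinate.

The standardization set is the whole examined set, not the subgroup. That
reading is deliberate: it is the only one under which the well-known
context dependence of classic aquagrams appears — removing groups from the
call changes the remaining groups' values, because $\mu_\lambda$ and
$\sigma_\lambda$ move. A per-group alternative is exposed via
`scope = "group"`, and the MSC reference can be fixed explicitly
(`msc_reference`) when values must be comparable across calls.

## The temperature-based aquagram

`temp_aquagram()` expresses a perturbation on a degree-Celsius scale: the
temperature change that would restructure pure water by the same amount at
that coordinate. The chain, per coordinate $c$:

1. **Reference**: a pure-water temperature ladder (the canonical design is
   26 steps of 2 °C between 20 and 70 °C, 3 consecutive scans each) with
   `temperature_C` metadata.
2. **Baseline**: each spectrum has the straight line through its values at
   1300 and 1600 nm subtracted (`baseline_correct()`), so the corrected
   spectrum is zero at both edges.
3. **Relative areas**: trapezoidal area of the corrected spectrum over the
   coordinate range, divided by the area over the full 1300–1600 nm window
   (`relative_areas()`). The ratio $r_c$ is invariant to any positive
   scaling of the spectrum — this is what removes pathlength and
   multiplicative scatter.
4. **Reference curves**: $r_c$ against temperature, smoothed by a
   tricube-weighted local polynomial regression (degree 2, span 0.5 of the
   points) and evaluated on a 0.1 °C grid (`build_reference_curves()`).
5. **Local calibration**: an ordinary least-squares line
   $r_c(T) = \alpha_c + \beta_c T$ fitted to the smoothed curve inside
   `experiment_T` ± 2 °C (`local_calibration()`).
6. **Inversion**: a group's mean relative area $\bar r_c$ maps to
   $T_c = (\bar r_c - \alpha_c)/\beta_c$.

Because each group is processed only through its own spectra and a fixed
reference, values are *subset stable*: adding or removing unrelated groups
changes nothing (the package asserts exact equality to 1e-10 in its
tests), in contrast to the classic flavour.

### Ordering of normalization and averaging

The group statistic is the mean of per-spectrum relative areas, not the
relative area of the mean spectrum. For identical consecutive scans the
two are the same; under per-spectrum multiplicative scatter they are not —
averaging raw spectra first lets the scatter factors reweight the mean,
while normalizing first cancels them exactly (the test suite checks
invariance to ±20% random affine distortions at 1e-9). This is the
package's design choice for making the normalization step do what it is
for.

### Conditioning near the isosbestic point

Between the growing (≈1412 nm) and shrinking (≈1462 nm) bands lies an
isosbestic, temperature-invariant wavelength. Coordinates whose range sits
near it have $\beta_c \approx 0$: their relative area carries almost no
temperature information, and inverting the calibration would amplify noise
into absurd °C values. Such coordinates are *flagged and suppressed*
(`conditioned = FALSE`, value `NA`), never reported from a near-zero
slope. The default threshold is relative,
$|\beta_c| \ge 0.05\,\max_{c'}|\beta_{c'}|$, because the natural scale of
the slopes is set by the data themselves; an absolute `beta_min` (relative
area per °C) can be supplied. A threshold proportional to each
coordinate's own curve range was considered and rejected: for monotone
curves the range is itself proportional to $|\beta_c|$, so such a rule can
never flag anything.

### Calibration windows

* With a single `experiment_T` (a solute experiment incubated at one
  temperature) all groups share one window.
* With `experiment_T = NULL` each group is calibrated at its own
  `temperature_C` — the only consistent way to display a temperature
  experiment itself across its whole 20–70 °C span.
* At the ends of the reference ladder the symmetric window is clamped to
  the curve span (e.g. the 20 °C group uses [20, 22] °C), keeping the edge
  groups representable at the cost of an asymmetric local fit.

### Confidence intervals

All intervals are percentile bootstrap intervals from resampling whole
spectra with replacement within a group (never wavelengths, never the
reference, which is treated as a fixed calibration), with
`n_boot = 1000` by default and the replicate chain identical to the point
estimate's. Bounds are clamped to bracket the point estimate, since raw
percentile bounds need not contain it at finite `n_boot`. With
`control_group` set, differences (group − control) are computed on paired
bootstrap replicates and appended as `mode = "delta"` rows.

## Pretreatments

* `msc()` regresses each spectrum on a reference (default: the mean
  spectrum) and removes the fitted affine distortion. With a *fixed*
  reference the correction is exactly invariant to per-spectrum affine
  distortions; with the data-dependent mean reference the invariance is
  only approximate, which is why `classic_aquagram()` exposes
  `msc_reference`.
* `snv()` centers and scales each spectrum by its own mean and sample SD.
* `sg_derivative()` computes Savitzky–Golay smoothed derivatives per nm
  (the 0.5 nm grid step is divided out), defaulting to the settings that
  resolve the 1412/1462 nm species bands: 2nd-order polynomial, 21 points,
  2nd derivative. Edge values come from the first/last window's polynomial
  and are flagged in an attribute.
* `pca_explained()` is mean-centered PCA; on simulated temperature series
  PC1 carries ≈99% of the variance, matching the usual dominance of the
  perturbation direction in water spectra.

## The synthetic water model

`nir_water_model()` generates spectra as Gaussian species bands on a
linear baseline with per-spectrum multiplicative/additive scatter and
photometric noise. Amplitudes respond linearly to temperature with
area-conserving coefficients, which yields the two qualitative signatures
of heated water by construction: a monotone blue shift of the band maximum
and an exact isosbestic point (`isosbestic_wavelength()`).

* `"two_band"` (default): 1412 nm (σ = 16 nm, growing) and 1462 nm
  (σ = 20 nm, shrinking). The minimal mechanism; coordinates that see only
  far Gaussian tails (C01, C02, C12) are correctly flagged
  ill-conditioned.
* `"four_band"`: adds broad flanking bands near 1360 nm (free OH / small
  clusters) and 1490 nm (strongly bonded S3/S4), giving every coordinate a
  usable temperature response. Band strengths were chosen once so that all
  12 calibration slopes are well conditioned over 20–70 °C while every
  amplitude stays positive; they are not a quantitative model of water —
  no synthetic coefficient is tied to instrument-scale absorbance.

Scatter is drawn per spectrum, never per wavelength, so MSC can remove it
exactly — which turns the MSC tests into true oracles. The default
photometric noise (0.002 AU) represents a high-quality averaged
transmittance scan; at that level adjacent 2 °C groups of 6 spectra are
cleanly separated by their 95% intervals.

`simulate_solute_series()` perturbs the spectrum by signed Gaussian
components scaled by `log10(1 + c_mM)`, with interleaved pure-water
controls. The default `structure_breaker()` models a KCl-like ion:
depletion of the hydrogen-bonded network bands (1450, 1467 nm), creation
of free/weakly bonded OH (1360, 1412 nm), and — because dissolved ions
displace water — a net *decrease* of total band area. The edges of the
first overtone then lose less than the average, their relative areas grow,
and the temperature equivalents come out positive at C01–C08 and negative
at C10–C12, the canonical structure-breaker pattern. Two modelling notes:

* A solute direction exactly proportional to the temperature direction
  (pure 1462 → 1412 transfer) would produce the *same* positive °C value
  at every conditioned coordinate — sign structure across coordinates
  requires a perturbation that is not collinear with warming. The
  displacement mechanism provides that non-collinearity physically.
* For an amplitude-only Gaussian mixture the raw-spectrum *argmax* blue
  shift under such a solute is antagonistic to the C10–C12 pattern
  (tilting the argmax of the broad flat-topped band requires depletion
  just above the peak, which drains exactly the C10–C12 ranges). The
  generator therefore shows the solute blue shift in the baseline-corrected
  spectral centroid, while the argmax blue shift holds for the temperature
  mechanism, where the band equilibrium genuinely moves.

## What passing tests do and do not show

The simulator emulates band structure, temperature response, scatter,
noise, replication and control interleaving. It does not emulate band
*shape* changes (shifts, narrowing), instrument line-shape effects,
detector nonlinearity, or baseline curvature beyond a straight line.
Passing the recovery and stability tests therefore demonstrates that the
algorithms are implemented correctly and behave as designed under their
stated assumptions — not that a particular instrument will achieve
±0.1 °C equivalents on real samples.

## Numerical choices and problem sizes

* Integration: trapezoidal rule on the native 0.5 nm grid. Window bounds
  are inclusive; wavelength matching uses a 1e-6 nm tolerance and nothing
  is ever interpolated implicitly.
* Smoother: `stats::loess` with `surface = "direct"` so that polynomial
  inputs are reproduced exactly (the test suite checks reproduction of an
  exactly linear relative-area trend to 1e-6).
* Degenerate inputs fail fast with named errors: zero-variance MSC
  reference, constant spectra in SNV, zero spectral SD at a coordinate in
  the classic standardization, non-positive total area, missing
  `temperature_C`.
* The validation suite uses 78-spectrum reference ladders throughout;
  recovery under 1%-of-peak noise uses 400-sample × 3-scan groups; the
  bootstrap coverage experiment uses 200 replicates of 30-spectrum groups
  at `n_boot = 500`. These sizes keep every experiment deterministic under
  a fixed seed and fast enough to re-run routinely.

## Known limitations

* Eq.-style classic values depend on the examined set by design; export
  them only together with the set definition.
* The temperature calibration is local: groups whose true equivalent lies
  far outside `experiment_T` ± 2 °C are extrapolated by the local line and
  should be re-run at a more appropriate `experiment_T`.
* `C07` is quoted in parts of the literature as 1432–1444 nm (center
  1438); the package uses the single consistent center ± 6 nm rule with
  the listed center 1440. Supply a custom scheme to override.
* The °C scale is only as good as the reference ladder; the package never
  resamples the reference, so reference noise enters as a fixed bias of
  the calibration, not as width in the reported intervals.
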