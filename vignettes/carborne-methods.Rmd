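---
title: "Methods: car-borne gamma-ray survey analysis with carborne"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: car-borne gamma-ray survey analysis with carborne}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carborne)
library(dplyr)
```

## The problem

Terrestrial gamma radiation in high-background areas comes almost entirely
from three sources mixed in the ground: ⁴⁰K, the ²³⁸U decay series and the
²³²Th decay series. A car-borne survey drives a NaI(Tl) scintillation
spectrometer along roads, logging counts every 30 s with GPS, and converts
those counts to outdoor air kerma rates and annual effective doses;
stationary spot measurements with full 1024-channel pulse-height spectra are
unfolded into per-nuclide activity concentrations (Bq/kg) and a per-nuclide
decomposition of the kerma rate. `carborne` implements that entire analysis
chain, together with a synthetic-data generator that produces spot spectra
and survey tracks with known ground truth, so every stage is testable
without access to field data.

## The spectrometric model

### Energy bins and response matrix

The analysis works on a fixed partition of 0–3.2 MeV into 22 bins whose
widths grow with energy (`energy_bins()`). Five bins are anchored by the
method itself: bin 14 (1.39–1.54 MeV) holds the 1.464 MeV ⁴⁰K line, bins 16
and 18 (1.69–1.84, 2.10–2.31 MeV) the 1.765 and 2.205 MeV ²¹⁴Bi lines, bin
20 (2.51–2.72 MeV) the 2.615 MeV ²⁰⁸Tl line, and bin 22 (3.0–3.2 MeV) lies
above every terrestrial line and indexes the cosmic-ray continuum. The
remaining edges are not pinned down by the method; the package freezes one
choice (documented in `energy_bins()`) as a named constant. Energies above
3.2 MeV are not evaluated.

The 22×22 response matrix (`build_response_matrix()`) maps incident flux per
energy bin to detected count rate per pulse-height bin for a 3-in × 3-in
NaI(Tl) crystal in an isotropic field. It is an analytic model, not a
transport calculation: each incident bin produces a Gaussian full-energy
photopeak at the bin centre — with FWHM(E) = k√E, the photostatistics law,
parameterised by the FWHM fraction at 0.662 MeV (default 7%) — plus a
Compton continuum flat in deposited energy up to the Compton edge. The
intrinsic total efficiency follows NaI attenuation through the crystal
length and a peak-to-total fraction decaying as a power of energy. The
matrix is nearly triangular (nothing is detected far above the incident
energy), with condition number ≈ 9.5, so unfolding amplifies counting noise
only mildly; `response_condition()` reports the factor.

Because commercial scintillators vary in resolution, `apply_def()`
re-broadens a standard matrix to an individual instrument: a
diagonal-elements fit that rescales the photopeak widths so FWHM(E) = k√E
interpolates widths measured at the 1.464 and 2.615 MeV calibration peaks,
leaving the continuum untouched and conserving every column sum to well
within 0.5%.

### Unit-activity flux library

To turn unfolded flux into activity concentrations the package needs the
gamma flux density at 1 m above ground per unit activity concentration of
each nuclide, for a source mixed uniformly through a semi-infinite soil
volume (`build_unit_flux_library()`). The embedded line library
(`nuclide_lines()`) lists the principal lines of each series per parent
decay under secular equilibrium, Beck-style.

The primary (uncollided) flux is computed by a seeded 1-D Monte Carlo:
each history samples an emission depth (exponential in soil optical depth)
and an upward direction cosine, and scores an attenuated flux estimator;
histories (default 10⁶ per nuclide) are allocated across lines by emission
intensity, and per-bin standard errors are reported. For the scattered
component the package uses a build-up treatment anchored to the
infinite-medium energy balance: in an infinite uniformly active medium the
absorbed dose rate equals the energy emission rate per unit mass, and at a
plane interface the equilibrium kerma falls to one half of that; the
scattered kerma of each line is therefore the difference between this limit
and the line's primary kerma (their ratio reduces to the soil attenuation
over air energy-absorption coefficient ratio), scaled onto the Monte Carlo
primary estimate and spread below the line energy as a down-scatter
continuum flat in kerma per unit energy above a 0.05 MeV floor. Soil is
fixed at ρ = 1.6 g/cm³ with quartz-like attenuation; coefficients are
standard tabulated values under log–log interpolation.

The per-nuclide kerma coefficients that fall out — about 0.044, 0.425 and
0.568 nGy/h per Bq/kg for ⁴⁰K, the ²³⁸U series and the ²³²Th series at the
default settings — sit within a few to ~13% of the ratios embedded in the
published spot table (0.0418, 0.440, 0.650), comfortably inside the 25%
envelope that a simplified desk-scale transport model is expected to
achieve, and reproduce the ordering Th > U > K that makes monazite sand
dominate the dose.

### Calibration

NaI gain drifts with temperature, so every spot spectrum is calibrated
individually on its own ⁴⁰K and ²⁰⁸Tl photopeaks. The spectrum is smoothed
by truncated Fourier expansion (`smooth_fourier()`; the DC term is kept so
total counts are conserved, and re-smoothing at the same order is the
identity). Coarse peak location runs on the log-stabilised smoothed
spectrum — natural spectra span three decades, and smoothing the raw counts
would let truncation ripple from the low-energy continuum bury the weak
2.615 MeV peak. The prominent ⁴⁰K peak is found first; the ²⁰⁸Tl search
window is then anchored to it (predicted channel ± 3%), which also excludes
the 2.448 MeV ²¹⁴Bi satellite 6% below. Each coarse location is refined on
the raw counts by a weighted least-squares fit of a Gaussian on a local
linear background over ±2.5σ; fits whose width leaves [0.4, 2.5]× the model
width are rejected in favour of the coarse estimate. The smoothing order
default (120 of 1024 channels) and the refinement window were chosen by
minimising peak-location error on synthetic fixtures across gains 250–350
channels/MeV and ±3% drifts; recovered gains stay within 0.5%. The final
channel→energy map is affine through both peaks (a proportional map was
rejected because real NaI chains have a nonzero offset). Channel counts are
then apportioned to the 22 bins by fractional energy overlap
(`rebin_to_energy()`), conserving counts exactly; 30-s mobile records are
never individually calibrated — their energy calibration would be far too
noisy — and contribute only total counts.

### Background subtraction and unfolding

Bin 22 contains no terrestrial signal, so the cosmic contribution is removed
by scaling a fixed template to the measured bin-22 content and subtracting
(`subtract_cosmic()`); the template is flat in pulse-height energy above
0.5 MeV, a documented package assumption since only the bin-22 indexing role
is prescribed by the method. The ⁴⁰K contamination in the photomultiplier
glass is removed as a pure-⁴⁰K response shape at a fixed instrument rate
(`subtract_pmt_background()`); the default rates (2 cps cosmic in bin-22
equivalent, 1 cps PMT) are assumptions, labelled as such, because no
instrument background magnitudes are published for this survey class.
Negative results of either subtraction are clipped to zero and flagged
rather than silently truncated, preserving diagnosability at low counts.

`unfold()` solves response × flux = count rate with a non-negativity
constraint (an unconstrained solve is accepted when it is already
non-negative; otherwise non-negative least squares, with a clipped fallback
flagged on the rare degenerate failure). Poisson variances of the raw bin
counts propagate linearly through the unconstrained inverse to a full flux
covariance.

### Activity estimation

`estimate_activities()` runs the successive approximation on the three
key-bin groups {14}, {16+18}, {20} — the anchored peak bins, with the two
²¹⁴Bi bins pooled for variance reduction. The interference system is nearly
triangular: nothing terrestrial lies above the ²⁰⁸Tl bin and ⁴⁰K reaches no
group but its own, so the iteration runs Th → U → K, stripping each
nuclide's library contribution from the lower groups, until every activity
moves less than 0.1% (50-iteration cap with a diagnostic error). On
noiseless mixtures this fixed point coincides with the direct 3×3 linear
solve to much better than 0.1%, which the test suite checks against the
direct inversion as an independent oracle. Statistical errors propagate the
flux covariance through the linear solve; kerma components are activity ×
kerma coefficient, and contributions are reported as integer percentages,
which by construction sum to 100 ± 1.

At the published survey's counting conditions (300 s at ~600 nGy/h) the
propagated kerma error is of order a few percent, consistent with the 2%
class error the survey reports; the exact published error model depends on
an integral-kerma formula in an inaccessible reference, so the Poisson
propagation here is a documented surrogate.

## The survey model

Inside-vehicle counts over 30 s convert to outdoor kerma as

K_out = 2 N_in × F_s × F_c,

with the factor 2 converting a 30-s count to counts per minute, the car-body
shielding factor F_s = 1.47 and the dose-rate conversion factor
F_c = 0.00244 nGy/h per cpm. Both factors are through-origin least-squares
slopes (`fit_shielding_factor()`, `fit_conversion_factor()`) — zero counts
must mean zero kerma, so an intercept is physically inadmissible. Annual
effective dose follows as

H (mSv/y) = K_out × DCF × T,

with DCF = 0.7 Sv/Gy and T = 8760 h: a deliberately conservative outdoor
estimate with no occupancy factor or building shielding (individual
dosimetry is out of scope). On the published maximum spot kerma of
2141 nGy/h this gives 13.1 → 13 mSv/y at the survey's two-significant-figure
reporting precision, and 12 mSv/y for the 2021 nGy/h Neendakara maximum.
Two quirks of the published table are worth noting and are deliberately not
"fixed": the prose reports the Neendakara maximum as 1.9 μGy/h where the
table's 2021 nGy/h rounds to 2.0, and a sand-thorium range of 0.7–2.3 kBq/kg
where the table maximum 2374 Bq/kg rounds to 2.4; the package follows
standard rounding throughout.

Regional statistics (`summarize_regions()`) report per-region mean, median,
minimum and maximum annual dose at two significant figures, the coefficient
of variation of the kerma rate (computed on kerma, not dose), and the
fraction of records above 1 mSv/y. `grid_dose_map()` averages points into
fixed lon/lat cells, keeping empty cells explicit. Coordinates are decimal
degrees, WGS-84 assumed, printed at 4 decimals; distances use a local
equirectangular approximation, adequate at the ~20 km survey scale.

## The synthetic-data generator

`spot_scene()` fixes a ground truth (activities, surface class, instrument
state, counting time — 300/600/900 s for high/mid/low-level sites, matching
survey practice) and `simulate_spot_spectrum()` produces the expected
1024-channel spectrum by folding the activities through the flux library
and the response model in channel space — photopeaks at the scene's gain
and resolution, continua below the Compton edges, the flat cosmic continuum
anchored to the scene's bin-22 rate, and the PMT ⁴⁰K component — then
Poisson-samples under the scene seed. The channel placement aggregates
exactly (in expectation) to the 22×22 matrix applied to the binned flux, so
estimator bias through the full chain stays far below counting error.

`make_activity_field()` builds per-nuclide activity grids from a smooth
seeded background plus Gaussian hotspots; `coastal_field()` is the preset
used in tests: mild inland background (150/60/100 Bq/kg for K/U/Th, typical
of the survey's soil rows) with thorium-rich hotspots along the western
edge peaking at monazite-sand levels (up to ~2300 Bq/kg Th). The hotspot
amplitudes and the inland background reproduce the qualitative signature of
the survey area — kerma variability concentrated in a coastal strip — but
no attempt is made to mimic real geography or mineralogy, and the synthetic
coastal coefficient of variation (~130%) is sharper than the published
39–95% range. `simulate_survey_track()` drives a polyline at constant speed
(default 40 km/h, 30-s interval, hence ~333 m spacing), inverts the K_out
equation for the expected inside count at the local true kerma, and
Poisson-samples.

What passing tests on these synthetics do and do not show: they validate
the arithmetic, the unfolding, the error propagation and the geometry of
the mapping stage under Poisson counting noise and gain drift; they cannot
validate the transport model against real soil spectra (spectral shape
differences, radon progeny disequilibrium, soil moisture), the behaviour of
a real vehicle's shielding anisotropy, or the published survey-level dose
statistics, which depend on the unavailable 2053-record field dataset.

## Numerical choices and problem sizes

All randomness flows from explicit integer seeds (scene seeds, library
seeds, a single root seed in `run_pipeline()` from which stage seeds are
derived); no hidden global RNG state is left behind. Degenerate inputs are
handled explicitly: all-zero spectra return unchanged with a warning, flat
spectra raise a typed calibration-failure condition so a caller can fall
back to a previous calibration, empty regions are dropped with a warning,
negative clips are flagged. The test suite runs the Monte Carlo at reduced
history counts (5×10⁴; standard errors well below every asserted tolerance)
and the full end-to-end recovery at 20 random scenes, sizes chosen so the
whole suite completes in a few seconds while leaving every statistical
assertion comfortably powered; the acceptance script uses the 10⁶-history
default.

## Known limitations

- The response model is analytic (no escape peaks, summing, or angular
  response); the vehicle geometry is covered only empirically by the
  shielding factor.
- The scattered-flux spectrum shape is a parametric continuum, not a
  transport result; only its kerma integral is anchored.
- Secular equilibrium is assumed within both series; no radon-progeny
  atmospheric correction.
- The successive approximation's error model is a linear Poisson
  propagation, a surrogate for the survey's integral-kerma error formula.
- The exact historical bin edges and the internals of the original
  diagonal-elements-fitting code are not published; the implementations
  here are documented surrogates that honour the published anchors.
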