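---
title: "Internal dosimetry of [68Ga]PSMA-11: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal dosimetry of [68Ga]PSMA-11: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmadosim)
```

psmadosim implements a complete MIRD-schema internal-dosimetry analysis for
the prostate cancer PET tracer [68Ga]PSMA-11: organ retention from activity
samples, exponential biokinetic fitting, time-integrated activity
coefficients (TIACs), a table-driven S-value dose engine with ICRP 103/60
effective dose, a unit-density-sphere Monte Carlo for the lacrimal glands
and eye lenses, and a partial-volume recovery-coefficient calculator. This
vignette records the models, their assumptions, and the design choices that
were genuinely open.

## Retention and TIACs

An organ's retention is the fraction of injected activity it holds,

$$U(t) = \frac{C_{\mathrm{median}}(t)\, M}{A_0},$$

with $C_{\mathrm{median}}$ the activity concentration (Bq/mL, unit tissue
density), $M$ the reference organ mass in grams, and $A_0$ the administered
activity. Masses come from the adult male reference phantom *including blood
content* (kidneys 422 g, liver 2360 g); using phantom rather than individual
masses removes per-patient volumetry error at the cost of assuming that
activity concentration is roughly independent of organ size.
`scale_tiac_to_mass()` exposes the converse operation: under the
equal-concentration assumption a TIAC scales proportionally with mass (a
2360-g reference liver TIAC of 0.23 h corresponds to 0.10 h for a 1000-g
patient liver).

Retention curves are fitted by unweighted least squares on the linear scale
(Levenberg–Marquardt, `minpack.lm`) as mono- or bi-exponentials with
nonnegative amplitudes and rates; model order, when not forced, is chosen by
an F-test at $\alpha = 0.05$. The blood curve is fitted with its amplitudes
constrained to sum to 1, i.e. forced through 100% at time zero, matching the
convention used for pooled, normalised blood data. Each fitted model yields
the closed-form TIAC

$$\tilde a = \sum_i \frac{a_i}{\lambda_{\mathrm{bio},i} + \lambda_{\mathrm{phys}}},$$

with $\lambda_{\mathrm{phys}} = \ln 2 / 67.71\ \mathrm{min} = 0.010237\
\mathrm{min}^{-1}$ used unrounded everywhere; the rounded
$0.01\ \mathrm{min}^{-1}$ appears only in displays. Rounding
$\lambda_{\mathrm{phys}}$ would propagate a 2% error through every TIAC tail.

**Uptake phases.** Parenchymal organs start at zero retention and peak
within the first scans. A sum of decaying exponentials with nonnegative
amplitudes cannot represent that, so `fit_retention(washin = TRUE)` fits the
matched-pair form $c\,(e^{-\lambda_s t} - e^{-\lambda_f t})$. Internally this
is stored as amplitudes $+c$ and $-c$; the sign constraint is the single
admitted departure from the amplitudes-$\ge 0$ invariant, and the pair's
closed-form TIAC is still nonnegative. Without the uptake phase, conservation
at $t=0$ (all activity in blood) and sub-percent noiseless TIAC round trips
are unattainable.

**Direct integration.** For organs with no acceptable retention equation
(the salivary-gland path) the TIAC comes straight from the samples by the
trapezoid rule with $t(0)=U(0)=0$ prepended and a pure physical-decay tail
$U(n)/\lambda_{\mathrm{phys}}$ after the last sample. The integrand must be
the *physically decaying* retention: PET data are decay-corrected at
acquisition, so `tiac_trapezoid()` refuses decay-corrected input and
`decay_uncorrect()` converts by $e^{-\lambda_{\mathrm{phys}} t}$. Only with
this interpretation is the pure-decay tail exact.

**Bladder.** Cumulated activity in the bladder contents uses the cumulative
decay-corrected urine-plus-bladder inflow $F(t)$; the physically decaying
content is $(F(t)-F(v))\,e^{-\lambda t}$ with $v$ the last void, zeroed at
the ICRP voiding times 3.5 and 7 h, integrated trapezoidally on a 0.5-min
grid with an analytic pure-decay tail beyond the last void.

**Remainder.** Rather than fitting an exponential to remainder time points,
the remainder TIAC is computed by closed-form bookkeeping: total-body decays
under the voiding convention ($1/\lambda$ minus the decays forgone by voided
urine) minus all source-organ TIACs. This guarantees that all sources plus
remainder add up to the physical decay budget of $1/\lambda_{\mathrm{phys}}
= 1.628$ h exactly, which a separately fitted remainder cannot.

**Blood as a source region.** Venous samples are concentrations; converting
them to a whole-blood source fraction needs a total blood mass, which the
reference tables here fix at 5600 g (reference adult male). A 6.5-min fast
component is not identifiable from venous samples starting at 45 min, so the
synthetic schedule includes image-derived blood points at 2–30 min; with the
pooled/constrained convention the fit then recovers both half-lives.

## The dose engine

Organ doses follow the MIRD product
$D_T = \sum_S \tilde a_S \cdot 3.6\times10^9 \cdot S(T \leftarrow S)$,
with S-values assembled from specific absorbed fractions:
$S = \sum_i y_i E_i\, \mathrm{SAF}(T \leftarrow S; E_i)$. Users with access
to full phantom SAF compilations can load them as CSV; those tables are
licensed and not shipped. In their place `simplified_saf()` builds a
self-contained table:

* electron (positron) self-SAF $\varphi_e/m$, with $\varphi_e$ from the
  package's sphere Monte Carlo run on a sphere of the organ's mass;
* photon self-SAF $\varphi_\gamma/m$ from a deterministic
  single-interaction $\mu_{en}$ chord quadrature;
* photon cross-fire as a uniform whole-body bath (every target receives the
  total-body absorbed fraction per total-body mass);
* electron cross-fire zero, as explicit rows so lookups stay strict.

This is adequate for a positron emitter in non-walled organs: it reproduces
the published 0.24 mGy/MBq kidney median from the published TIACs within a
few percent. Its known blind spot is wall/content geometry — bladder-wall
dose from content requires a user-supplied content-to-wall S-value (modern
electron SAFs roughly halve older wall estimates; recorded here as
documentation, not computed).

Cohort summaries are medians and ranges of *per-patient* doses, not doses of
median TIACs.

## Effective dose

Effective dose is the tissue-weighted sum $E=\sum_T w_T H_T$ with radiation
weighting factor 1, under ICRP 103 (default) or ICRP 60 weights; both sets
sum to exactly 1. Only male-phantom doses enter (the study population is
male), so this is the "male component" of $E$. Organs absent from a dose
table — breast, brain, most remainder tissues — are filled with the median
of the listed *non-uptake* organs (excluding kidneys, liver, spleen,
salivary and lacrimal glands, bladder wall): unlisted tissues see mostly the
photon background, which the esophagus/stomach-level coefficients represent.

The ICRP 103 remainder is the arithmetic mean of its 13 member tissues. For
ICRP 60 the historical convention is ambiguous; the package defaults to the
arithmetic mean (the mass-weighted variant is available via
`remainder_rule = "mass_weighted"`). The arithmetic rule keeps the two
schemes' results within ~8% of each other on the bundled cohort medians,
consistent with both schemes reporting the same 0.022 mSv/MBq; mass
weighting lets the muscle term dominate and pulls the schemes ~14% apart.

## Sphere Monte Carlo

Small-organ self-dose (the 0.7-g lacrimal gland) and the gland-to-lens
cross-dose use a deliberately desk-scale Monte Carlo:

* decay sites uniform in the source sphere, isotropic emission;
* positron kinetic energies sampled from an allowed beta spectrum with
  endpoint 1.899 MeV including the positron Coulomb suppression of low
  energies (sampled mean 0.84 MeV, matching the tabulated mean);
* straight-track CSDA transport with water stopping power represented by a
  two-parameter range–energy power law fitted to tabulated CSDA ranges
  (0.2–2 MeV); the law reproduces the 3.5-mm mean positron range. Track
  lengths are capped at the nuclide's 9.2-mm maximum range, which makes
  "no electron dose beyond a 9.2-mm surface gap" hold exactly;
* annihilation photons emitted back-to-back at the positron endpoint
  (clamped to the source surface for escaping positrons — their
  annihilation photons then still see a full chord, a small conservative
  bias), the 1.077-MeV line at the decay site;
* photon deposition by a single-interaction $\mu_{en}$ model along the
  chord, with $\mu_{en}$ attenuation to the target for cross-dose (no
  scatter buildup; in water at 0.5 MeV buildup roughly cancels the
  difference between $\mu$ and $\mu_{en}$ over a few centimetres).

No multiple scattering and no condensed-history physics: the target
accuracy is the ~15% band of the sphere absorbed-fraction estimate, and at
that band the 0.7-g sphere yields $1.18\times10^{-10}$ Gy/decay
($\varphi_e \approx 0.68$), against the published $1.19\times10^{-10}$
(428 mGy/MBq·h). Photon self-absorption in sub-gram spheres is under 3% of
the total, so its crude treatment is immaterial. Energy is conserved per
history by construction and checked in the tests; identical seeds give
bit-identical tallies.

The lens geometry is two spheres in water: a 0.7-g gland and a 0.2-g lens
at 24-mm centre separation (the eyeball diameter; the true gland–lens
distance is not published, so the separation is configurable). The surface
gap (~15 mm) exceeds the maximum positron range, so the lens dose is pure
photon dose, ~96% of it from the 511-keV pair — matching the published
"95% from annihilation photons". The absolute lens factor depends on
anatomy the two-sphere model does not have; only its order of magnitude and
photon share are meaningful, and the package makes no attempt to reproduce
the published $5.37\times10^{-14}$ Gy/decay exactly. (That figure and its
printed conversion 0.192 mGy/MBq·h disagree in the fourth digit anyway;
`per_decay_to_per_mbq_h()` converts exactly.)

The lacrimal coefficient combines the two-gland TIAC (0.00053 h for the
cohort median; interpreted as the pair total) split equally over the glands
with the sphere dose rate: 0.00053/2 × 428 ≈ 0.11 mGy/MBq.

## Partial-volume recovery

A 0.7–1 g gland is far below PET resolution, so activity is read from the
hottest voxel and corrected for partial volume. For a unit sphere imaged
with an isotropic Gaussian PSF the central (maximum) value has the closed
form

$$RC = \operatorname{erf}\!\left(\tfrac{R}{\sqrt2\sigma}\right) -
\sqrt{\tfrac{2}{\pi}}\,\tfrac{R}{\sigma}\,e^{-R^2/2\sigma^2},$$

which `recovery_coefficient()` cross-checks against a brute-force 3D
convolution on a fine grid; the two must agree within 1% or the call errors
rather than returning a doubtful number. The effective PSF defaults to
8-mm FWHM: the reconstruction's 6.4-mm post-filter combined in quadrature
with a ~4.8-mm scanner intrinsic resolution. The post-filter alone cannot
produce a factor-2 loss for a 10-mm sphere; with the 8-mm effective PSF the
correction factor is 2.17, i.e. 2 at the nearest integer — the
NEMA-phantom-derived factor used for the glands.

## The synthetic cohort

Patient images are not public, so `generate_cohort()` produces six synthetic
patients with the statistical structure the analysis assumes: weights
uniform on 67–90 kg, 2 MBq/kg administrations, bi-exponential blood
clearance (91% at 6.5 min, 9% at 4.4 h), uptake-washout organ kinetics with
peaks at the reported uptakes (kidneys 7%, liver 15%, spleen 2%, salivary
glands 0.5%; lungs 1.5% and lacrimal glands 0.03% chosen to match the
observed TIAC magnitudes), cumulative urinary excretion 25% with a 60-min
half-time, multiplicative Gaussian noise (CV 2%) truncated at zero, and
mild lognormal inter-patient variation of peaks (CV 15%) and half-times
(CV 10%). Uptake/washout half-times are package choices, not published
values. Sampling follows the study schedule: scans at 0/10/20/30/90/180/255
min, blood at 2–245 min, voids hourly to 4 h.

What the generator does *not* emulate: image reconstruction and
partial-volume effects, VOI delineation error, count-rate-dependent noise,
tracer metabolites, or inter-organ correlation of kinetics. Passing
round-trip tests therefore validates the estimator chain, not the imaging
chain.

**Discretization note.** With noise off, fitted-path organs (kidneys,
liver, lungs, spleen, blood) round-trip to their true TIACs within 1%. The
trapezoid-path organs cannot: on the study schedule the non-decay-corrected
curve spans 60–75-min gaps, and the trapezoid error of an exponential over
a gap $h$ is $\sim(\lambda h)^2/12 \approx 3$–6% per segment at
$\lambda \approx 0.014\,\mathrm{min}^{-1}$. The tests assert <1% for the
fitted path and <6% for the trapezoid path; this is a property of the
published scan schedule, not of the implementation.

## Problem sizes and numerics

Default problem sizes are chosen so every result is reproducible on a
laptop core: $10^6$ histories for the headline sphere dose (MC relative
standard error ~0.06%), $2\times10^4$ histories per organ for the
simplified SAF electron terms (these enter doses at the percent level),
0.5-mm grids for the PVE cross-check, 0.5-min integration steps for the
bladder, and 200 replicates for the blood-recovery experiment. All Monte
Carlo entry points take a `seed` and restore the caller's RNG state.
Fit non-convergence raises a typed condition carrying diagnostics — there
is no silent fallback; degenerate inputs (constant data, zero inflow,
single-sample trapezoids) are handled by the closed-form limits shown in
the tests.

## Known limitations

* The simplified SAF engine has no wall/content electron geometry and no
  organ-specific photon cross-fire; bladder-wall and skeleton doses are the
  least trustworthy targets.
* Sphere-model electron transport is straight-track CSDA; absorbed
  fractions carry ~10–15% model error in the 0.1–1 g range.
* The lens factor is an order-of-magnitude estimate by design.
* Effective dose is the male component only.
* The bundled cohort tables are published values used as inputs; the raw
  images they derive from are not available for re-analysis.
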