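# psmadosim

Internal radiation dosimetry of the prostate cancer PET tracer
[⁶⁸Ga]PSMA-11, for medical physicists and nuclear-medicine researchers who
need organ absorbed-dose coefficients and effective dose from biokinetic
data — or a fully synthetic, seeded test bench for such a pipeline.

The package implements the MIRD schema end to end:

* **Retention**: U(t) = C_median(t)·M / A₀ converts organ activity
  concentrations to fractions of injected activity using reference-phantom
  masses (kidneys 422 g, liver 2360 g, both including blood content).
* **Biokinetics**: mono-/bi-exponential least-squares fits (order by
  F-test), a blood fit constrained through 100% at t = 0, an uptake-washout
  pair form for organs that start at zero, and direct trapezoid integration
  with a physical-decay tail for organs without an acceptable retention
  equation. TIACs follow the closed form ã = Σᵢ aᵢ/(λ_bio,i + λ_phys),
  with λ_phys = ln 2 / 67.71 min for ⁶⁸Ga.
* **Bladder and remainder**: ICRP 3.5/7-h voiding applied to the cumulative
  urine-plus-bladder curve; remainder-body TIAC by exact decay-budget
  bookkeeping.
* **Dose engine**: S(T←S) = Σᵢ yᵢEᵢ·SAF assembled from user-supplied SAF
  tables or the self-contained `simplified_saf()` (sphere-Monte-Carlo
  electron self-absorption, μ_en photon self-dose, whole-body photon bath);
  D_T = Σ_S ã_S·3.6×10⁹·S(T←S); effective dose under ICRP 103 or ICRP 60
  weights.
* **Small-organ Monte Carlo**: unit-density-sphere self-dose for the 0.7-g
  lacrimal glands (beta-spectrum sampling, straight-track CSDA positrons,
  single-interaction photon deposition) and the gland→eye-lens cross-dose.
* **Partial-volume correction**: closed-form and numerically cross-checked
  recovery coefficients for hot spheres under a Gaussian PSF.
* **Synthetic cohort**: a seeded six-patient generator (2 MBq/kg, 67–90 kg,
  blood 91%@6.5 min + 9%@4.4 h, organ peaks at the reported uptakes) with
  known ground-truth TIACs for end-to-end validation.

## Worked example

```r
library(psmadosim)

coh <- generate_cohort(cohort_spec(), seed = 42)
blood <- subset(
  fraction_injected_activity(coh$samples, reference_organ_masses(),
                             coh$truth$patients),
  organ == "blood" & patient_id == "S1")
fit <- fit_retention(blood[, c("time_min", "value")], n_components = 2,
                     constrain_unity = TRUE, organ = "blood")
tidy(fit)
#> # A tibble: 2 × 5
#>   term        organ amplitude rate_per_min half_life_min
#> 1 component_1 blood    0.910       0.105            6.62
#> 2 component_2 blood    0.0901      0.00265        261.
tiac_from_model(fit)
#> [1] 0.2483761
```

The fit recovers the generating blood clearance (91% at 6.5 min, 9% at
4.4 h = 264 min) from 2%-noise samples; its TIAC of 0.25 h says each
injected becquerel yields the equivalent of 0.25 hours of decays inside the
blood pool.

```r
effective_dose(psma11_dose_coefficients())
#>   scheme  effective_dose_mSv_per_MBq fill_mGy_per_MBq remainder_mGy_per_MBq
#> 1 ICRP103                     0.0199           0.0125                0.0326
```

Applying ICRP 103 tissue weights to the bundled cohort-median organ
coefficients gives 0.020 mSv/MBq — a 160-MBq scan is ~3.2 mSv.

```r
sph <- sphere_self_dose(sphere_spec(0.7), n_histories = 1e6, seed = 1)
sph
#> <af_result> dose/decay = 1.185e-10 Gy (426.7 mGy/MBq.h), AF(e) = 0.675, ...
lacrimal_dose_coefficient(0.00053, per_decay_to_per_mbq_h(sph$dose_per_decay_Gy))
#> [1] 0.1130821
recovery_coefficient(10, combine_fwhm(6.4, 4.8))
#>   sphere_diameter_mm psf_fwhm_mm    rc rc_numeric correction_factor
#> 1                 10           8 0.461      0.460              2.17
```

A 0.7-g lacrimal gland receives ≈427 mGy per MBq·h of cumulated activity;
with the cohort-median two-gland TIAC of 0.00053 h that is 0.11 mGy/MBq —
the second-highest organ dose after the kidneys. The last line is the
partial-volume arithmetic behind reading such a gland from its hottest
voxel: a 10-mm sphere under the 8-mm effective PSF recovers only 46% of its
true concentration, so the maximum-voxel value is multiplied by 2.

See `vignettes/psma11-dosimetry.Rmd` for the models, assumptions and design
decisions.

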