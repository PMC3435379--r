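# optrheo

Optical rheology of fibrous tissue: estimate birefringence from Jones-matrix
polarization-sensitive OCT (PS-OCT) volumes, extract elastic parameters from
uniaxial tensile records, and correlate the two across a cohort of scleral
samples.

Collagen-rich tissue such as the sclera is birefringent in proportion to how
densely and uniformly its fibers are organized, and the same organization
governs its stiffness. If birefringence — measurable *in vivo*, without
contact, by PS-OCT — tracks elasticity, it becomes a non-invasive window on
tissue biomechanics relevant to myopia and glaucoma. This package implements
the complete analysis needed to test that link, plus ground-truth synthetic
generators so every stage is validated by parameter recovery.

## The models

**Birefringence.** From cumulative round-trip Jones matrices $J(z)$:
phase-aligned moving average (3 × 3), local matrices
$J(z{+}\Delta z)J(z)^{-1}$ over an 8-pixel (49 µm) separation, total
retardance $R$ by Lu–Chipman polar decomposition of the corresponding Mueller
matrix, then

$$\Delta n = \frac{R\,\lambda_0}{4\pi\,\Delta z}, \qquad \lambda_0 = 1.31\ \mu m .$$

A Monte-Carlo mean-estimator table undoes the upward noise bias of the
nonnegative retardance estimate, and the volume mean keeps only pixels with
effective SNR > 10 dB and degree of optic axis uniformity (DOAU) > 0.9, where
DOAU is the norm of the kernel-averaged Stokes representation of the local
eigen-axes (1 = uniform, 0 = random).

**Mechanics.** Engineering stress–strain from the final loading ramp
(0.04 N pre-load, ten 0–6.5% preconditioning cycles, ramp to 18% at
1.8 mm/min), fitted over 0–6.5% strain with the exponential model

$$\sigma = \sigma_0 + a\,(e^{b\varepsilon} - 1),$$

giving tangent modulus $E_0 = ab$ at 0% strain, structural stiffness
$E_0 \times$ thickness (thickness = segmented cross-section area / 4 mm
width), and the power $b$ (the slope of tangent modulus against stress).

**Statistics.** Two-sided Pearson tests of mean birefringence against each
elastic parameter per region (four strips per eye, optic nerve head to
equator), with significance stars and regression lines.

## Worked example

Recover birefringence from a noisy homogeneous phantom, fit a simulated
tensile record, and run a full 19-sample cohort:

```r
library(optrheo)

## phantom -> gated volume-mean birefringence (truth 1.5e-3, 30 dB SNR)
vol <- simulate_jones_volume(phantom_spec(dims = c(64, 64, 4), dn = 1.5e-3,
                                          snr_db = 30, rng_seed = 1))
pv <- process_volume(vol, pipeline_config())
pv$mean_birefringence
#> [1] 0.00149654
pv$n_valid
#> [1] 14336

## tensile record -> elastic parameters (truth a = 0.02 MPa, b = 40)
rec <- simulate_stress_strain(0.02, 40, area_mm2 = 3.2, noise_frac = 0.01,
                              rng_seed = 1)
ss <- compute_stress_strain(rec)
fit_exponential(ss$strain, ss$stress_mpa,
                stress_datum = rec$pre_load_n / rec$area_mm2)
#> <elastic_params> a = 0.02015 MPa, b = 39.88, E0 = a*b = 0.8036 MPa, RMSE 0.00105 MPa (n = 109, strain 0-0.065)

## linked cohort -> region x parameter correlation table
out <- run_cohort(simulate_cohort(cohort_spec(rng_seed = 42)))
subset(out$results, region == "B", c(parameter, n, r, p, stars))
#>              parameter  n          r            p stars
#> 4    tangent_modulus_0 19  0.7362233 3.256825e-04   ***
#> 5 structural_stiffness 19  0.7812347 7.849937e-05   ***
#> 6              power_b 19 -0.6845088 1.225303e-03    **
```

The phantom mean lands within 0.2% of the designed 1.5 × 10⁻³ after SNR/DOAU
gating and bias correction; the fit recovers the constitutive parameters to a
few tenths of a percent; and the cohort stage recovers the latent
organization structure the generator planted (a strong positive
birefringence–stiffness correlation in region B, with the power negatively
correlated).

The numbered scripts under `analysis/` run these studies at full size —
phantom recovery, bias-correction benefit at 15 dB, mechanics recovery over
100 seeds, and the cohort correlation table — writing their tables under
`results/`.

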