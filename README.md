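# srrdmri

Super-resolution reconstruction (SRR) and noise analysis for diffusion MRI.

High-resolution diffusion MRI at strong diffusion weighting runs into the
**rectified noise floor**: magnitude images of complex Gaussian noise are
Rice distributed, so at low SNR the measured signal is biased upward and no
amount of magnitude averaging fixes it. SRR acquires *thick slices* (aspect
factor α = slice thickness / in-plane voxel size, hence α-fold more signal
per voxel at unchanged noise) in N_R stacks rotated about the phase-encode
axis, and recovers the isotropic image by solving a regularized linear
inverse problem. This package is for researchers designing or analyzing
such protocols: it implements the reconstruction and quantifies both the
**accuracy** gain (how much further the b-value range extends before the
noise floor bites) and the **precision** side (how noise propagates through
the reconstruction, and the SNR efficiency against direct sampling once
scan time and T1 relaxation are accounted for).

## The model

Each rotated stack samples the high-resolution plane x linearly,
y_k = A_k x + ε_k, with a box slice profile; N_R ≥ ⌈(π/2)·α⌉ rotations
suffice for isotropic recovery. The reconstruction is the closed form

    x̂ = ((1 − λ′) AᵀA + λ′·N_R·α·I)⁻¹ Aᵀ y = C y,   0 ≤ λ′ ≤ 1,

whose λ′-parameterization keeps the output intensity scale independent of
the regularization (λ′ = 1 is the volume-normalized blurred average;
λ′ → 0 the unregularized solution). Key derived quantities:

- expected magnitude M = √(S² + (σ√(π/2))²), noise floor σ√(π/2);
- SNFR = S̄(0)/(σ√(π/2)) and the 5%-bias threshold
  β_thr = log(SNFR·√(f²−1)), b_thr = β_thr/D;
- noise propagation κ = mean over voxels of √(Σ_j C(i,j)²);
- SNR efficiency ρ = (1/κ)·[(1−e^(−TR_SRR/T1))/(1−e^(−TR_D/T1))]·
  √(TR_D/(N_R·TR_SRR)), with TR_SRR = TR_D/α at minimum, and comparisons
  at matched effective resolution (regularization matched to a Gaussian
  kernel; the smoothed direct reference carries its kernel noise factor).

See the methods vignette (`vignettes/srr-methods.Rmd`) for the full
account, including discretization and matching details.

## Worked example

Reconstruct a simulated water-cylinder acquisition at α = 3 and read off
the accuracy and precision summaries:

```r
library(srrdmri)

g <- acquisition_geometry(3, 64, tr_seconds = 4.3)   # N_R = 5 rotations
samp <- build_joint_system(g)
phan <- cylinder_phantom(64)                          # S0 = 1, D = 2.2
sim <- simulate_lowres_acquisition(phan, g, b_values = seq(0, 3, 0.3),
                                   noise = rician_noise(0.014, seed = 1))

op <- build_recon_operator(samp, lambda_prime = 0.02)
recons <- reconstruct_series(op, sim$stacks)

roi <- phan$roi & samp$interior
mbar <- vapply(recons, function(x) mean(x[roi]), numeric(1))
fit <- fit_biased_monoexp(mbar, seq(0, 3, 0.3), aspect_factors = 1)
cat(sprintf("fitted D = %.3f um2/ms, sigma_eff = %.4f\n",
            fit$diffusivity, fit$sigma))
cat(sprintf("SNFR = %.0f, b_thr = %.2f ms/um2\n",
            snfr(mbar[1], fit$sigma),
            threshold_attenuation(snfr = snfr(mbar[1], fit$sigma),
                                  diffusivity = fit$diffusivity)$b_thr))
kap <- as.numeric(noise_propagation(op))
cat(sprintf("kappa = %.3f, rho(no T1) = %.2f\n", kap,
            snr_efficiency_analytic(kap, g$n_rotations, aspect_factor = 3)))
```

This prints (seed 1):

```
fitted D = 2.199 um2/ms, sigma_eff = 0.0043
SNFR = 183, b_thr = 1.85 ms/um2
kappa = 0.634, rho(no T1) = 1.22
```

Reading: the thick-slice acquisition at α = 3 lifts the SNFR to ~183 —
close to 3× the α = 1 value of ~60 under the same noise — which extends
the usable b-range to ~1.85 ms/μm² before the 5% bias threshold (vs ~1.3
at α = 1). Reconstruction noise is suppressed (κ = 0.63), and after scan
time accounting the SNR efficiency exceeds 1.

A command-line interface wraps the same functions
(`inst/cli/srr.R`; subcommands `simulate`, `reconstruct`, `accuracy`,
`efficiency`, `match-reg`, `dotfraction`), writing NIfTI volumes with JSON
geometry sidecars and CSV tables, plus the resolved configuration of every
run.

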