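# noddisim

Simulation and fitting of the NODDI tissue model over multi-shell
diffusion MRI acquisition schemes.

Hybrid diffusion imaging (HYDI) acquires diffusion MRI on several q-space
shells at once — here five shells at b = 375–9375 s/mm², 126 measurements
in total — so that one dataset feeds DTI, q-space and multi-compartment
analyses. NODDI (neurite orientation dispersion and density imaging) was
published with its own two-shell protocol. `noddisim` answers, by
simulation, whether the two acquisitions yield interchangeable NODDI
estimates: it synthesizes signals from known tissue states on any scheme,
injects Rician noise at a b0-referenced SNR, fits the model, and compares
schemes statistically. It is aimed at diffusion-MRI researchers designing
or validating acquisition protocols.

## The model

The normalized signal for a measurement (b, **g**) is the three-compartment
mixture

    E = (1 − f_iso) [ f_ic · E_ic + (1 − f_ic) · E_ec ] + f_iso · exp(−b d_iso)

with Watson-dispersed intracellular sticks
E_ic = ∫ W(**n**; **μ**, κ) exp(−b d∥ (**g**·**n**)²) d**n**,
a hindered extracellular tensor with tortuosity d⊥ = d∥ (1 − f_ic)
averaged over the same Watson distribution, and isotropic free water.
Dispersion is reported as ODI = (2/π) arctan(1/κ). Fixed diffusivities:
d∥ = 1.7×10⁻³, d_iso = 3.0×10⁻³ mm²/s. The Watson-stick integral is
evaluated by a Funk–Hecke Legendre series and verified in the test suite
against an independent brute-force spherical quadrature
(`quadrature_signal_oracle()`) to 1e-6.

## Worked example

```r
library(noddisim)

# a white-matter-like tissue state and the two rival schemes
tissue <- tissue_params(f_ic = 0.7, kappa = 4, f_iso = 0,
                        mu = c(0, 0, 1))
hydi  <- build_protocol("p12345")
noddi <- build_protocol("NODDI-p14")

# noise-free synthesis and fit on the HYDI scheme
sig <- synthesize_signal(hydi, tissue)
fit <- fit_noddi(sig)
tidy(fit)
#> # A tibble: 7 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 icvf   7.00e- 1
#> 2 kappa  4.00e+ 0
#> 3 odi    1.56e- 1
#> 4 fiso   1.41e-10
#> 5 mu_x   2.18e-10
#> 6 mu_y  -1.35e-10
#> 7 mu_z   1   e+ 0
```

The noise-free fit returns the ground truth: ICVF 0.700, κ 4.00
(ODI 0.156), FISO ≈ 0, fiber direction along +z. With noise:

```r
noisy <- add_rician_noise(sig, snr_b0 = 20, seed = 1)
fit20 <- fit_noddi(noisy, fit_options(objective = "rician-likelihood",
                                      snr_b0 = 20))
round(tidy(fit20)$estimate[c(1, 3, 4)], 3)   # icvf, odi, fiso
#> [1] 0.730 0.179 0.009

# effective SNR per shell at SNR_b0 = 20: the outermost shell of the
# full HYDI scheme sits near the noise floor
shell_snr_report(hydi, snr_b0 = 20, orientations = 50)
#> # A tibble: 6 × 5
#>   shell     b n_dir snr_mean snr_sd
#>   <int> <dbl> <int>    <dbl>  <dbl>
#> 1     0     0     1    20      0
#> 2     1   375     6    14.4    1.62
#> 3     2  1500    21     6.83   2.81
#> 4     3  3375    24     3.73   2.42
#> 5     4  6000    24     2.66   1.95
#> 6     5  9375    50     2.11   1.64
```

A scaled-down scheme comparison (the `"desk"` preset: ICVF {0.5, 0.8} ×
κ {1, 4}, 50 orientations, 5 trials) runs the whole pipeline and applies
a paired t-test per metric and SNR:

```r
cfg <- experiment_config(preset = "desk",
                         fit = fit_options(objective = "rician-likelihood",
                                           snr_b0 = 20))
res <- run_experiment(cfg)                      # ~4000 fits, a few minutes
compare_schemes(res, "NODDI-p14", "p12345", metric = "icvf_est", snr = 20)
plot_recovery_summary(res, snr = 20)
```

`load_roi_reference()` ships a 48-region white-matter reference table
(means ± sd of eight diffusion metrics across 52 healthy adults) that
motivates the "realistic" corner of the simulation grid — e.g.
`load_roi_reference("GCC")$icvf_mean` is 0.722.

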