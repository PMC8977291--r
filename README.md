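# dlmrc

Compressed-sensing reconstruction and diagnostic statistics for dark-lumen
MR colonography, exercised entirely on synthetic data.

Dark-lumen MR colonography renders the water-filled colon lumen dark
against an enhancing bowel wall. Faster scans mean undersampled k-space;
`dlmrc` reconstructs such data by **split Bregman iteration with a
patch-based, graph-Laplacian-regularized dictionary-learning prior**, and
evaluates the result the way a quantitative reading would: PSNR
benchmarking against total-variation and zero-filling baselines, ADC
fitting from diffusion-weighted series, enhancement metrics from
time–intensity curves, and two-group ROC/accuracy statistics.

The reconstruction alternates, per outer Bregman iteration k:

    u^{k+1} = argmin_u min_{D,Γ}  Σ_i ‖α_i‖₁ + (λ/2)Σ_i ‖Dα_i − R_i u‖²
              + μ_g Tr(ΓLΓᵀ) + (μ/2)‖F_p u − f^k‖²
    f^{k+1} = f^k + f − F_p u^{k+1}        (add back the residual)

with R_i the 8×8 patch extractors, D a 4× overcomplete unit-norm
dictionary, Γ the sparse codes, L the Laplacian of a patch-similarity
graph, and F_p the mask-restricted orthonormal DFT. Sub-steps: OMP +
projected-gradient dictionary learning, an augmented-Lagrangian ℓ₁ coder
(FISTA + ridge-shrunk residual split + multiplier update), a closed-form
k-space image update, and the Bregman data feedback. See the methods
vignette (`vignettes/dark-lumen-reconstruction.Rmd`) for model,
assumptions and parameter rationale.

## Worked example

```r
library(dlmrc)

# a 64x64 bowel-wall phantom with one +60 lesion, 2.5x undersampled
ph <- make_phantom(64, 64,
                   lesions = list(list(center = c(32, 20), radii = 4,
                                       contrast = 60)), seed = 1)
mk  <- make_random2d_mask(c(64, 64), factor = 2.5, seed = 1)
ks  <- simulate_kspace(ph)
ksm <- ks$values * mk$mask

zf <- pmin(pmax(zero_fill_baseline(ksm, mk), 0), 255)
r  <- reconstruct(ksm, mk, recon_config(n_outer = 4, dict_iters = 2,
                                        n_inner = 5, graph_max_nodes = 500))
cat(sprintf("zero-fill %.2f dB, dictionary %.2f dB\n",
            psnr(ph$image, zf), psnr(ph$image, r$image)))
#> zero-fill 31.75 dB, dictionary 33.28 dB

# downstream diagnostics on a simulated 98-patient cohort
tab <- simulate_cohort(cohort_spec(seed = 1))
cohort_report(tab, adc_threshold = 1.25)
#> Cohort diagnostic report
#>      group  n  adc_mean    adc_sd   adc_min  adc_max n_correct n_error accuracy_pct
#>  algorithm 49 1.5762001 0.2580013 0.8634430 2.044537        45       4           91
#>    control 49 0.9441298 0.1344625 0.6673058 1.256226        44       5           89
#> t = 15.208, df = 96, p = 2.61e-27
#> ROC: AUC = 0.9704; Youden threshold 1.2736 (sens 91.8%, spec 100.0%)
#>   at threshold 1.2500: sens 91.8%, spec 98.0%
```

(The PSNR line is what this light 4-iteration configuration prints on the
64×64 example — the dictionary reconstruction recovers ~1.5 dB over
zero-filling here, and 5–6 dB at the full default settings on 128×128
phantoms. The cohort numbers are one seeded draw from the stated
two-group design — ADC 1.55 ± 0.31 vs 0.92 ± 0.14 × 10⁻³ mm²/s,
n = 49/49; per-draw accuracies fluctuate around the design values
46/49 → 93% and 41/49 → 83%.)

## Command line

```sh
Rscript -e 'dlmrc::cli_main()' simulate --height 64 --width 64 --seed 1 \
    --out phantom.png --kspace-out kspace.json --cohort-out cohort.csv
Rscript -e 'dlmrc::cli_main()' mask --trajectory random2d --factor 2.5 \
    --height 64 --width 64 --out mask.json
Rscript -e 'dlmrc::cli_main()' reconstruct --input kspace.json --mask mask.json \
    --n-outer 3 --out recon.png
Rscript -e 'dlmrc::cli_main()' evaluate --factors 2.5,4 --out benchmark.csv
Rscript -e 'dlmrc::cli_main()' diagnose --cohort cohort.csv --out report.csv
```

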