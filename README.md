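# rlre — weighted low-rank matrix restoration for MR image denoising

`rlre` is an R package for denoising grayscale magnetic-resonance images by
robust low-rank decomposition, together with the image-quality metrics and
diagnostic-accuracy statistics needed to evaluate such a denoiser in a
clinical-imaging study (e.g. comparing MRI sequences for discriminating
prostate cancer from benign hyperplasia against pathology).

## The model

An observed image matrix `D` (pixels on the 0–255 scale) is decomposed as

```
D = H + S + E
```

where `H` is the low-rank anatomical background, `S` is sparse impulsive
corruption and `E` is dense Gaussian noise, by solving

```
min_{H,S,E}  Σ_j w_H,j σ_j(H)  +  λ1 ‖W_S ∘ S‖_1  +  λ2 ‖E‖_F²
subject to   H + S + E = D
```

with inverse-magnitude weights `w = c/(σ + ε)`: large singular values and
large sparse entries are penalised less, so genuine structure survives the
shrinkage. The problem is solved by an inexact augmented-Lagrangian scheme
alternating three closed-form proximal steps — weighted singular-value
thresholding for `H`, weighted entrywise soft-thresholding for `S`, a linear
shrinkage for `E` — with one-step reweighting. The restored image is `H`.
Setting all weights to 1 and dropping `E` recovers the classical robust-PCA
baseline (`solve_rl()`), kept as a comparator.

The Gaussian penalty is noise-adaptive by default, `λ2 = 0.5/(n·σ_n²)` on
the unit intensity scale, with `σ_n` estimated by a Marchenko–Pastur median
rule when not supplied. See the methods vignette
(`vignettes/rlre-methods.Rmd`) for the full calibration story.

Also included:

* **Metrics** — global PSNR (peak 255) and SSIM (whole-image statistics,
  both the simplified closed form and the stabilised three-component form).
* **Phantoms** — seeded synthetic images with exact ground-truth triples
  `(H*, S*, E*)`, plus a factorial benchmark harness over noise levels,
  seeds and algorithms.
* **Diagnostics** — sensitivity, specificity, accuracy, Cohen's kappa and
  Pearson χ² comparisons for 2×2 contingency tables; the three
  MRI-sequence tables used in the motivating study ship as a CSV fixture.
* **CLI** — `denoise`, `phantom`, `benchmark`, `dxstats` subcommands
  (`inst/cli/rlre`), reading/writing plain-text PGM (and PNG when the
  optional `png` package is present).

## Worked example

```r
library(rlre)

ph  <- make_phantom(phantom_spec(rows = 64, cols = 64, rank = 3,
                                 sparse_fraction = 0.05, sparse_amplitude = 50,
                                 noise_sigma = 15, seed = 1))
fit <- solve_rlre(ph$degraded)
fit
#> <decomposition_result> 64 x 64, 30 iterations, converged
#>   residual 7.721e-08 | rank(H)~10 | nnz(S) 44 | ||E||_F 949.3

psnr(ph$clean, ph$degraded)                      # 22.51 dB  (input)
psnr(ph$clean, fit$H)                            # 30.50 dB  (restored)
ssim(ph$clean, fit$H, mode = "stabilized")       # 0.9505
psnr(ph$clean, solve_rl(ph$degraded)$H)          # 27.91 dB  (unweighted baseline)
```

The weighted solver recovers the clean background to within ~30.5 dB from a
22.5 dB degraded input at noise σ = 15, about 2.6 dB ahead of the
unweighted baseline; the gap holds across σ = 5…25 (see the benchmark
tests).

Diagnostic statistics from the shipped contingency tables:

```r
accuracy_summary(mri_sequence_tables()$DCE)
#> <accuracy_summary> [DCE]  n = 150
#>   sensitivity 97.08%  specificity 92.31%  accuracy 96.67%
#>   kappa 0.8094 (good consistency)
```

Note: `diagnostic_discrepancies()` documents that the kappa values printed
in the source report (0.469/0.547/0.678) are not reproducible from its own
printed tables; the package reports the formula-true values.

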