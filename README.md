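# boxnoise

Localization noise — imprecise bounding-box boundaries, as opposed to wrong
class labels or missing objects — is the dominant annotation defect in
self-collected biological image datasets such as plant-disease collections,
where neither the domain expert nor the image annotator can afford to draw
pixel-perfect boxes. `boxnoise` is an R toolkit for people who curate or
consume such label sets: it measures how noisy an annotation set is,
synthesizes realistic noise at a chosen level, simulates the iterative
teacher–student correction loop used to clean such labels, curates
pseudo-labels, and scores detections.

## The model

Match each clean box to the same-category noisy box with the largest IoU,
and define for each of the four boundaries the signed absolute error
Δ = clean − noisy and its scale S (clean box width for the left/right
boundaries, height for top/bottom). Real-world boundary noise is
size-proportional and Gaussian:

- Δ ∼ N(0, (γ·S)²), independently per boundary,

where the scalar noise level is the root-mean-square relative error

- γ = sqrt( (1/n) Σᵢ (Δᵢ/Sᵢ)² ),   σ = sqrt( (1/n) Σᵢ Δᵢ² ),

and the local standard deviation of Δ grows linearly in box size with slope
≈ γ (the through-origin fit of the size-binned σ curve). Measured label sets
of this kind sit around γ ≈ 0.15.

Annotation correction merges a corrector's proposal B\* with the current
(noisy) box B as a convex combination,

- B_correct = λ·B\* + (1 − λ)·B,

iterated N times (teacher proposes, merged labels train the next teacher).
With a corrector whose proposals carry noise ρ·γ₀, the relative-error
variance follows v_{k+1} = λ²(ργ₀)² + (1 − λ)²·v_k and plateaus at
γ∞ = λργ₀ / sqrt(1 − (1 − λ)²), which is why a small iteration count
(default 3) suffices.

Detections are scored with IoU (intersection area / union area) and
11-point interpolated average precision at IoU ≥ 0.5 (mAP@50); pseudo-labels
are curated by a score cutoff (0.5), IoU-0.3 overlap resolution
(cross-category: higher confidence wins; same category: larger box wins) and
control-class stripping (background / unknown / healthy).

## Worked example

```r
library(boxnoise)

truth <- generateAnnotations(1700, size_range = c(32, 480), seed = 11)
noisy <- synthesizeNoise(truth, gamma = 0.15, seed = 12, clip = FALSE)
noiseReport(truth, noisy)
#> NoiseReport
#>   pairs: 5227 matched, 0 clean box(es) unmatched
#>   gamma (RMS relative error): 0.1500
#>   gamma per boundary: left=0.1513 top=0.1496 right=0.1501 bottom=0.1489
#>   sigma (RMS absolute error): 31.33 px
#>   sigma-size slope: 0.1541 over 8 size bin(s)
```

The report recovers the synthesis level: γ̂ = 0.1500 against the requested
0.15, per-boundary estimates agree within sampling error, and the σ-vs-size
slope (0.154) reproduces γ as the proportionality law predicts.

Simulating the correction loop with an oracle corrector of fidelity ρ = 0.5
(its proposals carry half the original noise) and λ = 0.5:

```r
corr <- makeOracleCorrector(truth, rho = 0.5, gamma0 = 0.15, seed = 5)
res <- runIterations(noisy, corr, n_iter = 5, lam = 0.5, reference = truth)
res$trace$gamma
#> [1] 0.14997 0.08364 0.05660 0.04701 0.04456 0.04359
gammaRecursion(0.15, 0.5, 0.5, 5)$gamma
#> [1] 0.15000 0.08385 0.05625 0.04688 0.04422 0.04353
```

γ falls from 0.150 to 0.044 across five iterations and flattens at the
closed-form fixed point (λργ₀/√(1−(1−λ)²) ≈ 0.0433) — most of the gain
arrives by iteration 3.

A shell entry point wiring all components (`generate`, `synthesize`,
`analyze`, `correct`, `simulate`, `postprocess`, `evaluate`) ships as
`inst/scripts/boxnoise`; every run writes a JSON manifest with its
parameters and input checksums.

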