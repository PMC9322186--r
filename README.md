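# hcwssc

Unsupervised land-cover and crop mapping from hyperspectral images with a
**hybrid changing-weight spectral similarity clustering** (HCW-SSC)
classifier: K-means whose assignment distance mixes two spectral
dissimilarity measures, chosen and weighted by a filter feature selection
run on the image itself.

## The method

A hyperspectral image assigns every pixel a reflectance spectrum over tens
of narrow bands. Different dissimilarity measures between two spectra
*X₁*, *X₂* see different physics:

| id  | measure | formula | sensitive to |
|-----|---------|---------|--------------|
| ED  | Euclidean distance | ‖X₁ − X₂‖₂ | brightness (magnitude) |
| SAC | spectral angle cosine | 1 − cos θ(X₁, X₂) | curve shape, scale-invariant |
| SCC | spectral correlation | 1 − r(X₁, X₂) | shape, affine-invariant |
| SID | spectral information divergence | KL(p‖q) + KL(q‖p), p = X₁/ΣX₁ | band-probability profile |

All four follow the same convention: 0 for identical spectra, larger is
less similar.

The classifier works in four steps:

1. **Feature extraction.** For each measure, a per-pixel *feature map*:
   the dissimilarity between the pixel and the scene mean spectrum μ.
2. **Filter selection.** The 4 × 4 Pearson correlation matrix ρ between
   the maps is computed; the pair with the minimum |ρ| carries the least
   duplicated information and is kept.
3. **Changing weights.** Each kept measure S is scored by its coefficient
   of variation CV_S = σ(S)/μ(S). The shares CVₛ₁/(CVₛ₁+CVₛ₂) (which sum
   to 1) are divided by the feature-map means μ̄_S to remove each
   measure's unit, giving the operative weights w₁, w₂.
4. **Hybrid K-means.** Pixels are assigned by
   argminⱼ [w₁·measure₁(Xᵢ, μʲ) + w₂·measure₂(Xᵢ, μʲ)] with the cluster
   centroids μʲ as references, iterating assignment and centroid means
   until fewer than a threshold fraction of pixels change label.

Accuracy is assessed after an optimal one-to-one cluster→class mapping via
overall accuracy, Cohen's kappa and per-class precision/recall/F1. Single
measure and unweighted-hybrid kernels are available as baselines, an elbow
curve (distortion/inertia vs K) suggests the cluster count, and a
triplet-library protocol (two same-class spectra plus one odd spectrum,
K = 2) benchmarks kernels on spectral libraries.

## Worked example

```r
library(hcwssc)

scene <- make_scene(rows = 64, cols = 64, n_bands = 30, n_classes = 5,
                    brightness_noise_sd = 0.15, additive_noise_sd = 0.01,
                    seed = 5)
res <- hcw_ssc(scene$cube, k = 5, seed = 5, n_init = 3, max_iter = 50)
res$selection
#> <measure_selection>
#>   pair: ED + SCC  (|rho| = 0.2321)
#>   norm weights: 0.3606, 0.6394
#>   kernel weights: 0.2137, 0.9133
glance(evaluate_classification(res$fit, scene$truth))
#> # A tibble: 1 × 5
#>   overall_accuracy kappa macro_f1 n_pixels n_classes
#>              <dbl> <dbl>    <dbl>    <int>     <int>
#> 1            0.999 0.999    0.999     4096         5
```

The selection picked the brightness measure (ED) and a shape measure (SCC)
as the least-correlated pair; the CV shares say SCC carries about twice
ED's share of discriminative variation, and after dividing by the map
means the shape term dominates the kernel (ED's raw distances are
numerically much larger, so its weight must be small for balance). The
weighted fit recovers the five planted classes almost perfectly.

The same pipeline runs from the shell:

```sh
exec/hcwssc simulate --out scene.dat --truth truth.dat --seed 5
exec/hcwssc hcwssc --input scene.dat --truth truth.dat -k 5 \
    --report report.json --seed 5
```

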