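---
title: "Hybrid changing-weight spectral similarity clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid changing-weight spectral similarity clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcwssc)
```

## The problem

Unsupervised classification of a hyperspectral image (HSI) asks a
clustering algorithm to partition pixels into land-cover or crop classes
using only their reflectance spectra. The choice of the dissimilarity
inside the clusterer decides what "different" means physically: Euclidean
distance (ED) between band vectors responds to brightness, which within a
crop varies with illumination, canopy density and viewing geometry; the
spectral angle (SAC), correlation (SCC) and information divergence (SID)
respond to the shape of the spectral curve, which tracks the material
itself. No single measure is best for every scene, and a naive sum of two
measures is dominated by whichever has the larger numeric scale — ED
distances on reflectance cubes are often hundreds of times larger than an
angle in `[0, 2]`.

The classifier implemented here addresses both problems with a filter
feature selection run on the image itself before clustering: pick the two
measures that duplicate the least information on *this* scene, and weight
them so that each contributes in proportion to how discriminative it is,
on a common dimensionless scale.

## The model

**Feature extraction.** For measure $m$ the feature map is
$F_m(i) = m(X_i, \mu)$, the dissimilarity of pixel $X_i$ to the scene mean
spectrum $\mu$ (band-wise mean over valid pixels). All four measures obey
the same convention — 0 for identical spectra, larger is less similar —
so each map is a scalar image summarising one physical axis of variation.

**Pair selection.** The four maps are correlated pairwise (Pearson, pixels
paired positionally) and the unordered pair with the minimum $|\rho|$ is
kept. Two nearly uncorrelated features carry close to independent
information; two highly correlated ones would just double-count.

**Changing weights.** Each selected measure $S$ is scored by its
coefficient of variation $CV_S = \sigma(F_S)/\operatorname{mean}(F_S)$
(population standard deviation by default — the pixels of a scene are the
complete population of interest, not a sample; the convention is an
argument). The shares

$$\tilde w_k = \frac{CV_{S_k}}{CV_{S_1} + CV_{S_2}}, \qquad
\tilde w_1 + \tilde w_2 = 1$$

express relative discriminability, and dividing each share by its
feature-map mean removes the measure's unit:

$$w_k = \tilde w_k \,/\, \operatorname{mean}(F_{S_k}).$$

Both weight sets are reported: the sum-to-one shares (`norm_weights`) for
interpretation, the dimensionless $w_k$ as the operative kernel weights.
These two published forms conflict if read as one formula — shares sum to
one, operative weights do not — and the package resolves this by treating
the mean division as the final, unit-removing step that the clustering
kernel consumes, while keeping the shares for reporting.

**Hybrid K-means.** Assignment generalises classical K-means to

$$c_i = \arg\min_j \; w_1\, S_1(X_i, \mu^j) + w_2\, S_2(X_i, \mu^j),$$

with the cluster centroid $\mu^j$ (band-wise member mean) as the
per-cluster reference spectrum. The published notation wraps this scalar
in a squared norm; since weights and measures are non-negative, squaring
a non-negative scalar cannot change the argmin, so the scalar itself is
used. Iteration alternates assignment and centroid means and stops when
the fraction of pixels changing label falls below `change_threshold`
(0 = run to exact label stability), or at `max_iter`.

Two points are deliberate:

* **Objective descent is only guaranteed for single-ED.** The centroid
  mean minimises summed squared Euclidean distance, so classical K-means
  descends; for angle/correlation/divergence kernels the mean update is a
  heuristic and the objective trace is recorded but not asserted. The
  tests assert monotone descent for single-ED only. Convergence is
  enforced by the change threshold and the iteration cap, matching how
  such kernels are used in practice.
* **Empty clusters are re-seeded deterministically** to the pixel most
  dissimilar (under the kernel) to the cluster's previous centroid. This
  keeps K constant and, usefully, acts as a repair mechanism: on a
  well-separated scene an initialisation that drew two centroids from one
  class empties a cluster in the next sweep and the re-seed lands in the
  missed class.

**Degenerate inputs.** An all-zero spectrum has no angle or probability
profile (SAC/SID) and a band-constant spectrum has no correlation (SCC).
In scalar calls these are errors. Inside vectorised map/assignment
computation such entries are replaced by the largest finite value
observed, with a warning — a degenerate pixel should sort as "maximally
dissimilar", never win an argmin through NaN ordering. SID adds
$\varepsilon = 10^{-12}$ to the normalised probabilities before the
logarithms so zero bands stay finite; the logarithm base is natural by
default and configurable (`log_base = 2` gives bits), since either
convention appears in the literature and only the scale, not any
comparison, changes.

## Evaluation

Cluster labels are arbitrary, so evaluation first finds the one-to-one
cluster-to-class assignment maximising matched pixels — an exact optimum
computed by a bitmask dynamic program over classes, with surplus clusters
(K greater than the number of classes) falling back to their majority
class. The confusion matrix follows the predicted-rows / true-columns
convention. Overall accuracy is trace over total; Cohen's kappa uses the
marginal-product chance agreement
$p_e = \sum_c \mathrm{rowSum}_c \,\mathrm{colSum}_c / N^2$, which reduces
exactly to the familiar binary TP/TN/FP/FN expression at two classes (a
tested identity) and generalises it beyond; precision, recall and F1 are
one-vs-rest per class with macro averaging, and an undefined ratio (empty
row or column) is reported as `NA` with F1 = 0 by convention.

## What the synthetic generators emulate

Real benchmark scenes for this kind of classifier are airborne or
satellite HSI with field-surveyed truth, preprocessed in commercial
software. The generators reproduce the *structure* those experiments rely
on, at desk scale:

* `make_endmembers()` draws smooth positive spectra (baseline + 2–4
  Gaussian bumps on a 400–1000 nm axis, the VNIR window of typical
  airborne imagers) and rejection-samples until all pairwise spectral
  angles exceed `class_separation` (default 0.25 rad), so between-class
  shape differences are guaranteed, not hoped for.
* `make_scene()` plants the endmembers in a deterministic layout (default
  64 × 64 × 30, 5 classes, vertical blocks) and adds two *independent*
  noise processes: multiplicative lognormal brightness noise (default sd
  0.15), which moves ED while leaving shape measures untouched, and
  additive Gaussian noise (default sd 0.01 reflectance), which perturbs
  shape too. This separation is what makes the weighted-versus-unweighted
  comparison meaningful: a brightness-noise-dominated scene renders ED
  uninformative by construction.
* `make_triplets()` builds the spectral-library benchmark: 80 groups of
  two same-class spectra (default: brightness-scaled by U(0.7, 1.3),
  shape preserved exactly) plus one other-class spectrum.

What they do **not** emulate: mixed pixels and abundance gradients, sensor
artefacts (smile/frown, striping), atmospheric residuals, spatially
correlated noise, class boundaries that follow terrain. Passing the
synthetic suites therefore demonstrates the algorithmic claims — correct
measures, correct selection arithmetic, recovery when classes are
separable, the benefit of CV weighting under brightness noise, linear
scaling — not field-scale accuracy on real imagery.

## Protocol and problem sizes used by the tests

The test-suite and acceptance-script sizes are the package's own
protocol choices: planted-recovery runs use the generator's default
64 × 64 × 30 scene with `n_init = 3` restarts; the weighted-versus-
unweighted comparison uses 20 seeded 48 × 48 scenes at brightness sd 0.5
(heavy, deliberately ED-hostile) and counts wins; runtime scaling times
the full pipeline on sides 32–256 with the minimum of repeated runs to
damp timer noise, and checks the log–log slope against the linear-time
expectation (each stage visits every pixel a bounded number of times per
sweep).

The triplet protocol deserves a note: with three spectra and K = 2 there
are only three distinct centroid initialisations, and a single random
draw fails about a third of groups *whatever the kernel*, because drawing
both centroids from the same-class pair can trap the two-iteration fit.
The benchmark is meant to score kernels, not draws, so the acceptance
protocol evaluates each group with `n_init = 3` — exhaustive over
initialisations, best kernel objective kept — while
`classify_triplet()`'s own default stays single-run to match the
classical protocol (K = 2, 2 iterations, 2% change threshold).

## Numerical choices and tie-breaks

* Pair-selection ties (equal $|\rho|$): lexicographic in the canonical
  measure order ED < SAC < SCC < SID.
* Argmin ties in assignment: lowest cluster index.
* Best-of-restarts ties: lowest restart seed.
* The elbow suggestion maximises the second difference of inertia and is
  advisory; `elbow()` uses `n_init = 5` so the inertia curve is monotone.
* SCC is computed as centred cosine (algebraically identical to
  1 − Pearson r) in the vectorised path; the scalar and matrix routes
  agree to 1e−10 in tests.
* Vectorised ED uses the expanded quadratic form with clipping at zero,
  so identical spectra can leave residues of order 1e−8 in the distance
  (1e−16 in its square); tests and downstream logic use tolerances, never
  exact-zero comparisons, on that path.

## Known limitations

* Hybrid-kernel K-means has no convergence guarantee beyond the iteration
  cap; pathological oscillation is possible and is surfaced by
  `converged = FALSE` with the full change-fraction trace.
* The CV weighting assumes feature-map means are positive and meaningful
  scales; a map with mean zero (possible only on degenerate scenes) is
  excluded from selection rather than weighted.
* The optimal cluster-to-class mapping is exact only up to 25 classes
  (bitmask width); beyond that the evaluation errors rather than silently
  approximating.
* TIFF I/O carries no wavelength or georeference metadata; the ENVI
  format is the lossless route and carries `map info` strings through
  untouched.
* Runtime is linear in pixels but the constant is R's: scenes up to a few
  hundred thousand pixels are comfortable, full satellite tiles are not
  the target.
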