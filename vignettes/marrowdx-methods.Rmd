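---
title: "Contextual leukocyte analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual leukocyte analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

marrowdx implements a contextual analysis chain for stained bone-marrow
smear images: colour and texture modelling, Markov-random-field (MRF)
segmentation of leukocyte nuclei and whole cells, rule-based cell
identification, separation of overlapped cells, a 67-descriptor feature
panel, supervised classification of acute-leukemia families (ALL/AML) and
FAB subtypes (L1, L2, M2, M3, M5), and per-patient majority-vote diagnosis.
This vignette records the models, their assumptions, and the design
decisions taken where the method leaves details open.

## Colour model

Wright staining gives leukocyte nuclei dark purple tones and erythrocytes
orange/rose tones. In CIE L\*a\*b\* this concentrates the useful contrast in
two planes: L\* (nuclei are the darkest structures) and b\* (purple/blue
chroma is negative, orange/rose positive). `rgb_to_lab()` applies the
textbook sRGB → XYZ (D65 white point) → L\*a\*b\* transform; commonly cited
reference formulas leave the white point open, so D65 with sRGB primaries
is assumed. The inverse `lab_to_rgb()` exists mainly so the synthetic renderer
can compose scenes directly in Lab, where the stain's orderings can be
imposed by construction.

`cluster_channel()` groups a channel's scalar intensities with k-means
(k = 2 on L\* for the nucleus model, k = 3 on b\* for the whole-cell model;
both are `color.k_L` / `color.k_b` config keys). Because the observations
are one-dimensional, the k-means optimum consists of contiguous intervals
in sorted order; the solver therefore computes the **exact** global optimum
by a weighted dynamic program over the intensity histogram (up to 1024
bins) followed by deterministic Lloyd refinement on the full data. Random
restarts were considered and rejected: on realistic smear L\* histograms —
a dominant bright background mode, a mid cytoplasm/erythrocyte shelf and a
small dark nucleus mode — restart-based k-means reproducibly settles in a
local optimum that merges nuclei with cytoplasm, which is fatal for the
downstream foreground statistics. The exact solver is also deterministic,
so the `seed`/`restarts` arguments are retained only for interface
compatibility.

The foreground group is chosen by the operational reading of the stain
relations: the minimum-mean L\* group in nucleus mode (darkest), the
minimum-mean b\* group in cell mode (most blue/purple). Ties break to the
lowest group index.

## Wold texture model

A channel's texture is decomposed into three mutually orthogonal fields
with disjoint frequency support:

* **harmonic** — isolated spectral peaks (perceived periodicity);
* **generalized evanescent** — energy concentrated along spectral lines
  (perceived directionality), found with a Hough transform at 1° angular
  and 1-bin radial resolution, up to 4 lines;
* **stochastic** — the remaining spectrum (perceived randomness).

Peaks are local maxima of the amplitude spectrum over a toroidal
8-neighbourhood that exceed the amplitude threshold, with a minimum
separation of 2 bins between accepted peaks; the DC bin is excluded and
conjugate partners travel together so every field stays real-valued.

Two scale conventions had to be fixed:

* the **amplitude threshold** (default 10, `texture.amplitude_threshold`)
  is interpreted on sinusoid-amplitude units, `2|F|/N`, of the
  mean-subtracted DFT, so "10" means a sinusoid of 10 intensity units on
  an 8-bit channel. This is the only normalization under which a fixed
  threshold of 10 is scale-meaningful across image sizes.
* the decomposition acts on the mean-subtracted plane and stores the mean
  separately; `harmonic + evanescent + stochastic + mean` reconstructs the
  input to numerical precision, and a constant plane yields an exactly
  zero stochastic field.

The per-pixel texture observations needed by the MRF are obtained by
decomposing the texture channel (default L\*, `texture.channel`) **once
globally** and then taking windowed local mean energies (16×16 boxes,
`texture.window`) of the structural (harmonic + evanescent) and stochastic
fields. Re-running the decomposition inside a sliding window per pixel
would compute the same kind of observable at roughly four orders of
magnitude more cost.

## MRF segmentation

Each pixel carries three observations — channel intensity (L\* in nucleus
mode, b\* in cell mode), structural texture energy and stochastic texture
energy — modelled as class-conditional Gaussians assumed independent
across fields (log-likelihoods add). The label prior is a Potts model on
the 8-neighbourhood with smoothness weight `mrf.beta` (default 1.5). The
MAP labelling is estimated by iterated conditional modes (ICM) from the
per-pixel maximum-likelihood start, raster-scan order, keeping the current
label on ties — which guarantees a non-increasing global energy trace. At
`beta = 0` the output equals the ML labelling exactly.

Numerical choices:

* texture energies enter on a **log scale** (`log(energy + 1e-3)`). Raw
  windowed energies are heavy-tailed at region edges; with raw energies,
  background pixels near erythrocyte boundaries match the wide foreground
  Gaussian and generate false-positive blobs. The log transform is
  variance-stabilizing and removed this failure mode.
* class variances are floored at `mrf.var_floor` (default 1e-6) so
  noise-free scenes (zero within-class variance) stay well-defined; the
  floor also makes the likelihood dominate any smoothing weight there, so
  noise-free two-class scenes are recovered exactly.
* masks are cleaned by removing 8-connected objects under 50 px and
  filling enclosed holes under 200 px (`clean.*`), matching the intended
  presentation of final masks; cytoplasm is the cell mask minus the
  nucleus mask.

Segmentation quality is scored with predicted-count denominators:
`precision = TP/P`, `fp_rate = FP/P`, `fn_rate = FN/N`, where `P`/`N` are
the predicted foreground/background pixel counts, reported in percent.

## Cell identification and separation

Regions (8-connected components) are described by area, boundary-step
perimeter (diagonal steps count √2 — the convention matters for
reproducing circularity values), circularity `perimeter² / (4π·area)`,
and the second-moment-ellipse axes and eccentricity (foci distance over
major axis, in [0, 1); the ratio definition of the feature table is used
rather than the unnormalized centre–focus distance mentioned in passing).

A nucleus-mask region is a *nucleus* if its area lies in
`[rules.min_area, rules.max_area]` and circularity ≤ 1.5 and
eccentricity ≤ 0.95; a region failing the shape test but no larger than
twice the area bound is an *overlapped* aggregate; everything else is
rejected. The thresholds are config keys, and `derive_shape_rules()`
re-derives them by classification-tree induction on labelled
regular/irregular example regions, the same induction route the method
prescribes for tuning them. A cell is accepted when it contains a nucleus with containment
proportion ≥ 0.95 (the method's fixed threshold) that is darker (lower
mean L\*) than the cell's cytoplasm; cells holding two or more matched
nuclei are flagged overlapped; matching is injective.

Overlapped aggregates are split at concave points: convexity-defect apexes
of depth ≥ 3 px, taken as all sufficiently separated local maxima of the
depth profile along each hull chord (a chord spanning several waists —
three cells in a row — then contributes one apex per waist). The deepest
apex is paired with its euclidean-nearest partner across the waist, the
boundary is cut, and each open fragment is closed by linear interpolation
of the boundary radius over angle about the fragment centroid (sampled at
1°), which maps back to a smooth conic-like arc in cartesian space. The
fragment's own boundary points are kept verbatim, so children preserve the
parent's original silhouette outside the cut. Children are rasterized,
3×3-closed, clipped to the parent, made disjoint by assigning contested
pixels to the nearer fragment centroid, and re-examined recursively (depth
limit 4). Interpolation is per fragment; convex inputs pass through
unchanged, which also makes the operation idempotent.

## Feature panel

The 67 descriptors expand, per region and channel, into a flat table of
232 columns (`mdx_feature_schema("expanded")` is the single source of
truth for names and order): 14 morphological features for nucleus and
cell, area only for the cytoplasm, five intensity statistics and five GLCM
statistics for nucleus/cytoplasm/cell over R, G, B and gray
(0.299R + 0.587G + 0.114B), ten eigen values for the nucleus and cell
crops per channel, and three size ratios. Images are **not** normalized
before extraction; absolute size and colour are diagnostic.

Conventions fixed here: population (1/n) variance, mode ties to the
smallest value, GLCM with 32 gray levels at offset (0, 1), symmetric,
restricted to pixel pairs inside the region, entropy in bits; eigen values
come from the row-covariance matrix of the bounding-box crop with
out-of-region pixels filled by the region mean (rows as observations is
the only reading under which "first 10 eigen values" of a single-channel
crop is well defined), clamped non-negative, sorted, zero-padded to 10.

## Classification and diagnosis

Six tasks are supported (ALLvsAML, L1vsL2, the three one-vs-rest AML
binaries, and three-class M2vsM3vsM5), evaluated by stratified 10-fold
cross-validation with pooled accuracy, TPR, TNR (macro-averaged when
multiclass) and Mann-Whitney AUC (one-vs-rest averaged when multiclass).
The learner roster spans the instance-based, tree, regression and
committee families: kNN with
inverse-distance class support (continuous scores for AUC even at k = 1),
random forest (100 trees), ridge-penalized multinomial logistic (a plain
penalized fit stands in for boosted simple-logistic variants), linear-kernel
SVM with probability calibration, and a random
committee of ten seed-varied small forests with randomized `mtry`.
`compare_feature_subsets()` runs the full panel and the cell-only columns
under identical fold assignments.

Patient diagnosis pools per-sample predictions:

* **cascade** — family by majority of ALLvsAML votes; then only the
  winning family's subtype classifiers are consulted (L1vsL2 for ALL, the
  three one-vs-rest binaries for AML). A wrong family call necessarily
  forces a wrong subtype, the scheme's documented failure mode.
* **fusion** — all seven classifiers vote on every sample; each vote is
  one unit split equally over the subtypes the prediction supports (an
  ALLvsAML vote for ALL adds 1/2 to L1 and L2; a one-vs-rest "rest" vote
  splits over the two remaining AML subtypes), so a patient's tally sums
  exactly to `n_samples × n_classifiers`.

The winner needs a strict plurality. "Not determined" triggers when the
top-two tally gap falls below `diagnosis.min_margin`; the default is an
epsilon, i.e. only exact ties are undetermined, which is the natural
reading of a majority-vote rule with an explicit undetermined outcome.
Diagnosis summaries report percent correct / not determined / failed per
family and subtype; the three always sum to 100.

## Synthetic study conditions

No public image collection exists for these conditions, so the
package ships a generator whose defaults define the study conditions used
by the tests and the acceptance script:

* 256×256 8-bit smears with four leukocytes among twelve erythrocytes;
  nuclei rendered at L\* ≈ 38 (darker than cytoplasm ≈ 72 by
  construction), leukocyte chroma at negative b\*, erythrocytes positive;
* per-image stain heterogeneity as an additive Lab shift drawn from
  N(0, (3, 2, 2)) plus Gaussian sensor noise of sd 4 (8-bit units), the
  level of a well-exposed camera; smooth within-region texture grain so
  no region is degenerate for the texture statistics;
* cells as randomly rotated ellipses with low-order Fourier boundary
  jitter, nuclei as smaller offset ellipses — the simplest geometry that
  exercises the circularity/eccentricity/containment rules;
* forced overlaps translate a neighbour until masks intersect by 10-30%
  of the smaller area, producing the concave waists the separator needs;
* subtypes differ by parameterized statistics only (cell size,
  nucleus/cell ratio, chroma, grain) — no cytological realism is claimed.

Feature-space experiments use a class-conditional Gaussian model over the
schema: unit-variance features whose class means sit at a controlled
pairwise distance along random orthonormal directions (optionally
restricted to one region's columns). Cohort experiments default to a
separation of 5 pooled SDs — "moderate" in the sense that per-cell subtype
accuracy lands near 80-90%: per-cell calls are informative but fallible,
so patient-level voting is exercised meaningfully rather than trivially. Benchmarks in the test suite use 100
smears for segmentation, 200 crops for the eigen-variability property,
20 permutation seeds for the chance-level check, and 10 seeds × 20
patients for the fusion-vs-cascade comparison.

What passing these tests does **not** show: robustness to real staining
chemistry, focus blur, dense clumping beyond pairwise/triple overlaps,
uneven illumination fields, or cytological subtype morphology. The
synthetic conditions validate the machinery (segmentation energy model,
geometry, voting logic), not clinical performance.

## Known limitations

* ICM is a greedy MAP solver; it inherits the quality of the ML start and
  cannot escape label-field local minima (simulated annealing or graph
  cuts would, at much higher cost, and are out of scope).
* The evanescent stage detects at most four straight spectral lines;
  curved directional structures leak into the stochastic field.
* All size features are in pixels; no pixels-per-micron calibration is
  attempted, so sizes are not physical lengths.
* With very few samples per patient the majority vote is fragile — the
  diagnosis stage is intended as a second opinion over many cells, not a
  single-cell caller.
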