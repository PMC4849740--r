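---
title: "Comparing model and human shape representations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing model and human shape representations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapersa)
```

## The problem and the pipeline

Human object recognition is dominated by shape, but "shape" is ambiguous:
the *physical form* of an image (its pixels, its bounding envelope) can be
dissociated from the *perceived shape* that drives human similarity
judgments. `shapersa` implements the representational-similarity pipeline
used to ask which of the two a candidate representation carries:

1. standardize stimuli (`preprocess_image`, `make_silhouette`);
2. extract features — shallow models computed here (`pixelwise_features`,
   `gaborjet_features`, `hog_features`) or deep-layer activations ingested
   from an external container (`load_activation_matrix`);
3. build a representational dissimilarity matrix per layer
   (`compute_rdm`), with dissimilarity one minus the Pearson correlation
   of feature rows;
4. correlate model RDMs with reference RDMs over their upper triangles
   (`rdm_correlation`), with percentile-bootstrap CIs
   (`bootstrap_rdm_correlation`), noise ceilings (`noise_ceiling`) and
   paired group tests (`paired_group_test`);
5. for naming data, compare accuracy vectors with the consistency
   statistic (`consistency`, `score_naming`) and test the
   difficulty-alignment slope (`naming_slope_test`);
6. for non-accidental-property triplets, score strict ordering reversals
   (`nap_evaluate`).

The key assumption throughout is that second-order structure — which
stimuli a representation treats as similar — is the right level at which
to compare systems with incommensurable first-order codes (pixel vectors,
filter energies, behavioral arrangements). RDM correlation inherits the
usual caveat that it is blind to monotone but nonlinear relations between
dissimilarity scales; a Spearman option is provided on
`rdm_correlation` for sensitivity checks.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| image side | 256 | px | working resolution of all image models |
| silhouette threshold | 0.5 | intensity in [0,1] | midpoint of the unit range; stimuli are rendered binary so any interior value works |
| Gabor jet | 5 frequencies, 8 orientations, 10×10 grid | – | classic jet geometry, 4000 features |
| jet frequency bank | π/2 · 2^−(0..4) | rad/px | octave spacing from the half-Nyquist band |
| jet bandwidth σ | 2π | – | ≈ 1-octave filters, the standard jet choice |
| HOG | 9 orientations, 8 px cells, 3×3 blocks | – | canonical descriptor geometry |
| bootstrap iterations | 1000 | – | percentile CIs stable to ~0.01 at this size |
| CI level | 95% (2.5/97.5 percentiles) | – | convention |
| p-value floor | 1/n_iter | – | the percentile of an empty tail is uninformative; reported as p < .001 at the default |

## What the synthetic generators emulate

The generators plant the statistical structure each analysis is designed
to detect, so recovery is a meaningful test of the code path:

* `generate_shape_set` renders a factorial design in which contour class
  (spiky star / smooth blob / rectilinear polygon) and bounding-box aspect
  ratio are crossed orthogonally. Aspect-ratio levels are geometrically
  spaced on [0.62, 1.61] — a visually clear range whose extremes still fit
  a 256-px frame at constant area. All contours are 4-fold symmetric, so
  the rendered bounding-box aspect ratio equals the planted scaling
  exactly up to pixelation; rendering is binary with no anti-aliasing so
  pixel-counting oracles are exact.
* `simulate_observer_rdms` adds i.i.d. Gaussian noise (SD 0.3 by default,
  in dissimilarity units — moderate inter-observer disagreement) to the
  upper triangle of a true RDM, mirrors it, and clips at zero. Clipping
  rather than resampling introduces a small positive bias near zero
  dissimilarities, negligible at the default noise.
* `simulate_layer_features` draws Gaussian features whose row-correlation
  matrix realizes a blend of two reference RDMs, weight w of "perceived"
  against 1 − w of "physical". References are z-scored over their upper
  triangles before blending so neither scale dominates; the blended target
  is mapped into correlation range (scaled by −0.3, clipped at ±0.8) and
  projected to the nearest valid correlation matrix by eigenvalue
  clipping. A monotone w-plan across six layers with 1000 features per
  layer and feature noise 0.1 is the default study condition: it emulates
  the qualitative crossover in which perceived-shape correlation rises
  with depth while physical correlation falls at the top.
* `generate_triplet_features` plants 22 base/NAP/metric triplets with
  Euclidean displacements of 1 and 2 (NAP closer — the conservative
  linear-metric ordering), the NAP displacement confined to a diagnostic
  subspace of the first ⌈p/10⌉ coordinates. Amplifying that subspace by
  the perceptual gain (default 5, comfortably past the reversal point of
  2) reverses every triplet.
* `simulate_naming` draws Bernoulli responses at planted item
  difficulties.

What the generators do **not** emulate: photorealistic objects or 3-D
geometry, structured (non-i.i.d.) observer noise, arrangement-task
geometry constraints (noise is applied to dissimilarities directly, a
stand-in rather than a claim about how arrangement data behave), semantic
structure in naming errors, and response times. Passing recovery tests
therefore demonstrates that the pipeline measures what it claims on data
with known ground truth — not that any particular model family matches
human behavior on real stimuli.

## Numerical choices and degenerate inputs

* **Undefined diagonal.** RDM diagonals are stored as `NA`, never zero,
  so no statistic can silently include them. Bootstrap resamples that
  draw a stimulus twice create cells pairing a stimulus with its
  duplicate; these are marked undefined and dropped the same way,
  avoiding spurious perfect agreement.
* **Normalized Euclidean metric.** Defined as Euclidean distance between
  feature rows scaled to unit norm, removing overall activation
  magnitude — the evident intent of "normalized"; it also makes triplet
  outcomes invariant under common orthogonal transforms of feature space.
* **Correlation guards.** Constant feature rows and zero-variance upper
  triangles raise errors naming the offending stimulus or participant;
  degenerate bootstrap replicates become `NA` and are excluded from
  percentiles.
* **MDS.** Classical Torgerson double-centering (`cmdscale`), not
  iterative stress minimization: deterministic, seedless, adequate for
  visualization. Axis signs are fixed by making each axis's first nonzero
  loading positive.
* **Gabor jet.** The bank is built analytically (octave-spaced complex
  Gabors, magnitude read-out on the node lattice) and numerically
  mean-corrected so a constant image yields exactly zero response. Node
  positions are the centers of a 10×10 tiling — the border-inclusion
  question is thereby settled in favor of no nodes on the border.
* **Silhouettes.** Foreground is the largest connected component below
  threshold, holes filled (`EBImage::fillHull`); multi-blob images
  therefore lose satellite blobs by design, and the "filling only adds
  pixels" guarantee applies to connected shapes.
* **Triplet ties** (equal distances) count as failures and are tallied
  separately rather than split, since the criterion is *strictly* more
  dissimilar.
* **Paired test conventions.** Replicate draws are shared across all
  models compared against a reference (`bootstrap_rdm_correlations`), so
  group averages are paired by construction; exact all-zero difference
  distributions return p = 1; the two-tailed p doubles the smaller tail
  and caps at 1.
* **Noise-ceiling z-scoring** is per participant over upper-triangle
  cells — the standard reading when the axis is unstated.
* **Zero-dynamic-range images** return a constant image with a warning
  flag rather than an error, so batch preprocessing survives blank
  frames.

## Open design choices

Where the method family leaves latitude, this package fixes: Rec.601
luminance weights for grayscale conversion; row-major, origin-top-left
feature ordering (pinned so activation containers are bit-reproducible);
behavioral RDM stacks averaged by simple cellwise mean; naming
consistency computed against the mean-human accuracy vector rather than
per-participant pairing; group tests one-tailed by default in the
drivers, with the tail always recorded in the output. The naming driver
exposes the candidate-set size as a configuration knob without claiming a
faithful default, since equating model and human response-set sizes is an
unresolved design question. For naming slope tests under complete
separation the Wald statistic degenerates, so the p-value falls back to a
likelihood-ratio test and the slope is flagged infinite.

## Problem sizes

The validation suite runs at deliberately small scale, chosen so each
property is measured with adequate Monte-Carlo resolution while the whole
suite stays interactive: 9-stimulus factorial sets, 600–1000 features per
simulated layer, panels of 4–8 observers, 20 replicates for layer-profile
recovery, 100–200 simulations for calibration checks, and 10,000 random
triplets for the chance-level evaluation. Real analyses would typically
use the default 1000 bootstrap iterations throughout (several calibration
tests use fewer per replicate, since it is the outer simulation count
that controls their resolution).

## Known limitations

Pearson RDM correlation is sensitive to the marginal distribution of
dissimilarities; the binary reference RDMs used by the synthetic designs
are balanced but mutually anticorrelated (≈ −0.33 for a 3×3 design), so
"no preference" sits below zero, not at it — the layer-profile plots make
this visible. The noise ceiling assumes exchangeable participants.
Multiple comparisons across layers or models are not corrected for.
Deep networks are consumed only as activation files; nothing here
validates how those activations were produced.
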