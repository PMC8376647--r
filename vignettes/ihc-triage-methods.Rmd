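---
title: "Methods: triaging prostate biopsies for advance IHC ordering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triaging prostate biopsies for advance IHC ordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decision being modelled

A pathologist reading a prostate needle biopsy orders basal-cell marker
IHC when a focus of glands is *ambiguous*: neither clearly benign nor
clearly malignant on H&E morphology. The package models this as a
two-stage classification. First, a tile-level classifier distinguishes
ambiguous from certain tissue — grouping clearly-benign and
clearly-malignant together as "certain", because both are resolvable
without a stain, and treating intermediate differentiation as "ambiguous".
Second, a slide-level model decides whether the slide as a whole warrants
an advance IHC order, working from the *distribution* of tile evidence
rather than any single tile, because (a) annotators disagree at tile
granularity and (b) an order can be driven by several weak foci in
different places.

## Tile ensemble

Each ensemble member is a compact network: a 456-dimensional fixed tile
representation (12×12 per-channel block means plus 8-bin per-channel
intensity histograms) feeds a 64-unit ReLU stage, a sigmoid attention gate
modulates it, a second ReLU stage with a residual connection follows, a
32-dimensional ReLU embedding layer forms the penultimate features, and a
2-way softmax closes the network (~40k parameters). Members differ only in
initialization and data order (distinct per-member seeds); each trains the
full epoch budget with Adam — no early stopping — with online augmentation
(affine jitter, flips, Gaussian intensity noise, and a random radial gain
on the Fourier magnitude in [0.8, 1.2]) as the regularizer. Augmented
views are pre-sampled per tile (3 views plus the original) and pooled, so
the member loop is pure matrix arithmetic.

Because certain tiles heavily outnumber ambiguous ones once all non-focus
tissue tiles are used, the member loss weights classes by inverse
frequency. This keeps the conventional 0.5 label threshold calibrated;
without it the threshold drifts toward the majority class and the
slide-level ambiguous-tile counts lose their meaning even while the
ranking (AUC) stays high.

The ensemble prediction for a tile is the arithmetic mean of member
softmax rows; the label is its argmax with ties resolved to "ambiguous"
(over-calling costs one IHC order; under-calling delays a cancer
diagnosis). Uncertainty is exposed three ways, all computed: the entropy
of the mean distribution (bits), the across-member variance of the
ambiguous-class probability (population variance, so a single-member
ensemble gives exactly 0), and a surrogate loss — the cross-entropy of the
mean row against its own argmax — which stands in for a true loss at
inference time when no labels exist. Focus-level calls average tile mean
probabilities over the tiles comprising the focus.

Key defaults: 3 members, 20 epochs (desk scale; the configuration accepts
the full-scale 200), batch 16, learning rate 1e-3, embedding dimension
D = 32, tiles 96 px at 4 µm/px. The full-scale operating point of
1024-px tiles at 1.0 µm/px remains available through `tile_grid()`.

## Slide features and decision

A slide is summarized by `8 D + 6` numbers: median, mean, population
variance and population excess kurtosis of each embedding dimension,
computed separately over ambiguous-labelled and certain-labelled tiles;
the variance across tiles of the mean ambiguous probability; the variance
of the surrogate loss; the two group counts; and two indicator flags for
empty groups (slides with no ambiguous tiles occur in practice, so the
zero-fill path is mandatory, not defensive). Excess kurtosis uses the
uncorrected moment ratio m4/m2² − 3 with the convention that a constant
sample maps to 0 — centring the no-signal case at the normal-distribution
reference.

The decision model is gradient-boosted trees (xgboost: 200 rounds, depth
3, learning rate 0.1, row subsample 0.8, feature subsample 0.5 per tree,
single-threaded for reproducibility). The per-tree feature subsampling is
the "random" ingredient of a random-boosted-trees design and matters at
desk scale: with 262 slide features and 60 training slides, full-feature
trees can separate the training set on spurious embedding statistics and
generalize erratically; forcing each tree onto a random half of the
features spreads the model's reliance across the distribution statistics. Splits follow the study protocol: each of three
independent splits draws 200 *distinct* slides stratified so the
control:ordered ratio is 0.4 (57:143 at the reference corpus size of 299),
leaving 99 held-out slides. The protocol's description of drawing with
replacement is arithmetically inconsistent with 99 slides remaining, so
distinct draws are used — the only reading that honours the 200/99
partition. Operating points are chosen on the ROC as the smallest
threshold whose specificity meets the target, i.e. the most sensitive
point above the specificity floor; the average false-positive rate at a
point is the mean over annotator reference label sets of FP over all
slides, which is the convention consistent with the economics table's
cost arithmetic.

## Workflow economics

Durations are carried in minutes/hours and rounded half-up to integers
only at the end (banker's rounding is wrong for currency and day counts).
The per-row arithmetic is: turnaround savings (days) =
round(d · n · 74 h / 24); reporting savings (hours) =
round(d · n · 11 min / 60); extra cost = round(f · n · £11), with
n = 380 audited IHC-requested cases, d the detection fraction and f the
false-positive fraction of the operating assumption (reflex testing is
d = f = 1). The cost base is the 380 IHC-requested cases — the only
convention that reproduces every audited cost cell. The `_exact` columns
expose the unrounded values; two of them land on 1171.67 and 1054.5,
so the half-up integers (1172, 1055) can differ by a day from figures
rounded under other conventions.

Two audit-derived figures deserve care. The session-duplication model sums
the duplicated components of a two-session read: 7.5 min re-reviewing the
H&E, 1.5 min for the extra decision, 1.0 min raising the request — 10.0
min. The per-case reporting saving used in the table, 11 min, is a
separate, deliberately conservative scenario input, not the component sum;
`session_duplication()` reports the sum without forcing agreement.
Similarly the 74 h (3 d 2 h) per-case turnaround saving is the table's
generator as given; the audit's mean difference (77 h) and its CI lower
bound are alternative choices selectable through `econ_params()`.

The Welch–Satterthwaite interval is implemented from group summaries
(n, mean, sd): effective df = (v1 + v2)² / (v1²/(n1−1) + v2²/(n2−1)) with
vi = sdi²/ni, collapsing to n1+n2−2 for equal variances and equal n. Where
only printed CIs exist (the audits release no raw data), differences are
reported with pass-through CIs rather than recomputed ones.

## What the synthetic generator emulates — and what it does not

Slides are stylized H&E rasters (480×480 px at 4 µm/px ≈ a 1.9 mm field):
a curved tissue band on white background filled with glands on a jittered
lattice. One parameter α ∈ [0, 1] drives morphology monotonically: gland
radius shrinks (factor 1 − 0.58 α), lumina close (lumen fraction
0.62 − 0.52 α), outlines become irregular (angular perturbation ∝ α) and
nuclear density rises (40 + 160 α nuclei per tile area). Mid-range α
(default interval [0.35, 0.65]) is "ambiguous" — the middle of the
benign→malignant continuum, mirroring the conceptual framing of the
decision; the extremes are certain. IHC-needed slides carry 1–3 foci
(irregular 16-gons, radius 50–70 px — deliberately tile-scale so a 96-px
tile can be dominated by a focus) with α drawn from the ambiguity
interval over an extreme-α background; controls are uniformly extreme,
benign or malignant 50:50. The class mix 219:40:40 scaled by
largest-remainder apportionment, the reason codes sampled proportionally
to the audited focus counts, and the slide-level label rule (at least one
ambiguous focus of at least 0.01 mm²) reproduce the corpus structure.

The generator does *not* emulate: stain variation beyond Gaussian channel
jitter, scanner artefacts (blur, folds, debris, pen marks), nuclear
texture, stromal architecture, multi-level pyramids, or annotator
disagreement. Passing the end-to-end tests therefore shows that the
pipeline's machinery — masking, tiling, training, uncertainty,
aggregation, decision — recovers a real signal it was pointed at; it says
nothing about absolute performance on clinical slides, which is why the
per-pathologist validation agreement ships as a fixed reference table
rather than a recomputable quantity.

## Numerical and implementation choices

- **Coordinates**: 0-based, x rightward, y downward, half-open rectangles
  everywhere; annotation polygons at base-level pixels regardless of the
  annotated magnification.
- **Tissue segmentation**: HSV saturation clipped at 0.2, then Otsu.
  H&E tissue is multimodal in saturation (pale stroma vs strongly stained
  epithelium); unclipped Otsu happily separates those two instead of
  background from tissue. After thresholding: closing (disc r = 4 px),
  hole filling (gland lumina are tissue), opening, and removal of
  components under 0.01 mm². A learned segmenter can replace the
  thresholding step via `mask_fun` without touching the contract.
- **Resampling**: area averaging with fractional edge weights via an
  integral image — constant regions stay exactly constant.
- **Polygon–tile overlap**: Sutherland–Hodgman clipping plus the shoelace
  formula (no geometry package of this kind is available to R here);
  self-touching outlines are repaired by vertex cleanup, self-crossing
  ones rejected.
- **AUC**: rank-based Mann–Whitney with ties at 0.5, identical to the
  trapezoidal ROC area; verified in tests against a brute-force pair oracle
  and an independent ROC implementation.
- **Determinism**: one master seed; stage, member and per-slide seeds are
  derived through a fixed affine hash, so any prefix of the pipeline
  reproduces bit-exactly. Tie-breaks: label ties to "ambiguous";
  apportionment remainder ties to the earlier class.
- **Desk problem sizes**: the bundled study uses 90 slides (60 train / 30
  test in fold 1), ~700 training tiles, 3 members × 20 epochs, and
  evaluates tile-level AUC on held-out focus vs control tiles and
  slide-level AUC on the 30 held-out slides. These sizes were chosen so a
  full study is a coffee-break run on a laptop CPU while keeping enough
  held-out slides for a meaningful AUC.

## Known limitations

- The tile representation is engineered (block means + histograms), not
  learned from pixels; it suffices for the synthetic morphology continuum
  but would need the full-scale configurable architecture for clinical
  H&E.
- The surrogate loss is self-referential by construction; where labels
  exist the true cross-entropy can be substituted.
- Slide-level AUC at desk scale rests on 30 held-out slides (7 controls),
  so single-slide fluctuations move it by ~0.03.
- The economics model is linear bookkeeping by design: no discounting,
  staffing constraints, or site-to-site cost variation.
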