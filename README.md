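# ihctriage

Advance immunohistochemistry (IHC) ordering for prostate needle biopsies,
decided from the H&E slide alone — plus the workflow economics of doing so.

## The problem

A quarter to a half of prostate biopsy cases cannot be signed out on H&E
morphology alone: foci of glands are too small, too unusual, or too
atypical-but-probably-benign to call, and the pathologist orders basal-cell
marker IHC (CK5/6, 34BE12, P63) to resolve them. Because the order is only
raised *after* the first read, the case waits for staining and is then
reviewed a second time — days of turnaround and a duplicated reporting
session per case. If an algorithm can predict, at scanning time, which
slides will need IHC, the stain is ready for the first and only read.

`ihctriage` implements that triage pipeline end to end:

1. **Tissue segmentation and tiling** — saturation-channel Otsu with
   morphological cleanup behind a pluggable contract; half-open grid tiles
   filtered by tissue fraction.
2. **Ambiguity ensemble** — a deep ensemble of small residual-attention
   tile classifiers separating *ambiguous* from *certain* gland morphology.
   Member softmax rows are averaged into the predictive distribution
   p(certain), p(ambiguous); disagreement across members, entropy and a
   surrogate loss quantify uncertainty. Focus-level calls average tile
   probabilities over the tiles comprising the focus.
3. **Slide features** — per-slide distribution statistics (median, mean,
   variance, excess kurtosis) of tile embeddings, computed separately for
   ambiguous- and certain-labelled tiles, plus prediction-probability and
   loss variance: a fixed-length vector of 8D + 6 entries.
4. **IHC decision** — gradient-boosted trees on the slide feature vectors;
   three stratified 200/99 training splits with the control:ordered ratio
   fixed at 0.4; ROC operating points selected at target specificities.
5. **Workflow economics** — audited turnaround/reporting differences,
   Welch–Satterthwaite intervals, the session-duplication model, and the
   savings/cost table per operating assumption.
6. **Synthetic cohort generator** — needle-biopsy-like slides whose gland
   morphology follows a single parameter α ∈ [0, 1] (benign → ambiguous →
   malignant), with ground-truth tissue masks, GeoJSON focus annotations
   carrying the 8 reason codes, and a manifest mirroring the clinical
   corpus structure (IHC-requested : benign control : malignant control =
   219 : 40 : 40, scaled). Every stage is trainable and testable with no
   clinical data.

## Worked example

The economics table, from the audited inputs (380 IHC-requested cases,
74 h turnaround and 11 min reporting saved per detected case, £11 per
unnecessary order):

```r
library(ihctriage)
econ_table()[, c(1:3, 4:6)]
#>              label detection_fraction false_positive_fraction
#>     reflex_testing               1.00                    1.00
#>  point_1_spec_0.60               0.60                    0.15
#>  point_2_spec_0.75               0.75                    0.33
#>  point_3_spec_0.90               0.90                    0.48
#>  turnaround_savings_days reporting_savings_hours extra_cost_currency
#>                     1172                      70                4180
#>                      703                      42                 627
#>                      879                      52                1379
#>                     1055                      63                2006
```

Reading the table: operating the classifier at specificity 0.9 saves about
1055 case-days of turnaround and 63 pathologist-hours across the audited
cases while over-ordering IHC on 48% of slides (£2006) — similar time
savings to reflex-testing every case, at half its £4180 cost.

A full synthetic study — generate 90 slides, segment, tile, train the
3-member ensemble, aggregate, decide, evaluate:

```r
report <- run_pipeline(run_config("study_out", seed = 0))
report$metrics[c("tile_auc", "slide_auc", "tissue_iou_mean")]
#> $tile_auc
#> [1] 0.982438
#> $slide_auc
#> [1] 0.9440994
#> $tissue_iou_mean
#> [1] 0.9958022
```

Held-out tile-level AUC for ambiguous-vs-certain morphology is ~0.98,
slide-level AUC for the IHC-request decision ~0.94, and the classical
tissue mask overlaps the generator's ground truth at IoU ~0.996. A thin
CLI wraps the same functions: `inst/cli/ihc-triage run-all --out study_out
--seed 0`.

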