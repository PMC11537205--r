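# phenopatch

Marker-gated cell phenotyping and patch classification for multiplexed
immunofluorescence (MxIF), at desk scale.

## What problem this solves

H&E staining is everywhere in pathology, but most cell *subtypes* —
helper T cells, epithelial progenitors, goblet cells — cannot be named
from H&E appearance alone; they are normally identified with specialized
marker stains. MxIF images one tissue section through many stain/bleach
rounds, so every nucleus carries a vector of marker intensities and its
subtype follows from rule-based **marker gating**: threshold each
channel's mean intensity over the instance, then walk an ordered cascade
of biological rules (Muc2⁺ → goblet, CD3d⁺CD4⁺ → helper T, …) until the
first match wins. Gated MxIF can then serve as a label factory for
training patch classifiers on H&E-like renderings of the same tissue,
and predictions can be scored even when the only available ground truth
uses coarser parent labels (lymphocyte, epithelial, connective).

`phenopatch` implements that full pipeline as composable, deterministic,
tested R functions, for image-analysis researchers who want to exercise
and evaluate the pipeline mechanics without access to a real MxIF cohort:

* a **synthetic MxIF generator** (17 gating + 10 nuisance channels at
  0.32 µm/px, elliptical nuclei plus Muc2 goblet blobs, known phenotype
  per instance, Crohn's-like slide/patient/site provenance);
* a **14-class gating engine** (per-instance mean intensities, strict
  per-slide thresholds, ordered first-match rule cascade over 17 key
  stains);
* a **deterministic pseudo-H&E renderer** and coarse parent-labeled tile
  sets with per-site colour shifts;
* **localization**: a classical fallback segmenter, external mask
  ingestion, cubic/nearest resolution resampling;
* a **patch dataset and training harness**: 41×41 px patches at
  0.5 µm/px (20.5 µm) normalized per patch, patient-level 12/4/4
  cross-validation folds, class-balanced batches, Adam + one-cycle
  training with per-sample normalization and validation-loss checkpoint
  selection;
* an **evaluation suite**: one-to-one greedy instance matching at
  IoU > 0.25, precision/recall/F1/mean-IoU, per-class
  PPV/NPV/prevalence, parent-class bounded metrics
  (PPV upper bound, NPV lower/upper bounds), prevalence-normalized PPV,
  per-class DQ⁺ = TP/(TP + FP/2 + FN/2), and a tie-corrected Friedman
  rank test for cross-site stability.

The key statistics, in the field's notation: for class *c*,
PPV = TP/(TP+FP), NPV = TN/(TN+FN), prevalence = n_c/N; against parent
labels only, PPV_upper(c) = #(pred=c ∧ parent(gt)=parent(c)) / #(pred=c)
with true PPV ≤ PPV_upper and NPV_lower ≤ true NPV ≤ NPV_upper.

## Worked example

```r
library(phenopatch)

cfg <- sim_config(image_height_px = 512L, image_width_px = 512L,
                  n_cells = 150L, seed = 7L)
tissue <- generate_tissue(cfg)
tissue
#> <synthetic_tissue> slide01 / patient01 / site01: 150 instance(s), 27 channel(s)

# gate the MxIF: mean intensity -> stain calls -> rule cascade
cells <- gate_cells(tissue$image, tissue$instances, cfg$thresholds)
mean(cells$class == tissue$truth$class)
#> [1] 1

# localize instances without any pretrained model and score detection
merged <- merge_nuclear_channels(tissue$image)
seg <- segment_fallback(merged, seg_config(), cfg$resolution_um_per_px)
m <- match_instances(seg, tissue$instances, iou_threshold = 0.25)
m
#> <match_result> 150 matched pair(s), 0 FP, 0 FN (IoU > 0.25)
round(detection_metrics(m), 3)
#> precision    recall        f1  mean_iou
#>     1.000     1.000     1.000     0.893

# score fine-grained calls against coarse parent labels
mapping <- default_class_mapping()
parent_gt <- apply_class_mapping(tissue$truth$class, mapping)
keep <- !is.na(parent_gt)
bounded_metrics(cells$class[keep], parent_gt[keep], mapping,
                classes = c("helper_t", "enterocyte", "progenitor"))
#>        class     parent n_pred ppv_upper npv_lower npv_upper
#> 1   helper_t lymphocyte     12         1     0.717         1
#> 2 enterocyte epithelial     28         1     0.789         1
#> 3 progenitor epithelial     13         1     0.676         1
```

Reading the output: gating recovers every simulated phenotype exactly at
this noise level; the fallback segmenter finds all 150 instances with
mean IoU 0.89 against the generative masks; and with only parent labels
available every fine prediction is parent-consistent (PPV upper bound 1),
while the NPV lower bounds stay below 1 because ambiguous negatives —
other epithelial or lymphocyte nuclei — are pessimistically treated as
misses.

A deterministic pseudo-H&E rendering (`render_pseudo_he()`), patch
extraction (`extract_patches()`), patient folds
(`make_patient_folds()`), and the compact trainable classifier
(`train_classifier()` / `predict_patches()`) complete the pipeline; see
the methods vignette (`vignettes/phenopatch-methods.Rmd`) for the models,
parameter choices and their rationale.

A thin command-line front end over the same functions is included at
`inst/cli/phenopatch.R` (`simulate`, `gate`, `segment`, `evaluate`).

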