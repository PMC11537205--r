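---
title: "Marker-gated phenotyping and patch classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gated phenotyping and patch classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopatch)
```

## The problem

Hematoxylin and eosin (H&E) is the ubiquitous histology stain, but most
cell subtypes cannot be read off it directly: identifying a helper T cell
or an epithelial progenitor normally requires specialized markers.
Multiplexed immunofluorescence (MxIF) images the same section through many
stain/bleach rounds, so each nucleus carries a vector of marker
intensities from which its subtype follows by rule-based gating. That
makes MxIF a label factory for H&E-like images of the same tissue: gate
the MxIF, render the tissue in an H&E-like appearance, and train a patch
classifier on the transferred labels.

`phenopatch` implements this pipeline at desk scale, end to end and fully
testable, on synthetic tissue with known phenotypes:

1. **`sim_config()` / `generate_tissue()`** — synthetic MxIF tissue with a
   known class per instance;
2. **`gate_cells()`** — mean-intensity gating plus an ordered 14-class
   rule cascade;
3. **`render_pseudo_he()`** — a deterministic H&E-like rendering;
4. **`segment_fallback()` / `resample_image()`** — instance localization
   and resolution handling;
5. **`extract_patches()` / `make_patient_folds()` /
   `balanced_batch_indices()` / `train_classifier()`** — the patch
   classification dataset and training harness;
6. **`match_instances()`, `classification_metrics()`,
   `bounded_metrics()`, `dq_plus()`, `friedman_test()`** — the evaluation
   suite, including bounded metrics for scoring fine-grained predictions
   against coarse parent labels.

## The gating model

Each instance (nucleus, or mucin goblet for goblet cells) gets, per
channel, the arithmetic mean intensity over its pixels. A stain call is
positive iff that mean **strictly exceeds** the per-slide, per-channel
threshold; strictness makes the boundary case deterministic. Class
assignment is an ordered cascade (`default_rule_table()`): the first rule
whose required-positive channels are all positive and required-negative
channels all negative wins. The packaged order puts specific markers
before lineage-generic ones:

goblet (Muc2) → enteroendocrine (CgA) → progenitor (Sox9 or OLFM4) →
enterocyte (PanCK and NaKATPase) → helper T (CD3d, CD4) → cytotoxic T
(CD3d, CD8) → CD3d+CD4−CD8− T → B (CD20) → macrophage (CD68) → monocyte
(CD11b) → myeloid other (Lysozyme) → leukocyte other (CD45) → fibroblast
(SMA) → stromal undetermined (Vimentin).

Every nucleus rule also requires DAPI, so the cascade references 17
distinct key stains for 14 classes. A no-match vector yields
`"unclassified"`; such instances count in detection metrics but are
excluded from training patches and classification metrics. Because the
cascade is first-match-wins, rule order matters: CD4+CD8+ double-positive
T cells resolve to helper T under the default order, and
`default_rule_table(double_positive_policy = "demote_to_parent")` instead
sends them to the generic T class. The enterocyte conjunction
(PanCK **and** NaKATPase) is the default; `enterocyte_operator = "or"`
relaxes it. Both switches exist because the underlying gating literature
does not pin these cases down.

## The synthetic tissue generator

The generator is the package's study-condition definition, not a tuning
surface. Defaults: a 1024×1024 px slide at 0.32 µm/px, 600 cells, marker
on/off means 180/20 against thresholds of 100, Gaussian channel noise of
SD 10 clipped at zero, and 10 nuisance channels alongside the 17 gating
channels (a 27-channel panel). Cells are ellipses placed by rejection
sampling of centres with a minimum centre distance (largest first); this
is the simplest geometry that exercises IoU matching nontrivially while
guaranteeing non-overlap, so zero-noise gating is exact by construction.
The class mixture (`default_class_mixture()`) loosely follows colonic
mucosa: epithelium dominant, enteroendocrine rare, immune and stromal
populations moderate.

Each class's "on" channels are exactly the required-positive channels of
its gating rule(s) (plus DAPI for nucleus classes); lineage markers that
the rules do not need (e.g. CD45 on T cells) are left off so the on-set
equals the class's defining key stains. Goblets are larger Muc2-only
blobs with no DAPI, mirroring gating on the goblet rather than a nucleus.

The Gaussian on/off intensity model is an assumption of convenience: real
MxIF intensity distributions are not documented in enough detail to copy,
and nothing downstream depends on the distributional family — only on the
on/off separation relative to the thresholds. Similarly, channel noise is
i.i.d. per pixel; real stains have spatially structured noise,
autofluorescence and bleed-through that this simulator deliberately does
not model. Passing tests therefore demonstrate correctness of the
*pipeline mechanics* under known conditions, not performance on real
tissue.

### Designed learnability structure

The pseudo-H&E rendering (`render_pseudo_he()`) is a fixed analytic
colour map — nuclei hematoxylin purple scaled by DAPI, goblets pale,
everything else eosin pink — rather than a learned style-transfer model.
The only class information that survives it is geometry: size,
eccentricity and the per-class DAPI "dome" chromatin texture set in
`default_class_geometry()`. That table encodes, by design, which classes
a rendering-only classifier can learn:

* **designed-separable** (`designed_separable_classes()`): goblet,
  enterocyte, progenitor, enteroendocrine, fibroblast, macrophage — each
  has geometry distinct from all other 13 classes;
* **designed-unlearnable pair** (`designed_unlearnable_pair()`): helper T
  and cytotoxic T share identical geometry and differ only in CD4/CD8,
  channels invisible in the rendering — a built-in negative control
  mirroring the real-world finding that only a subset of subtypes is
  learnable from H&E appearance;
* the remaining classes overlap each other moderately, as real
  lamina-propria populations do.

## Localization and resampling

`segment_fallback()` is a classical segmenter (Gaussian smoothing, Otsu
or fixed threshold, connected components, optional distance-transform
watershed, minimum-area filter) over the DAPI+Muc2 merge. It exists so
the pipeline runs with no pretrained weights; external masks can be
ingested with `ingest_mask()` instead.

Intensity images are resampled between physical resolutions (0.32 →
0.5 µm/px in the default flow) with separable Keys cubic convolution
(a = −0.5), pixel-centre aligned; overshoot below zero is clipped because
intensities are physical. Label maps use nearest-neighbour lookup, which
provably introduces no new ids. Output shape is
`round(shape × from_res / to_res)`.

## Patch dataset and training contract

Patches are 41×41 px at 0.5 µm/px (20.5 µm — about two cell diameters),
centred on the rounded centroid (banker's rounding for determinism), with
out-of-bounds pixels filled by edge replication: zero-fill would paint
dark corners that read as fake nuclei. Each patch is min-max normalized
to [0, 1] individually, jointly across the three channels by default
(`normalize = "per_channel"` is available; "individually normalized" is
read as per-patch).

`make_patient_folds()` partitions patients — never slides — into rotating
groups: 20 patients under 5 folds give 12/4/4 train/validation/test with
each patient tested exactly once; stratification tags are dealt
round-robin so tissue region and disease status appear in every split
whenever counts permit. `balanced_batch_indices()` draws each batch slot
class-first (uniform over classes, then uniform with replacement within
the class), so the expected per-class share of every batch is 1/14
regardless of prevalence.

`train_classifier()` implements the training contract: class-balanced
minibatches, cross-entropy, Adam, a one-cycle learning-rate schedule
(30 % linear warmup from peak/25, cosine decay to peak/10⁴), and
selection of the checkpoint with the lowest validation loss. The backbone
is a deliberately compact choice — average-pool by 2, flatten,
standardize per sample, one ReLU hidden layer (48 units), softmax. The
geometric class signal needs no more capacity, and the backbone is
configuration, not contract. What *is* contract: every internal
normalization is per sample, so a prediction is bit-for-bit independent
of the batch it is computed in (asserted in the tests by predicting the
same patch alone and inside a shuffled batch). Desk defaults are 2,000
steps with batch 256; the reference-scale 20,000 steps remain selectable
in `train_config()`.

## Evaluation suite

**Matching.** `match_instances()` performs one-to-one matching with IoU
strictly greater than 0.25 (lenient, to tolerate label sets cropped
differently), greedy in descending IoU with deterministic tie-breaks.
Greedy was chosen over optimal assignment because it is the standard in
nucleus-evaluation practice and deterministic; the acceptance suite
verifies it attains the exhaustive optimum on 200 jittered-copy fixtures
with up to six instances.

**Direct metrics.** `detection_metrics()` gives precision, recall, F1 and
mean IoU of true positives; `classification_metrics()` gives per-class
confusion, accuracy, PPV, NPV and prevalence. Classification can be
scored over all ground-truth instances (ground-truth-centroid regime) or
over matched pairs only (predicted-centroid regime, the
`match_instances()` output feeding the pair list); unmatched predictions
affect only detection metrics.

**Bounded metrics.** When ground truth carries only parent labels
(`default_class_mapping()`: helper T → lymphocyte, enterocyte →
epithelial, progenitor → epithelial, fibroblast → connective, stromal
undetermined → connective, plus natural lineage parents for the remaining
lymphocytes; goblet and the myeloid/leukocyte catch-alls droppable), a
fine class c with parent P gets:

* `ppv_upper` = #(pred = c ∧ parent = P) / #(pred = c) — every
  parent-consistent prediction optimistically counted correct, so true
  PPV ≤ `ppv_upper`;
* `npv_lower` = definite true negatives / negatives — ambiguous negatives
  (parent = P) all pessimistically treated as missed c, so
  `npv_lower` ≤ true NPV;
* `npv_upper` additionally credits ambiguous negatives predicted as a
  *sibling* of c. The sibling-credit construction is this package's
  definition — the validity orderings above, verified over 1,000 random
  scenarios, are the contract, not any particular published number.

`prevalence_normalized_ppv()` divides an upper-bound PPV by prevalence
(1 = chance level). `dq_plus()` computes the detection-quality term of
panoptic quality, TP / (TP + FP/2 + FN/2), per class under the matching.
In parent mode the default false-negative attribution is *optimistic*
(ambiguous parent instances are credited to siblings, FN = 0), which is
what makes the parent-mode value a provable upper bound on the
uncomputable fine-grained DQ+ — the pooled alternative
(`fn_mode = "pooled"`) charges the class with every unexplained parent
instance and is not a bound, because sibling instances leak into it.
`friedman_test()` implements the within-block rank test with tie
correction for cross-site stability comparisons; it agrees with
`stats::friedman.test` on tie-free data, and the tie-corrected form is
why it is implemented in-package.

## Numerical choices and degenerate inputs

* Thresholding at exactly the threshold is negative; IoU at exactly the
  matching threshold is unmatched (both strict).
* Patch normalization guards near-constant patches:
  (max − min) < 10⁻¹² maps to all zeros.
* Empty inputs return empty structures, not errors (empty instance map →
  zero-row cell table; blank image → empty segmentation); truly undefined
  rates (0/0) are `NA`, and empty detection denominators yield 0 with a
  warning.
* All randomness flows through explicit integer seeds via a private RNG
  stream that restores the caller's RNG state; equal seeds are
  bit-identical.

## Problem sizes used in the shipped checks

The test and acceptance runs use the generator defaults (600-cell
1024×1024 slides): one zero-noise slide for the exact gating round-trip,
five slides from five synthetic patients (three train, one validation,
one test; ~1,800/600/600 patches) for classifier parameter recovery over
five training seeds, 200 jittered-copy fixtures for the matching oracle,
and 1,000 random confusion scenarios for the bound sandwich. These sizes
were chosen so a full run completes in minutes on a single CPU core while
every class remains represented.

## Known limitations

* The simulator's ellipse-with-Gaussian-noise model omits overlapping
  cells, segmentation errors correlated with phenotype, autofluorescence
  and stain bleed-through; results on it bound what the code does, not
  what real tissue yields.
* The pseudo-H&E renderer carries a geometric class signal only; it is
  not photorealistic and is not meant to train models for real H&E.
* The fallback segmenter is a baseline, not a replacement for learned
  instance segmentation.
* The rule cascade's exact precedence in the originating gating
  literature is not fully published; the packaged order is one defensible
  transcription, versioned with the package and overridable via
  `rule_table()` / YAML.
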