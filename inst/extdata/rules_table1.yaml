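# Ordered marker-gating rule cascade for the 14 colon cell/nucleus classes.
# Evaluation is first-match-wins, top to bottom: specific markers precede
# lineage-generic markers, so "(other)" classes only catch cells that no more
# specific rule claimed. Progenitor is encoded as two adjacent rules (Sox9 or
# OLFM4). Goblet cells are gated on the Muc2-positive goblet, not a nucleus,
# so the goblet rule does not require DAPI. Every nucleus-class rule requires
# DAPI; together the cascade references 17 distinct key stains.
- class: goblet
  positive: [Muc2]
  negative: []
- class: enteroendocrine
  positive: [DAPI, CgA]
  negative: []
- class: progenitor
  positive: [DAPI, Sox9]
  negative: []
- class: progenitor
  positive: [DAPI, OLFM4]
  negative: []
- class: enterocyte
  positive: [DAPI, PanCK, NaKATPase]
  negative: []
# first-match order (helper before cytotoxic) resolves CD4+CD8+ double
# positives to helper T under the default policy
- class: helper_t
  positive: [DAPI, CD3d, CD4]
  negative: []
- class: cytotoxic_t
  positive: [DAPI, CD3d, CD8]
  negative: []
- class: cd3_t
  positive: [DAPI, CD3d]
  negative: [CD4, CD8]
- class: b_cell
  positive: [DAPI, CD20]
  negative: []
- class: macrophage
  positive: [DAPI, CD68]
  negative: []
- class: monocyte
  positive: [DAPI, CD11b]
  negative: []
- class: myeloid_other
  positive: [DAPI, Lysozyme]
  negative: []
- class: leukocyte_other
  positive: [DAPI, CD45]
  negative: []
- class: fibroblast
  positive: [DAPI, SMA]
  negative: []
- class: stromal_undetermined
  positive: [DAPI, Vimentin]
  negative: []
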