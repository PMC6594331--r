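---
title: "Methods: fixed-threshold B−G nucleus segmentation and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-threshold B-G nucleus segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukoseg)
```

## The model

On a Wright–Giemsa stained peripheral blood smear imaged in 8-bit RGB, the
dye concentrates in nuclear chromatin and turns it purple: blue strongly in
excess of green. Everything else on a well-prepared smear — pink
erythrocytes, plasma background, pale-blue cytoplasm, and even dye-stain
debris — keeps B − G low. Two empirical bands make this usable as a
segmentation statistic: nucleus (and platelet) pixels sit above 110 while
stain pixels sit below 50, regardless of illumination and staining
variation, because a global intensity change moves B and G together and
cancels in the difference. A *fixed* threshold T0 anywhere in \[50, 100\]
therefore separates nuclear material from everything else at the cost of
one saturating 8-bit subtraction and one comparison per pixel — no
histogram, no per-image threshold search. That speed is the method's point:
it is built for real-time autoscanning, where an Otsu- or clustering-based
segmenter is orders of magnitude slower.

Platelets share the nucleus color but not its size, so they are removed by
a connected-component area filter rather than by color. Localization uses
projection profiles: the first/last nonzero column and row sums of a
nucleus mask give its bounding box, whose integerized midpoint is the
reported center. Width and height are reported as `w = x_r − x_l` and
`h = y_b − y_t` on closed 0-based boxes (a single pixel has `w = h = 0`).

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `t0` | 80 | intensity | B−G binarization threshold; any value in the empirical band \[50, 100\] separates nuclei from stains. 80 is the band midpoint; values outside the band are accepted but warned about. |
| `min_nucleus_area_px` | 500 | px | platelet size filter at nominal 1024×768 magnification; sits between synthetic platelet areas (< 200 px) and lobe areas (> 800 px). Scale-dependent. |
| `connectivity` | 8 | — | component connectivity; 8 keeps lobes joined by thin chromatin strands in one region. |
| `s0` | 2500 | px | largest area a single lobe can have; larger regions are whole nuclei and never merge. |
| `d0` | 60 | px | largest centroid distance at which two small regions are lobes of the same nucleus. |
| `ratio_min` | 0.26 | — | minimum cytoplasm/nucleus area ratio of a genuine leukocyte; strictly below ⇒ artifact. |
| `roi_margin_factor` | 1.5 | — | cytoplasm search window = nucleus bbox scaled by this factor about its center. |

The 110/50 bands and the 0.26 ratio floor are published empirical
constants. S0 and D0 are *not* published ("set by large numbers of
experimental statistics"); the defaults here were fixed once against the
synthetic generator's geometry at 1024×768 and are fully configurable.

## Design choices where the source is ambiguous

* **Saturating subtraction.** "8-bit subtraction" could wrap modularly;
  wrap-around would turn pink erythrocytes (G > B) into bright foreground,
  contradicting the published channel profiles, so `max(B − G, 0)` is used.
* **Inclusive comparisons.** Binarization keeps `D ≥ t0` (so t0 = 50 is
  consistent with stains being *strictly* below 50); the size filter keeps
  area ≥ `min_area`; lobe pairs at exactly `d0` merge. All three boundaries
  are arbitrary at the stated precision and are fixed and tested.
* **Grouping as transitive closure.** The published lobe judgment iterates
  over region pairs "until all regions have been judged", which is
  order-dependent as stated. The order-free completion — single-linkage
  closure of the `D ≤ D0` relation among regions with area ≤ S0 — is what
  "belong to the same nucleus" implies for three or more lobes, and it makes
  the partition invariant under permutation of the region list (tested).
  Regions larger than S0 are exempt from merging but still *emitted* as
  nuclei: the source says they are not lobes, not that they are discarded.
* **Height sign.** The published height formula reads `y_t − y_b`, which is
  ≤ 0 whenever `y_t` is the topmost row in screen coordinates; we treat it
  as a sign typo and report `h = y_b − y_t ≥ 0`.
* **INT as floor.** The "integralization operator" is floor; on the
  non-negative coordinates used here floor and truncation coincide.
* **Accuracy rounding.** Detection accuracy is `100·TP/n`, reported to one
  decimal with half-up rounding. The published per-type table is internally
  inconsistent on this point: 245/246 and 136/138 print as 99.6 and 98.6
  (half-up), while 43/45 prints as 95.5 (truncation). Half-up reproduces
  four of the five printed cells and the printed 97.40 average; the fifth
  cell is treated as a typo in the source.

## Cytoplasm segmentation and the artifact rule

Nucleus-colored debris survives every color/size stage; what it lacks is
cytoplasm. For each located nucleus we segment cytoplasm inside a window
1.5× its bounding box and flag the object as an artifact when
cytoplasm area / nucleus area < 0.26 (strict; equality is kept). The cited
cytoplasm method combines Otsu thresholds on the saturation (S) and blue
(B) components, but *how* they combine is not specified in the source. Our
reading, isolated behind `cyto_method = "s_otsu_minus_nucleus"`:

1. Exclude every already-segmented first-stage foreground pixel (all
   nuclei *and* platelets) from the window's S and B histograms. The
   remainder is approximately a two-class background-vs-cytoplasm
   population — the regime Otsu's criterion is designed for. Without this
   exclusion the nucleus' own high-S mode (or a neighbour's, in clumped
   smears) pulls the threshold above the cytoplasm mode and genuine cells
   lose their cytoplasm.
2. Threshold S and B at their Otsu optima and intersect the two
   above-threshold foregrounds.
3. Require a minimal between-class contrast (mean difference ≥ 15 gray
   levels in both channels), because Otsu *always* produces a split: in a
   window containing no cytoplasm at all (the artifact case) it would
   otherwise split the background noise itself and scattered speckle would
   masquerade as cytoplasm.
4. The cell is the nucleus united with every foreground component touching
   it; cytoplasm is the cell minus the nucleus.

In clumped scenes a neighbour's cytoplasm connected through a touching rim
is counted too; the error is upward only, which can only *keep* a genuine
cell, never reject one. The same S/B thresholding over the whole image
(no exclusion, no nucleus to anchor on) is exposed as
`segment_nucleus_sab()`, the per-image-Otsu comparator the fixed-threshold
method is benchmarked against.

## What the synthetic generator emulates — and what it does not

`generate_scene()` renders the *stated world* of the method: the color
geometry of a stained smear, not its photometric realism.

* **Palette bands.** Pre-noise, nucleus/platelet material has B − G in
  \[140, 165\], stains in \[13, 37\], cytoplasm in \[30, 37\], and
  erythrocytes/background have G − B ≥ 5. Pixel noise is Gaussian with
  σ = 3, *truncated at ±2σ* per channel; with these sub-bands the post-noise
  image satisfies the >110 / <50 separability bands *by construction*
  (truncation matters: unbounded noise would violate them with positive
  probability, and the separability guarantee is stated as exact).
* **Geometry.** Nuclei are unions of 1–5 elliptical lobes (single lobes
  908–2124 px, chain lobes 848–1244 px, all above the 500 px size filter
  and below S0). Multi-lobe nuclei are generated in two variants —
  connected by thin chromatin bridges, or deliberately disconnected with
  consecutive centroids ≤ 57 px apart — so both the connectivity path and
  the D0-grouping path are exercised. Lobes of *different* cells are kept
  ≥ 63 px apart (> D0) and nuclei never overlap: the method itself assumes
  non-overlapping leukocytes, and the clumped mode places cells with
  touching cytoplasm but disjoint nuclei to probe exactly that boundary.
* **Cytoplasm.** Each leukocyte gets a pale-blue rim (scaled-lobe union)
  with planted cytoplasm/nucleus ratio ≥ 0.42 (target 0.5–0.9), i.e. safely
  above the 0.26 floor; artifacts get the nucleus palette and no rim.
* **Illumination.** A per-scene channel offset in ±20 is supported, with
  the B and G offsets constrained equal — an unequal shift would destroy
  the very B−G invariance the method relies on, and the generator refuses
  to claim palette compliance it cannot deliver.

Not emulated: optical blur and focus variation, chromatic staining
gradients within one cell, textured chromatin, touching/overlapping nuclei,
camera vignetting. A green test on synthetic scenes therefore establishes
the *logic* of every stage (thresholding, filtering, grouping,
localization, ratio arithmetic) and the self-consistency of the whole
pipeline; it does not establish clinical segmentation accuracy, which in
the source is measured on hospital images unavailable here.

## Numerical and degenerate-input conventions

* Otsu's threshold maximizes between-class variance over all 256 splits;
  ties take the smallest threshold; a single-bin histogram returns that bin
  flagged degenerate. Equality with an exhaustive-search oracle is tested
  on random histograms.
* Connected-component labels are assigned in raster-scan order, so
  labelings are deterministic and comparable across implementations.
* An empty mask is a domain error for localization (there is no box to
  report); a zero-area nucleus is a domain error for the ratio rule; a
  degenerate cytoplasm window (constant channels, or no non-nucleus
  pixels) yields cytoplasm area 0 without error.
* Images are 8-bit throughout; 16-bit inputs are rejected rather than
  silently rescaled. Label masks serialize as 16-bit PNG (≤ 65535 labels).
* The whole pipeline is a pure function of (image, configuration): rerunning
  it byte-identically reproduces its outputs, which is tested.

## Known limitations

* Genuinely overlapping nuclei are out of scope (watershed-style splitting
  is deliberately absent); the method's own applicability claim is limited
  to smears where leukocytes do not overlap.
* S0 and D0 are calibration constants; at magnifications other than the
  nominal 1024×768 frame they must be rescaled by the user.
* The artifact rule assumes cytoplasm is *visible* around a genuine cell;
  a leukocyte whose cytoplasm is fully occluded would be rejected.
* Leukocyte *classification* (Neu/Lym/Mon/Eos/Bas) is not implemented;
  `count_report()` consumes labels produced elsewhere (on synthetic data,
  from ground truth).
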