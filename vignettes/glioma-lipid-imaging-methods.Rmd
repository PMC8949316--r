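---
title: "Methods: imaging lipidomics of glioblastoma proliferative regions"
author: "glioLipidIMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging lipidomics of glioblastoma proliferative regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioLipidIMS)
```

# Overview

`glioLipidIMS` implements, end to end, the analysis of a MALDI imaging mass
spectrometry (IMS) lipidomics study of human glioblastoma (GBM): sections of
healthy and tumor tissue, incubated with or without temozolomide (TMZ), are
imaged pixel by pixel; pixels are clustered by lipid profile; the cluster
overlapping the proliferative (MKI67+) region of interest is selected; and
lipid class and species compositions are compared between study arms. The
transcriptional side mirrors the companion in-silico analysis: co-expression
modules over molecular subtypes (Classical, Mesenchymal, Proneural, Neural,
plus normal samples), module–subtype enrichment, survival stratified by
lipid-enzyme expression, and methylation–expression coupling.

Because no raw patient spectra or processed matrices are publicly deposited
for this kind of study, the package ships a synthetic-data generator whose
defaults are parameterized to the published summary numbers, giving every
downstream stage a ground truth to be tested against.

# Lipid mass arithmetic

Lipids are handled at *sum composition* resolution: class plus total chain
carbons and total chain double bonds (e.g. PI 38:4). The elemental formula of
such a species is a closed-form function of the totals; no sn-1/sn-2 isomer
needs to be resolved, and any chain split gives the same formula. Per-class
rules are verified in the tests against an independent backbone-enumeration
oracle that assembles the molecule from glycerol, fatty acids, sphingoid
bases and headgroups with one water per condensation.

Two conventions matter:

* **PE plasmalogens (`PE_P`)** carry the 1-O-alk-1'-enyl (vinyl ether)
  linkage: relative to the diacyl PE of the same shorthand, one oxygen fewer
  with the same hydrogen count (the ether linkage adds 2 H, the vinyl double
  bond — which the shorthand does not count — removes them). Plasmanyl
  (O-alkyl) species are not modeled separately: in brain, PE ether lipids
  are overwhelmingly plasmalogens.
* **Sphingolipids** (SM, sulfatide, hexosylceramide, ceramide) depend on the
  sphingoid hydroxylation: `d` (dihydroxy) or `t` (trihydroxy), written as
  in `SM d36:1`, `Sulf t42:1`. The listed double-bond count includes the
  sphingoid base's.

Monoisotopic element masses live in one constants table (6 decimals); proton,
sodium and potassium cation masses fold in the electron mass. Adduct policy
follows standard MALDI brain-lipid practice: `[M−H]⁻` for PE, PE P-, PI, PS,
PG and sulfatides in negative mode; `[M+H]⁺` (optionally `[M+Na]⁺`/`[M+K]⁺`)
for PC, SM, hexosylceramide, ceramide and DG in positive mode.

## The default panel

The packaged panel (`defaultLipidPanel()`) holds **124 species over 11
classes**, the scale reported for this tissue, and includes every species the
study's results name. The exact species list is a reconstruction — the
original database of >30,000 candidates is not enumerable from the published
material — so the panel was curated once with two constraints: realistic
brain species (even-numbered chains, C32–C44) and same-polarity mass spacing
above 70 ppm. The spacing makes sum-composition annotation on this panel
unambiguous at the default 9 ppm tolerance; on denser panels the annotator
flags every assignment with other in-tolerance candidates as `ambiguous`
(tandem-MS disambiguation is out of scope, so ambiguity must stay visible).

## Annotation tolerance

The default tolerance of 9 ppm is the instrument's stated worst-case mass
accuracy; typical accuracy is better than 3 ppm, which is the default mass
jitter of the generator. With jitter bounded at 3 ppm and panel spacing over
70 ppm, every simulated peak re-annotates to its generating species — a
round-trip property the tests assert.

# Synthetic sections

`simulateSection()` emulates one tissue section in one ion mode on a pixel
grid (default 60 × 60, 50 µm raster semantics):

* an elliptical tissue area covers 80% of the grid (the rest are matrix-only
  background pixels);
* a contiguous blob of 20% of the tissue pixels is the planted proliferative
  region (compact, like MKI67+ zones; 10–30% is the plausible range and the
  fraction is a parameter);
* every tissue pixel carries one peak per panel species of that mode:
  intensity `class share × species fraction × LogNormal(0, σ)`, m/z jittered
  uniformly within ±3 ppm;
* background pixels carry 5–20 uniform-random "chemical noise" peaks with
  ~1% of a tissue pixel's TIC, so background filtration and the presence
  filter are exercised non-trivially.

Intensity noise is multiplicative log-normal because MALDI intensity
variation is positive and heteroscedastic; σ = 0.3 is the default study
condition. All draws flow from one integer seed; reruns are identical.

## Composition profiles

The packaged composition configuration (`lipidomeProfiles()`, YAML in
`inst/extdata/`) defines, per study arm, class shares of TIC per ion mode
and within-class species mole percentages. The class shares are chosen so
that, **after TIC normalization**, the planted ratios equal the published
fold changes exactly: GBM vs healthy PE ×1.5, PI ×3.6, SM ×1.8, sulfatide
÷2.9; TMZ vs vehicle healthy PI ×2.2, HexCer ÷1.8, sulfatide ÷1.6. Because
normalized shares must sum to one, the classes with no reported change (PS
and PG in negative mode; PC, ceramide and DG in positive mode) absorb the
complement — an unavoidable compositional constraint that mirrors how
closure affects the real measurements as well. Species tables carry the
printed mole percentages (PI 38:4 at 54.9% healthy / 75.7% GBM / 80.4%
TMZ-treated healthy, PE 36:1 at 35.6% healthy, PE P-36:2 at 20.8% healthy,
and so on); panel species not named share the class remainder equally.

The surrounding non-proliferative tissue uses a separate, clearly distinct
white-matter-like profile (`bulk_parenchyma`: sulfatide/HexCer-rich,
long-chain species dominant). It is a synthetic design choice, not a
measured composition, and exists so that segmentation has two genuinely
different tissue populations to separate.

Group sizes default to 5 sections per arm, matching the study's n = 4–5
(figure legends alternate between the two; 5 was fixed once for all
defaults).

# Processing and segmentation

* **Alignment** is greedy centroid clustering along the sorted global peak
  list: a new consensus bin opens when a peak's ppm gap to the running
  intensity-weighted bin centroid exceeds the tolerance. Within a bin each
  pixel contributes its maximum-intensity peak (centroided data should hold
  at most one true peak per species).
* **TIC normalization** divides each pixel by its summed intensity over kept
  features; pixels with zero annotated intensity are dropped with a logged
  count. Normalization is idempotent.
* **Presence filter**: a feature counts as present in a sample when detected
  in at least 1% of that sample's analyzed pixels (the published analysis
  never defines "present"; 1% is exposed as a parameter), and features
  present in at least ⌈0.8 n⌉ of the n samples are retained ("at least
  80%", hence the ceiling). "Samples" are sections; patients or pixels would
  be alternative units and the function accepts any grouping.
* **Background filtration** removes pixels whose raw TIC (computed before
  annotation, over all peaks) falls below 10% of the median pixel TIC.
* **Segmentation** is k-means (10 restarts, seeded) on TIC-normalized
  feature vectors with Euclidean distance; `log1p` intensities are available
  as an option. The published analysis used a proprietary hierarchical
  region-clustering algorithm that is not described in reproducible detail;
  k-means stands in behind the same interface, and only the grouping of
  lipid-similar pixels matters downstream. The segment count ranges over
  2–8 (the wider of the two ranges the study states) and is selected by
  maximum mean silhouette, computed on a seeded subsample of at most 500
  pixels to keep the distance matrix small.
* **ROI matching** replaces visual inspection with the Dice coefficient
  2|A∩B|/(|A|+|B|) between each cluster and the ROI mask; the argmax cluster
  is selected, ties break toward the larger cluster and are logged.

# Composition statistics

Pixel vectors are averaged within the selected cluster per section; class
share is the class sum over the section's TIC and species values are
percentages of their class total. These within-class percentages are called
mole% by convention, but they are intensity shares — MALDI intensities are
not molar-corrected, and ionization efficiency differs across classes, so
comparisons are meaningful only within a class. Sections (not pixels) are
the biological replicates in all between-group statistics, avoiding
pseudo-replication.

Group comparisons use the two-sample Student t-test by default (the source
analysis states only "t-test"; Welch is a switch), report fold changes as
group2/group1 with decreases displayed as "x-fold decrease", star p < 0.05 /
0.01 / 0.001 on raw p-values as published, and additionally emit a
Benjamini–Hochberg column for transparency without using it for stars.
Species averaging under 5% in both groups are flagged out of display,
mirroring the figures. PCA is computed on z-scored features without using
group labels; group separation is quantified by the silhouette of the groups
in the PC1–2 plane (replacing "clear visual separation" with a number).

# Expression, modules and enrichment

`simulateExpressionStudy()` generates a genes × samples matrix over the five
subtype labels. Planted module genes follow

```
expr = effect * ((subtype indicator) - p + 2 * activity) + N(0, 1)
```

where `activity` is a per-sample latent module factor, centered within
subtype groups. Two deliberate choices:

* The *same* effect parameter scales both the subtype mean shift and the
  latent factor. A mean shift alone of 1.5 z-units yields within-module
  correlations near 0.26, which no threshold-9 unsigned network can detect;
  with the factor, effect 1.5 gives correlations near 0.9, effect 0 gives
  exactly no structure, and detectability rises monotonically in between —
  the behavior the planted-truth tests require.
* Centering the factor within subtypes keeps subtype contrasts attributable
  solely to the planted effect, so enrichment ranking is not corrupted by
  factor noise shared across a module.

Module detection reconstructs the published network recipe: adjacency
|Pearson r|^β with β = 9 (unsigned, the tool's default), dissimilarity 1 −
adjacency, average-linkage hierarchical clustering cut at 0.8, clusters
below the minimum size (30) pooled as "not correlated", modules with
eigengene correlation above 0.9 merged ("similar modules were merged" is all
the source states; 0.9 is this package's choice), eigengene = first
principal component over samples, hubs = highest intramodular connectivity.
An optional variance filter before network construction is not applied by
default, since the original tool's filtering settings are unstated.

The module–subtype normalized enrichment score is a reconstruction of GSEA
semantics: genes ranked by mean z-scored expression in the subtype's
samples; weighted Kolmogorov–Smirnov running sum (weight exponent 1); NES =
ES / mean|ES| over 1000 size-matched random gene sets; p from the
permutation tail with BH correction across module × subtype cells. The
enrichment statistic itself is cross-checked in the tests against an
independent implementation (`fgsea::calcGseaStat`). Gene-set permutation
(rather than phenotype permutation) was chosen because it is exactly
reproducible under a seed and appropriate at these sample sizes.

# Survival and methylation

Survival times are exponential with log-hazard proportional to the z-scored
expression of the five planted risk genes (PLA2G5, FABP7, ELOVL2, PLA2G2A,
ALOX5AP — the genes the study links to poor overall survival), censored at a
fixed horizon; baseline median survival defaults to 450 days, in the range
reported for GBM. Kaplan–Meier estimation and the two-group log-rank test
wrap the survival package; the expression split is at the median with ties
to the low group (the original browser tool's cut-point is unstated; the
quantile is a parameter). Disease-specific survival is the same machinery on
a second event column. Subtype comparisons of expression and methylation use
ordinary one-way ANOVA with Tukey HSD, as published. Methylation betas for
the three coupled probes are `plogis(-1.5 z + noise)`, anticorrelated with
expression as the published figures show.

# Numerical choices and degenerate inputs

* Zero-variance features are dropped with a warning before PCA z-scoring and
  before network construction.
* A zero-variance, equal-mean two-group comparison returns p = 1 by
  convention; a no-event log-rank likewise.
* Dice ties select the larger cluster (logged); silhouette below 0.1 during
  segmentation warns of weak structure.
* All seeds are 32-bit integers; child seeds are derived arithmetically so
  that arms and sections never share a stream.
* The presence filter, annotation and alignment are deterministic; k-means
  and all generators are deterministic given their seed.

# Problem sizes

Defaults were fixed once to keep a full desk-scale study tractable: sections
of 60 × 60 pixels (3,600 spectra, ~124 peaks each), 5 sections per arm,
expression studies of 600 genes × 100 samples, 1000 gene-set permutations
per NES cell (200 in the orchestrated pipeline default). The complete
two-arm pipeline including the transcriptome stages runs in well under a
minute; the test suite exercises reduced grids where full size adds nothing.

# What passing tests do and do not show

The generator reproduces the *statistical skeleton* of the real study:
compositional fold changes and mole percentages, compact ROI geometry,
multiplicative intensity noise, ppm-scale mass error, planted co-expression
and survival structure. It does not emulate isotope envelopes, peak shapes,
matrix cluster chemistry, intra-class ionization bias, spatial intensity
gradients, batch effects between ion modes, or the histological complexity
of infiltrative tumor margins. Recovery of the planted parameters therefore
validates the pipeline's correctness and calibration — not the biological
claims, which only real spectra could test. Class-share fold changes are
also subject to compositional closure: a "3.6-fold PI increase" in
TIC-normalized data is interpretable only alongside the behavior of the
other classes, which is why the packaged profiles pin the unchanged classes
explicitly.
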