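---
title: "From multi-omics tables to images and back: the pixelomics method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-omics tables to images and back: the pixelomics method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pixelomics)
```

## The problem

Drug-response panels and similar multi-omics studies produce a handful of
aligned numeric tables — gene expression, copy-number alteration (CNA) and
somatic mutation status over the same genes and samples — with dimensionality
d in the tens of thousands and sample counts n in the hundreds. Classical
tabular learners treat each gene as an independent coordinate and struggle in
this d >> n regime. pixelomics takes the image route instead: genes are
arranged as points in a 2D frame so that *similar genes become neighboring
pixels*, each omics layer is painted onto the same pixel locations as one
color channel, and the resulting p x q x L tensors are classified with a
convolutional network. Convolutions then exploit the engineered spatial
coherence, and the decision can be decoded back to genes through
class-activation maps (CAMs).

## The transform

Given an aligned dataset M = {M_1, ..., M_L} of d x n layers:

1. **Element arrangement.** The training portion of one layer (or a
   concatenation, see modes below) is embedded gene-wise into the plane: the
   genes are the observations, the training samples the features. t-SNE
   (exact, cosine distance) is the default; UMAP, Gaussian kernel PCA and PCA
   are available. Only training samples may be used — the layout is part of
   the fitted model.
2. **Minimum-area bounding rectangle.** Computed over the convex hull by
   rotating calipers (the optimal rectangle has a side collinear with a hull
   edge). Ties between equal-area candidates go to the smallest non-negative
   angle, collinear clouds fall back to a unit-thickness padded segment, so
   the step is total and deterministic.
3. **Rotation.** A rigid rotation aligns the rectangle with the axes;
   pairwise distances are preserved to machine precision.
4. **Quantization.** Coordinates are binned into a p x q integer frame
   (default 64 x 64 for the bundled scenario; 224 x 224 reproduces the input
   contract of large pretrained backbones) with half-open bins and the
   extremes pinned to the frame edges. Pixel coordinates are 0-based,
   row-major, row 0 at the top.
5. **Normalization ("norm-2").** Per layer, on training samples only:
   y = ln(x - min_train + 1), then min-max to [0, 1] using the training
   extremes of y; held-out values are clipped into the training range. A
   layer that is constant on the training samples normalizes to all zeros
   with a warning (this arises naturally in late iterative stages).
6. **Mapping.** Every gene deposits its normalized value at its pixel;
   co-located ("batch") genes are averaged; empty pixels stay 0. The same
   pixel locations are reused for every layer, which is what lets channel c
   of the image carry layer c while keeping genes spatially aligned across
   channels.

Two arrangement modes are provided. **Dominant** (default): the layout is
computed once from the most informative layer, typically expression.
**Equal contribution**: each layer is embedded separately and the per-gene
concatenation of all stage-1 coordinates (a 2L-dimensional point per gene) is
embedded again with the same method. The two-stage combination rule is a
design choice of this package: the upstream literature specifies only that
the arrangement is performed twice, so the rule is isolated behind the
`mode` flag and recorded in the pixel map metadata.

## Mutation-layer propagation

Somatic mutation calls are extremely sparse binary vectors; fed directly into
a CNN channel they mostly produce dead inputs. The package densifies them by
guilt-by-association over a protein-protein interaction network using the
diffusion state distance (DSD): He_b(u) is the expected visit-count profile
of a b-step simple random walk from node u (counting the start visit), and
DSD(u, v) = ||He_b(u) - He_b(v)||_1, an L1 metric. Per sample, mutated genes
keep the maximal score 1; every other in-network gene receives the inverse
DSD to its closest mutated gene, normalized by the largest finite inverse
among non-mutated genes and scaled to [0, 0.99] so that true mutations remain
strictly on top; genes disconnected from every mutated gene score 0 and
off-network genes keep their raw value. The walk length defaults to b = 7
steps — exact, cheap and directly testable against walk enumeration — with a
closed-form converged variant (`steps = "converged"`) behind a flag. Edge
weights are ignored for transition probabilities by default (uniform over
neighbors), with a weighted option, since interaction confidences need not
reflect walk propensities. The original binary layer is retained alongside
the propagated one (suffix `_raw`) for audit.

## Classifier

The bundled architecture is a deliberately small CNN: three 3x3
convolution blocks (8, 16, 32 channels, ReLU, 2x2 max-pooling), global
average pooling (GAP) and a linear softmax head, trained with SGD
(momentum 0.9, L2 weight decay 1e-4, learning rate 0.05, 30 epochs,
batch 16 by default). It is implemented in vectorized base R (im2col +
BLAS), is exactly reproducible under a seed, and trains on the bundled
scenario in about a minute on one CPU. The GAP head is not incidental: it
makes the CAM decomposition exact, since each class logit is the spatial
mean of the classifier-weight-weighted sum of the final activation
channels. The tunable hyperparameters exposed for search are the paper
trio — initial learning rate, momentum, L2 — via a pluggable
budget-limited search (`hyperparameter_search()`, random search by
default) that returns the configuration with minimal validation error.
The learning rate default of 0.05 was chosen once as the smallest rate at
which the GAP architecture reliably leaves its plateau within the default
epoch budget on the bundled scenario.

Large pretrained backbones (e.g. 224 x 224 x 3 residual networks) are part
of the upstream experimental setup but are not bundled: no deep-learning
framework ships with this package's dependency set, and the desk-scale
network is the supported classifier. The input-resize contract is still
honored — images whose frame differs from the configured `input_size` are
bilinearly resized on the way in.

Label handling follows the drug-response convention: continuous logIC50
values are split at the median (balanced classes; values equal to the
threshold go to the non-respondent class, a fixed tie rule) or at the mean
as a fallback. The training pool is split 90:10 into training and validation
(train = floor(n x ratio) per class when stratified, at least one validation
sample per class); augmentation generates synthetic samples as the
elementwise mean of two distinct same-class images, with the factor
config-exposed because the upstream protocol does not state a magnitude.
Pixel map, normalization and augmentation only ever see the training
portion.

## CAM gene selection

For a training image e_j and class c, the raw CAM is the weighted channel
sum of the last ReLU activation block, w_c' A. Two refinements make the maps
decodable in practice:

* **Zero-input baseline.** An empty image produces a non-zero constant map
  from the biases alone; this baseline is subtracted so "no evidence"
  anchors at zero, and negative values — evidence *against* the class — are
  clipped. Without this, a class that the network encodes purely as the
  absence of the other class's signal (a common solution for two-class
  softmax heads) yields a map whose min-max normalization assigns high
  values to background pixels, and thresholding selects almost every gene.
  With it, such a class contributes a near-zero map and few or no genes.
* **Shared evidence scale.** For selection, per-sample maps are kept on a
  common scale ("evidence" mode), class averages avgR_i are computed as
  plain arithmetic means, and the averages are jointly rescaled so the
  strongest class average peaks at exactly 1. The red-zone threshold
  (default 0.6, config-exposed; the upstream per-drug values are not
  public) then reads as "fraction of the maximal class evidence" — the
  shared color scale under which a heat-map's red zone is defined. For
  standalone visualization, `compute_cam()` defaults to the conventional
  per-map min-max normalization instead, with flat maps normalizing to all
  zeros.

The mask is the strict comparison avgR_i > threshold; the element decoder
returns every gene whose pixel lies in the mask (all members of a batch
pixel together), per class; the final subset is the union over classes, with
per-class counts reported. Selection can be iterated: each stage re-runs the
full pipeline (arrangement, mapping, training, CAM, decoding) on the genes
selected by the previous stage, training a fresh model because the input
dimensionality changes; stages stop early with a notice when fewer than 3
genes remain.

Selected subsets are tested for pathway over-representation with one-sided
Fisher exact tests (the upper hypergeometric tail) against a GMT collection,
Benjamini-Hochberg corrected. The universe defaults to the dataset's gene
space — the space selection actually operated on — rather than the union of
the collection.

## The synthetic study conditions

`synthetic_scenario()` defines the self-contained benchmark every stage is
tested on: two classes (NR/R) of 60 samples each, d = 600 genes, a planted
module of m = 40 genes, three layers. Expression is Gaussian (mean 6, SD 1,
non-negative scale so the log normalization is exercised without guards)
with a delta = 3 SD mean shift on the module in the R class; CNA is an
integer-discretized correlated copy of the same contrast (dosage calls
clipped to [-2, 2]); mutation is Bernoulli background at rate 0.02, enriched
to 0.3 on the module in the R class; a logIC50-like continuous response
(lower in respondents) accompanies the labels. A toy interaction network
(scale-free by default; lattice and path available) places the planted genes
on a connected neighborhood so DSD propagation forms hotspots. All
randomness derives from the single scenario seed; the 64 x 64 frame and
these sizes were fixed once so that a full pipeline run takes on the order
of a minute on a single CPU while preserving the d >> n character of the
real problem.

What the generator does *not* emulate: realistic expression marginals and
gene-gene correlation beyond the planted module, dosage segmentation
structure in CNA, mutual exclusivity patterns in mutations, and batch
effects. Passing the bundled checks therefore demonstrates that the
machinery recovers a planted signal under controlled conditions, not that it
reproduces any particular clinical benchmark.

## Numerical choices and degenerate inputs

* Quantization uses floor with an edge guard so the maxima land exactly on
  row/column p-1, q-1; an all-coincident cloud maps to a single pixel.
* Rectangle ties (exact squares) resolve to the smallest angle in
  [0, pi/2); hull degeneracies fall back to the segment direction.
* Collision averaging is exact (sum / count, verified against brute-force
  grouping); empty pixels are 0, which doubles as the CNN background value.
* Binarization refuses all-identical responses; splits refuse single-sample
  classes under stratification and suggest the non-stratified path.
* t-SNE perplexity defaults to min(30, (d - 1) / 3) so small stage-2 gene
  sets remain embeddable; the distance is config-exposed (cosine default).
* Max-pooling breaks ties by first-window-position, making training
  bit-reproducible under a seed; all stochastic steps (embedding,
  initialization, shuffling, splits, augmentation pairs, search) consume
  explicit seeds derived from the run seed.
* AUC uses the rank (Mann-Whitney) statistic with ties counted half;
  the confusion matrix is taken at probability 0.5.

## Problem sizes used by the bundled checks

The test suite exercises the full pipeline at the default scenario
(d = 600, m = 40, n = 120, 64 x 64 frame, 30 epochs) over five seeds for the
planted condition and five for the signal-free null, plus many small
fixtures (toy graphs up to 15 nodes for the DSD metric suite, <= 100-gene
frames for the collision oracle, 200-gene universes for the enrichment
oracle). `scripts/acceptance.R` re-runs the planted condition on five seeds
and the null on three, reporting medians.

## Known limitations

* The desk-scale CNN is the only bundled classifier; transfer learning from
  pretrained image backbones is out of scope here.
* The equal-contribution stage-2 rule is one defensible reading of a
  two-stage arrangement; alternatives (e.g. averaging per-layer layouts)
  would be legitimate and are not implemented.
* DSD is computed densely per connected component (O(v^3) in component
  size), appropriate for dataset-restricted subgraphs rather than full
  interactome-scale graphs.
* CAM localization is limited by the resolution of the last activation
  block (a factor-8 upsampling at the default depth); very tight red zones
  can land between occupied pixels and select few genes — the iterative
  mode and a lower threshold are the remedies.
* Two-class problems are the tested target; the code paths are written for
  c >= 2 but multi-class selection behavior is not benchmarked.
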