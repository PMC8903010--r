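---
title: "Classifying CTCF–CTCF interaction topologies and calling loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CTCF–CTCF interaction topologies and calling loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Most Hi-C loop analyses either average the signal around a list of candidate
anchor pairs (aggregate peak analysis) or call loops by testing individual
matrix cells against a background model. `hicloops` takes a different route:
it *classifies* the interaction pattern of every candidate CTCF–CTCF pair
instead of averaging over them, and then uses the discovered pattern classes
to train a supervised loop caller.

The pipeline, end to end:

1. **Peak preparation.** CTCF ChIP-seq peaks are intersected across
   replicates, annotated with the strand of their best binding motif
   (`p < 0.05`, strict), and reduced to *isolated* peaks — those with no
   neighboring peak center strictly within 50 kb — so that each submatrix
   reflects a single CTCF–CTCF pair.
2. **Pair enumeration and submatrix extraction.** All same-chromosome pairs
   of isolated peaks separated by 45 kb–1.5 Mb (inclusive) are enumerated
   and a 9×9 window at 5 kb resolution is cut from the contact matrix,
   centered on the two anchor bins (row axis: upstream anchor; column axis:
   downstream anchor).
3. **Value transform.** Each window is z-scored over its own 81 cells and
   passed through the logistic function, mapping it into (0, 1). The
   transform is rank-preserving per window and removes depth differences, so
   downstream classification responds to interaction *shape* only.
4. **Self-organizing feature map.** The transformed 81-vectors train a
   Kohonen grid. Each sample's best-matching unit (BMU) is the neuron with
   the nearest weight vector (Euclidean); all neurons within Chebyshev grid
   distance `learning_radius` of the BMU move toward the sample by
   `step * exp(-d²/(2·std²))`, `d` being Euclidean grid distance. Three
   selection metrics summarize a trained map: the percentage of samples in
   non-singleton neurons, the mean pairwise distance between occupied-neuron
   weights, and a compartment segregation score (mean absolute per-neuron
   average of the anchor compartment eigenvalues).
5. **Neuron clustering.** Occupied neurons are summarized by a
   representative submatrix, embedded in 2-D with a fuzzy k-nearest-neighbor
   manifold layout (neighborhood 6, minimum embedded distance 0.3, 100
   epochs), and grouped by hierarchical density clustering (minimum cluster
   size 6, minimum samples 6, noise allowed). Clusters are numbered by
   descending central-pixel intensity of their medoid, so cluster 1 is the
   most loop-like and the last cluster the flattest.
6. **Loop caller.** A feed-forward network — 81 inputs, a 1024-unit ReLU
   layer, dropout 0.2, and a 4-unit softmax with no bias on the final layer
   (88,064 trainable parameters) — is trained on balanced loop/no-loop sets
   drawn from the loop-like and flat cluster sides (80/20 train/test split).
   Calling scans a chromosome with a 9×9 window at step 1 over the 45 kb –
   1.5 Mb band, transforms each window exactly as at training time, records
   the loop-class probability, thresholds it (default 0.9), groups
   above-threshold cells into 8-connected components, and emits one call per
   component at its maximum-probability cell.
7. **Benchmarks.** Reproducibility is measured with the exact-anchor Jaccard
   index (and a loose variant with ±k-bin greedy one-to-one matching);
   biological relevance with chromatin-state categories at the anchors
   (promoter–enhancer, heterochromatin–heterochromatin, "not expected") and
   the fraction of calls with convergent CTCF motifs (a "+" motif in the
   upstream anchor bin and a "−" motif in the downstream bin).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| pair separation | 45 000–1 500 000 | bp | brackets typical TAD-scale loops; also the scanning band (9–300 bins at 5 kb) |
| isolation window | 50 000 | bp | one CTCF pair per window; strictly-within exclusion, ties at exactly 50 kb kept |
| motif significance | 0.05 | p-value | strict `<`; the lowest-p motif sets a peak's strand |
| SOFM grid | 30×30 | neurons | the standard map (900 neurons); toy-scale runs in this package use 12×12 |
| learning radius / std / step / epochs | 5 / 0.5 / 0.01 / 30 | grid units / – / – / – | the standard training schedule; constant across epochs |
| embedding | 6 / 0.3 / 100 | neighbors / min dist / epochs | density-clustering pre-processing |
| density clustering | 6 / 6 | min cluster size / min samples | smallest acceptable neuron group; smaller groups become noise |
| training set | 6000 + 6000, 20% held out | submatrices | balanced classes; capped at the smaller side when data are scarce |
| dropout | 0.2 | – | regularization for an 88k-parameter model |
| call threshold | 0.9 | probability | high-precision calling; exposed as a flag |

## What the synthetic generator emulates — and what it does not

`synthetic_spec()`/`simulate_contacts()` build one chromosome as a power-law
distance decay (`scale · d^-α`, default α = 1) plus, optionally: planted
loops (2-D Gaussian bumps at chosen anchor-bin pairs, amplitude expressed
most usefully via `decay_value()` as a multiple of the local background), a
checkerboard A/B compartment structure (same-parity blocks scaled 1.5×,
which yields clean eigenvector sign recovery at toy scale), and
multiplicative log-normal noise (positive, right-skewed, unit mean —
matching the gross error structure of normalized Hi-C counts).
`simulate_ctcf_world()` composes a full study world: stranded peaks with
isolated spacing, convergent pairs, and loops planted on a configurable
fraction of them with amplitudes 4–10× background and per-loop widths of
0.8–1.8 bins. The defaults encode a chromatin landscape in which a majority
of convergent, isolated CTCF pairs loop — consistent with loop-extrusion
expectations for this selected class of pairs — and with heterogeneous loop
strength and focal width, which is what spreads loop submatrices over
several neurons of the map.

The generator does **not** emulate: TAD-scale block structure and corner
stripes, anchor-sharing stripe artifacts, coverage heterogeneity or unmappable
bins, trans contacts, or replicate-level biological variability. Passing
tests on these worlds therefore demonstrates that the machinery is correct
and recovers planted signal under realistic noise — not that the caller's
precision/recall will transfer unchanged to real Hi-C maps.

## Numerical choices

* **The sigmoid transform** is per-window z-score (sample sd, `n−1`)
  followed by the logistic map. A constant window has no shape information
  and maps to all 0.5. This is the single most consequential
  under-determined step in the method and is isolated in one function
  (`sigmoid_transform()`), so alternates (global scaling, log-then-logistic)
  can be swapped without touching anything else.
* **Observed/expected**: the expected value at distance *d* is the mean over
  valid bin pairs on that diagonal; bins with zero marginals are masked
  before both the expected means and the correlation matrix. Every valid
  diagonal of O/E averages to 1 by construction. Correlation columns with
  zero variance are set to zero correlation. The leading eigenvector is the
  one with the largest-magnitude eigenvalue; its share of the total absolute
  spectrum is reported, with a low-confidence flag below 10%.
* **Eigenvector sign** is arbitrary; orientation requires a user-supplied
  per-bin reference (e.g. active-state density) and flips the vector so the
  correlation with the reference is positive. Without a reference the track
  is flagged un-oriented.
* **SOFM schedules**: step and radius are constant across epochs; the
  neighborhood cutoff is Chebyshev (square neighborhoods on the grid) while
  the Gaussian factor uses Euclidean grid distance; both metrics are
  exposed. BMU ties break to the lowest neuron index. Weight init is uniform
  (0, 1) from the seed, matching the transformed data range; the update rule
  keeps weights in (0, 1) for step ≤ 1.
* **Neuron representatives**: `neuron_medoids()` returns an actual member
  submatrix (display and summaries); `neuron_means()` returns the per-neuron
  average. The *clustering* path uses the means: a medoid of a flat neuron
  is a single noisy sample, and at toy scale a set of such medoids is
  mutually equidistant 81-dimensional noise that no density clusterer can
  separate, whereas the means concentrate tightly by pattern class.
* **Embedding**: the fuzzy graph uses locally adaptive kernels (bisection to
  `log2(k)` neighbor mass) with probabilistic-union symmetrization, and the
  attraction/repulsion curve parameters are fitted from `min_dist` at run
  time. Layout updates are applied in deterministic per-epoch batches with
  edge weights as multipliers (rather than stochastic per-edge scheduling),
  with PCA initialization — reproducibility from the seed alone was
  prioritized over fidelity to any particular reference implementation.
* **Density clustering** follows the condensed-tree construction: core
  distances at `min_samples` (self included), mutual-reachability
  single-linkage (via `hclust`), condensation at `min_cluster_size`, and
  excess-of-mass selection. The root (born at λ = 0, hence with inflated
  mass) is only eligible when the tree contains no true split, so a single
  dense blob yields one cluster while any genuine split is honored.
* **The caller network** keeps two printed quirks verbatim: four softmax
  output units for a two-class problem (classes occupy units 1–2; units 3–4
  are never targets) and no bias on the final layer, which is what makes the
  parameter count exactly 81·1024 + 1024 + 1024·4 = 88,064. Training
  specifics left open by the source method are fixed as: Adam (default
  rate 10⁻³), batch 64, 20 epochs, inverted dropout, all seeded.
* **Call grouping**: 8-connected components over above-threshold cells; the
  call sits at the component's maximum, ties resolved to the smallest
  `(bin_i, bin_j)` lexicographically.
* **Loose Jaccard matching** is greedy one-to-one in ascending anchor order;
  at tolerance 0 it reduces exactly to the exact-anchor index.
* **Coordinates**: BED-style 0-based half-open positions everywhere;
  `bin = floor(position / resolution)`.

## Problem sizes used by the test suite

The packaged checks run the whole chain at desk scale: two training
chromosomes of 600 bins at 5 kb (~3 Mb each, ~40 isolated peaks, ~600
pairs per chromosome), a 12×12 map with neighborhood std 1.0, and a separate
600-bin evaluation chromosome with 10 planted loops of amplitude ≥ 5× the
local background. The broader neighborhood (std 1.0 instead of 0.5) and the
smaller grid are scale choices: with a few hundred submatrices of limited
diversity, the standard 30×30/0.5 configuration degenerates to
winner-take-all dynamics in which every loop maps to one neuron, leaving the
neuron-level clustering nothing to work with. The standard parameters remain
the package defaults for realistically sized data.

## Known limitations

* The embedding and density clustering are compact implementations written
  for this package; they follow the published constructions but are not
  drop-in replacements for reference implementations (no approximate nearest
  neighbors, no spectral initialization, batch rather than asynchronous
  layout updates).
* Matrices are assumed pre-normalized; no balancing is performed. HDF5
  cooler containers are not read — use dense text or `dump`-style sparse
  triples.
* The cluster count on arbitrary data is data-dependent; exactly ten classes
  is a property of one dataset, not of the method.
* Scanning cost grows with the band area; the per-window transform plus a
  dense forward pass is vectorized in chunks but still O(band · 81 · 1024).
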