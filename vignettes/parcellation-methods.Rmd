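---
title: "Individual-level connectivity parcellation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-level connectivity parcellation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcparc)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, the numerical decisions, and
the known limitations.

## The model

The pipeline assumes that a cortical region of interest (ROI) decomposes
into K functional networks, that vertices of the same network share a
common latent BOLD time course in the 0.01–0.08 Hz band, and that the
*connectivity profile* of a vertex — its vector of Pearson correlations
with every cortical vertex — is therefore approximately constant within a
network and distinct across networks. Individuals share a common network
layout up to spatially coherent boundary shifts.

Three consequences drive the design:

1. **Group atlas by profile clustering.** Averaging profiles across
   subjects suppresses subject-specific noise; clustering the averages with
   spherical k-means (cosine similarity on L2-normalized profiles) recovers
   the shared layout. The objective is the aggregate distance
   $\sum_v (1 - \cos(c_v, \mu_{l(v)}))$, the natural spherical k-means
   objective.
2. **Individualization by reference-signal correlation.** If a subject's
   vertex truly belongs to network *l*, its time course correlates most
   with network *l*'s mean time course. Starting the iteration from the
   group atlas anchors the label space and regularizes against noise;
   restricting the reference update to *high-confidence* vertices
   (confidence $r_{\max}/r_{2nd} > 1.3$) keeps ambiguous boundary vertices
   from dragging the references.
3. **Validation by ordering, not by absolute value.** Absolute Dice or
   homogeneity numbers depend on data quality; the diagnostic orderings do
   not: intra-subject reproducibility must exceed inter-subject similarity,
   and a subject's own parcellation must be more homogeneous (connectional
   homogeneity higher, task inhomogeneity lower) than the group
   parcellation evaluated on the same data.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band edges | 0.01–0.08 | Hz | standard resting-state analysis band; the latent model lives here |
| filter order | 4 | — | Butterworth prototype, applied forward–backward (zero phase) |
| k-means restarts | 500 | — | escapes local minima; on desk-scale problems the best restart is reached long before 500, the cost is seconds |
| K range | 2–24 | — | candidate model orders for selection |
| small-cluster threshold | 10 | mm² | spatial components at or below this area are absorbed by neighbor vote |
| confidence threshold | 1.3 | ratio | strict inequality; vertices at exactly 1.3 are excluded |
| iterations | 10 | — | consecutive-iteration Dice is ~1 well before 10 on synthetic cohorts |
| Mantel permutations | 10,000 | — | add-one two-sided p; 999 in simulation studies for speed |
| cluster-forming threshold | 8 | \|t\| | threshold on the one-sample t statistic; configurable (see below) |
| cluster permutations | 5000 | — | sign-flipping of subject maps |

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code; its defaults define the
package's reference study conditions: 8 subjects × 2 sessions on a level-3
icosphere (642 vertices, ROI = a contiguous 25% polar cap of ~160
vertices), K_true = 4 contiguous networks, boundary jitter 0.2, SNR 1,
200 timepoints at TR 2.8 s, latent correlation 0.2. The mesh radius
(100 mm) makes vertex areas a few mm², so the 10 mm² rule is exercised at
a realistic scale. Sample sizes and session structure are a desk-scale
analog of a 30-subject, two-resting-session protocol; TR and run length
(~9 min) match common resting-state acquisitions; jitter 0.2 produces
inter-subject Dice near 0.7, in the range reported for individual cortical
parcellations; latent correlation 0.2 reflects the moderate between-network
coupling of real resting-state networks.

What it emulates: a shared group layout with subject-specific, spatially
coherent boundary flips (only boundary vertices change, adopting a
neighboring network's label); band-limited (0.01–0.08 Hz) Gaussian-process
network latents with controllable pairwise correlation; white measurement
noise with sd = 1/SNR; structured non-ROI cortex (the same latents through
a second, spatially independent layout) so profiles carry genuine
long-range information; task z-maps constant on designated effect networks
plus noise; smooth anatomy fields (thickness 2.5 ± 0.3 mm, curvature
0 ± 0.15 mm⁻¹) generated independently of the network labels.

What it does not emulate: hemodynamic convolution, motion and physiological
artifacts, spatial autocorrelation of the noise, inter-subject surface
registration error, multi-hemisphere structure. Passing tests therefore
show the algorithms are correct and well-calibrated under the stated
generative model — not that real auditory-cortex data will reach the same
Dice values.

## Numerical choices

* **Self-correlation entries** are kept in the profile matrix and masked to
  0, so all profiles live in one vector space and can be averaged; dropping
  the self entry (a length-V−1 vector per vertex) would misalign
  coordinates across vertices.
* **Zero-phase filtering** uses odd-reflective padding of 3× the filter
  length and step steady-state initial conditions; with TR 2.8 s the
  0.01 Hz edge otherwise rings visibly. Conditioning is near-idempotent on
  in-band content (profile changes < 0.02) but not literally idempotent —
  an IIR band edge re-attenuates on every pass.
* **Empty k-means clusters** are repaired by seizing the vertex farthest
  from its assigned centroid; ties in assignment go to the lowest label.
* **Silhouette** uses the standard per-sample Rousseeuw form with cosine
  distance and the nearest-other-cluster mean for *b*; singleton clusters
  and exact a = b = 0 ties score 0. A variant that averages over *all*
  other clusters exists in the literature's looser prose; the standard form
  was chosen because it is the established definition and is what generic
  implementations compute.
* **Model-order selection** takes strict interior local maxima of
  Dice × silhouette; endpoints are never selected and plateaus resolve to
  the smallest K, so the rule is deterministic.
* **Label matching** between independently clustered parcellations is the
  assignment problem on the vertex-overlap matrix, solved exactly
  (maximum-weight bipartite matching); Dice between unmatched clusterings
  is meaningless.
* **Confidence flooring**: the runner-up correlation is floored at 1e-6, so
  a non-positive second correlation yields very high confidence; a vertex
  whose *best* correlation is non-positive gets confidence 1 (it supports
  no network). Zero-variance vertices are assigned label 1, confidence 1,
  and flagged rather than dropped.
* **Reference updating** averages the high-confidence signal with the
  *current* reference (loop semantics); a config flag switches to always
  averaging with the original group reference for sensitivity analysis.
  Both keep constant weights across iterations. Signals are standardized
  before every average so high-variance vertices cannot dominate.
* **Sample standard deviation** (N−1) is used in functional inhomogeneity;
  single-vertex networks contribute sd 0 with a warning, and networks with
  fewer than two vertices are excluded from connectional homogeneity.
* **Dice conventions**: the parcellation-level Dice is the *unweighted*
  network mean, while both homogeneity metrics are *size-weighted* — the
  two conventions are intentional and implemented exactly as defined.
  Inter-subject Dice pools all cross-subject session pairings.
* **Permutation p-values** use the add-one convention and are two-sided
  for the Mantel test (|null| ≥ |observed|); they can never be 0.
* **Cluster-forming threshold** is interpreted as a threshold on |t| of the
  one-sample statistic (the quantity being permuted); the sign-flipping
  scheme is the standard exact permutation family for a symmetric
  one-sample null.
* **Multiple runs** are conditioned per run and then concatenated in time;
  profiles are computed once on the concatenated series rather than
  averaged across runs (one fewer estimator, and correlations over the
  longer series are better conditioned).

## Problem sizes used in the validation battery

The test suite and `scripts/acceptance.R` run the reference cohort above,
with 20 replicate cohorts (5 in the test suite) for the intra- versus
inter-subject ordering, 500 replicates × 999 permutations for Mantel
type-I error, and 200 replicates × 499 sign-flip permutations for the
cluster-extent family-wise error, the latter at forming threshold 1.5 so
that null clusters actually form and the calibration of the correction is
informative (at high thresholds the discreteness of small integer extents
makes the test conservative, which is the expected behavior of
extent-based corrections, not an error).

## Known limitations

* The generator's noise is white; real fMRI noise is temporally and
  spatially autocorrelated, which will lower real-data confidence values.
* Individualization never relabels vertices outside the ROI, and the
  non-ROI layout is shared across subjects; whole-cortex individualization
  is out of scope.
* GLM estimation of task contrasts is out of scope: the pipeline consumes
  z-maps and effect maps as inputs.
* On-disk matrix interchange is TSV and ASCII GIFTI (plus FreeSurfer
  .annot for labels); there is no HDF5 or CIFTI backend.
* The reassignment of small clusters can, in principle, absorb a network
  entirely; its label is then left empty rather than renumbered, so label
  identities stay comparable with the input.
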