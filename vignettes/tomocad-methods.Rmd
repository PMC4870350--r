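---
title: "Detecting microcalcification clusters in tomosynthesis volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microcalcification clusters in tomosynthesis volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomocad)
```

## The detection problem

Digital breast tomosynthesis (DBT) reconstructs a quasi-3D breast volume
from a small number of X-ray projections. The reconstructed grid is highly
anisotropic — the reference geometry here is a 0.1 x 0.1 mm in-plane pitch
with a 1 mm slice interval — and limited-angle reconstruction smears every
object along the depth axis (interplanar artifact). The clinically
meaningful finding addressed by this package is the *microcalcification
cluster* (MCC): a spatial grouping of sub-millimetre bright calcium
deposits. Individual microcalcifications (MCs) are compact, high-contrast
blobs; the main confounders are elongated bright structures (vessels,
ducts, fibrous strands) and slowly varying textured background.

`tomocad` implements a candidate-generation + rule-based screening
pipeline:

1. **Prescreening subsampling** — each slice is max-pooled in-plane by a
   factor of 10, taking the 0.1 mm pitch to an approximately isotropic
   1 mm grid. Max-pooling (not strided sampling) is used so that a bright
   sub-voxel MC cannot fall between samples.
2. **Multiscale Hessian objectness** — bright-blob evidence from the
   eigenvalues of the Gaussian-smoothed Hessian, maximized over scales.
3. **SNR enhancement** — a slice-wise zero-sum band-pass filter built from
   three nested box means (15/7/3 full-resolution pixels), which extracts
   local signal relative to the slowly varying background; negative
   responses are clamped to zero.
4. **MOR** — the voxelwise product of objectness and the (max-pooled) SNR
   field; both channels must agree before a voxel scores.
5. **Candidate extraction** — connected components of the MOR field
   thresholded to yield about 500 seed objects per volume, and of the
   SNR3D statistic (local variance over local mean of the SNR field)
   binarized at 3.2 to yield individual MC candidates.
6. **Clustering** — each seed collects MC candidates whose centroids lie
   within 5 mm.
7. **False-positive reduction** — two cluster rules (at least 9 member
   voxels within the radius; at least 2 other seeds within 5 mm), tight
   bounding cubes, transitive merging of overlapping cubes, and a
   cube-content rule (at least 80 candidates and 140 mm^3 at clinical
   scale).
8. **Evaluation** — a detection is a true positive when it shares any
   volume with a truth box; performance is summarized as sensitivity
   versus mean false positives per volume (FROC) with a normalized
   partial area.

## The objectness response and its shape term

After smoothing at scale $\sigma$, the Hessian at a bright-blob center has
three large, nearly equal, negative eigenvalues
$\lambda_1 \le \lambda_2 \le \lambda_3 \le 0$; a bright line leaves one
eigenvalue near zero and a bright plane two. The response is the product
of a *shape* term and a *structureness* term
$1 - \exp\{-(\lambda_1^2 + \lambda_2^2 + \lambda_3^2)/2\gamma^2\}$, gated
to zero unless $\lambda_3 \le 0$.

Two shape terms are available. The `as_printed` form uses
$\lambda_1^2 / (2\alpha^2 \lambda_2 \lambda_3)$. Because $|\lambda_1|$ is
the *largest* magnitude, this ratio grows without bound as
$\lambda_3 \to 0^-$, i.e. it is maximal for ideal *lines*, which
contradicts the goal of enhancing spherically symmetric objects. The
default `blobness_corrected` mode therefore uses the conventional
smallest-over-largest blobness ratio
$\lambda_3^2 / (2\alpha^2 |\lambda_1 \lambda_2|)$, which is identically
zero for ideal lines and planes and approximately $1/2\alpha^2$ for
spheres. Both modes agree exactly on equal triples (the shape ratio is 1),
so the documented spot value $O(-1,-1,-1) \approx 0.15352$ at
$\alpha = 0.1$, $\gamma = 3$ holds in either mode.

Defaults: $\alpha = 0.1$, $\gamma = 3.0$ (applied to eigenvalues in
physical units, one $\gamma$ for all scales), scales
$\{0.5, 1.0, 1.5\}$ mm. The scale list targets the subsampled grid, where
MC analogues occupy roughly one to three voxels; it is fully
configurable. Ties across scales resolve toward the smallest scale.
Derivatives are taken as central differences of the smoothed volume
(smooth first, then differentiate), with per-axis voxel sigmas
$\sigma / \mathrm{spacing}$ so a single physical scale behaves
consistently on anisotropic grids. All convolutions use mirror-reflected
boundaries, which avoids the rim responses that zero padding would
create.

### What subsampling does to thin lines

A practical caveat established while validating the discrimination
property: after x10 max-pooling, a line thinner than the coarse voxel
aliases into a staircase of bright voxels. The staircase kinks are
*genuinely* blob-like at every smoothing scale — no scale choice on the
coarse grid restores the line's along-axis invariance. Line suppression
by the objectness filter is therefore a property of grids that resolve
the line; on the coarse grid the pipeline relies on the band-pass/SNR3D
channel and the false-positive rules to control elongated structures.
The package's discrimination test accordingly measures blob-versus-line
response on the full-resolution grid, excluding axis points inside the
blob's blurred support and within one smoothing support of the volume
faces (the mirror boundary folds a line into a corner there, which
measures the padding, not the filter).

## The SNR channel

The band-pass kernel is assembled from three nested square mean filters
of sizes $M_1 > M_2 > M_3$ (defaults 15/7/3 pixels, i.e. 1.5/0.7/0.3 mm
at the reference pitch): the $M_3$ core mean minus the mean over the
annulus between the $M_2$ and $M_1$ windows, with a guard ring in
between that removes the artifact of pixels immediately adjacent to the
candidate. The weights sum to zero, so constant backgrounds respond
exactly zero; negative responses are clamped (a darker-than-background
excursion is not MC evidence). Filtering is slice-independent, matching
the physics: depth blur makes in-plane contrast the reliable signal.

The SNR3D statistic divides the local variance of the SNR field by the
local mean over a 9 x 9 x 3 voxel window (about 0.9 x 0.9 x 3 mm), with
a relative floor of $10^{-12} \times \max(\mathrm{SNR})$ guarding the
division and zero output where the local mean is not positive. The
variance-over-mean form follows the source description literally; the
conventional `std_over_mean` form is available behind a switch
(`snr3d_form`), since the source text calls the quantity a "ratio"
without resolving the squaring. The fixed binarization threshold 3.2 is
the default for fidelity; a count-targeted mode
(`threshold_for_count`) is available because grey-level statistics of
other detectors or of synthetic data need not match the clinical scale
at which 3.2 was chosen.

## Candidate extraction and clustering choices

* Connectivity defaults to 26 (faces, edges, corners); 6 and 18 are
  available. Component labels are assigned in ascending order of each
  component's first raster voxel, making every downstream table
  deterministic.
* The seed threshold is found by bisection on the component count.
  Counts are not monotone in the threshold (lowering it merges
  components as well as adding them), so the search tracks the best
  threshold seen and falls back to the nearest achievable count,
  preferring the higher threshold on ties, with a warning.
* Cluster membership uses centroid-to-centroid Euclidean distance in
  physical millimetres (anisotropy already absorbed), inclusive at
  exactly 5 mm. An MC candidate may join several clusters.
* `member_voxel_count` counts member-candidate voxels *within the
  association radius of the seed centroid* — the quantity the first
  false-positive rule thresholds — rather than the candidates' total
  voxel counts; this caps the contribution of long elongated candidates
  that merely graze the neighborhood. The cluster score is this same
  count, because it is the quantity the pipeline's own rules act on, and
  any monotone score yields a valid FROC sweep.

## False-positive reduction

Rule boundaries are inclusive exactly as printed: "fewer than 9 member
voxels" eliminates, 9 keeps; "fewer than 2 nearby seeds" eliminates, 2
keeps; "fewer than 80 candidates or less than 140 mm^3" eliminates, the
boundary values keep. "Nearby" seeds exclude the cluster's own seed
(counting it would weaken the rule to "at least one other seed");
inclusive counting is available via `include_own_seed`. The examination
of "more than one combined cube" is recorded (`merged_from`) but is not
an elimination rule by default (`require_merged_from_gt1`), since the
printed elimination criteria are the count/volume thresholds.

Cube merging groups cubes sharing any volume by transitive closure and
replaces each group by the tight box over its member cubes, expanded to
a cube on the longest side. Expansion can create fresh overlaps, so the
grouping is iterated — but group bounds are always recomputed from the
*original* member cubes, never from previously expanded intermediates.
Anchoring the bounds this way prevents the expansion from compounding
(iterating on expanded cubes can swallow an entire volume) and gives a
fixed point at which output cubes are pairwise disjoint, making the
operation idempotent.

One structural property worth knowing: the *final detection count* is
not monotone in the rule thresholds. Raising a cluster-rule threshold
can eliminate a cluster whose cube bridged two groups; the merged cube
then splits into several disjoint cubes, each of which may still pass
the content rule, so the number of surviving detections can rise. The
keep-set of each individual rule is monotone in its own threshold (and
is tested), but the merge stage breaks monotonicity of the end-to-end
count. This is inherent to combine-then-threshold cascades of this
shape, not an implementation artifact — a single-pass transitive closure
reproduces it.

### Clinical versus phantom rule profiles

The 80-candidate / 140 mm^3 content thresholds reflect the candidate
population of full-resolution clinical volumes (thousands of candidates
per view). The bundled generator produces 25.6 x 25.6 x 40 mm blocks
whose clusters contain 5--12 MC analogues totalling a few mm^3, so the
clinical thresholds would eliminate every genuine cluster.
`fp_params_phantom()` keeps the two cluster rules at their printed
values and scales the content thresholds to the generator's cluster
composition: at least 4 candidates (below the smallest cluster the
generator can emit) and 1 mm^3. The clinical profile `fp_params()`
remains the default everywhere else.

## The phantom generator

The generator emulates the features of reconstructed DBT that the
pipeline exercises, with known ground truth:

* **MC analogues**: isotropic Gaussian blobs parameterized by
  full-width-at-half-maximum diameter (0.2--0.8 mm, the conventional way
  MC "size" is quoted), grouped in clusters of 5--12 within a 4 mm
  radius (inside the 5 mm association rule). Cluster centers keep at
  least two radii of separation so distinct findings stay distinct.
  Depth positions snap to slice centers, because a 1 mm slice interval
  cannot represent sub-slice structure.
* **Distractors**: full-extent Gaussian-profile cylinders oriented
  in-plane (0.6 mm FWHM) and z-normal Gaussian slabs (0.8 mm), at
  contrast 10 — comparable to, but below, the MC contrast of 20.
* **Background**: in-plane correlated Gaussian noise (0.3 mm correlation
  length); flat and low-frequency-gradient variants exist.
* **Depth artifact**: the whole volume is convolved along z with a
  Gaussian of 1.5 mm sigma, the simplest model of interplanar blur.
* **Normalization**: grey levels are scaled so the background noise has
  unit standard deviation *after* the depth blur, which makes contrast
  values, gamma = 3, and the SNR3D threshold 3.2 meaningful across
  phantoms. Inserted amplitudes are pre-compensated for the attenuation
  of each object's on-grid peak by the discrete depth blur, so a truth
  record's `contrast` is the peak actually measurable in the final
  volume — the natural definition, since detection operates on the
  reconstructed (blurred) data.

What the phantom does **not** model: anatomical breast texture, the
spatially varying noise of a real detector, reconstruction streaks, MC
shape irregularity (real MCs are elongated/stellate as often as round),
and the full candidate population of a clinical view (about 500 seeds
arise here from noise, but the ~5000-candidate scale of clinical SNR
images is not reproduced). Passing the bundled tests therefore
demonstrates that the pipeline's machinery works as specified — not that
clinical sensitivity/FP figures transfer.

## Evaluation conventions

Matching uses axis-aligned box intersection in mm; any strictly positive
shared volume is a true positive (face contact is not). Metrics are
pooled view-based: sensitivity over all truths across volumes, false
positives averaged per volume, with separate means for truth-containing
and truth-free volumes. The FROC sweep runs over the pooled distinct
detection scores plus a sentinel above the maximum (yielding the 0-FP
endpoint); the normalized partial area integrates the best sensitivity
per FP rate by trapezoid over $[0, \mathrm{fp_{max}}]$, extends the
curve rightward at its last sensitivity, and divides by
$\mathrm{fp_{max}}$, so a perfect detector scores exactly 1.
`fp_max` is a free parameter (20.44 FPs/volume is the documented
clinical normalization bound; the bundled experiments use 10).

## Problem sizes and numerical checks

The bundled test fixtures use 25.6 x 25.6 x 40 mm phantoms
(256 x 256 x 40 voxels) — about one-fiftieth the voxel count of a
clinical DBT view, enough to exercise every stage at realistic physical
scales while a 20-volume batch runs in minutes on one CPU. Closed-form
checks anchor the numerics: smoothed-Gaussian Hessian eigenvalues agree
with the analytic value to better than $10^{-3}$ relative at a 0.125 mm
grid step (the discretization error of central differences is
$h^2/4(s^2+\sigma^2)$, which sets the step); the band-pass kernel's
weights, the objectness spot value, and the FROC trapezoid arithmetic
are exact. Connected-component labeling and cube merging are
cross-checked against independent pure-R flood-fill and union-find
oracles on randomized inputs.

```{r example, eval = FALSE}
# one positive phantom through the whole pipeline
ph <- generate_phantom(phantom_config(seed = 42))
run <- run_pipeline(ph$volume, truths = ph$truth$clusters,
                    cfg = pipeline_config(fp = fp_params_phantom()))
run$report$counts
run$match$sensitivity
```

## Known limitations

* The paper-printed parameter set (alpha, gamma, 3.2, 500, the rule
  thresholds) was tuned for a specific clinical detector and geometry;
  on other data the count-targeted threshold modes and the
  `fp_params()` fields are the intended adjustment points.
* Objectness on the x10-subsampled grid cannot suppress sub-voxel
  elongated structures (aliasing; see above).
* Detection counts are not monotone in the FP-rule thresholds (merge
  splitting; see above).
* Truth regions are axis-aligned boxes; the any-overlap criterion is
  generous and should not be compared against stricter
  center-containment scoring without adjustment.
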