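---
title: "Quantifying gamma-H2AX nano-foci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gamma-H2AX nano-foci: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanofoci)
```

## The problem

After a DNA double-strand break (DSB), histone H2AX is phosphorylated
(gamma-H2AX) over large chromatin regions around the lesion. Under
super-resolution microscopy a conventional gamma-H2AX "focus" resolves
into several *nano-foci* of roughly 200 nm lateral diameter, each
corresponding to a chromatin unit in the tens-of-kilobase range.
Nano-foci arrange into *clusters* — groups of nano-foci whose centroids
lie within a linkage cutoff of each other — and a cluster, rather than a
nano-focus, corresponds to one DSB. The package quantifies this picture
from two sides:

* **imaging** — segmenting nuclei and nano-foci from anisotropic 3D
  voxel stacks, estimating each focus's DNA content from its DAPI share,
  measuring shell (surround) intensities, clustering centroids and
  computing cluster metrics, and comparing between-channel proximity to
  a uniform-sphere Monte-Carlo null;
* **genomics** — binned ChIP-Seq coverage: smoothing, genome-mean
  normalization, Spearman correlation against feature tracks,
  imaging-guided percentile filtering into "1D domains", CTCF boundary
  analysis, IUPAC motif scanning, and the DSB-count arithmetic.

Every stage is generatively testable: the synthetic-data module plants
nuclei, foci, clusters, coverage domains and boundary peaks with known
ground truth.

## Image analysis model

A stack is a set of channels over a common `[x, y, z]` voxel grid with
physical voxel sizes (lateral, axial) in nm; the defaults, 39 nm and
125 nm, reflect typical 3D-SIM sampling, and all physical measurements
(centroids, distances, volumes) honour this anisotropy. Coordinates are
voxel centres: a voxel with 0-based index $i$ sits at $(i + 1/2)\,s$ for
voxel size $s$.

**Nucleus.** The DAPI channel is thresholded; 26-connected components
below a volume floor (default 200 µm³, scaled down for the small
synthetic demo stacks) are discarded; internal cavities are filled; two
rounds of dilation followed by morphological closing with a 3×3×3 box
absorb DAPI-weak volumes; the largest surviving component is the
nucleus. Hole filling uses 6-connectivity for the background so that
diagonal leaks do not connect cavities to the outside.

**Nano-foci.** Voxels at or above an intensity threshold (default 1000
counts on the 16-bit scale) form 26-connected components; components
below 0.001 µm³ or whose intensity-weighted centroid falls outside the
nucleus are dropped. 26-connectivity is the natural choice for dense
blob-like objects; centroids are intensity-weighted because they are
stable under partial voxelization of small objects. A minimum volume of
0.001 µm³ corresponds to ~5.3 voxels at the default sizes; the floor is
configurable.

**Touching-object separation.** Components larger than twice a nominal
single-object volume (default 0.05 µm³) are split by a
marker-controlled watershed: markers are local intensity maxima at
least one equivalent-sphere diameter of the nominal volume apart
(~457 nm), voxels are claimed in order of decreasing intensity by
adjacent labelled regions, and ties go to the nearest marker. Fragments
below the minimum object volume are merged back into the piece with the
nearest marker, so splitting never manufactures sub-threshold objects.
The original analysis used a commercial black-box step; the marker
spacing rule above is this package's documented equivalent.

**Shells.** Each focus is dilated by a per-axis Chebyshev box (default
3 voxels, i.e. 117 nm laterally and 375 nm axially), its own voxels are
subtracted, the result is clipped to the nucleus, and voxels contested
by several shells go to the focus with the nearest centroid. Shell
statistics (max/mean per channel, optionally normalized to the nuclear
maximum) quantify the signal surrounding a focus; foci whose shell is
fully clipped are flagged rather than silently dropped.

## DNA content

The DNA content of a focus is its share of the integrated nuclear DAPI
signal scaled to the genome size:

$$\mathrm{content}_{kb} = \frac{\mathrm{DAPI}_{focus}}{\mathrm{DAPI}_{nucleus}}
  \cdot G_{Mbp} \cdot 10^3 \,/\, c_{cc}$$

where $G$ is the (karyotype-derived) genome size — a required input, no
default is asserted — and $c_{cc}$ a per-nucleus cell-cycle factor. The
source describes a cell-cycle correction without giving a formula; here
$c_{cc}$ is defined as nuclear integrated DAPI over a G1 reference
value, supplied by the user (default 1, i.e. no correction). Pooled
values outside the 0.5th–99.5th percentiles are flagged as discarded;
percentiles are linear-interpolation order statistics
(`stats::quantile()` type 7), stated explicitly because implementations
differ — 1000 distinct values retain exactly 990.

## Clustering and cluster metrics

Foci whose centroids are *strictly* closer than the cutoff (default
500 nm) are linked; clusters are connected components of this graph
(single linkage). Pairs at exactly the cutoff are not linked, following
the strict reading of "closer than"; this only matters on degenerate
inputs. Per cluster the package reports:

* integrated volume — sum of member focus volumes;
* inter-focal volume — exact convex-hull volume of the member
  centroids, computed by brute-force supporting-plane detection with
  fan triangulation (exact for the small clusters that occur here);
  clusters with fewer than 4 non-coplanar centroids report 0 with a
  degeneracy flag rather than being dropped;
* shortest path — the shortest *open Hamiltonian path* over member
  centroids, solved exactly by Held–Karp dynamic programming up to 10
  members (clusters have a median of ~4 members, so the exact path is
  the common case) and by nearest-neighbour construction plus 2-opt
  refinement above, flagged via `path_exact`;
* mean pairwise inter-centroid distance;
* summed member DNA content (conserved: cluster sums equal focus sums).

`cutoff_scan()` recomputes the partition over a cutoff range; the count
is non-increasing in the cutoff by construction.

## Spatial null model

Between-channel proximity (e.g. gamma-H2AX to CTCF) is the per-query
nearest-neighbour distance. The null model draws the observed numbers
of query and target objects uniformly in a sphere whose radius matches
the sphere-equivalent mean nuclear volume (radius $R U^{1/3}$, uniform
direction), 100 iterations by default. Points are dimensionless — no
hard-core exclusion is imposed, as none is stated for the original
simulations. Both the pooled distance distribution and per-iteration
medians are returned, since either convention may be compared against
observations; the comparison reports quantiles and the direction of the
effect only, with no p-value machinery.

For a query at the centre, $P(d \le r) = 1 - (1 - (r/R)^3)^{n}$. This
ignores edge effects; the exact law for a uniformly placed query
(integrating the two-sphere lens volume over the query radius) deviates
from it by up to ~0.049 in Kolmogorov distance at $n = 200$, $R = 5$ µm.
The test suite therefore checks the sampler against the exact law (at
Kolmogorov distance < 0.01) as well as against the centre-point
approximation; with the approximation, agreement better than ~0.05
cannot be expected at these parameters no matter how many iterations are
run, because the deviation is the approximation's own bias.

`ratio_per_structure()` fits the per-structure ratio (e.g. nano-foci
per phospho-Ku70 structure) as a least-squares slope through the
origin, with the intercept model reported alongside and a degeneracy
flag for constant predictors.

## Genomic integration

Coverage is binned into non-overlapping 10-kb intervals as RPKM, with
reads assigned by midpoint (configurable in principle to
overlap-proportional; midpoint conserves read counts exactly).
Smoothing is a centred moving average of $w \in 1..25$ bins, truncated
at chromosome ends; for even $w$ the window is left-heavy. Feature
correlation is Spearman's rho with average ranks, bins with missing
feature values excluded pairwise; a mode excluding zero-signal bins is
provided since the treatment of unmappable bins is a genuine open
choice.

The imaging-guided domain caller retains bins at or above the
$(100 - f)$-th percentile of the (smoothed) track, where $f$ is the
measured gamma-H2AX volume fraction in percent — a 7.81% volume
fraction samples the 92.19th percentile. Ties at the threshold are all
retained, which matters only for degenerate tracks. Maximal runs of
retained bins become "1D domains" with no gap tolerance; linear
coverage is conserved (retained bins × bin size). `match_smoothing()`
scales the 3D nano-focus count to the haploid genome (ploidy factor
3.12 for the aneuploid cell line modelled here), scans all $w$
exhaustively, and picks the window whose domain count is closest to the
target, ties to the smaller $w$.

Boundary analysis measures, per domain boundary, the distance to the
nearest peak (peak position = interval midpoint) and sums peak scores
in 100-kb bins from 300 kb outside to 100 kb inside the boundary,
mirroring the direction at right-hand boundaries. "Maximum occupancy"
filtering keeps peaks whose score equals the file's maximum score.
Motif scanning matches an IUPAC consensus (a configuration input, not
hard-coded) on both strands via `Biostrings`, merges overlapping
same-strand matches, and reports successive-start inter-site distances
overall and per strand; a palindromic consensus yields coincident
records on the two strands. The expected DSB count scales a
30–55 per-Gy diploid yield by dose and half the ploidy factor, rounded
to the nearest 10 (470–860 at 10 Gy).

## The synthetic-data generator

The generator emulates what the pipeline needs to see, not the optics:

* a spherical nucleus of uniform DAPI signal (the sphere matches the
  null-model geometry; no nuclear envelope texture, no chromocentres);
* nano-foci as isotropic Gaussian intensity blobs (sigma 60 nm,
  amplitude 5000 against the 1000-count threshold, giving a thresholded
  lateral diameter of ~215 nm to match the ~200 nm scale); there is no
  point-spread-function model — blob parameters are stand-ins, not
  claims about the data;
* clusters of 4 foci (the observed median) with centres at least 2 µm
  apart and members spread with sigma 150 nm, at least 350 nm apart
  (the separation at which two blobs' summed profile saddles below the
  detection threshold, keeping planted foci individually resolvable)
  and resampled until single-linkage connected at 450 nm, so a planted
  cluster is a cluster under the 500 nm linkage definition;
* optional DAPI dimming inside foci with shell brightening, and marker
  channels offset from focus centroids by a configurable distance;
* Gaussian read noise on images (sd 20 counts), Poisson counts on
  tracks (background 5, enrichment 50 reads/bin by default — a 10×
  enrichment), all seeded and bit-reproducible.

Planted per-focus DNA fractions are defined as the noiseless DAPI mass
over the *nominal thresholded support* of each blob: DNA content is an
extensive region integral, so the truth must fix the region of
integration. Recovery is unbiased; the per-focus scatter (~3% sd)
comes from support-boundary voxels flipping under read noise, so
recovery tests assert the median and mean relative error, not the
worst focus.

What passing these tests does *not* show: robustness to SIM
reconstruction artifacts, chromatic shift, non-spherical nuclei,
intensity-dependent noise, overlapping clusters, or mappability
structure in real coverage — none of which the generator emulates.

## Problem sizes and numerical choices

The default demo stack is 160×160×48 voxels (a scaled-down nucleus of
~100 µm³ at true voxel sizes), 5 clusters × 4 foci; synthetic tracks
are 1000–2000 bins; the null model uses 100 iterations of 1000×200
points. These sizes make every stage's behaviour measurable in seconds
while leaving all algorithmic paths identical to full-size inputs.
Degenerate inputs are handled explicitly: empty label grids give empty
tables, singleton clusters report zero path/hull metrics, constant
tracks retain all bins under the tie rule, clipped shells and
chromosomes without peaks are flagged missing, and geometry that cannot
fit the requested plant fails loudly rather than truncating.
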