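---
title: "Reconstructing root-system structure models from laser scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing root-system structure models from laser scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootqsm)
```

## The problem

Excavated coarse-root systems of trees can be scanned with a terrestrial
laser scanner (TLS) to millimeter accuracy, but a point cloud is not a
phenotype. The traits breeders and ecologists actually use — basal root
diameters (RD), lateral-root counts by branching order, total root length,
surface area and volume — require a structural reconstruction: a
*quantitative structure model* (QSM) that represents the root system as a
tree of tapered cylinders. `rootqsm` implements that reconstruction and the
accuracy-evaluation toolkit around it, together with a synthetic
root-system generator that provides exact cylinder-level ground truth, so
the whole chain is testable without access to field scans.

## The pipeline

Given a single registered cloud of one root system (meters, z up), the
stages of `reconstruct_root()` are:

1. **Orientation.** Field scans stand the way the root grew: collar up.
   `invert_axis()` mirrors z inside its own range so the collar becomes the
   lowest point and bottom-up modeling can start there.
2. **Denoising.** Classic statistical outlier removal
   (`remove_outliers()`): a point is kept iff its mean distance to its k
   nearest neighbours is within `mean + std_ratio * sd` of that statistic
   cloud-wide (defaults k = 8, std_ratio = 2, the usual SOR settings).
3. **Thinning.** `downsample_cp()` is voxel-grid thinning with cubic edge
   CP ("cloud parameter", default 0.003 m). One *original* point per
   occupied voxel is kept — the one nearest the voxel centroid — rather
   than the centroid itself, so later radius fits see true surface points.
   The voxel grid is anchored at the origin so CP sweeps nest consistently.
   CP is interpreted as a length in meters; values of 0.001–0.004 match
   the millimeter regime of TLS returns. Only the monotone "larger CP =
   stronger thinning" semantics is relied upon anywhere.
4. **Geodesic field.** A symmetric k-nearest-neighbour graph (k = 10) with
   Euclidean edge weights stands in for a full 3D Delaunay triangulation;
   for surface-sampled clouds the geodesics are equivalent at a fraction
   of the cost. Disconnected components (occlusion gaps) are bridged by
   repeatedly adding the shortest edge between the smallest component and
   the rest. Dijkstra's algorithm then yields per-point geodesic distance
   and predecessor from the collar source.
5. **Collar anchoring.** A geodesic source *on* the root surface distorts
   the field: shells wrap around the taproot circumference and the far
   side appears as a separate chain. `anchor_collar()` therefore inserts
   one synthetic point at the collar-center (the densest 1 cm slab in the
   bottom decimeter — the collar is the thickest structure there, so a
   drooping lateral tip cannot masquerade as the base) and connects it to
   the whole collar ring with offset weights, making the first geodesic
   shell a complete ring. This mirrors the common "root disk" trick of
   trunk-modeling software.
6. **Skeletonization.** Points are binned by `floor(dist / hs)` with
   `hs` the bin length ("height segmentation"). Within a bin, connected
   components of the bin-restricted graph become clusters (distinct roots
   crossing the same geodesic shell stay apart); clusters wider than
   `4 * hs` are split by seeded K-means. Cluster centroids become skeleton
   nodes; each node's parent is found by walking its members' shortest-path
   predecessors into a lower bin (majority vote, ties to the nearest
   candidate).
7. **Cylinder fitting.** One cylinder per skeleton edge, fitted to the
   member points of its endpoint nodes by Levenberg–Marquardt nonlinear
   least squares on the radial residuals `d_i - r` (relative tolerance
   1e-8, 200 iterations max; fit capped at 400 points; members farther
   than 2.5 times the median axis distance are trimmed as junction
   contamination). Cylinder endpoints are the node centroids, so chains
   are exactly contiguous; leaf cylinders are extended to their farthest
   member point and the collar cylinder down to the lowest collar return,
   recovering the half-bin lost at each tip. Failed fits inherit a radius
   interpolated along their branch and are flagged; a tapering prior caps
   every radius at 1.2 times its predecessor's.
8. **Branch decomposition and ordering.** Chains between bifurcations are
   assembled bottom-up from the collar. At each bifurcation the child
   chain with the largest *entry radius* — the median over its first three
   cylinders, since the very first one shares the junction node's mixed
   points — continues the parent's branch and order; the others become
   children with order + 1. Radius estimates within 25% of each other are
   treated as indistinguishable; inside that band a taper-plausibility
   rule applies (a chain whose downstream length is less than eight times
   its entry radius is a severed ring arc, not a root of that caliber),
   then the longest downstream path, then the straighter chain. A
   `longest_path` continuation rule is available as a configuration
   switch. The maximal order-0 path is the taproot.
9. **Junction refinement.** A side branch's first decimeters are welded to
   the parent surface and its chain only separates some way above the true
   junction. Each branch's own axis is cast backwards onto the nearby
   parent axis (and, where neighbouring bases are entangled, the
   grandparent axis); the base is moved to the closest-approach point and
   the branch is reparented when its axis clearly emanates from the
   grandparent. This recovers the hidden base length — without it total
   length is biased several percent short — and honest attachment
   positions for detection scoring.
10. **Pruning.** Childless stubs shorter than `prune_min_length`
    (default 0.05 m) and "ghost" stubs — one-to-three-cylinder dead ends
    whose radius is at least 70% of the root they sit on, the signature of
    severed ring arcs — are removed, the digital analogue of clipping stub
    roots in the field protocol.

## Trait extraction

Totals are additive over cylinders: length is the cylinder-length sum,
volume `sum(pi r^2 L)`, and surface area the lateral surface
`sum(2 pi r L)` (end caps are internal at joints). Counting follows the
coarse-root protocol: a branch is counted iff its measured basal diameter
exceeds 0.5 cm, and the headline `n_roots` sums the taproot and the first-
and second-order laterals only.

Basal diameter is measured from the cloud, not the model
(`basal_diameter()`): the local cloud is rotated so the branch axis is
vertical, sliced into 1 cm slabs starting just above the attachment
(offset by the parent's local radius plus 1 cm, and past the welded
stretch where the branch has no surface of its own), and a least-squares
circle — algebraic Kåsa solution plus one Gauss–Newton refinement pass —
is fitted to each slab's planar projection. Slabs polluted by the parent
surface betray themselves through implausible radii or large radial
residuals and are skipped, and a slab grazing a child junction is caught
by a median-consistency check across slabs; the first three clean,
consistent slabs are averaged. The
measurement also reports *where* it was taken, so a reference diameter can
be read off at the same cross-section — the way caliper and cloud
measurements are co-located on a real root. When the slab measurement is
infeasible (sparse thin laterals) the smallest of the branch's first three
cylinder radii serves as fallback.

## Evaluation machinery

`r_squared()`, `rmse()`, `rrmse()` (percent of the reference mean),
`mae()` and `pearson_r()` implement the agreement statistics for paired
diameter measurements; `match_roots()` performs greedy closest-first
one-to-one matching of same-order roots by attachment distance, feeding
`recall()`, `precision()`, `f1()` and `accuracy()`. Two conventions are
worth stating: true negatives are undefined for open-world root detection,
so `accuracy()` refuses to invent them unless a closed candidate universe
is supplied; and published-style tables round half-up to two decimals
(`round_half_up()` — base R's `round()` rounds half to even). Overall
detection rows are reported under both aggregations (pooled counts and
per-order means), since either convention appears in practice. The p-value
attached to Pearson r is a two-sided t approximation and is labelled as
such. Greedy matching was chosen over optimal assignment for transparency;
with tolerances well below typical root spacing the two coincide.

## The synthetic generator

`generate_root_system()` builds a known cylinder tree — a tapered taproot
with first- and second-order laterals at stratified, jittered insertion
heights and azimuths — then samples each cylinder's lateral surface with a
Poisson point process, adds radial Gaussian noise, and optionally removes
one contiguous angular sector per cylinder (a scanner shadow, the TLS
failure mode, rather than random dropout). Seeded per-cylinder substreams
make output bit-identical for identical seeds. Radius tapers linearly at
`taper_rate` per meter, floored at 20% of the basal radius; growth
directions random-walk with a small per-segment jitter but never turn back
above the collar plane (roots do not grow out of the soil).

Defaults describe a mature, deep-rooted ornamental tree of the size class
scanned in root-phenotyping field work: taproot ~1.8 m deep (collar radius
5 cm), five first-order laterals with two second-order laterals each,
insertion angles around 55 degrees, 2e4 points/m² (sub-centimeter spacing)
and 1 mm noise. Two fixed presets emulate the two field habits: `vertical`
(long taproot, steep laterals) and `horizontal` (short 0.9 m taproot,
near-horizontal laterals whose spread exceeds the rooting depth —
expressed through `lateral_length_ratio = 1.3`).

What the generator does *not* emulate: bark texture and non-circular
cross-sections, soil remnants and fine-root fuzz, registration error
between scan stations, density falloff with range, and curved grain at
junctions. Passing the recovery tests therefore demonstrates the
correctness of the reconstruction logic under clean branching geometry,
not field-grade robustness; on real scans the published experience — RD
recovered far better from clouds directly than from models, detection F1
around 0.8 — is the realistic expectation.

## Problem sizes and numerical choices

Synthetic validation runs use `hs = 0.05` m and `cp = 0.003`: the
conventional meter-scale default of `hs = 0.5` is appropriate for whole
trees but would collapse a 2 m root system into a handful of nodes. The
presets produce 2–3e4 points; a full pipeline run takes a few seconds, and
the complete recovery suite (two noise-free runs plus twenty millimeter-
noise replicates) stays within a few minutes on one CPU. Determinism is
end-to-end: K-means uses a fixed seeded initialization, ties break on the
lowest index, and identical seed + configuration reproduce trait tables
byte for byte.

Degenerate inputs fail loudly rather than silently: empty clouds, fewer
than seven or collinear points for a cylinder, collinear points for a
circle, constant vectors for correlations, and zero denominators for
detection metrics are all errors carrying context.

## Known limitations

- Branches thinner than ~3 points per cross-section ring cannot be
  circle-measured and fall back to model radii.
- Two laterals inserted within about one parent diameter of each other can
  still merge into a parent–child pair under heavy noise; the grandparent
  reparenting pass resolves the common cases but is not a full structural
  optimization.
- Accuracy ("TN") for detection is only defined against an explicit
  candidate universe.
- The LAS writer covers point format 0 at 0.1 mm scale — adequate for
  root-scale clouds, not a general LAS toolkit.
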