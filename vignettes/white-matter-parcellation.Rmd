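---
title: "Cortex-associated white-matter parcellation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortex-associated white-matter parcellation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractparc)
```

## The model

`tractparc` assigns every white-matter voxel of an individual subject to
a cortical region of origin, using only that subject's data: a cortical
parcellation in the diffusion grid, and fiber orientation information.
The procedure has three stages.

**1. Tracking and labeling.** Streamlines are reconstructed with
deterministic FACT tracking: within each voxel the path is a straight
segment along that voxel's principal diffusion direction, and the
direction switches when the path crosses a voxel boundary. Propagation
stops when the path leaves the tracking mask, meets an undefined (zero)
direction, or would have to turn by more than the stopping angle.
Because diffusion-tensor principal directions are axial (a direction and
its negation are the same physical orientation), the tracker resolves
the sign of every voxel's vector against the incoming step, and each
seed grows bidirectionally. Determinism is deliberate: a probabilistic
tracker would make the parcellation non-reproducible run to run.
Each streamline endpoint that falls in a voxel with a nonzero cortical
label yields one labeled streamline oriented out of that endpoint; a
fiber connecting two cortical regions therefore contributes once per
end, exactly as if it had been seeded from both regions. Streamlines
touching no cortical label at either end are dropped (and counted).

**2. Candidate image.** Every labeled streamline deposits one count for
its label in every white-matter voxel it traverses. Traversal is
computed by sampling each polyline segment at a fixed sub-step plus its
endpoints; a streamline contributes at most one count per voxel no
matter how often it re-enters (presence in a voxel is binary, which also
removes any dependence on the tracker's step geometry). The result is,
per voxel, a count vector $L$ over a single global ordered label list —
the candidate image.

**3. Voting.** For a voxel with counts $L$, the local label probability
is $p^L_i = L_i / \sum_j L_j$. The 26 neighbors contribute their own
count fractions weighted by the inverse Euclidean length of the offset
$n$: $p^N_i = \sum_{n \in N} \lVert n\rVert_2^{-1}\, L^n_i / \sum_j
L^n_j$, where neighbors outside the volume or with empty lists
contribute nothing. The overall score is $p_i = w^L p^L_i + w^N p^N_i$
with $w^L + w^N = 1$, and the voxel receives $\arg\max_i p_i$. White
matter voxels with no fibers locally nor in any neighbor stay unlabeled
(0).

### Assumptions

* The cortex parcellation and the white-matter mask live on the same
  grid as the direction field / tractogram; registration happens before
  this package.
* The principal direction is a usable proxy for fiber orientation —
  the single-tensor assumption. In crossing regions it is not, and the
  parcellation inherits that limitation (see below).
* The white-matter mask is authoritative: counts and labels exist only
  inside it, and at the cortex/white-matter interface the cortex label
  of the starting voxel wins for labeling purposes.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `wLocal`, `wNeighbor` | 0.5 / 0.5 | – | Only the constraints $0 \le w \le 1$, $w^L + w^N = 1$ are inherent to the method; no canonical published values exist, so the package defaults to the symmetric point and the command-line interface requires both explicitly, so every run's log is unambiguous. |
| `angleThreshold` | 35 | degrees | The standard stopping angle of deterministic tensor tracking. |
| `maxSteps` | 2000 | voxel transitions | Safety cap per half-track; never reached on desk-scale grids. |
| `substep` | 0.25 | voxels | Segment sampling interval for voxelization. At interval $h$, a chord shorter than $h$ can be missed; 0.25 cannot skip any voxel a segment crosses substantially, and the sub-step can be lowered where corner-grazing voxels matter. |
| `seedsPerVoxel` | 1 | – | Seeds at cortex voxel centers; $k > 1$ uses a fixed regular sub-grid inside each voxel, so seeding is reproducible. |
| `normalizeNeighbors` | `FALSE` | – | The neighbor sum is *not* divided by the total neighbor weight $6 + 12/\sqrt2 + 8/\sqrt3$; the literal formulation of the neighbor term is unnormalized, and since normalization is a voxel-wise positive rescaling of $p^N$ only, it changes results only through the mixing with $p^L$. The normalized variant is available for study. |
| tie-break | lowest label ID | – | Argmax ties are broken deterministically and order-independently. |

Two further behavior switches exist because the method description
leaves them genuinely open: `countTraversals` (count every distinct
entry of a fiber into a voxel instead of binary presence) and
`fillNearestCortex` (assign voxels the vote leaves empty from the
nearest-cortex baseline as a post-pass; off by default — unlabeled
voxels are reported, not silently filled).

## Numerical choices

* All computation happens in 0-based continuous voxel-index coordinates
  with voxel centers at integers; voxel $(i,j,k)$ owns the half-open box
  $[i-\tfrac12, i+\tfrac12)\times\cdots$. World/mm coordinates appear
  only at I/O boundaries (NIfTI affines, TrackVis voxel-mm points, and
  physical distances in the nearest-cortex baseline, which are
  anisotropy-aware).
* TrackVis `.trk` stores points with the voxel *corner* at the origin;
  the reader and writer apply the half-voxel shift symmetrically, so
  round trips are exact to float32 precision (~1e-6 voxel).
* Exact-boundary degeneracies in the tracker (a direction parallel to a
  face, a seed exactly on a boundary) are resolved by a $10^{-6}$-voxel
  nudge across the face being crossed, making the boundary sequence
  deterministic.
* The vectorized voting implementation accumulates the neighbor term by
  array shifting over the 26 offsets; tests hold it to voxel-for-voxel
  identity with a naive per-voxel triple loop.
* Out-of-volume neighbors contribute zero — no mirroring or clamping.
* A half-open-interval consequence worth knowing: a track that exits
  through the high face of the grid has its final point attributed to an
  out-of-bounds voxel and therefore carries no label from that end.
  Labels still propagate from such faces because the seeds of that face
  produce the same geometric tracks oriented from in-bounds voxels.

## The phantom generator

`makePhantom()` builds scenes of tubular bundles (straight, arc,
crossing pairs) whose direction field follows the bundle tangent, with
cortex slabs at the faces where bundles terminate, the white-matter mask
as the tube interiors, and per-voxel ground truth. `makeCandidateFixture()`
bypasses tracking and produces candidate images directly from truth:
each white-matter voxel receives 8–12 counts of its true label, and with
probability `noise` a voxel is corrupted so that a random wrong label
strictly outnumbers the true one — the purely local vote then
misclassifies exactly the corrupted voxels, which is the cleanest way to
exercise what the neighbor term is for. All randomness derives from one
integer seed through named per-artifact streams, so adding an artifact
kind never shifts existing fixtures.

What the phantoms emulate: bundle geometry, cortical seeding, label
mixing, crossings (flagged in a sidecar mask, with truth defined by
nearest-bundle-axis dominance since truth in a crossing is genuinely
ambiguous). What they do not emulate: diffusion signal formation, noise
in the tensor fit, partial-volume effects at the gray/white interface,
gyral geometry, or realistic fiber dispersion. Passing phantom tests
therefore demonstrates the correctness of the *algorithmic* chain, not
the anatomical validity of parcellations on real data.

## Design decisions on open points

* **Neighbor weighting.** The inverse-distance form
  $\lVert n \rVert_2^{-1}$ is used; where a condensed rendering of the
  combined formula could be misread as multiplying by
  $\lVert n\rVert_2$, the explicit neighbor-term definition wins.
* **Per-end labeling.** A cortex-to-cortex streamline is emitted once
  per labeled endpoint. This makes externally supplied whole-brain
  tractograms behave like region-seeded tracking, which is the semantics
  the method's description implies.
* **One count per fiber per voxel.** Presence-based counting is robust
  to step size and re-entry; traversal counting remains available as a
  switch.
* **Second pass without re-tracking.** The candidate image is populated
  by iterating over the stored streamlines; since tracking is
  deterministic, re-running the tracker would reproduce the same
  polylines at pure cost.
* **Empty voxels stay 0.** No silent nearest-cortex fallback; the count
  of unlabeled white-matter voxels is part of every run's log.
* **Nearest-cortex baseline by exact search.** Distances are physical
  (mm); the implementation is an exact chunked all-pairs search, checked
  against a per-voxel brute-force loop. A distance transform would be
  asymptotically faster but is unnecessary at these problem sizes.

## Problem sizes in the test suite

The suite validates on grids of $6^3$–$40^3$ voxels: 100 random $8^3$
candidate images with 10 labels for the oracle-equivalence check, a
$40^3$ two-bundle phantom (176 streamlines, 1584 white-matter voxels)
for end-to-end exact recovery, 20-seed repetitions for the noisy
neighbor-benefit comparison, and random $12^3$ grids for the
nearest-cortex oracle. These sizes exercise every code path (boundaries,
ties, crossings, empty voxels) while keeping the whole suite fast enough
to run habitually; the method itself has no size-specific logic, and
scaling to full-brain grids is a matter of runtime only.

## Known limitations

* Single-tensor directions cannot represent crossing fibers: in a 90°
  crossing phantom the non-dominant bundle's tracks terminate at the
  crossing, and deep voxels beyond it can stay unlabeled unless seeded
  from the far side or filled by the baseline post-pass. Orientation
  models that resolve crossings would slot in as a different
  direction-field producer.
* The parcellation sharpens near cortex and blurs with depth — deep
  voxels are crisscrossed by fibers of many origins, so their label
  distributions flatten. A probabilistic (soft) output would expose
  this honestly but is out of scope here.
* Group averaging assumes the input parcellations are already
  co-registered; no registration is performed.
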