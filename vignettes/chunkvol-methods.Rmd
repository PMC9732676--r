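---
title: "Methods: chunked processing of dense 3D segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chunked processing of dense 3D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunkvol)
```

`chunkvol` processes dense 3D segmentation and microscopy volumes the way
the field processes datasets too large for one machine: the volume lives
as a regular grid of chunk files, work is cut into idempotent grid tasks
distributed through a lease-based queue, and per-chunk results are
stitched in a merge pass. This vignette explains the models and numerical
choices behind each stage, what the synthetic fixtures do and do not
emulate, and the known limitations.

## Storage model

A dataset is a directory with an `info` JSON describing dtype, layer kind
and an ordered list of scales; mip 0 is the highest resolution and each
further scale carries the cumulative downsample factor in its nm/voxel
resolution. Chunks are half-open, 0-based world-voxel boxes named
`x0-x1_y0-y1_z0-z1`, stored in x-fastest (column-major) voxel order —
which is also R's native array order, so `raw` encoding is a straight
dtype serialization. Volumes are *declared complete*: a missing chunk is
an error, and zero-filling is strictly opt-in (`fill_missing = TRUE`),
because silently fabricating background is the kind of failure that is
otherwise discovered months later.

Sharded scales condense many chunks into write-once container files. A
label (for image scales: the chunk's linear grid index) is preshifted,
hashed (identity by default, or a splitmix-style 64-bit mixing hash
implemented with exact 16-bit limb arithmetic on doubles), and split into
minishard and shard numbers. The file holds a fixed-size shard index
(2^minishard_bits pairs of 64-bit offsets), then the minishard indices
(three delta-encoded u64 arrays — labels, payload gaps, sizes —
optionally DEFLATE-wrapped), then the payloads; all offsets are relative
to the end of the shard index. A cold lookup therefore costs exactly
three byte-range reads. Because deflated index sizes depend on the
offsets they encode, the index region length is fixed-point iterated and
padded when the compressed indices come up short. Labels are carried in
doubles and must stay below 2^53; chunk grids and segment ids in this
package's scope are far below that. Bit-exact interoperability with
other readers of the sharded format is best effort — the two-level
lookup structure and its economics are the tested contract, byte layout
dialects differ.

Brotli second-stage compression is not provided — no brotli binding
exists in the R dependency set this package targets — so the
second-stage options are none or a gzip (DEFLATE) container signaled by
a `.gz` suffix. `png` chunk encoding is 8-bit (the R `png` binding
writes 8-bit); `jpeg` is 8-bit and lossy, provided through `EBImage`
when available.

## Segmentation codecs

`cseg` (compressed_segmentation style) cuts the volume into 8×8×8-voxel
blocks; each block stores a sorted palette of its distinct labels and
per-voxel palette indices bit-packed at the smallest width in
{0,1,2,4,8,16,32} that addresses the palette (0 bits for constant
blocks). Edge blocks are packed at full block geometry with padding
indices ignored on decode, which keeps every block independently
decodable — the property behind `cseg_decode_block`'s random access.

`compresso` style: a voxel is boundary when its +x or +y in-slice
neighbor carries a different label (the last row/column is never
boundary under this rule — one of several consistent conventions, fixed
here). The boundary field is bit-packed into 4×4×1 windows as 16-bit
words; zero-word runs are run-length encoded. The non-boundary field's
per-slice 4-connected components each store one label, with component
ids assigned by first occurrence in scan order so encoder and decoder
number them identically. Boundary voxels are then decoded sequentially
in scan order from their first in-slice 4-neighbor with a known label
(non-boundary, or boundary already decoded; order −x, −y, +x, +y);
the encoder simulates that exact walk and stores the voxels where it
fails as explicit (location, label) pairs. Letting already-decoded
boundary voxels serve as references matters: on dense Voronoi-like
segmentation it reduces ambiguous voxels from roughly half of the
boundary to a handful, which is the difference between the codec
beating and losing to gzipped raw. Both streams carry versioned headers;
they are this package's own dialect, not interchange formats.

## Downsampling

Average pooling in `accumulate` mode carries exact integer sums across
all requested mips and divides once per level with plain floor — the
error against the exact real mean stays below one grey level at every
mip because the sums are exact. `per_level` mode, provided to
demonstrate the truncation pathology, recomputes each level from the
previous one with truncating division and can lose up to 0.75 grey
levels per level under 2×2 pooling and 0.875 under 2×2×2 (the worst
integer residues), i.e. 7.5 and 8.75 after 10 mips — enough to make deep
mips visibly darker. Floor rather than round-half was chosen
deliberately: it matches the truncation framing the accumulate mode
exists to fix, and it makes every test value exactly reproducible. Odd
axes replicate their last plane so edge averages stay unbiased.

Mode pooling for labels takes each block's most frequent label,
recursively per mip; ties break to the modal label whose first
occurrence in the block's flattened x-fastest order is earliest. The
output label set is always a subset of the input's — downsampling never
invents an id. Sparse average pooling skips zero voxels (all-zero blocks
stay 0), for data where background would dilute a sparse signal.

Task planning emits grid tasks sized `chunk_size × factor^mips` so every
emitted mip writes chunk-aligned regions; five mips per task by default,
one for sharded sources (write-once shards cannot be re-rendered
mip-by-mip). Superdownsampling — re-planning with a previous top mip as
the new source — differs from one deep pyramid only by the one rounding
at the pass boundary, hence by at most one grey level per voxel.

Uncompressed, the pyramid adds `sum_k 1/4^k → 1/3` (33%) of the base
image for 2×2 pooling and `sum_k 1/8^k → 1/7` (14%) for 2×2×2, with mip 1
alone contributing 25% and 12.5%; the acceptance script measures these
from a built pyramid rather than quoting the series.

## Meshing

Surfaces are extracted by marching cubes over the binary indicator of
each label, with triangle vertices at the exact midpoints of cube edges
whose endpoints straddle the label — for a binary field the
interpolation weight is exactly ½. Exact midpoints are what make
stitching trivial: neighboring tasks overlap by one voxel on their
positive faces, so the cells touching the shared plane see identical
data and emit bit-identical vertex coordinates, and `merge_fragments`
can deduplicate on exact float equality (safe because every coordinate
is grid-derived, never computed differently on the two sides).

The 256-entry case table is generated constructively at first use
rather than transcribed: for each corner configuration, each cube face
gets the segments separating its inside from outside corners (a face
with two diagonally opposite inside corners — the ambiguous case —
always keeps them separated, the fixed deterministic rule), the
segments are chained into closed loops (each cut edge has exactly one
incoming and one outgoing segment, which the generator asserts), and
loops are fan-triangulated with a fixed orientation. Because the
segment layout depends only on the face's 2D pattern, adjacent cells
always agree on their shared face, so closed objects produce watertight,
consistently wound meshes — including across the ambiguous
configurations where the classic transcribed table can leave pinholes.
Objects touching the volume boundary are left open there (no artificial
capping), so "interior object ⇒ watertight merged mesh" is the invariant
the QC tests assert.

Simplification is iterative quadric-error edge collapse in the
Garland–Heckbert sense, with three soundness guards: a collapse is
rejected if it would flip a surviving triangle normal, if the edge is
not bordered by exactly two live triangles, or if the link condition
fails (the endpoints' common neighbors must be exactly the two opposite
vertices — otherwise the collapse pinches the surface); a fourth bound
rejects collapses whose quadric error exceeds `max_error_nm` (default
40 nm, with a reduction target expressed as a factor, e.g. 100).
Candidates are processed cheapest-first in sweeps with a dirty-vertex
set, which keeps the cost near-linear without a mutable priority queue.
`mesh_qc` computes the edge-incidence census (watertight = every
undirected edge in exactly two triangles), winding consistency (every
directed half-edge appears once, paired with its reverse), and signed
divergence-theorem volume and centroid.

## Skeletonization

Centerlines are traced TEASAR-style per connected component per label.
The distance-to-boundary field (DBF) is an exact anisotropic Euclidean
distance transform: distance from each voxel center to the nearest
center of a differing-label voxel, computed separably (first axis by two
linear sweeps, further axes by shift-and-min over the squared-distance
field, with the shift range capped by the current worst finite distance).
Volume edges continue the object — an object touching the dataset edge
is not artificially thin there; task faces are instead handled by the
border-target mechanism. Per-label transforms run inside padded
bounding boxes, since the nearest differing voxel of any mask voxel is
always within one voxel of the mask.

The penalty field `P(v) = 1 + M (1 − DBF(v)/max DBF)^p` with `p = 16`
and `M = 1e5` makes minimal-penalty paths hug the medial axis; edge
weights on the 26-connected voxel graph are the anisotropic step length
times the mean endpoint penalty. Shortest paths and distance fields are
computed with igraph. Fragment roots sit at the first border target when
the component touches a task face — paths then radiate from the shared
boundary and no stub is left next to a target — otherwise at the voxel
geodesically farthest from an arbitrary seed. Paths are traced first to
every border target (invalidating as they go; the alternative of
deferring invalidation until after the border phase has no observable
benefit on the phantoms), then repeatedly to the farthest non-invalidated
voxel; after each path every voxel within `scale · DBF(v) + const` of a
path vertex `v` is invalidated (rolling ball). Objects whose peak DBF
reaches `soma_accept` switch to soma mode: root at the DBF peak, one
soma-radius invalidation (`soma_scale`, `soma_const`), paths radiating
from the center; `soma_detect` marks the re-examination threshold.
Objects below `dust_threshold` voxels are skipped. Default parameters
(`scale` 3, `const` 50 nm, `soma_detect` 1100 nm, `soma_accept` 3500 nm,
`soma_scale` 1, `soma_const` 300 nm) are a parameterization proven on
cortical segmentation at 16–40 nm working resolution; tests on
unit-anisotropy phantoms pass smaller `const` values explicitly, since
50 of those units would swallow a toy tube whole.

A border target is defined per 2D 4-connected component of each label's
cross-section on a task face: the peak of the component's 2D distance
transform, with ties broken in precedence order — closest to the
component centroid, then to the face center, then to the image corners,
then to the image edge. All four metrics are mirror-invariant, so the
task on the other side of the face (seeing the same slice through the
one-voxel overlap) picks the same world voxel; a residual tie (annuli,
X-shapes and similar symmetric components can leave up to eight
candidates) falls back to the smallest world coordinate
lexicographically — an explicit, documented asymmetric tie-breaker
chosen because *some* total order is required for stitching to be
deterministic. A shape contacting an edge line of the task box appears
in two faces' cross-sections and yields two targets; a corner, three.

`merge_skeletons` fuses vertices with identical world coordinates
(radius and type take the maximum across copies), then removes every
cycle by keeping the maximum spanning forest under edge weight = mean
endpoint radius — the thick centerline path through a loop survives and
the thin redundant edge goes. Terminal branches shorter than
`tick_threshold` whose far end is a junction are pruned iteratively.
Components whose minimum pairwise vertex distance is smaller than *both*
components' distances to the volume boundary are joined by their closest
vertex pair ("min over both components" is this package's reading of
the otherwise underdetermined rule; it is deliberately conservative —
two fragments are only joined when neither could plausibly continue
past the dataset edge instead). The result is always a forest, which is
also what makes SWC export (rooted per tree at the highest-radius
vertex) well-defined; cyclic input to the SWC writer is an error by
design.

## Contrast correction

Per-Z-slice histogram equalization in two passes. Pass 1 lays square
patches (default 64×64) on a regular grid covering at least the
requested fraction of the slice area (default 1%) and writes one JSON
per slice with the binned counts (2^bitdepth bins) and patch geometry.
Pass 2 builds, per slice, the LUT
`out(v) = floor((F(v) − clip_low) / (1 − clip_low − clip_high) · maxval)`
clamped to [0, maxval], where `F` is the normalized sample CDF and the
clip fractions (default 0.01 each) saturate the tails. The mapping is a
pure per-slice LUT, so chunked application is identical to whole-slice
application — the property that lets pass 2 run as grid tasks — and it
is monotone and idempotent up to quantization. Histograms are sampled at
the working mip (not forced to mip 0): the correction applies to the
data it will rewrite.

## Task queue

One JSON file per task in a queue directory. Leasing stamps
`lease_expiry = now + seconds` under an on-disk mutex (`dir.create`,
atomic on POSIX filesystems, stands in for advisory file locking);
an unexpired lease excludes other workers and an expired one re-exposes
the task, so execution is at-least-once and every pipeline task is
written to be idempotent — re-execution rewrites byte-identical output,
which the tests audit with directory digests. The clock is injectable,
so lease expiry and renewal are tested with simulated time. Failed
handlers leave the task in place (no dead-letter queue — retries are
infinite by design); the worker loop backs off exponentially when the
queue is empty and can terminate automatically when it drains.

## Synthetic fixtures and what passing means

`make_dense_labels` (seeded Voronoi labeling) emulates the geometry of
densely packed cellular segmentation: every voxel labeled, smooth
convex-ish boundaries, realistic boundary density. It does not emulate
split/merge errors, thin processes crossing hundreds of chunks,
ultrastructure texture, or the heavy-tailed size distribution of real
segmentations. Tube, ball and Y-branch phantoms provide analytic ground
truth (centerline length, volume, junction position) for meshing and
skeletonization; the graded-noise image drives pyramid and contrast
tests. Passing therefore demonstrates correctness of the formats,
codecs, stitching contracts and algorithms at desk scale — not
robustness to the pathologies of real automatic segmentation, nor the
throughput claims that motivate the chunked design in production.

Problem sizes were chosen to keep the full suite comfortably within a
single-CPU run: volumes up to 64³ (512×512×64 for the pyramid
arithmetic, where the numbers only stabilize with depth), tube phantoms
of 60–100 voxels, and a radius-14 ball with proportionally scaled soma
thresholds standing in for full-size somata.

## Known limitations

* Shard files, cseg/compresso streams and mesh/skeleton binaries are
  self-consistent dialects; cross-tool byte compatibility is untested.
* Labels and byte offsets ride in doubles: exact below 2^53.
* Meshing does not cap objects at dataset boundaries; only interior
  objects are guaranteed watertight.
* Soma handling is per-chunk: a soma split across tasks is skeletonized
  without full context, the known weak spot of crude grid division.
* The queue's mutual exclusion relies on `dir.create` atomicity, which
  holds on local POSIX filesystems but is not guaranteed on all network
  mounts.
* Multi-channel volumes pass through metadata but are not processed.
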