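---
title: "Methods: quantifying retinogeniculate circuit segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying retinogeniculate circuit segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitseg)
```

This vignette documents the models, parameters and numerical choices
behind `circuitseg`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic benchmarks do and do
not establish.

## Data model

All coordinates are nanometres, in `(x, y, z)` order matching the SWC
column order. Voxel-to-physical scaling (for serial-section EM volumes,
where cutting compresses tissue anisotropically; e.g. 26 x 20 x 40 nm
per voxel) is applied exactly once, at load time — readers take a
`voxel_scaling`, writers emit nm. SWC structure codes follow the de
facto convention (1 soma, 2 axon, 3 dendrite; others preserved unused).

Synapse tables are CSV with the fixed header
`synapse_id,pre_cell,post_cell,x_nm,y_nm,z_nm,pre_class,post_class`.
One record is one counted input: a bouton with several release sites
onto the same target appears once. Presynaptic cells need not have
skeletons — RGC axons are typically represented by their boutons only,
so unresolved endpoints are flagged as orphans rather than rejected.
Synapse direction relative to a focal cell is inferred from which side
the cell appears on (`post_cell` = input, `pre_cell` = output), so no
direction column is needed.

## Bouton field classification

The island is identified optically in the original preparations; a
computational pipeline needs an explicit surrogate. We use a gridded
Gaussian kernel density of all RGC bouton positions:

* **bandwidth** (kernel SD): default 2x the mean nearest-neighbour
  bouton spacing. Smaller values fragment the fields; larger values
  bleed density across the exclusion zone.
* **grid step**: bandwidth / 2 — fine enough that voxelisation does not
  move boutons across the threshold surface.
* **level fraction**: 0.1. Voxels with density at or above 0.1x the
  global maximum are "field"; 6-connected components of such voxels are
  candidate fields.

The island is the component with the smallest volume-to-bouton-count
ratio (the most compact dense component — the analogue of a bright,
distinct cluster); boutons in any other component are non-island;
boutons below threshold (in particular, stray boutons in the middle of
the exclusion zone) are ambiguous. If every bouton falls in one
component the labeling carries a `no_split` flag rather than failing —
the caller decides. The mean nearest-neighbour spacing is estimated
from a deterministic stride subsample of up to 1024 query points (each
query sees every point), which is unbiased and keeps the estimate
reproducible.

The island boundary is never defined quantitatively in optical data —
it is drawn by eye — so the density-isocontour definition here is a
methodological choice, stated as such.

## Exclusion-zone measurement

Shell thickness is measured radially: rays are cast from the island
bouton centroid along a deterministic quasi-uniform direction sample
(Fibonacci sphere, default 500 rays). Along each ray, boutons within a
perpendicular tube radius (default 2x bandwidth) are collected, and the
gap between the last island bouton and the first non-island bouton
beyond it estimates the local thickness; rays that never meet a
non-island bouton are excluded and counted. The median over rays is the
headline statistic; a `no_zone` flag is raised when it falls below 3x
the mean bouton spacing (a gap indistinguishable from inter-bouton
spacing is not a zone).

Ray directions are expressed in the island's principal-axis frame with
an intrinsic sign convention (positive third moment along each axis),
which makes the measurement equivariant under rigid motions of the data
to machine precision. Radial measurement is adequate for convex-ish
islands; for strongly concave islands it would underestimate local
thickness — a documented limitation.

## Separation projection

The axis maximising the 1D margin between the projected supports of the
two fields is found by scanning a Fibonacci-sphere grid at the requested
angular resolution (default 2 degrees), then refining the two spherical
angles by alternating golden-section search (three rounds, shrinking
windows). Ties during the scan resolve to the lexicographically
smallest axis, making the search fully deterministic. The reported
margin is clamped at zero; when the classes interpenetrate the count of
points inside the overlap interval is reported instead. The returned
3 x 3 rotation is right-handed with the separation axis as its third
row, oriented so the island projects low.

Note that a field that fully surrounds the island admits no separating
slab, so the margin on default synthetic circuits is legitimately zero;
real reconstructions sample a partial surround, which is where a
positive margin (the "clearest separation" view) comes from. The
operation's accuracy is therefore validated on slab-separated
constructions with known gaps.

## Capture statistics

A TC's innervation profile counts its RGC inputs per field label and
its *primary dendrites* — soma-adjacent subtrees whose subtree carries
at least one RGC synapse. Synapses attach to the nearest skeleton node;
attachments farther than 500 nm raise a warning but still count, since
every reconstruction is partial. Capture classes: `no_rgc` (no RGC
input), `ambiguous_zone` (more than `ambiguous_fraction` = 0.5 of
inputs ambiguous — the single observed cell of this kind was handled
narratively in the source data, so the cutoff is ours and is a config
knob), `pure_island` / `pure_nonisland` (all field-assignable input
from one field), else `mixed`.

The null model: each of a cell's $k_i$ RGC-connected primary dendrites
independently joins either field with probability 1/2, so the cell is
captured with probability $p_i = 2^{1-k_i}$ and the captured-cell count
is Poisson-binomial. The exact distribution is computed by sequential
convolution — $O(n^2)$ in the number of cells, which is tens at most, so
clarity beats FFT. The Monte Carlo path simulates the dendrite coins
directly (default 100,000 trials, one seeded generator per result, seed
recorded). Quantile convention, taken verbatim from the model's
definition: the smallest $m$ whose empirical CDF reaches the level
("$m$ or fewer captured in at least 99% of trials"). Cells with no
RGC-connected dendrite are excluded from the null (the dendrite-count
list counts *connected* dendrites by definition); the summary records
`n_eligible` alongside `n_tc` to keep the cell selection explicit.
Exceedance reporting gives exact and empirical upper tails only — the
null is a reference model, not a designed hypothesis test, and the
package deliberately avoids significance wording.

Arbor asymmetry is summarised by the offset from the soma centroid to
the centroid of the cell's RGC input positions, plus its projection on
the outward radial direction from the island centroid through the soma
(positive = away from the island).

## Neurite geometry

Skeletons decompose into branches: for each soma-adjacent subtree the
trunk is the longest root-to-tip path, and side subtrees hanging off a
trunk are decomposed recursively. The exclusion-zone crossing test
samples each branch polyline (including its attachment edge) at arc
steps of at most 200 nm — below typical neurite radius — and asks, per
point, whether it is below the density threshold *and* within
(median gap + bandwidth) of the nearest island bouton; this confines
"the zone" to the bouton-free shell adjacent to the island rather than
all empty space.

LIN branch types: `lin_shaft` for path length >= 100 um (shaft
dendrites span hundreds of micrometres); `lin_axon_like` for branches
with outputs and no inputs; `lin_targeted` for branches up to 2x the
nominal 20 um targeted reach with synapse density >= 0.5 per um; else
`unclassified`. The thresholds are scale choices justified by the
qualitative anatomy, not measured constants, and all are config values.
Raising `targeted_reach` can only grow the targeted set — it never
reclassifies a targeted branch as shaft, since the shaft rule depends
on length alone. TC branches are split proximal/distal by mean radius
(> 400 nm) or the presence of an RGC input, mirroring the qualitative
proximal-to-distal transition. Field purity of a branch is
max(island, nonisland) / (island + nonisland), ambiguous excluded,
undefined (NA) without field-assignable inputs.

## The synthetic generator

The generator emulates the *statistical* structure the analysis
consumes, not tissue realism:

* Island: uniform boutons in an ellipsoid (default semi-axes 15, 12,
  10 um — an idealisation of an irregular optical island that preserves
  its topology: dense core, bouton-free shell, surround).
* Exclusion zone: a shell of width 10 um (semi-axes grown by the
  width), containing zero boutons by construction.
* Surround: uniform boutons in an ellipsoidal annulus of thickness
  6 um beyond the shell. Sampling the surround as a bounded annulus —
  rather than an unbounded box — keeps its density comparable to the
  island's (roughly 0.07 vs 0.10 boutons/um^3 at the defaults of 800
  island and 3300 surround boutons), which a single relative density
  threshold requires. These sizes are chosen self-consistently
  (island ≫ shell ≫ bouton spacing), not presented as measured values.
* TCs: nine somata, quasi-uniformly spread over the inner quarter of
  the shell (their nuclei sit in the zone; a cell captured by the
  surround must reach across it, as such arbors do). Primary dendrite
  counts default to the observed per-cell list (2,2,3,4,4,4,5,5,7).
  Each TC draws a home field; each dendrite follows it with probability
  `segregation`, else flips a fair coin — so segregation 1 reproduces
  full capture and segregation 0 *is* the independent-dendrite null,
  making the generator an end-to-end check of the null-model code path.
  Total RGC inputs per cell are drawn uniformly from 0–118 and floored
  at the dendrite count, because the dendrite list counts dendrites
  that have at least one RGC input. Dendrites select boutons of their
  field with a Gaussian distance decay from the soma (SD 10 um):
  proximal arbors collect input locally, and a heavier-tailed decay
  would let the sheer volume of distant neuropil outweigh the near
  field. Dendrite polylines simply chain the selected bouton positions
  — tortuosity and branching angles are deliberately not modelled, only
  what the analysis consumes (topology and synapse positions).
* LINs: soma in the shell; two shaft branches (>= 100 um) running
  through the island and outward, with sparse inputs/outputs only
  outside the shell; one short tortuous targeted neurite per field
  (~16 um path, ~20 dense inputs adopted from that field's boutons plus
  outputs); one short output-only axon-like branch angled away from the
  shaft's input sites.

All randomness flows from one seed recorded in the provenance;
identical configs give byte-identical datasets. `degrade_circuit`
provides a partial-reconstruction harness (i.i.d. synapse drops,
isotropic Gaussian position jitter with RMS displacement
`jitter_sd * sqrt(3)`).

What passing synthetic benchmarks does *not* show: robustness to
irregular island shapes, partial surround coverage, anisotropic bouton
densities, registration error between modalities, or tracing errors
other than uniform synapse loss and jitter. Those require real
annotated volumes.

## Problem sizes and runtime envelope

Defaults were chosen so a full pipeline run (generate, classify,
profile, null model, neurites, report) takes on the order of a second:
4100 boutons, 9 TCs, 2 LINs, a density grid of roughly 80^3 voxels
(separable Gaussian blur as three dense matrix products; connected
components via `igraph` on the 6-neighbour voxel graph). The
calibration benchmark runs 100 independent seeds at segregation 0 and
checks that the observed capture count lands in the exact null's
central 99% interval in at least 95 of them. The Monte Carlo null at
100,000 trials takes well under a second.

## Output contract

Every run writes its resolved configuration and seed next to its
outputs; summaries are versioned (`schema_version`) and checked
structurally against the schema shipped in `inst/schema/` by
`validate_summary()` (required keys and version; a lightweight check by
design). JSON/CSV outputs are byte-identical across reruns of the same
config and seed; figures are compared structurally (existence,
non-emptiness), not byte-wise.
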