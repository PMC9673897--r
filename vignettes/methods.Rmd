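---
title: "Methods: the ease-of-social-distancing index pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ease-of-social-distancing index pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdindex)
```

## The model

The index summarises, for each street-block-scale spatial unit in an urban
area, how hard physical distancing is likely to be. It averages two 0–10
scores:

* a **built score** — the fraction of the unit covered by building
  footprints, binned by deciles (0 when no building is present);
* a **population-density score** — the unit's mean residential density
  classified against thresholds from an idealised spacing model.

The spacing model tiles the plane with regular hexagons, one person at each
centroid. With apothem $d$ (half the centre-to-centre spacing) a hexagon
covers $A(d) = 2\sqrt{3}\,d^2$ and the maximum sustainable density is
$T(d) = 10^6 / A(d)$ persons per km². A 2 m distancing requirement with
freedom to move needs $d = 3$ m ($A = 31.18$ m², $T = 32{,}075$ /km²);
sweeping $d$ in 1 m steps up to 11 m ($A = 419.16$ m², $T = 2{,}386$ /km²)
produces the score bands 10 down to 2, with positive densities below
$T(11)$ scoring 1 and zero population scoring 0.

```{r}
build_threshold_table()
```

**Threshold comparisons use the unrounded $T(d)$.** The printed anchors
(32,075; 2,386) are nearest-integer renderings of $10^6/31.1769\ldots$ and
$10^6/419.1563\ldots$; a density equal to the printed 32,075 therefore sits
marginally *below* the exact score-10 bound and classifies as 9. Rounding
the thresholds before comparison would reproduce the printed integer but
break the exact identity $T(d)\,A(d) = 10^6$ that the table is built on, so
the unrounded form is used throughout and the printed values are treated as
display renderings.

The index is $(\mathrm{BUILTscore} + \mathrm{POPscore})/2$, a multiple of
0.5 in $[0, 10]$; a missing population score propagates as the numeric
nodata value −99 (never null, so attribute tables stay type-stable).

### Assumptions

* Residential (census-anchored, night-time) population is the relevant
  exposure; daytime redistribution is out of scope.
* Building height and floor space are ignored; the built score measures
  ground coverage only.
* The spacing thresholds assume obstruction-free movement, so they are
  upper bounds on feasible spacing in real streetscapes.

## Pipeline stages and tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| urban classes | 21–30 | — | settlement-model classes treated as urban |
| quality flag | 1 | — | urban-centre true-positive marker |
| component buffer | 3000 | m | growth margin around contiguous urban cells |
| fringe area | 100,000 | m² | faces larger than this on the urban fringe are subdivided |
| minimum unit area | 10,000 | m² | 1 ha floor for spatial units |
| minimum units/extent | 30 | — | extents with fewer units are excluded |
| apothem sweep | 3–11 by 1 | m | population-score thresholds |
| nodata | −99 | — | attribute marker for missing data |

The defaults are the published operating point of the method; all are
exposed through `sdi_config()` and the command-line driver.

Stage order follows the published flow: extents → units → built metrics →
density metrics → scores. The 30-unit filter is applied **before** scoring;
scoring dropped extents would only discard work, and their records never
reach the output schema.

### Urban extents

Components use 8-connectivity so diagonal strings of settled cells are not
split into separate urban areas. Buffering and hulling are done in a local
azimuthal equidistant frame centred on the component centroid (see
*Coordinate handling*). Hull merging iterates to a fixpoint: merging two
hulls can create overlap with a third, and the published description
("overlapping hulls are a single urban area") only makes sense at the
fixpoint. Extent IDs are `ISO3_NNNN`, numbered south-to-north then
west-to-east by centroid (rounded to 10⁻⁶ to keep exact coordinate ties
stable against boolean-op jitter).

Coastal trimming takes a national *land polygon* (admin boundary minus
optional water polygons) rather than a raw coastline polyline: without a
polygon-assembly step a line cannot bound a clip region, and the synthetic
inputs supply land and water polygons directly.

### Street-block units

All linear features, land-use outlines and the extent boundary are noded
(split at mutual intersections, including collinear overlaps) and the faces
of the resulting planar arrangement are extracted by the half-edge walk:
outgoing edges are sorted by angle at every vertex, each directed edge is
followed into its face, counter-clockwise cycles are bounded faces and
clockwise cycles become holes of the smallest containing face. Land-use
polygons contribute their outlines *and* their interiors become standalone
faces — an airport is its own unit.

Numerical choices:

* **Snap tolerance 10⁻³ m (1 mm)** in the metric frame. Clipper's integer
  scaling perturbs clipped coordinates by up to ~10⁻⁶ of a unit; snapping
  at 1 mm absorbs that while being five orders of magnitude below any
  feature of interest. Boolean operations fix the Clipper resolution at
  10⁻⁹ so jitter stays far below the snap.
* **Dangling line ends are kept**; a dead-end road contributes no face
  boundary and is traversed out-and-back by the walk, leaving areas exact.
* Degenerate rings (fewer than 3 distinct vertices, zero area) are dropped
  on read with a warning, or rejected when `repair = FALSE`.

Fringe faces (> 100,000 m² crossing a BUA/SSA *boundary curve* — crossing
the curve, not merely lying inside the polygon) are re-polygonised with
residential outlines in a single global arrangement, so face adjacency
stays consistent for the merge step.

Sub-hectare faces merge iteratively, smallest first, into the neighbour
sharing the longest common boundary; ties go to the larger neighbour, then
the lowest stable face ID. Merged areas are accumulated additively (not
re-measured from the unioned polygon), which preserves the partition's
total area to machine precision. An isolated sub-threshold face with no
neighbour is retained with a warning; a single face below the floor simply
remains (there is nothing to merge it into).

### Scoring

Zonal density averages the cells whose centroids fall inside the unit,
dropping nodata cells. When no usable centroid falls inside — a unit
smaller or thinner than one 3-arc-second cell — the density is interpolated
**bilinearly at the unit centroid** from the 4 nearest cell centres, with
nodata neighbours dropped and weights renormalised; if that also fails the
unit is −99. Bilinear interpolation reproduces a constant field exactly and
is the simplest scheme consistent with "interpolating neighbouring grid
cell values". Densities are carried in double precision and never rounded
before classification.

Building footprints are dissolved before summation so overlapping digitised
roofs cannot push the built proportion above 1, then clipped to the unit;
a footprint straddling a boundary contributes exactly its clipped share to
each side (conservation is tested to < 10⁻⁶ relative).

### Coordinate handling

Two CRS families are supported: a local metric plane and geographic lon/lat
(WGS84). Per-extent metric work on geographic data uses an azimuthal
equidistant projection on the sphere of Gaussian curvature radius
$\sqrt{MN}$ at the centre latitude, which keeps planar areas within 0.1% of
geodesic areas over city-sized windows (asserted in the tests via an
independent geodesic-area computation).

## Output schema

The three published layers are written as GeoJSON under the stems
`{ISO3}_SocialDistancing_v1_0_{index|urban_extents|urban_points}`, with the
exact published field names (`uext_ID`, `adm0_ISO3`, `UNIT_AREA`,
`BUILT_AREA`, `BUILT_PROP`, `NBUILTPROP`, `POP_DENS`, `BUILTscore`,
`POPscore`, `INDEXvalue`; extent and point layers analogous). This R stack
has no GDAL binding, so Shapefile/GeoPackage/GeoTIFF drivers are not
offered; GeoJSON (vectors) and ESRI ASCII grid with a JSON CRS sidecar
(rasters) are plain-text, lossless for attributes, and round-trip tested.

## The synthetic generator

`generate_city()` builds a toy country exercising every pipeline stage with
known ground truth. Cities are regular street grids (default 6 × 6 blocks
of 300 m — one city alone clears the 30-unit filter). Per-block targets are
realised *exactly*:

* buildings are squares centred (with seeded jitter) in a 5 × 5 subcell
  lattice, side $\sqrt{p}\times$ subcell, so coverage equals the target $p$
  identically and no building straddles a block;
* population counts are density × cell area for every 100 m cell whose
  centre lies in the block, so the zonal mean equals the target for any
  subset of covered cells.

Default fields sweep all built scores 1–10 and population scores 0–10 and
include three designed blocks: no-buildings/no-people (index 0), 95%
built at 35,000 /km² (index 10), and a nodata-population block (−99).
Density values sit mid-band so classification is insensitive to
floating-point noise, and blocks with people always have buildings,
mirroring population rasters constrained to settled cells.

`generate_edge_cases()` adds a 40 m strip unit with no cell centroid
(forcing the bilinear fallback), a footprint straddling two units, a
sub-hectare sliver that must merge away, a fringe group subdivided by
residential outlines, and two further cities yielding a 29-unit extent
(excluded) and a 30-unit extent (kept).

What the generator does **not** emulate: realistic building shapes and
sizes, demographic structure, raster/vector misregistration, OSM topology
errors, or density gradients within blocks. Passing tests therefore
demonstrate correctness of the computational chain under clean planted
conditions, not robustness to survey-grade messiness.

Problem sizes throughout the suite are deliberately small — a ~14 km toy
country on a 100 m population grid (~20,000 cells), 36–99 units per run,
oracle sweeps of 50–100 random cases — chosen so the whole chain, including
the exhaustive oracles, runs in about a minute while still covering every
branch of the method.

## Validation module

Units are classed `Informal`/`Other` either by ≥ 50% area overlap with
informal-settlement polygons (the threshold is inclusive) or by the modal
type of intersecting buildings (ties and building-free units default to
`Other`, ties are reported). Joint score distributions and exceedance
proportions exclude −99 units, so proportions are over units with data;
including them would deflate both classes by an amount unrelated to
distancing feasibility. On fixtures with high densities planted inside the
informal polygons, the informal exceedance of POPscore ≥ 7 strictly
dominates the other class, reproducing the qualitative published contrast.

## Known limitations

* No GDAL formats (Shapefile/GeoPackage/GeoTIFF); conversion must happen
  outside the package.
* The noding step is quadratic in segment count — fine at city scale with
  per-extent processing, not tuned for continental runs.
* Hull merging and extent clipping operate on geographic coordinates
  directly when inputs are geographic; over very large extents (hundreds of
  km) hulls back-projected from the metric frame can be marginally
  non-convex.
* The apothem-to-distancing-rule mapping is documented for the 2 m → 3 m
  case only; the model is parametrised by apothem directly.
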