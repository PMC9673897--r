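# sdindex — ease of social distancing index for urban areas

`sdindex` computes a per-street-block **ease of social distancing index**
for urban areas, the kind of high-resolution feasibility map produced for
sub-Saharan African cities during the COVID-19 pandemic. It is aimed at
spatial epidemiologists and population geographers who work with settlement
model rasters, urban-centre databases, OpenStreetMap features, building
footprints and gridded population estimates.

## The method

For each urban area the pipeline:

1. **Delineates the urban extent.** Settlement-model classes 21–30
   (peri-urban through urban centre) are reclassified to a binary urban
   grid; connected components (8-connectivity) contiguous with a
   quality-flagged urban centre (`QA2_1V = 1`) are buffered by 3 km and
   replaced by their convex hull; overlapping hulls merge until the extents
   are disjoint, and extents are clipped to the national land polygon.
2. **Builds street-block spatial units.** Roads, railways, waterways and
   land-use boundary outlines are noded and polygonised inside each extent.
   Faces larger than 100,000 m² that cross a built-up-area (BUA) or
   small-settled-area (SSA) boundary are subdivided with residential
   land-use outlines; faces below 1 ha (10,000 m²) are merged iteratively
   into neighbours; extents with fewer than 30 units are excluded.
3. **Scores the built environment.** Building footprints are dissolved,
   clipped to each unit, and summed:
   `BUILT_PROP = BUILT_AREA / UNIT_AREA`. The built score is 0 with no
   buildings, otherwise the decile bin: `(0, 0.1] → 1`, …, `(0.9, 1] → 10`.
4. **Scores population density.** A density raster (counts ÷ cell surface
   area, 3-arc-second grid) is averaged over the cells whose centroids fall
   in the unit (bilinear fallback at the unit centroid for units smaller
   than a cell). Thresholds come from an idealised hexagonal tessellation in
   which each person occupies one hexagon of apothem *d* (half the
   centre-to-centre spacing):

   A(d) = 2·√3·d², T(d) = 10⁶ / A(d) persons/km²

   For a 2 m distancing rule, *d* = 3 m: A = 31.18 m², T = 32,075 /km² —
   densities at or above that score 10. Sweeping *d* to 11 m
   (A = 419.16 m², T = 2,386 /km²) yields scores 9…2; positive densities
   below T(11) score 1; zero population scores 0; missing data is −99.
5. **Computes the index**: `INDEXvalue = (BUILTscore + POPscore) / 2`, in
   {0, 0.5, …, 10}, −99 when the population score is missing. High values
   mean distancing is hard (dense people *and* dense buildings).

There is no GDAL in this stack: vector I/O is GeoJSON, raster I/O is ESRI
ASCII grid, and the planar geometry (noding, face extraction, boolean ops
via Clipper/`polyclip`) is built in.

## Worked example

The package ships a seedable synthetic-country generator that emulates
every production input (settlement grid, urban centres, streets, land-use,
footprints, population rasters) with planted per-block ground truth:

```r
library(sdindex)

print(build_threshold_table())
#>  apothem_m hex_area_m2 max_density_km2 pop_score
#>          3       31.18           32075        10
#>          4       55.43           18042         9
#>          ...
#>         11      419.16            2386         2

bundle <- generate_city(city_config(seed = 1))
res <- sdi_pipeline(bundle)
print(res)
#> Ease-of-social-distancing pipeline result
#>   urban extents: 1 found, 0 excluded (<30 units), 1 kept
#>   spatial units: 37 built, 37 scored, 1 nodata
#>   index values: 0.0-10.0 (median 5.0)

write_outputs(res, "output")   # XXX_SocialDistancing_v1_0_{index,urban_extents,urban_points}
plot(res)                      # units shaded by index value
```

The 36 planted blocks cover every built score (0–10) and population score
(0–10) including a no-building/no-population block (index 0), a fully built
high-density block (index 10) and a missing-population block (index −99);
the pipeline reproduces all of them exactly, plus the 37th unit: the urban
fringe ring inside the extent hull, which scores 0.

A command-line driver wraps the same functions:

```sh
Rscript inst/cli/sdi.R thresholds
Rscript inst/cli/sdi.R synth --dir fixture --seed 1
Rscript inst/cli/sdi.R run --dir fixture --out output
Rscript inst/cli/sdi.R validate --dir fixture
```

## Limitations

The index uses residential (night-time) population only, ignores building
height and floor space, and the spacing thresholds assume obstruction-free
movement; see the methods vignette (`vignettes/methods.Rmd`) for the full
discussion of assumptions, parameter choices and numerical tolerances.
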