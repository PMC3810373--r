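---
title: "Building and deforming a generic 3D anchor model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and deforming a generic 3D anchor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchor3d)
```

## The modelling idea

A dactylogyridean anchor drawn in lateral view is, geometrically, a
curved strip: a medial path runs from the inner-root end of the base,
through the shaft, to the tip of the recurved point, and the outline is a
varying width swept along it, with lobes (the outer root, occasionally an
"ear") protruding from one side. `anchor3d` exploits this: point
primitives are laid out on the drawing as rows across the local width at
stations along the medial path, each primitive is duplicated on two
parallel planes, and the resulting rectangular building blocks are welded
into a closed, all-quad control mesh. The displayed surface is the
Catmull-Clark subdivision of that mesh, and every control vertex is a
pilot point for deformation.

The assumptions this rests on:

* the anchor is drawn in lateral view and its outline is a simple,
  counter-clockwise closed polygon;
* at every station, the line normal to the medial path crosses the
  outline on both sides of the path — the shape is strip-like, never
  branching;
* depth is not informative: the model is a constant-thickness slab, and
  deformation targets are 2D outlines.

## Site densification

Seven intervals of normalized medial arc length carry the labels I–VII of
the sites of high morphological variation. The packaged intervals place
I–II on the inner-root region, IV on the outer root, III and V on the
shaft, VI on the region where ear extrusions form, and VII on the
recurved point. A site with in-plane count c receives `n_along` stations
of `n_across` primitives using the fixed factorizations 4 = 2×2, 6 = 3×2,
8 = 4×2, 16 = 4×4. Counts are read as *in-plane* primitives (the z
duplication doubles them in 3D); this is consistent with a rectangular
surface having 4 point primitives while the block has 8. Extrusion-prone
sites (VI, VII) get 4 primitives across the width because a lobe needs
resolution transversally as well as longitudinally.

Where the across-resolution changes (2 ↔ 4 between a normal span and a
16-count site), the gap between the last coarse and the first fine
station is meshed with a two-quad transition template — the hexagonal
region with 2 coarse and 4 fine boundary points splits into exactly two
quads with one interior edge and no added vertices. This keeps the
boundary mesh all-quad and conforming (no T-junctions, no zero-area
faces); a duplicated-station scheme was rejected because it necessarily
creates either degenerate quads or edges shared by the wrong number of
faces.

The chord at a station is bounded by the outline crossings *nearest the
medial point*, one on each side. Using all crossings of the infinite
normal line would reject every realistic anchor — a shaft normal
eventually also hits the distant recurved point. An error is still raised
when a side has no crossing at all.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `site_config()` counts | 4 / 8 / 8 / 8 / 8 / 6 / 16 / 16 | primitives | per-site densification (normal, I–VII) |
| `n_normal_stations` | 12 | stations | resolution of unannotated spans |
| `thickness` | 1 | grid units | slab depth; purely a display choice for lateral-view drawings |
| `display_levels` | 2 | levels | Catmull-Clark depth for display, silhouettes and fitting; 2 is visually smooth at these block resolutions |
| `fit_tolerances()` | rel 0.015, iou 0.95, lambda 0.8 | — | stopping rule and step fraction of the fitting loop |
| `optimize_site()` | step 2, max_count 32 | primitives | optimization increments and ceiling |

The fit tolerances operationalize a visual criterion ("the model fills
the target outline"): the mean symmetric silhouette distance must drop
below 1.5% of the target bounding-box diagonal *and* the silhouette/target
area IoU must reach 0.95. The step fraction λ = 0.8 converges in a few
iterations on these coarse control meshes; iterations that would increase
the mean distance are rolled back with a halved step (up to 5 halvings)
so accepted traces are monotone by construction.

## The deformation loop

Fitting does not move boundary pilots *onto* the target outline. Because
Catmull-Clark smoothing pulls the surface inside its control cage, a
model whose boundary pilots sit exactly on the target would still show a
silhouette strictly inside it. Instead each boundary pilot is charged
with the *silhouette residual* at its arc position: the silhouette and
the target are aligned by normalized arc length (brute force over 64
cyclic offsets × 2 orientations), and the pilot moves λ·(target point −
silhouette point), in-plane only, with z preserved. At convergence the
pilots sit slightly outside the target outline, exactly compensating the
subdivision shrinkage. Interior and back-layer vertices follow by
inverse-distance-weighted (power 2) interpolation of the boundary
displacements; a Laplacian solve would also work but is unnecessary at
~100 in-plane points and would add a solver dependency to a loop that is
deterministic as written.

The silhouette itself is the contour between front-facing (face normal
with positive z) and back-facing faces of the subdivided mesh, projected
to the x–y plane; for a z-symmetric slab this is a single closed loop.
Under edge-on rotations the projection can self-occlude: contour loops
contained in the main loop are then ignored, while genuinely disjoint
components raise an error.

## Numerical choices

* **Area IoU by rasterization.** No polygon-clipping library is assumed;
  IoU is estimated on a 160 × 160 grid over the joint bounding box
  (320 × 320 in the closed-form unit tests), giving ~1% accuracy at the
  sizes used. The estimate is deterministic for a fixed grid.
* **Distances.** Mean symmetric and Hausdorff distances use 256 boundary
  samples per polygon measured against the other polygon's full segment
  set, so they are exact up to the sampling of the *source* curve only.
* **Degeneracy guards.** Zero-area quads are rejected at build time at
  1e-9 grid-units²; polygons with area below 1e-9 are rejected by the fit
  metrics; welds where three blocks share a face raise a topology error.
* **Hull certificate.** `limit_check()` certifies subdivision hull
  containment with a support-function test over 256 quasi-uniform
  directions. A point inside the hull can never fail the test, so it
  cannot produce false alarms; it detects displaced vertices rather than
  proving containment to machine precision.
* **Orientation.** Faces are wound counter-clockwise seen from outside;
  the weld inherits consistent orientation from the hexahedra and the
  global sign is fixed by the signed volume.

## The synthetic generator

`generate_synthetic_anchor()` sweeps an asymmetric width profile along an
analytic medial curve whose heading bends through the shaft and curls
through the point. The outer root is a Gaussian lobe on the outer side
inside the site IV interval; the optional ear is a lobe on the inner side
inside site VI; ornament ripples are seeded sinusoids scaled by the local
half-width. `variant_params(seed)` jitters the default dimensions by
15–30% (ears on even seeds) to emulate across-species diversity:
stubbier or longer shafts, stronger curl, enlarged roots.

What the generator emulates well: strip-like hook geometry, realistic
proportions (shaft ≈ 14 grid units, point ≈ 7.5, roots ≈ 3–4), smooth
lobed protrusions, exact knowledge of the medial path. What it does not:
hand-drawn irregularity, branching roots drawn as separate prongs,
open or self-overlapping outlines, digitization noise. Passing the test
suite therefore shows the pipeline is correct and the deformation
machinery reaches sub-grid accuracy on strip-like targets; it does not
show that an arbitrary scanned illustration can be fitted without first
preparing a clean outline and medial path (automatic medial-axis
extraction is deliberately out of scope).

## Problem sizes

The packaged configuration yields a control mesh of 188 vertices, 372
edges and 186 faces; at display level 2 the fitted surface has ~3,000
faces. Property suites run 50 seeded template/mesh builds; the
deformation suite fits 8 seeded variants (each converging in ≤ 5
accepted iterations); the optimization demo visits counts 4 → 6 → 8.

## Known limitations

* Branching root morphologies that violate the two-crossing assumption
  cannot be laid out; they would need a multi-strip or volumetric layout.
* Boundary/crease subdivision rules are unimplemented — every assembled
  mesh is closed, so they are never needed in this pipeline.
* Fitting matches silhouettes; it cannot recover out-of-plane (z)
  structure from a 2D drawing, and z is preserved during deformation.
* Per-site optimization is independent site by site; interactions between
  adjacent sites (a chosen count changing a neighbour's requirement) are
  not modelled.
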