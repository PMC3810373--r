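Package: anchor3d
Title: Deformable Generic 3D Models of Monogenean Haptoral Anchors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds a deformable generic three-dimensional model of the
    haptoral anchor of dactylogyridean monogeneans from a two-dimensional
    outline template. Point primitives laid out along the anchor outline
    are extruded into hexahedral building blocks, welded into a closed
    all-quad control mesh, and smoothed by Catmull-Clark subdivision. The
    generic model is deformed into new anchor shapes either by direct
    manipulation of pilot points fitted to a target outline or by
    wholesale replacement of the control-vertex coordinate table, with
    silhouette-based fit metrics, per-site primitive-count optimization,
    and readers and writers for coordinate tables and standard mesh
    formats (OBJ, PLY, STL, SVG overlays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
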