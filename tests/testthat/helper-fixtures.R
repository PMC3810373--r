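# Fixtures and independent oracles, built in code at test time.

# A straight rectangular "anchor": outline with 3 points per side (12
# total), horizontal medial line. Useful for predictable strip layouts.
rect_template <- function(L = 10, W = 2, name = "rect") {
  outline <- rbind(
    c(0, 0), c(L / 2, 0), c(L, 0),
    c(L, W / 2), c(L, W),
    c(L / 2, W), c(0, W),
    c(0, W / 2)
  )
  medial <- cbind(seq(0.3, L - 0.3, length.out = 20), W / 2)
  template2d(name, outline, medial, grid_spacing = 1)
}

# layout with a single row of n+1 two-point stations (n in-plane quads)
row_layout <- function(n, L = 10, W = 2) {
  layout_strip(rect_template(L, W), preliminary_config(),
               n_normal_stations = n + 1)
}

# Independent brute-force oracle for welded-block combinatorics: counts
# boundary faces / vertices / edges by explicit enumeration of the six
# faces of every hexahedron, pairing equal vertex sets.
brute_force_weld_counts <- function(blocks) {
  face_corners <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                       c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  keys <- character(0)
  faces <- list()
  for (b in blocks) {
    for (fc in face_corners) {
      f <- b[fc]
      keys <- c(keys, paste(sort(f), collapse = "/"))
      faces[[length(faces) + 1]] <- f
    }
  }
  tab <- table(keys)
  boundary <- faces[tab[keys] == 1]
  verts <- unique(unlist(boundary))
  edges <- unique(unlist(lapply(boundary, function(f) {
    idx <- cbind(f, f[c(2, 3, 4, 1)])
    paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]), sep = "/")
  })))
  list(V = length(verts), F = length(boundary), E = length(edges))
}

# polygon area by the cross-product formula, written independently of the
# package's shoelace helper (absolute value)
oracle_polygon_area <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

# a tiny independent OBJ parser: counts vertices and faces
oracle_parse_obj <- function(path) {
  lines <- readLines(path)
  list(V = sum(grepl("^v ", lines)), F = sum(grepl("^f ", lines)))
}

# the packaged generic model, built once per test run
generic_model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_final_model(anchor_template(), site_config())
    cache
  }
})
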