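# Hexahedral block assembly. Every in-plane point primitive is duplicated
# at z = +t/2 (front layer) and z = -t/2 (back layer); each in-plane quad
# between adjacent stations becomes one rectangular building block
# (hexahedron). Welding the blocks and dropping interior shared faces
# yields a closed, consistently oriented, all-quad boundary mesh.

# Relative ordering of the 8 block vertices: front quad counter-clockwise
# seen from +z, then the matching back quad.
HEX_FACES <- list(
  front = c(1, 2, 3, 4),
  back  = c(5, 8, 7, 6),
  s1    = c(1, 5, 6, 2),
  s2    = c(2, 6, 7, 3),
  s3    = c(3, 7, 8, 4),
  s4    = c(4, 8, 5, 1)
)

#' Extrude a strip layout into hexahedral building blocks
#'
#' @param layout a [layout_strip()] result with at least 2 stations.
#' @param thickness slab thickness in grid units (> 0); the two layers sit
#'   at z = +/- thickness/2.
#' @return List with `vertices` (data frame: id, x, y, z, station_index,
#'   across_index, layer, site; ids contiguous from 0) and `blocks` (list
#'   of 8-long integer vectors of 0-based vertex ids).
#' @export
#' @examples
#' lay <- layout_strip(anchor_template(), preliminary_config(), 10)
#' ext <- extrude_strip(lay, thickness = 1)
#' length(ext$blocks)
extrude_strip <- function(layout, thickness = 1) {
  stopifnot(inherits(layout, "strip_layout"))
  if (length(layout$stations) < 2)
    abort_anchor("extrusion needs at least 2 stations", "anchor3d_build_error")
  if (!is.numeric(thickness) || thickness <= 0)
    abort_anchor("thickness must be > 0", "anchor3d_parameter_error")
  st <- layout$stations
  k <- vapply(st, function(s) nrow(s$points), 0L)
  # in-plane point index table: front id = 2p-1, back id = 2p (1-based)
  offs <- c(0L, cumsum(k))
  P <- sum(k)
  xy <- do.call(rbind, lapply(st, `[[`, "points"))
  station_index <- rep(seq_along(st), k)
  across_index <- unlist(lapply(k, seq_len))
  site <- rep(vapply(st, `[[`, "", "site"), k)
  front_id <- function(t, j) 2L * (offs[t] + j) - 1L
  back_id <- function(t, j) 2L * (offs[t] + j)
  verts <- data.frame(
    id = seq_len(2L * P) - 1L,
    x = rep(xy[, 1], each = 2),
    y = rep(xy[, 2], each = 2),
    z = rep(c(thickness / 2, -thickness / 2), P),
    station_index = rep(station_index, each = 2),
    across_index = rep(across_index, each = 2),
    layer = rep(c("front", "back"), P),
    site = rep(site, each = 2),
    stringsAsFactors = FALSE
  )
  # in-plane quads (A at station t, B at station t+1), each listed
  # counter-clockwise seen from +z as (A_left, A_right, B_right, B_left)
  quads <- list()
  for (t in seq_len(length(st) - 1)) {
    ka <- k[t]; kb <- k[t + 1]
    if (ka == kb) {
      for (j in seq_len(ka - 1))
        quads[[length(quads) + 1]] <- c(t, j, t, j + 1, t + 1, j + 1, t + 1, j)
    } else if (ka == 2 && kb == 4) {
      # all-quad 2 -> 4 transition: two trapezoid halves
      quads[[length(quads) + 1]] <- c(t, 1, t, 2, t + 1, 4, t + 1, 3)
      quads[[length(quads) + 1]] <- c(t, 1, t + 1, 3, t + 1, 2, t + 1, 1)
    } else if (ka == 4 && kb == 2) {
      quads[[length(quads) + 1]] <- c(t, 1, t, 2, t + 1, 2, t + 1, 1)
      quads[[length(quads) + 1]] <- c(t, 2, t, 3, t, 4, t + 1, 2)
    } else {
      abort_anchor(sprintf("unsupported across-resolution transition %d -> %d between stations %d and %d",
                           ka, kb, t, t + 1), "anchor3d_build_error")
    }
  }
  blocks <- vector("list", length(quads))
  for (q in seq_along(quads)) {
    idx <- matrix(quads[[q]], ncol = 2, byrow = TRUE)  # 4 x (station, across)
    ip <- offs[idx[, 1]] + idx[, 2]
    # enforce counter-clockwise front quads (guards against a locally
    # reversed chord ordering)
    quad_xy <- xy[ip, , drop = FALSE]
    area2 <- signed_area(quad_xy)
    if (abs(area2) < 1e-9)
      abort_anchor(sprintf("degenerate (zero-area) quad between stations %d and %d",
                           idx[1, 1], idx[3, 1]), "anchor3d_degeneracy_error")
    if (area2 < 0) ip <- rev(ip)
    blocks[[q]] <- c(2L * ip - 1L, 2L * ip) - 1L  # front then back, 0-based
  }
  list(vertices = verts, blocks = blocks)
}

# undirected edge table of a face matrix (F x 4, 1-based vertex rows);
# returns list(edges = E x 2 sorted pairs, face_edge = F x 4 edge ids,
# counts = faces per edge)
mesh_edge_table <- function(faces) {
  f <- as.matrix(faces)
  e1 <- cbind(as.vector(f), as.vector(f[, c(2, 3, 4, 1)]))
  key <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  uk <- unique(key)
  eid <- match(key, uk)
  edges <- cbind(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))[!duplicated(eid), , drop = FALSE]
  edges <- edges[order(unique(eid)), , drop = FALSE]
  list(edges = edges,
       face_edge = matrix(eid, ncol = 4),
       counts = tabulate(eid, nbins = length(uk)),
       directed = e1, eid = eid)
}

quad_mesh_new <- function(vertices, faces, vdata = NULL) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces, vdata = vdata),
            class = "quad_mesh")
}

#' @export
print.quad_mesh <- function(x, ...) {
  et <- mesh_edge_table(x$faces)
  cat(sprintf("<quad_mesh>: V=%d E=%d F=%d\n",
              nrow(x$vertices), nrow(et$edges), nrow(x$faces)))
  invisible(x)
}

# Newell normals for (possibly non-planar) quads, rows not normalized
face_normals <- function(vertices, faces) {
  n <- matrix(0, nrow(faces), 3)
  for (i in 1:4) {
    a <- vertices[faces[, i], , drop = FALSE]
    b <- vertices[faces[, (i %% 4) + 1], , drop = FALSE]
    n[, 1] <- n[, 1] + (a[, 2] - b[, 2]) * (a[, 3] + b[, 3])
    n[, 2] <- n[, 2] + (a[, 3] - b[, 3]) * (a[, 1] + b[, 1])
    n[, 3] <- n[, 3] + (a[, 1] - b[, 1]) * (a[, 2] + b[, 2])
  }
  n / 2
}

mesh_signed_volume <- function(vertices, faces) {
  vol <- 0
  for (tri in list(c(1, 2, 3), c(1, 3, 4))) {
    a <- vertices[faces[, tri[1]], , drop = FALSE]
    b <- vertices[faces[, tri[2]], , drop = FALSE]
    c0 <- vertices[faces[, tri[3]], , drop = FALSE]
    vol <- vol + sum(a[, 1] * (b[, 2] * c0[, 3] - b[, 3] * c0[, 2]) +
                     a[, 2] * (b[, 3] * c0[, 1] - b[, 1] * c0[, 3]) +
                     a[, 3] * (b[, 1] * c0[, 2] - b[, 2] * c0[, 1]))
  }
  vol / 6
}

#' Weld hexahedral blocks into a closed quad boundary mesh
#'
#' Generates the six faces of every block, removes faces shared by two
#' blocks (interior welds) and keeps the boundary. The result is a closed,
#' consistently outward-oriented all-quad 2-manifold.
#'
#' @param vertices,blocks output of [extrude_strip()].
#' @return A `quad_mesh` (vertices V x 3 matrix, faces F x 4 of 1-based
#'   indices counter-clockwise from outside, vertex metadata in `$vdata`).
#' @export
#' @examples
#' lay <- layout_strip(anchor_template(), preliminary_config(), 10)
#' ext <- extrude_strip(lay)
#' mesh <- assemble_mesh(ext$vertices, ext$blocks)
#' validate_mesh(mesh)$is_closed
assemble_mesh <- function(vertices, blocks) {
  if (length(blocks) == 0)
    abort_anchor("no blocks to assemble", "anchor3d_build_error")
  V <- as.matrix(vertices[, c("x", "y", "z")])
  faces <- matrix(0L, nrow = 6 * length(blocks), ncol = 4)
  row <- 1L
  for (b in blocks) {
    hex <- b + 1L  # to 1-based
    for (fc in HEX_FACES) {
      faces[row, ] <- hex[fc]
      row <- row + 1L
    }
  }
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = " "))
  cnt <- table(key)
  if (any(cnt > 2))
    abort_anchor("non-manifold weld: a face is shared by more than two blocks",
                 "anchor3d_topology_error")
  boundary <- faces[cnt[key] == 1, , drop = FALSE]
  if (nrow(boundary) == 0)
    abort_anchor("welding left no boundary faces", "anchor3d_topology_error")
  # degenerate-face guard
  nrm <- face_normals(V, boundary)
  if (any(sqrt(rowSums(nrm^2)) < 1e-9))
    abort_anchor("degenerate (zero-area) boundary face after welding",
                 "anchor3d_degeneracy_error")
  mesh <- quad_mesh_new(V, boundary, vdata = vertices)
  # outward orientation: consistent by construction, but fix the global
  # sign from the signed volume as a safeguard
  if (mesh_signed_volume(V, boundary) < 0)
    mesh$faces <- boundary[, 4:1, drop = FALSE]
  mesh
}

#' Unique wireframe edges of a mesh
#'
#' @param mesh a `quad_mesh`.
#' @return E x 2 matrix of 1-based vertex index pairs, each edge once.
#' @export
wireframe_edges <- function(mesh) {
  stopifnot(inherits(mesh, "quad_mesh"))
  mesh_edge_table(mesh$faces)$edges
}

#' Structural report on a quad mesh
#'
#' Computes closedness (every edge in exactly two faces), orientation
#' consistency (each shared edge traversed in opposite directions by its
#' two faces), the V/E/F counts, the Euler characteristic and the number
#' of degenerate (zero-area) faces. Reports, never throws.
#'
#' @param mesh a `quad_mesh`.
#' @return A `mesh_report` list.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "quad_mesh"))
  et <- mesh_edge_table(mesh$faces)
  is_closed <- all(et$counts == 2)
  # orientation: for every undirected edge used twice, the two directed
  # copies must run in opposite directions
  dkey <- paste(et$directed[, 1], et$directed[, 2])
  is_oriented <- is_closed && !anyDuplicated(dkey)
  nrm <- face_normals(mesh$vertices, mesh$faces)
  degen <- sum(sqrt(rowSums(nrm^2)) < 1e-9)
  V <- nrow(mesh$vertices); E <- nrow(et$edges); F <- nrow(mesh$faces)
  structure(list(is_closed = is_closed, is_oriented = is_oriented,
                 V = V, E = E, F = F, euler = V - E + F,
                 degenerate_faces = degen),
            class = "mesh_report")
}

#' @export
print.mesh_report <- function(x, ...) {
  cat(sprintf("<mesh_report>: V=%d E=%d F=%d euler=%d closed=%s oriented=%s degenerate=%d\n",
              x$V, x$E, x$F, x$euler, x$is_closed, x$is_oriented, x$degenerate_faces))
  invisible(x)
}

#' Count in-plane point primitives assigned to a site
#'
#' Counts distinct in-plane positions (front-layer vertices) tagged with
#' the given site label.
#'
#' @param x a `generic_model`, `quad_mesh` with vertex metadata, or the
#'   vertex data frame from [extrude_strip()].
#' @param site a site label (`"I"`..`"VII"` or `"normal"`).
#' @return Integer count.
#' @export
#' @examples
#' model <- build_final_model(anchor_template(), site_config())
#' count_site_primitives(model, "IV")
count_site_primitives <- function(x, site) {
  if (inherits(x, "generic_model")) x <- x$control_mesh$vdata
  if (inherits(x, "quad_mesh")) x <- x$vdata
  if (is.null(x) || !all(c("layer", "site") %in% names(x)))
    abort_anchor("vertices carry no site tags", "anchor3d_lookup_error")
  if (!site %in% c(SITE_LABELS, "normal"))
    abort_anchor(sprintf("unknown site label '%s'", site), "anchor3d_lookup_error")
  sum(x$layer == "front" & x$site == site)
}
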