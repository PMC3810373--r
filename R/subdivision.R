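# Catmull-Clark subdivision for closed quad meshes. One level inserts a
# face point (face centroid) per face and an edge point (mean of the two
# edge endpoints and the two adjacent face points) per edge, and moves
# every old vertex to (Q + 2R + (n-3)S)/n with Q the mean of its adjacent
# face points, R the mean of its incident edge midpoints, S its old
# position and n its valence. All weights are nonnegative and each new
# position is a convex combination of old ones, so the refined mesh stays
# inside the convex hull of its control mesh.
#
# Because the rule is linear in the positions, a level is represented as a
# sparse matrix S with new_vertices = S %*% old_vertices; the deformation
# loop reuses the operator across iterations since topology never changes.

# One subdivision level of the connectivity: sparse operator + new faces.
cc_level_operator <- function(faces, nv) {
  et <- mesh_edge_table(faces)
  if (any(et$counts != 2))
    abort_anchor("Catmull-Clark requires a closed 2-manifold quad mesh",
                 "anchor3d_topology_error")
  nf <- nrow(faces); ne <- nrow(et$edges)
  # triplets for face points: 1/4 of each face vertex
  fp_i <- rep(nv + seq_len(nf), 4)
  fp_j <- as.vector(faces)
  fp_x <- rep(0.25, 4L * nf)
  # edge -> adjacent faces
  ef <- matrix(0L, ne, 2)
  fidx <- rep(seq_len(nf), 4)
  for (k in seq_along(et$eid)) {
    e <- et$eid[k]
    if (ef[e, 1] == 0L) ef[e, 1] <- fidx[k] else ef[e, 2] <- fidx[k]
  }
  # edge points: 1/4 each endpoint + 1/4 each adjacent face point
  ep_row <- nv + nf + seq_len(ne)
  ep_i <- c(rep(ep_row, 2), rep(ep_row, each = 8))
  ep_j <- c(et$edges[, 1], et$edges[, 2],
            as.vector(t(cbind(faces[ef[, 1], , drop = FALSE],
                              faces[ef[, 2], , drop = FALSE]))))
  ep_x <- c(rep(0.25, 2L * ne), rep(0.25 * 0.25, 8L * ne))
  # vertex update: valence n (= number of incident edges = faces, closed)
  val <- tabulate(as.vector(et$edges), nbins = nv)
  # Q: mean of adjacent face centroids -> (1/(4n)) on each vertex of each
  # incident face; R: mean of edge midpoints, weighted 2 -> (1/n^2) on each
  # edge endpoint (2/n * 1/n * 1/2 * 2 endpoints); S: (n-3)/n on itself.
  q_i <- integer(0); q_j <- integer(0); q_x <- numeric(0)
  # Q/n term: each incident face spreads its centroid over its 4 vertices,
  # so corner vtx receives 1/(4 n^2) from every vertex of every incident face
  for (c0 in 1:4) {
    vtx <- faces[, c0]
    q_i <- c(q_i, rep(vtx, 4))
    q_j <- c(q_j, as.vector(faces))
    q_x <- c(q_x, rep(1 / (4 * val[vtx]^2), 4))
  }
  r_i <- c(et$edges[, 1], et$edges[, 2], et$edges[, 1], et$edges[, 2])
  r_j <- c(et$edges[, 1], et$edges[, 2], et$edges[, 2], et$edges[, 1])
  r_x <- 1 / c(val[et$edges[, 1]], val[et$edges[, 2]],
               val[et$edges[, 1]], val[et$edges[, 2]])^2
  s_i <- seq_len(nv); s_j <- s_i; s_x <- (val - 3) / val
  S <- Matrix::sparseMatrix(
    i = c(fp_i, ep_i, q_i, r_i, s_i),
    j = c(fp_j, ep_j, q_j, r_j, s_j),
    x = c(fp_x, ep_x, q_x, r_x, s_x),
    dims = c(nv + nf + ne, nv)
  )
  # new faces: each old face (a,b,c,d) splits into 4 quads around its face
  # point, preserving orientation
  fpt <- nv + seq_len(nf)
  ept <- nv + nf + et$face_edge  # edge point ids per face edge (ab, bc, cd, da)
  new_faces <- rbind(
    cbind(faces[, 1], ept[, 1], fpt, ept[, 4]),
    cbind(faces[, 2], ept[, 2], fpt, ept[, 1]),
    cbind(faces[, 3], ept[, 3], fpt, ept[, 2]),
    cbind(faces[, 4], ept[, 4], fpt, ept[, 3])
  )
  list(S = S, faces = new_faces)
}

# Composed operator over `levels` levels for fixed connectivity.
cc_operator <- function(faces, nv, levels) {
  S <- Matrix::Diagonal(nv)
  f <- faces
  n <- nv
  for (l in seq_len(levels)) {
    op <- cc_level_operator(f, n)
    S <- op$S %*% S
    f <- op$faces
    n <- nrow(op$S)
  }
  list(S = S, faces = f, nv = n)
}

#' Catmull-Clark subdivision of a closed quad mesh
#'
#' Standard Catmull-Clark refinement. One level maps a mesh with V
#' vertices, E edges and F faces to one with V + E + F vertices, 4F faces
#' and 2E + 4F edges, preserving the Euler characteristic. `levels = 0`
#' returns the input unchanged.
#'
#' @param mesh a closed, consistently oriented `quad_mesh`.
#' @param levels number of refinement levels (>= 0).
#' @return The subdivided `quad_mesh` (vertex metadata is dropped for
#'   `levels > 0`).
#' @export
#' @examples
#' cube <- unit_cube_mesh()
#' nrow(catmull_clark(cube, 1)$vertices)  # 8 + 12 + 6 = 26
catmull_clark <- function(mesh, levels = 1) {
  stopifnot(inherits(mesh, "quad_mesh"))
  if (!is.numeric(levels) || levels < 0 || levels != round(levels))
    abort_anchor("levels must be a nonnegative integer", "anchor3d_parameter_error")
  if (levels == 0) return(mesh)
  op <- cc_operator(mesh$faces, nrow(mesh$vertices), levels)
  quad_mesh_new(as.matrix(op$S %*% mesh$vertices), op$faces)
}

#' Check hull containment of a subdivided mesh
#'
#' Certifies that every subdivided vertex lies inside the convex hull of
#' the control vertices, via a support-function test over a fixed
#' quasi-uniform set of directions: for each direction d, the maximum of
#' d . p over subdivided vertices must not exceed the maximum over control
#' vertices (up to a small tolerance). Points genuinely inside the hull
#' can never fail this test; points displaced well outside it are
#' detected.
#'
#' @param mesh the control `quad_mesh`.
#' @param subdivided a subdivision of it.
#' @param n_directions number of test directions.
#' @return `TRUE` if no direction certifies a vertex outside the hull.
#' @export
limit_check <- function(mesh, subdivided, n_directions = 256) {
  stopifnot(inherits(mesh, "quad_mesh"), inherits(subdivided, "quad_mesh"))
  D <- fibonacci_directions(n_directions)
  hc <- D %*% t(mesh$vertices)       # directions x control vertices
  hs <- D %*% t(subdivided$vertices)
  scale <- max(abs(mesh$vertices)) + 1
  all(apply(hs, 1, max) <= apply(hc, 1, max) + 1e-9 * scale)
}

#' Axis-aligned unit cube as a quad mesh
#'
#' A convenience fixture: the cube `[0,1]^3` with outward-oriented quad
#' faces, used to exercise the subdivision and export code.
#'
#' @return A `quad_mesh` with V=8, E=12, F=6.
#' @export
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  # vertices: 1 (0,0,0) 2 (1,0,0) 3 (0,1,0) 4 (1,1,0) 5 (0,0,1) 6 (1,0,1)
  # 7 (0,1,1) 8 (1,1,1)
  f <- rbind(
    c(5, 6, 8, 7),  # z = 1, outward +z
    c(1, 3, 4, 2),  # z = 0, outward -z
    c(1, 2, 6, 5),  # y = 0
    c(3, 7, 8, 4),  # y = 1
    c(1, 5, 7, 3),  # x = 0
    c(2, 4, 8, 6)   # x = 1
  )
  quad_mesh_new(v, f)
}
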