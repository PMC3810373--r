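# Direct-manipulation deformation. The generic model keeps a coarse
# control mesh whose vertices are all pilot points; the displayed surface
# is its Catmull-Clark subdivision. Fitting to a 2D target outline moves
# the boundary pilots so that the SILHOUETTE of the subdivided surface
# matches the target, propagating displacements to interior and
# back-layer vertices by inverse-distance weighting.

#' The deformable generic model
#'
#' Bundles the control mesh (with vertex metadata), the pilot-point set
#' (always every control vertex), the vertex-to-site map, the source
#' template and the display subdivision level.
#'
#' @param control_mesh a `quad_mesh` with vertex metadata (`$vdata`).
#' @param template the source `template2d`.
#' @param layout the [layout_strip()] the mesh was built from.
#' @param display_levels Catmull-Clark levels used for display,
#'   silhouettes and fitting (default 2).
#' @return A `generic_model`.
#' @export
generic_model <- function(control_mesh, template, layout, display_levels = 2) {
  stopifnot(inherits(control_mesh, "quad_mesh"), inherits(template, "template2d"))
  if (is.null(control_mesh$vdata))
    abort_anchor("control mesh must carry vertex metadata", "anchor3d_build_error")
  structure(
    list(control_mesh = control_mesh,
         pilots = control_mesh$vdata$id,
         site_map = stats::setNames(control_mesh$vdata$site,
                                    control_mesh$vdata$id),
         template = template,
         layout = layout,
         display_levels = display_levels),
    class = "generic_model"
  )
}

#' @export
print.generic_model <- function(x, ...) {
  rep <- validate_mesh(x$control_mesh)
  cat(sprintf("<generic_model '%s'>: control V=%d E=%d F=%d, %d pilot points, display level %d\n",
              x$template$name, rep$V, rep$E, rep$F, length(x$pilots),
              x$display_levels))
  invisible(x)
}

#' Fit tolerances for deformation and optimization
#'
#' @param rel maximum mean symmetric silhouette distance as a fraction of
#'   the target bounding-box diagonal.
#' @param iou minimum silhouette/target area intersection-over-union.
#' @param lambda step fraction applied to pilot displacements per
#'   iteration.
#' @return A `fit_tolerances` list.
#' @export
fit_tolerances <- function(rel = 0.015, iou = 0.95, lambda = 0.8) {
  structure(list(rel = rel, iou = iou, lambda = lambda),
            class = "fit_tolerances")
}

# --- silhouette ------------------------------------------------------------

# chain directed contour edges into loops; edges is n x 2 (from, to)
chain_loops <- function(edges) {
  loops <- list()
  nxt <- split(seq_len(nrow(edges)), edges[, 1])
  used <- rep(FALSE, nrow(edges))
  for (start in seq_len(nrow(edges))) {
    if (used[start]) next
    loop <- integer(0)
    e <- start
    repeat {
      used[e] <- TRUE
      loop <- c(loop, edges[e, 1])
      cand <- nxt[[as.character(edges[e, 2])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      e <- cand[1]
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

silhouette_from_subdivided <- function(vertices, faces, strict = TRUE) {
  nrm <- face_normals(vertices, faces)
  scale <- max(abs(vertices[, 1:2])) + 1
  front <- nrm[, 3] > 1e-9 * scale
  et <- mesh_edge_table(faces)
  # adjacency: the two faces of every edge
  ef <- matrix(0L, nrow(et$edges), 2)
  fidx <- rep(seq_len(nrow(faces)), 4)
  for (k in seq_along(et$eid)) {
    e <- et$eid[k]
    if (ef[e, 1] == 0L) ef[e, 1] <- fidx[k] else ef[e, 2] <- fidx[k]
  }
  if (any(ef[, 2] == 0L))
    abort_anchor("silhouette requires a closed mesh", "anchor3d_topology_error")
  contour <- which(front[ef[, 1]] != front[ef[, 2]])
  if (!length(contour))
    abort_anchor("mesh has no front-facing contour in the x-y projection",
                 "anchor3d_geometry_error")
  # direct each contour edge as traversed by its front face, so loops run
  # with the front region on the left (counter-clockwise in projection)
  dir_edges <- matrix(0L, length(contour), 2)
  for (q in seq_along(contour)) {
    e <- contour[q]
    f <- if (front[ef[e, 1]]) ef[e, 1] else ef[e, 2]
    fv <- faces[f, ]
    a <- et$edges[e, 1]; b <- et$edges[e, 2]
    pos_a <- match(a, fv)
    dir_edges[q, ] <- if (fv[(pos_a %% 4) + 1] == b) c(a, b) else c(b, a)
  }
  loops <- chain_loops(dir_edges)
  polys <- lapply(loops, function(idx) vertices[idx, 1:2, drop = FALSE])
  areas <- abs(vapply(polys, signed_area, 0))
  main <- which.max(areas)
  if (length(polys) > 1) {
    others <- setdiff(seq_along(polys), main)
    big <- others[areas[others] > 1e-6 * areas[main]]
    for (k in big) {
      inside <- pracma::inpolygon(polys[[k]][, 1], polys[[k]][, 2],
                                  polys[[main]][, 1], polys[[main]][, 2])
      if (!all(inside)) {
        if (strict)
          abort_anchor("projection yields multiple disjoint silhouette components",
                       "anchor3d_geometry_error")
      }
      # contained loops are self-occluded folds; the outer boundary is the
      # silhouette
    }
  }
  ensure_ccw(polys[[main]])
}

#' Silhouette of a mesh in the template plane
#'
#' Subdivides the mesh `levels` times, classifies faces as front-facing
#' (normal with positive z) and extracts the closed contour between front
#' and back regions, projected to the x-y plane. Returns a simple,
#' counter-clockwise polygon.
#'
#' @param mesh a closed `quad_mesh`.
#' @param levels Catmull-Clark levels to apply before projecting.
#' @return n x 2 matrix, the silhouette polygon.
#' @export
#' @examples
#' model <- build_final_model(anchor_template(), preliminary_config())
#' sil <- silhouette(model$control_mesh, levels = 1)
silhouette <- function(mesh, levels = 0) {
  stopifnot(inherits(mesh, "quad_mesh"))
  sub <- catmull_clark(mesh, levels)
  silhouette_from_subdivided(sub$vertices, sub$faces, strict = TRUE)
}

# --- fit metrics -----------------------------------------------------------

target_outline <- function(target) {
  if (inherits(target, "template2d")) target$outline
  else as.matrix(target)
}

#' Silhouette-versus-target fit metrics
#'
#' Mean symmetric nearest-point distance (each polygon resampled at
#' `n_samples` points, distances measured to the other polygon's full
#' boundary), a sample-based Hausdorff distance, the mean distance as a
#' fraction of the target bounding-box diagonal, and the rasterized area
#' IoU.
#'
#' @param model_silhouette silhouette polygon (n x 2).
#' @param target a `template2d` or target polygon.
#' @param n_samples boundary samples per polygon (>= 256 by default).
#' @param grid_n IoU rasterization resolution.
#' @return A `fit_report` with fields `mean_sym_dist`,
#'   `mean_sym_dist_rel`, `hausdorff`, `iou`.
#' @export
fit_report <- function(model_silhouette, target, n_samples = 256, grid_n = 160) {
  sil <- as.matrix(model_silhouette)
  tgt <- target_outline(target)
  if (abs(signed_area(sil)) < 1e-9 || abs(signed_area(tgt)) < 1e-9)
    abort_anchor("degenerate polygon (area < 1e-9)", "anchor3d_geometry_error")
  a <- resample_closed(sil, n_samples)
  b <- resample_closed(tgt, n_samples)
  dab <- dist_to_polyline(a, tgt, closed = TRUE)
  dba <- dist_to_polyline(b, sil, closed = TRUE)
  msd <- (mean(dab) + mean(dba)) / 2
  diag <- polygon_bbox_diag(tgt)
  structure(list(
    mean_sym_dist = msd,
    mean_sym_dist_rel = msd / diag,
    hausdorff = max(dab, dba),
    iou = polygon_iou(sil, tgt, grid_n = grid_n)
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report>: mean_sym=%.4f (rel %.4f)  hausdorff=%.4f  iou=%.4f\n",
              x$mean_sym_dist, x$mean_sym_dist_rel, x$hausdorff, x$iou))
  invisible(x)
}

# --- pilot bookkeeping -----------------------------------------------------

# In-plane boundary cycle of a layout: (station, across) pairs walking the
# left side tip-ward, around the last station, back along the right side
# and around the first station. Returns 1-based row indices into the
# in-plane point table (station-major order).
boundary_cycle_inplane <- function(layout) {
  st <- layout$stations
  k <- vapply(st, function(s) nrow(s$points), 0L)
  offs <- c(0L, cumsum(k))
  Tn <- length(st)
  idx <- integer(0)
  for (t in seq_len(Tn)) idx <- c(idx, offs[t] + 1L)                 # left side
  if (k[Tn] > 1) idx <- c(idx, offs[Tn] + 2:k[Tn])                   # far cap
  for (t in rev(seq_len(Tn - 1))) idx <- c(idx, offs[t] + k[t])      # right side
  if (k[1] > 2) idx <- c(idx, offs[1] + rev(2:(k[1] - 1)))           # near cap
  unique(idx)
}

# front/back control-vertex rows for each in-plane point p: front 2p-1, back 2p
model_inplane <- function(model) {
  vd <- model$control_mesh$vdata
  P <- nrow(vd) / 2
  list(P = P,
       xy = as.matrix(model$control_mesh$vertices[2 * seq_len(P) - 1, 1:2, drop = FALSE]),
       front_rows = 2 * seq_len(P) - 1,
       back_rows = 2 * seq_len(P))
}

# apply in-plane displacements (P x 2) to both layers of the control mesh
apply_inplane_displacement <- function(model, disp) {
  ip <- model_inplane(model)
  V <- model$control_mesh$vertices
  V[ip$front_rows, 1:2] <- V[ip$front_rows, 1:2] + disp
  V[ip$back_rows, 1:2] <- V[ip$back_rows, 1:2] + disp
  model$control_mesh$vertices <- V
  vd <- model$control_mesh$vdata
  vd$x <- V[, 1]; vd$y <- V[, 2]; vd$z <- V[, 3]
  model$control_mesh$vdata <- vd
  model
}

# --- direct manipulation ---------------------------------------------------

#' Move selected pilot points
#'
#' Displaces the selected control vertices exactly by the given vectors;
#' topology and all other vertices are untouched (no proportional
#' falloff).
#'
#' @param model a `generic_model`.
#' @param selection vector of pilot ids (0-based, as in `$pilots`).
#' @param displacements numeric matrix (length(selection) x 3) of
#'   displacement vectors, or a single vector recycled to all.
#' @return The deformed `generic_model`.
#' @export
#' @examples
#' model <- build_final_model(anchor_template(), preliminary_config())
#' moved <- move_pilots(model, 0, c(1, 0, 0))
move_pilots <- function(model, selection, displacements) {
  stopifnot(inherits(model, "generic_model"))
  if (!length(selection)) return(model)
  if (!all(selection %in% model$pilots))
    abort_anchor("selection contains unknown pilot ids", "anchor3d_lookup_error")
  if (is.null(dim(displacements)))
    displacements <- matrix(displacements, nrow = length(selection), ncol = 3,
                            byrow = TRUE)
  rows <- match(selection, model$control_mesh$vdata$id)
  V <- model$control_mesh$vertices
  V[rows, ] <- V[rows, , drop = FALSE] + displacements
  model$control_mesh$vertices <- V
  vd <- model$control_mesh$vdata
  vd$x <- V[, 1]; vd$y <- V[, 2]; vd$z <- V[, 3]
  model$control_mesh$vdata <- vd
  model
}

#' Correspond boundary pilots to a target outline
#'
#' Aligns the model silhouette to the target outline by normalized arc
#' length, brute-forcing the cyclic offset (64 candidates) and
#' orientation (2) that minimize the mean distance between the resampled
#' curves, then maps every front-layer boundary pilot to the target point
#' at the arc position of its nearest silhouette point.
#'
#' @param model a `generic_model`.
#' @param target a `template2d` (or target polygon).
#' @return A `correspondence`: `pairs` (data frame id, tx, ty),
#'   `cyclic_offset`, `orientation`.
#' @export
correspond_pilots <- function(model, target) {
  stopifnot(inherits(model, "generic_model"))
  sub <- catmull_clark(model$control_mesh, model$display_levels)
  sil <- silhouette_from_subdivided(sub$vertices, sub$faces)
  corr <- correspond_silhouette(model, sil, target_outline(target))
  corr
}

# internal: correspondence given an already computed silhouette
correspond_silhouette <- function(model, sil, tgt, n_align = 256) {
  a <- resample_closed(sil, n_align)
  b <- resample_closed(tgt, n_align)
  best <- list(cost = Inf, offset = 0, orient = 1L)
  for (orient in c(1L, -1L)) {
    bb <- if (orient == 1L) b else b[rev(seq_len(n_align)), , drop = FALSE]
    for (off in 0:63) {
      shift <- round(off / 64 * n_align)
      rolled <- bb[((seq_len(n_align) - 1 + shift) %% n_align) + 1, , drop = FALSE]
      cost <- mean(sqrt(rowSums((a - rolled)^2)))
      if (cost < best$cost) best <- list(cost = cost, offset = off / 64, orient = orient)
    }
  }
  tgt_o <- if (best$orient == 1L) tgt else tgt[rev(seq_len(nrow(tgt))), , drop = FALSE]
  ip <- model_inplane(model)
  bcyc <- boundary_cycle_inplane(model$layout)
  near <- nearest_on_polyline(ip$xy[bcyc, , drop = FALSE], sil, closed = TRUE)
  tpt <- closed_polyline_at(tgt_o, near$s + best$offset)
  structure(list(
    pairs = data.frame(id = model$control_mesh$vdata$id[ip$front_rows[bcyc]],
                       tx = tpt[, 1], ty = tpt[, 2]),
    cyclic_offset = best$offset,
    orientation = best$orient,
    boundary_inplane = bcyc,
    sil_point = near$point,
    target_point = tpt
  ), class = "correspondence")
}

#' Fit the generic model to a target outline
#'
#' Iterative direct-manipulation fitting: at each iteration boundary
#' pilots are corresponded to the target through the current silhouette
#' and moved a fraction `lambda` of the silhouette residual (in-plane; z
#' is preserved), interior and back-layer vertices follow by
#' inverse-distance-weighted (power 2) interpolation of the boundary
#' displacements, and the silhouette of the subdivided mesh is re-scored.
#' Iterations that would increase the mean symmetric distance are rolled
#' back with a reduced step; the loop stops when both tolerances are met
#' or at `max_iters` (returned with `converged = FALSE`, no exception).
#'
#' @param model a `generic_model`.
#' @param target a `template2d` or target polygon.
#' @param max_iters maximum accepted iterations.
#' @param tol a [fit_tolerances()].
#' @return A `deformation_result`: `model`, `fit` (final [fit_report()]),
#'   `iterations`, `trace` (per-iteration metrics, non-increasing in
#'   `mean_sym_dist`), `converged`.
#' @export
#' @examples
#' model <- build_final_model(anchor_template(), preliminary_config())
#' res <- fit_to_template(model, model$template, max_iters = 5)
#' res$fit
fit_to_template <- function(model, target, max_iters = 200,
                            tol = fit_tolerances()) {
  stopifnot(inherits(model, "generic_model"))
  tgt <- target_outline(target)
  diag <- polygon_bbox_diag(tgt)
  op <- cc_operator(model$control_mesh$faces, nrow(model$control_mesh$vertices),
                    model$display_levels)
  sil_of <- function(m) {
    sv <- as.matrix(op$S %*% m$control_mesh$vertices)
    silhouette_from_subdivided(sv, op$faces)
  }
  score <- function(sil) {
    a <- resample_closed(sil, 256)
    b <- resample_closed(tgt, 256)
    (mean(dist_to_polyline(a, tgt)) + mean(dist_to_polyline(b, sil))) / 2
  }
  # initial similarity alignment: match silhouette bbox centre and diagonal
  sil <- sil_of(model)
  sdiag <- polygon_bbox_diag(sil)
  sc <- diag / sdiag
  ctr_s <- colMeans(apply(sil, 2, range))
  ctr_t <- colMeans(apply(tgt, 2, range))
  ip <- model_inplane(model)
  disp0 <- cbind((ip$xy[, 1] - ctr_s[1]) * (sc - 1) + (ctr_t[1] - ctr_s[1]),
                 (ip$xy[, 2] - ctr_s[2]) * (sc - 1) + (ctr_t[2] - ctr_s[2]))
  model <- apply_inplane_displacement(model, disp0)
  sil <- sil_of(model)
  ms <- score(sil)
  trace <- data.frame(iteration = 0, mean_sym_dist = ms,
                      mean_sym_dist_rel = ms / diag, iou = NA_real_)
  converged <- FALSE
  iter <- 0
  iou_last <- NA_real_
  check_tol <- function(ms, sil) {
    if (ms / diag > tol$rel) return(list(ok = FALSE, iou = NA_real_))
    iou <- polygon_iou(sil, tgt, grid_n = 160)
    list(ok = iou >= tol$iou, iou = iou)
  }
  ck <- check_tol(ms, sil)
  trace$iou[1] <- ck$iou
  if (ck$ok) converged <- TRUE
  while (!converged && iter < max_iters) {
    corr <- correspond_silhouette(model, sil, tgt)
    bcyc <- corr$boundary_inplane
    resid <- corr$target_point - corr$sil_point
    lam <- tol$lambda
    improved <- FALSE
    for (try in 1:5) {
      bd <- resid * lam
      ipc <- model_inplane(model)
      disp <- matrix(0, ipc$P, 2)
      disp[bcyc, ] <- bd
      interior <- setdiff(seq_len(ipc$P), bcyc)
      if (length(interior)) {
        d2 <- outer(ipc$xy[interior, 1], ipc$xy[bcyc, 1], "-")^2 +
              outer(ipc$xy[interior, 2], ipc$xy[bcyc, 2], "-")^2
        w <- 1 / (d2 + 1e-12)
        w <- w / rowSums(w)
        disp[interior, ] <- w %*% bd
      }
      cand <- apply_inplane_displacement(model, disp)
      sil_c <- tryCatch(sil_of(cand), anchor3d_error = function(e) NULL)
      ms_c <- if (is.null(sil_c)) Inf else score(sil_c)
      if (ms_c <= ms + 1e-12) {
        model <- cand; sil <- sil_c; ms <- ms_c
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
    iter <- iter + 1
    ck <- check_tol(ms, sil)
    iou_last <- ck$iou
    trace <- rbind(trace, data.frame(iteration = iter, mean_sym_dist = ms,
                                     mean_sym_dist_rel = ms / diag,
                                     iou = ck$iou))
    if (ck$ok) converged <- TRUE
  }
  fit <- fit_report(sil, tgt)
  structure(list(model = model, fit = fit, iterations = iter,
                 trace = trace, converged = converged),
            class = "deformation_result")
}

#' @export
print.deformation_result <- function(x, ...) {
  cat(sprintf("<deformation_result>: %d iterations, converged=%s\n",
              x$iterations, x$converged))
  print(x$fit)
  invisible(x)
}

#' Deform a model by wholesale coordinate replacement
#'
#' Replaces every control-vertex position from a coordinate table (the
#' programmatic analogue of re-entering Cartesian coordinates); topology
#' is unchanged. The table must contain exactly one row per control
#' vertex with matching ids.
#'
#' @param model a `generic_model`.
#' @param table a [coordinate_table()] or data frame with columns id, x,
#'   y, z.
#' @return The deformed `generic_model`.
#' @export
deform_by_coordinates <- function(model, table) {
  stopifnot(inherits(model, "generic_model"))
  tab <- if (inherits(table, "coordinate_table")) table$rows else as.data.frame(table)
  vd <- model$control_mesh$vdata
  if (nrow(tab) != nrow(vd))
    abort_anchor(sprintf("coordinate table has %d rows but the model has %d control vertices",
                         nrow(tab), nrow(vd)), "anchor3d_table_error")
  rows <- match(vd$id, tab$id)
  if (anyNA(rows))
    abort_anchor("coordinate table ids do not match the model's vertex ids",
                 "anchor3d_table_error")
  V <- cbind(tab$x[rows], tab$y[rows], tab$z[rows])
  model$control_mesh$vertices <- V
  vd$x <- V[, 1]; vd$y <- V[, 2]; vd$z <- V[, 3]
  model$control_mesh$vdata <- vd
  model
}

#' Silhouettes of a rotated model
#'
#' Applies rigid rotations about a coordinate axis (anti-clockwise,
#' degrees) and returns the silhouette of each view.
#'
#' @param mesh a `quad_mesh`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angles numeric vector of degrees.
#' @param levels subdivision levels applied before projecting.
#' @return List of `list(angle, silhouette)` entries.
#' @export
#' @examples
#' model <- build_final_model(anchor_template(), preliminary_config())
#' views <- rotate_views(model$control_mesh, "x", c(0, 45), levels = 1)
rotate_views <- function(mesh, axis = c("x", "y", "z"), angles, levels = 2) {
  stopifnot(inherits(mesh, "quad_mesh"))
  axis <- match.arg(axis)
  sub <- catmull_clark(mesh, levels)
  ctr <- colMeans(sub$vertices)
  lapply(angles, function(ang) {
    R <- rotation_matrix_3d(axis, ang)
    V <- sweep(sub$vertices, 2, ctr) %*% t(R)
    V <- sweep(V, 2, ctr, `+`)
    list(angle = ang,
         silhouette = silhouette_from_subdivided(V, sub$faces, strict = FALSE))
  })
}
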