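# Readers and writers. All writers are deterministic: fixed float
# formatting (%.17g round-trips doubles exactly), LF line endings, no
# timestamps. Vertex ids are 0-based in every file; internal R indices
# are 1-based, converted only at this boundary.

fmt_num <- function(x) sprintf("%.17g", x)

write_lines_lf <- function(lines, path) {
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    abort_anchor(sprintf("cannot write '%s'", path), "anchor3d_io_error"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Coordinate table of a model's control vertices
#'
#' One row per control vertex: id (0-based, contiguous), Cartesian x, y,
#' z in grid units, and the site label the vertex belongs to.
#'
#' @param model a `generic_model`.
#' @return A `coordinate_table` (field `rows`: data frame).
#' @export
coordinate_table <- function(model) {
  stopifnot(inherits(model, "generic_model"))
  vd <- model$control_mesh$vdata
  structure(list(rows = data.frame(id = vd$id, x = vd$x, y = vd$y, z = vd$z,
                                   site = vd$site, stringsAsFactors = FALSE)),
            class = "coordinate_table")
}

#' Write / read control-vertex coordinate tables
#'
#' CSV with mandatory header `id,x,y,z,site`, comma separator, `.`
#' decimal mark, LF endings, full double precision (values round-trip
#' exactly). `read_coordinate_table` tolerates extra columns (ignored
#' with a warning) and reports parse problems with the offending line
#' number.
#'
#' @param model a `generic_model` or `coordinate_table`.
#' @param path file path.
#' @return `write_coordinate_table` returns `path` invisibly;
#'   `read_coordinate_table` returns a `coordinate_table`.
#' @export
#' @examples
#' model <- build_final_model(anchor_template(), preliminary_config())
#' f <- tempfile(fileext = ".csv")
#' write_coordinate_table(model, f)
#' tab <- read_coordinate_table(f)
#' nrow(tab$rows)
write_coordinate_table <- function(model, path) {
  tab <- if (inherits(model, "coordinate_table")) model else coordinate_table(model)
  r <- tab$rows
  lines <- c("id,x,y,z,site",
             sprintf("%d,%s,%s,%s,%s", r$id, fmt_num(r$x), fmt_num(r$y),
                     fmt_num(r$z), r$site))
  write_lines_lf(lines, path)
}

#' @rdname write_coordinate_table
#' @export
read_coordinate_table <- function(path) {
  if (!file.exists(path))
    abort_anchor(sprintf("coordinate table '%s' does not exist", path),
                 "anchor3d_io_error")
  lines <- readLines(path)
  if (!length(lines))
    abort_anchor("empty coordinate table", "anchor3d_parse_error")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  need <- c("id", "x", "y", "z", "site")
  miss <- setdiff(need, header)
  if (length(miss))
    abort_anchor(sprintf("line 1: missing column(s) %s", paste(miss, collapse = ", ")),
                 "anchor3d_parse_error")
  extra <- setdiff(header, need)
  if (length(extra))
    message(sprintf("read_coordinate_table: ignoring unknown column(s) %s",
                    paste(extra, collapse = ", ")))
  col <- match(need, header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  n <- length(parts)
  get <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else NA_character_, "")
  id_s <- get(col[1])
  id <- suppressWarnings(as.integer(id_s))
  num <- lapply(2:4, function(j) suppressWarnings(as.numeric(get(col[j]))))
  bad <- which(is.na(id) | is.na(num[[1]]) | is.na(num[[2]]) | is.na(num[[3]]))
  if (length(bad))
    abort_anchor(sprintf("line %d: non-numeric or missing value", bad[1] + 1L),
                 "anchor3d_parse_error")
  if (anyDuplicated(id)) {
    d <- which(duplicated(id))[1]
    abort_anchor(sprintf("line %d: duplicate id %d", d + 1L, id[d]),
                 "anchor3d_parse_error")
  }
  if (!setequal(id, seq_len(n) - 1L))
    abort_anchor("ids must be contiguous from 0", "anchor3d_parse_error")
  structure(list(rows = data.frame(id = id, x = num[[1]], y = num[[2]],
                                   z = num[[3]], site = get(col[5]),
                                   stringsAsFactors = FALSE)),
            class = "coordinate_table")
}

as_mesh <- function(x) {
  if (inherits(x, "generic_model")) x$control_mesh
  else if (inherits(x, "quad_mesh")) x
  else abort_anchor("expected a quad_mesh or generic_model", "anchor3d_parameter_error")
}

#' Export meshes to OBJ, PLY and STL
#'
#' OBJ and PLY keep the quad faces (1-based indices in OBJ, 0-based in
#' PLY per the format standards); STL splits each quad into two triangles
#' along its shorter diagonal with outward normals. Output is
#' deterministic.
#'
#' @param mesh a `quad_mesh` (or `generic_model`, whose control mesh is
#'   exported).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".obj")
#' write_obj(unit_cube_mesh(), f)
write_obj <- function(mesh, path) {
  mesh <- as_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  write_lines_lf(c(
    sprintf("v %s %s %s", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
    sprintf("f %d %d %d %d", f[, 1], f[, 2], f[, 3], f[, 4])
  ), path)
}

#' @rdname write_obj
#' @export
write_ply <- function(mesh, path) {
  mesh <- as_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  write_lines_lf(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header",
    sprintf("%s %s %s", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
    sprintf("4 %d %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L, f[, 4] - 1L)
  ), path)
}

#' @rdname write_obj
#' @export
write_stl <- function(mesh, path) {
  mesh <- as_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  tris <- matrix(0L, 2 * nrow(f), 3)
  for (k in seq_len(nrow(f))) {
    q <- f[k, ]
    d13 <- sum((v[q[1], ] - v[q[3], ])^2)
    d24 <- sum((v[q[2], ] - v[q[4], ])^2)
    if (d13 <= d24) {
      tris[2 * k - 1, ] <- q[c(1, 2, 3)]
      tris[2 * k, ] <- q[c(1, 3, 4)]
    } else {
      tris[2 * k - 1, ] <- q[c(1, 2, 4)]
      tris[2 * k, ] <- q[c(2, 3, 4)]
    }
  }
  a <- v[tris[, 1], , drop = FALSE]
  b <- v[tris[, 2], , drop = FALSE]
  c0 <- v[tris[, 3], , drop = FALSE]
  n <- cbind((b[, 2] - a[, 2]) * (c0[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c0[, 2] - a[, 2]),
             (b[, 3] - a[, 3]) * (c0[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c0[, 3] - a[, 3]),
             (b[, 1] - a[, 1]) * (c0[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c0[, 1] - a[, 1]))
  len <- pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
  n <- n / len
  lines <- c("solid anchor3d")
  body <- vapply(seq_len(nrow(tris)), function(k) {
    paste(c(sprintf("facet normal %s %s %s", fmt_num(n[k, 1]), fmt_num(n[k, 2]), fmt_num(n[k, 3])),
            "  outer loop",
            sprintf("    vertex %s %s %s", fmt_num(a[k, 1]), fmt_num(a[k, 2]), fmt_num(a[k, 3])),
            sprintf("    vertex %s %s %s", fmt_num(b[k, 1]), fmt_num(b[k, 2]), fmt_num(b[k, 3])),
            sprintf("    vertex %s %s %s", fmt_num(c0[k, 1]), fmt_num(c0[k, 2]), fmt_num(c0[k, 3])),
            "  endloop", "endfacet"), collapse = "\n")
  }, "")
  write_lines_lf(c(lines, body, "endsolid anchor3d"), path)
}

#' Write an SVG overlay of target outline and model silhouettes
#'
#' Target outline stroked red, silhouettes filled grey at 50% opacity;
#' the y axis is flipped to the SVG screen convention and the viewBox is
#' the target bounding box padded by 10%.
#'
#' @param target a `template2d` (or outline polygon).
#' @param silhouettes list of silhouette polygons (possibly empty).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_svg_overlay <- function(target, silhouettes, path) {
  tgt <- target_outline(target)
  rng <- apply(tgt, 2, range)
  w <- diff(rng[, 1]); h <- diff(rng[, 2])
  pad <- 0.1 * max(w, h)
  x0 <- rng[1, 1] - pad; y0 <- rng[1, 2] - pad
  W <- w + 2 * pad; H <- h + 2 * pad
  # flip y: y' = (y0 + H) - (y - y0) ... map y -> ymax + pad - (y - ymin)
  flip <- function(p) cbind(p[, 1], 2 * y0 + H - p[, 2])
  pts <- function(p) paste(sprintf("%.6g,%.6g", p[, 1], p[, 2]), collapse = " ")
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%.6g %.6g %.6g %.6g">',
            x0, y0, W, H),
    vapply(silhouettes, function(s)
      sprintf('<polygon points="%s" fill="grey" fill-opacity="0.5" stroke="none"/>',
              pts(flip(as.matrix(s)))), ""),
    sprintf('<polygon points="%s" fill="none" stroke="red" stroke-width="%.6g"/>',
            pts(flip(tgt)), max(W, H) / 400),
    "</svg>"
  )
  write_lines_lf(lines, path)
}
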