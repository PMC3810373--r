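# 2D anchor templates: a closed outline on a Cartesian grid, a medial path
# running from the inner-root end of the anchor to the tip of its recurved
# point, and interval annotations marking the sites of high morphological
# variation (labels I-VII) along that path.

SITE_LABELS <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Construct a 2D anchor template
#'
#' A `template2d` holds the closed outline of an anchor drawn in lateral
#' view, the medial path used to parameterize positions along the anchor
#' (normalized arc length 0 at the inner-root end, 1 at the point tip), the
#' grid spacing of the Cartesian graph the drawing sits on, and interval
#' annotations for sites of high morphological variation.
#'
#' @param name template name.
#' @param outline closed, simple, counter-clockwise polygon (n x 2 matrix,
#'   n >= 8, grid units); the closing edge is implicit.
#' @param medial_path open polyline (m x 2) strictly inside the outline,
#'   both endpoints within one grid unit of the outline.
#' @param grid_spacing length of one grid square (default 1).
#' @param sites list of [site_annotation()] objects with pairwise
#'   non-overlapping intervals.
#' @return An object of class `template2d`.
#' @export
#' @examples
#' tpl <- generate_synthetic_anchor(anchor_params(seed = 1))
#' tpl
template2d <- function(name, outline, medial_path, grid_spacing = 1,
                       sites = list()) {
  outline <- as.matrix(outline)
  medial_path <- as.matrix(medial_path)
  tpl <- structure(
    list(name = as.character(name)[1], outline = outline,
         medial_path = medial_path, grid_spacing = grid_spacing,
         sites = sites),
    class = "template2d"
  )
  validate_template(tpl)
  tpl
}

#' @export
print.template2d <- function(x, ...) {
  cat(sprintf("<template2d '%s'>: %d outline vertices, %d medial points, grid %g\n",
              x$name, nrow(x$outline), nrow(x$medial_path), x$grid_spacing))
  if (length(x$sites)) {
    for (s in x$sites)
      cat(sprintf("  site %-6s [%.3f, %.3f]\n", s$label, s$s_start, s$s_end))
  } else cat("  (no site annotations)\n")
  invisible(x)
}

#' Validate a template's structural invariants
#'
#' Checks outline simplicity, closure, orientation and size, that the
#' medial path lies inside the outline with endpoints near it, and that
#' site intervals do not overlap.
#'
#' @param tpl a `template2d`.
#' @return `tpl`, invisibly; raises a classed error on violation.
#' @export
validate_template <- function(tpl) {
  o <- tpl$outline
  if (!is.numeric(o) || ncol(o) != 2 || nrow(o) < 8)
    abort_anchor("outline must be a numeric matrix with >= 8 rows and 2 columns",
                 "anchor3d_parameter_error")
  if (!is.numeric(tpl$grid_spacing) || tpl$grid_spacing <= 0)
    abort_anchor("grid_spacing must be > 0", "anchor3d_parameter_error")
  if (signed_area(o) <= 0)
    abort_anchor("outline must be counter-clockwise with positive area",
                 "anchor3d_degeneracy_error")
  if (!is_simple_polygon(o))
    abort_anchor("outline self-intersects (polygon is not simple)",
                 "anchor3d_degeneracy_error")
  m <- tpl$medial_path
  if (!is.numeric(m) || ncol(m) != 2 || nrow(m) < 2)
    abort_anchor("medial_path must be an open polyline with >= 2 points",
                 "anchor3d_parameter_error")
  if (!all(pracma::inpolygon(m[, 1], m[, 2], o[, 1], o[, 2])))
    abort_anchor("medial_path must lie strictly inside the outline",
                 "anchor3d_geometry_error")
  dend <- dist_to_polyline(m[c(1, nrow(m)), , drop = FALSE], o, closed = TRUE)
  if (any(dend > 1))
    abort_anchor("medial_path endpoints must lie within 1 grid unit of the outline",
                 "anchor3d_geometry_error")
  check_site_list(tpl$sites)
  invisible(tpl)
}

#' Annotate a site of high morphological variation
#'
#' @param label one of `"I"`..`"VII"` or `"normal"`.
#' @param s_start,s_end interval of normalized medial-path arc length,
#'   `0 <= s_start < s_end <= 1`.
#' @return A `site_annotation` list.
#' @export
site_annotation <- function(label, s_start, s_end) {
  label <- as.character(label)[1]
  if (!label %in% c(SITE_LABELS, "normal"))
    abort_anchor(sprintf("unknown site label '%s'", label), "anchor3d_parameter_error")
  if (!(is.numeric(s_start) && is.numeric(s_end) &&
        s_start >= 0 && s_start < s_end && s_end <= 1))
    abort_anchor("site interval must satisfy 0 <= s_start < s_end <= 1",
                 "anchor3d_parameter_error")
  structure(list(label = label, s_start = s_start, s_end = s_end),
            class = "site_annotation")
}

check_site_list <- function(sites) {
  if (!length(sites)) return(invisible(sites))
  labs <- vapply(sites, `[[`, "", "label")
  high <- labs[labs != "normal"]
  if (anyDuplicated(high))
    abort_anchor("labels I-VII may appear at most once each",
                 "anchor3d_annotation_error")
  iv <- cbind(vapply(sites, `[[`, 0, "s_start"), vapply(sites, `[[`, 0, "s_end"))
  ord <- order(iv[, 1])
  iv <- iv[ord, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-12))
    abort_anchor("site intervals must be pairwise non-overlapping",
                 "anchor3d_annotation_error")
  invisible(sites)
}

#' Attach site annotations to a template
#'
#' Spans of the medial path not covered by an annotation are implicitly
#' "normal" sites.
#'
#' @param template a `template2d`.
#' @param annotations list of [site_annotation()] objects.
#' @return The annotated template.
#' @export
#' @examples
#' tpl <- generate_synthetic_anchor(anchor_params(seed = 1))
#' tpl <- annotate_sites(tpl, default_site_annotations())
annotate_sites <- function(template, annotations) {
  stopifnot(inherits(template, "template2d"))
  annotations <- lapply(annotations, function(a) {
    if (!inherits(a, "site_annotation"))
      a <- site_annotation(a$label, a$s_start, a$s_end)
    a
  })
  check_site_list(annotations)
  template$sites <- annotations[order(vapply(annotations, `[[`, 0, "s_start"))]
  validate_template(template)
  template
}

#' The packaged seven-site annotation
#'
#' Fixed intervals along the medial path for the seven sites of high
#' morphological variation of a dactylogyridean anchor: inner-root tip (I),
#' inner root base (II), outer root (IV), lower and mid shaft (III, V),
#' the shaft region where "ear" extrusions form (VI), and the recurved
#' point (VII).
#'
#' @return List of seven [site_annotation()] objects.
#' @export
default_site_annotations <- function() {
  list(
    site_annotation("I",   0.01, 0.08),
    site_annotation("II",  0.09, 0.16),
    site_annotation("IV",  0.17, 0.27),
    site_annotation("III", 0.30, 0.40),
    site_annotation("V",   0.44, 0.52),
    site_annotation("VI",  0.56, 0.70),
    site_annotation("VII", 0.74, 0.92)
  )
}

#' Snap a template to a Cartesian grid
#'
#' Rounds every outline and medial-path coordinate to the nearest multiple
#' of `spacing`, emulating reading coordinates off graph paper. Raises a
#' degeneracy error if rounding makes the outline self-intersect.
#'
#' @param template a `template2d`.
#' @param spacing grid spacing (> 0).
#' @return The snapped template (with `grid_spacing` set to `spacing`).
#' @export
snap_to_grid <- function(template, spacing) {
  stopifnot(inherits(template, "template2d"))
  if (!is.numeric(spacing) || spacing <= 0)
    abort_anchor("spacing must be > 0", "anchor3d_parameter_error")
  snap <- function(m) round(m / spacing) * spacing
  out <- snap(template$outline)
  # drop consecutive duplicates created by coarse rounding
  keep <- c(TRUE, rowSums(abs(diff(out))) > 1e-12)
  if (sum(abs(out[1, ] - out[nrow(out), ])) < 1e-12) keep[nrow(out)] <- FALSE
  out <- out[keep, , drop = FALSE]
  if (nrow(out) < 8 || abs(signed_area(out)) < 1e-9 || !is_simple_polygon(out))
    abort_anchor("snapping degenerated the outline (self-intersection or collapse)",
                 "anchor3d_degeneracy_error")
  med <- snap(template$medial_path)
  keepm <- c(TRUE, rowSums(abs(diff(med))) > 1e-12)
  med <- med[keepm, , drop = FALSE]
  out <- ensure_ccw(out)
  # rounding can push the path ends of a narrow part (e.g. the point tip)
  # onto or over the outline: trim those, but an interior excursion means
  # the grid is too coarse for the shape
  inside <- pracma::inpolygon(med[, 1], med[, 2], out[, 1], out[, 2])
  first <- match(TRUE, inside)
  last <- length(inside) + 1L - match(TRUE, rev(inside))
  if (is.na(first) || last - first < 1 || !all(inside[first:last]))
    abort_anchor("snapping pushed the medial path outside the outline",
                 "anchor3d_degeneracy_error")
  tpl <- template
  tpl$outline <- out
  tpl$medial_path <- med[first:last, , drop = FALSE]
  tpl$grid_spacing <- spacing
  validate_template(tpl)
  tpl
}

#' Read / write templates as JSON
#'
#' The interchange format has keys `name`, `grid_spacing`, `outline`
#' (list of `[x, y]`), `medial_path` and `sites`
#' (`{label, s_start, s_end}`). The outline is stored counter-clockwise
#' and closed implicitly.
#'
#' @param template a `template2d`.
#' @param path file path.
#' @return `read_template_json` returns a `template2d`;
#'   `write_template_json` returns `path` invisibly.
#' @export
write_template_json <- function(template, path) {
  stopifnot(inherits(template, "template2d"))
  obj <- list(
    name = template$name,
    grid_spacing = template$grid_spacing,
    outline = unname(apply(template$outline, 1, function(r) c(r[1], r[2]), simplify = FALSE)),
    medial_path = unname(apply(template$medial_path, 1, function(r) c(r[1], r[2]), simplify = FALSE)),
    sites = lapply(template$sites, function(s)
      list(label = s$label, s_start = s$s_start, s_end = s$s_end))
  )
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_anchor(sprintf("cannot write '%s'", path), "anchor3d_io_error")
  invisible(path)
}

#' @rdname write_template_json
#' @export
read_template_json <- function(path) {
  if (!file.exists(path))
    abort_anchor(sprintf("template file '%s' does not exist", path), "anchor3d_io_error")
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    abort_anchor(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                                 "anchor3d_parse_error"))
  sites <- list()
  if (!is.null(obj$sites) && length(obj$sites)) {
    sdf <- as.data.frame(obj$sites)
    sites <- lapply(seq_len(nrow(sdf)), function(i)
      site_annotation(sdf$label[i], sdf$s_start[i], sdf$s_end[i]))
  }
  template2d(obj$name, as.matrix(obj$outline), as.matrix(obj$medial_path),
             grid_spacing = obj$grid_spacing, sites = sites)
}
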