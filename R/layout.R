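# Point-primitive layout: stations placed along the medial path, each
# carrying a row of in-plane point primitives across the local width of
# the anchor. Sites of high morphological variation receive densified
# stations according to the per-site primitive counts.

#' Per-site point-primitive counts
#'
#' In-plane primitive counts per site of high morphological variation. The
#' default transcribes the counts established for the generic anchor
#' model: 4 at normal sites, 8 at sites I-IV, 6 at site V and 16 at the
#' extrusion-forming sites VI and VII. Each count c is realised as
#' `n_along` stations of `n_across` primitives with the fixed
#' factorizations 4 = 2x2, 6 = 3x2, 8 = 4x2, 16 = 4x4.
#'
#' @param counts named numeric vector mapping site labels (and `"normal"`)
#'   to even counts >= 4.
#' @return A `site_config` object.
#' @export
#' @examples
#' site_config()             # the packaged final-model configuration
#' preliminary_config()      # 4 primitives everywhere
site_config <- function(counts = c(normal = 4, I = 8, II = 8, III = 8,
                                   IV = 8, V = 6, VI = 16, VII = 16)) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    abort_anchor("site counts must be named by site label", "anchor3d_parameter_error")
  bad <- setdiff(names(counts), c(SITE_LABELS, "normal"))
  if (length(bad))
    abort_anchor(sprintf("unknown site label(s): %s", paste(bad, collapse = ", ")),
                 "anchor3d_parameter_error")
  if (any(counts < 4) || any(counts %% 2 != 0))
    abort_anchor("every site count must be even and >= 4", "anchor3d_parameter_error")
  for (c0 in counts) site_factorization(c0)  # must factor as n_along x n_across
  if (!"normal" %in% names(counts)) counts <- c(counts, normal = 4)
  structure(list(counts = counts), class = "site_config")
}

#' @rdname site_config
#' @export
preliminary_config <- function() {
  site_config(c(normal = 4, I = 4, II = 4, III = 4, IV = 4, V = 4,
                VI = 4, VII = 4))
}

#' Factorize a site count into stations x across-points
#'
#' Fixed factorization `n_along x n_across`: counts that are multiples of
#' 4 and at least 16 use 4 points across the width (needed to shape
#' extrusions such as the ear), all other counts use 2 across.
#'
#' @param count even in-plane primitive count >= 4.
#' @return Integer vector `c(n_along, n_across)`, both >= 2.
#' @export
site_factorization <- function(count) {
  if (count < 4 || count %% 2 != 0)
    abort_anchor("site count must be even and >= 4", "anchor3d_parameter_error")
  n_across <- if (count >= 16 && count %% 4 == 0) 4L else 2L
  n_along <- as.integer(count / n_across)
  if (n_along < 2)
    abort_anchor(sprintf("count %d does not factor as n_along x n_across with both >= 2", count),
                 "anchor3d_parameter_error")
  c(n_along = n_along, n_across = n_across)
}

config_count <- function(config, label) {
  cts <- config$counts
  if (label %in% names(cts)) unname(cts[[label]]) else unname(cts[["normal"]])
}

#' Lay out point-primitive stations along a template
#'
#' Places stations along the medial path: inside a site interval with
#' count `c = n_along x n_across`, `n_along` stations of `n_across`
#' primitives each; normal spans receive 2-primitive stations. At every
#' station the local normal line is intersected with the outline and the
#' primitives are placed at equal fractions of the chord between the two
#' crossings nearest the medial point (one on each side), so the outermost
#' primitives of each station lie on the outline.
#'
#' @param template an annotated `template2d`.
#' @param config a [site_config()].
#' @param n_normal_stations total number of stations distributed over the
#'   normal (unannotated) spans, >= 2; the first and last normal stations
#'   cap the strip near the ends of the medial path.
#' @return A `strip_layout`: list of stations, each with fields `s`
#'   (normalized arc position), `points` (k x 2 matrix ordered from the
#'   left outline side to the right) and `site` label.
#' @export
#' @examples
#' lay <- layout_strip(anchor_template(), site_config(), n_normal_stations = 12)
#' length(lay$stations)
layout_strip <- function(template, config = site_config(),
                         n_normal_stations = 12) {
  stopifnot(inherits(template, "template2d"))
  if (!inherits(config, "site_config")) config <- site_config(config)
  if (n_normal_stations < 2)
    abort_anchor("n_normal_stations must be >= 2", "anchor3d_parameter_error")
  s_lo <- 0.005
  s_hi <- 0.995
  sites <- template$sites
  sites <- sites[order(vapply(sites, `[[`, 0, "s_start"))]
  # station positions and site labels
  st_s <- numeric(0); st_lab <- character(0)
  spans <- list()  # normal spans between sites
  cursor <- s_lo
  for (a in sites) {
    lo <- max(a$s_start, s_lo); hi <- min(a$s_end, s_hi)
    if (hi <= lo) next
    spans[[length(spans) + 1]] <- c(cursor, lo)
    fac <- site_factorization(config_count(config, a$label))
    pos <- seq(lo, hi, length.out = fac[["n_along"]])
    st_s <- c(st_s, pos)
    st_lab <- c(st_lab, rep(a$label, length(pos)))
    cursor <- hi
  }
  spans[[length(spans) + 1]] <- c(cursor, s_hi)
  # distribute normal stations over the spans proportionally to length,
  # forcing cap stations at the very ends of the path
  span_len <- vapply(spans, function(sp) max(sp[2] - sp[1], 0), 0)
  tot <- sum(span_len)
  if (tot > 0) {
    alloc <- pmax(0, round(n_normal_stations * span_len / tot))
    alloc[1] <- max(alloc[1], 1)
    alloc[length(alloc)] <- max(alloc[length(alloc)], 1)
    for (i in seq_along(spans)) {
      k <- alloc[i]
      if (k == 0 || span_len[i] <= 0) next
      a0 <- spans[[i]][1]; b0 <- spans[[i]][2]
      pad <- min(0.012, span_len[i] / (k + 1))
      first_span <- i == 1; last_span <- i == length(spans)
      lo <- if (first_span) a0 else a0 + pad
      hi <- if (last_span) b0 else b0 - pad
      pos <- if (k == 1) {
        if (first_span) lo else if (last_span) hi else (lo + hi) / 2
      } else seq(lo, hi, length.out = k)
      st_s <- c(st_s, pos)
      st_lab <- c(st_lab, rep("normal", length(pos)))
    }
  }
  ord <- order(st_s)
  st_s <- st_s[ord]; st_lab <- st_lab[ord]
  if (any(diff(st_s) < 1e-9))
    abort_anchor("station positions collide; reduce site density or station count",
                 "anchor3d_build_error")
  # per-station chords
  ev <- polyline_eval(template$medial_path, st_s)
  o <- template$outline
  stations <- vector("list", length(st_s))
  for (i in seq_along(st_s)) {
    lab <- st_lab[i]
    k <- if (lab == "normal") 2L else site_factorization(config_count(config, lab))[["n_across"]]
    t_all <- line_polygon_intersections(ev$point[i, ], ev$normal[i, ], o)
    t_left <- t_all[t_all > 0]
    t_right <- t_all[t_all < 0]
    if (!length(t_left) || !length(t_right))
      abort_anchor(sprintf("normal line at s = %.4f does not cross the outline on both sides", st_s[i]),
                   "anchor3d_geometry_error")
    tl <- min(t_left); tr <- max(t_right)  # nearest crossing on each side
    left_pt <- ev$point[i, ] + tl * ev$normal[i, ]
    right_pt <- ev$point[i, ] + tr * ev$normal[i, ]
    frac <- seq(0, 1, length.out = k)
    pts <- cbind(left_pt[1] + frac * (right_pt[1] - left_pt[1]),
                 left_pt[2] + frac * (right_pt[2] - left_pt[2]))
    stations[[i]] <- list(s = st_s[i], points = pts, site = lab)
  }
  structure(list(stations = stations, template_name = template$name),
            class = "strip_layout")
}

#' @export
print.strip_layout <- function(x, ...) {
  k <- vapply(x$stations, function(s) nrow(s$points), 0L)
  cat(sprintf("<strip_layout>: %d stations, %d in-plane primitives\n",
              length(x$stations), sum(k)))
  invisible(x)
}

# total in-plane primitive count of a layout
layout_primitive_count <- function(layout) {
  sum(vapply(layout$stations, function(s) nrow(s$points), 0L))
}
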