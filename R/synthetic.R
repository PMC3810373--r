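# Synthetic anchor outlines. A dactylogyridean anchor in lateral view is a
# hook: an inner root at the base, an outer root protruding from the base
# region, a gently curved shaft, and a strongly recurved point. Some
# species add an "ear" extrusion on the shaft and small ornament bumps.
# The generator sweeps a width profile along an analytic medial curve, so
# each template carries its medial path exactly.

#' Parameters of a synthetic anchor outline
#'
#' Lengths are in grid units (one Cartesian graph square), angles in
#' radians. The defaults describe a morphologically simple anchor of the
#' kind used as a generic template; variants are produced by perturbing
#' them (see [variant_params()]).
#'
#' @param shaft_length,shaft_curvature length of the shaft and total
#'   heading change along it.
#' @param point_length,point_curl length of the recurved point and its
#'   total curl angle.
#' @param inner_root_length,inner_root_width basal (inner root) segment
#'   length and full width.
#' @param outer_root_length,outer_root_width arc-length extent and
#'   protrusion of the outer-root lobe (site IV region).
#' @param ear logical; add an "ear" lobe inside the site VI interval.
#' @param ear_size protrusion of the ear lobe (grid units).
#' @param ornament_bumps number of small ornament ripples along the shaft.
#' @param ornament_amplitude ripple amplitude (grid units).
#' @param seed integer seed controlling ornament phases; output is a
#'   deterministic function of the parameters and the seed.
#' @return An `anchor_params` list.
#' @export
anchor_params <- function(shaft_length = 14, shaft_curvature = 0.55,
                          point_length = 7.5, point_curl = 1.9,
                          inner_root_length = 4, inner_root_width = 2.6,
                          outer_root_length = 3.2, outer_root_width = 2.0,
                          ear = FALSE, ear_size = 1.6,
                          ornament_bumps = 0L, ornament_amplitude = 0.15,
                          seed = 1L) {
  p <- list(shaft_length = shaft_length, shaft_curvature = shaft_curvature,
            point_length = point_length, point_curl = point_curl,
            inner_root_length = inner_root_length,
            inner_root_width = inner_root_width,
            outer_root_length = outer_root_length,
            outer_root_width = outer_root_width,
            ear = isTRUE(ear), ear_size = ear_size,
            ornament_bumps = as.integer(ornament_bumps),
            ornament_amplitude = ornament_amplitude,
            seed = as.integer(seed))
  class(p) <- "anchor_params"
  validate_anchor_params(p)
  p
}

validate_anchor_params <- function(p) {
  lens <- c("shaft_length", "point_length", "inner_root_length",
            "outer_root_length", "ear_size")
  for (f in lens)
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      abort_anchor(sprintf("anchor parameter '%s' must be > 0", f),
                   "anchor3d_parameter_error")
  if (p$inner_root_width <= 0 || p$inner_root_width >= p$inner_root_length * 2)
    abort_anchor("anchor parameter 'inner_root_width' must be positive and smaller than its part",
                 "anchor3d_parameter_error")
  if (p$outer_root_width <= 0 || p$outer_root_width >= p$outer_root_length * 2)
    abort_anchor("anchor parameter 'outer_root_width' must be positive and smaller than its part",
                 "anchor3d_parameter_error")
  if (p$ornament_bumps < 0)
    abort_anchor("anchor parameter 'ornament_bumps' must be >= 0",
                 "anchor3d_parameter_error")
  invisible(p)
}

# smooth ramp: 0 below a, 1 above b, C1 in between
smoothstep <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  t * t * (3 - 2 * t)
}

#' Generate a synthetic anchor template
#'
#' Builds a hook-shaped closed outline plus its medial path from
#' [anchor_params()]. The same parameters and seed always give an
#' identical template. The outline is the sweep of an asymmetric width
#' profile along the medial curve: the outer-root lobe widens the outer
#' (right) side inside the packaged site IV interval and the optional ear
#' widens the inner (left) side inside the site VI interval.
#'
#' @param params an [anchor_params()] object.
#' @return An unannotated `template2d` (use [annotate_sites()] /
#'   [default_site_annotations()] to mark sites).
#' @export
#' @examples
#' tpl <- generate_synthetic_anchor(anchor_params(seed = 7))
#' nrow(tpl$outline)
generate_synthetic_anchor <- function(params = anchor_params()) {
  if (!inherits(params, "anchor_params")) params <- do.call(anchor_params, params)
  validate_anchor_params(params)
  p <- params
  m <- 161
  L <- p$inner_root_length + p$shaft_length + p$point_length
  a <- seq(0, L, length.out = m)
  r1 <- p$inner_root_length
  r2 <- r1 + p$shaft_length
  # heading: starts pointing up, bends rightwards through the shaft, then
  # curls through the point
  theta <- pi / 2 -
    p$shaft_curvature * smoothstep(a, r1, r2) -
    p$point_curl * smoothstep(a, r2, L)
  # integrate with midpoint headings
  th_mid <- (theta[-1] + theta[-m]) / 2
  da <- diff(a)
  path <- rbind(c(0, 0), cbind(cumsum(da * cos(th_mid)), cumsum(da * sin(th_mid))))
  u <- a / L
  # symmetric base width profile, tapering toward the tip
  h_base <- p$inner_root_width / 2
  h_tip <- 0.14
  h <- h_tip + (h_base - h_tip) * (1 - u)^1.4
  wl <- h
  wr <- h
  # outer-root lobe (site IV interval, centred at s = 0.22)
  sig4 <- max(p$outer_root_length / L / 2.5, 0.015)
  wr <- wr + (p$outer_root_width / 2) * exp(-((u - 0.22) / sig4)^2)
  # ear lobe (site VI interval, centred at s = 0.63)
  if (p$ear)
    wl <- wl + (p$ear_size / 2) * exp(-((u - 0.63) / 0.045)^2)
  # ornament ripples on the shaft, phases drawn from the seed
  if (p$ornament_bumps > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(p$seed)
    phases <- stats::runif(p$ornament_bumps, 0, 2 * pi)
    win <- smoothstep(u, 0.25, 0.35) * (1 - smoothstep(u, 0.75, 0.85))
    # ripples scale with the local half-width so the narrow point region
    # is never pinched through the medial line
    for (k in seq_len(p$ornament_bumps))
      wl <- wl + p$ornament_amplitude * win * (h / h_base) *
        sin(2 * pi * (k + 2) * u + phases[k])
  }
  tang <- rbind(cbind(cos(theta[-m]), sin(theta[-m])), c(cos(theta[m]), sin(theta[m])))
  nrm <- cbind(-tang[, 2], tang[, 1])
  left <- path + nrm * wl
  right <- path - nrm * wr
  outline <- rbind(left, right[rev(seq_len(m)), , drop = FALSE])
  # thin the outline to keep files and intersection tests light
  keep <- unique(c(seq(1, 2 * m, by = 2), m, m + 1, 2 * m))
  outline <- outline[sort(keep), , drop = FALSE]
  outline <- ensure_ccw(outline)
  # medial path trimmed so it stays strictly interior, endpoints close to
  # the end caps
  inset <- min(0.35, L * 0.01)
  keepm <- a >= inset & a <= L - inset
  medial <- path[keepm, , drop = FALSE]
  template2d(
    name = sprintf("synthetic-anchor-seed%d%s", p$seed, if (p$ear) "-ear" else ""),
    outline = outline, medial_path = medial, grid_spacing = 1, sites = list()
  )
}

#' The packaged generic anchor template
#'
#' The base template for the generic deformable model: a morphologically
#' simple anchor (no ear, no ornaments) generated with the default
#' [anchor_params()] and annotated with the packaged seven-site intervals.
#'
#' @return An annotated `template2d`.
#' @export
#' @examples
#' tpl <- anchor_template()
#' length(tpl$sites)
anchor_template <- function() {
  annotate_sites(generate_synthetic_anchor(anchor_params()),
                 default_site_annotations())
}

#' Seeded anchor-shape variants
#'
#' Deterministically jitters the default anchor parameters to emulate the
#' across-species shape diversity of dactylogyridean anchors (stubbier or
#' longer shafts, stronger or weaker point curl, larger roots, with an ear
#' on even seeds). Used as deformation targets for the generic model.
#'
#' @param seed integer; same seed always returns the same parameters.
#' @return An [anchor_params()] object.
#' @export
variant_params <- function(seed) {
  seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  j <- function(x, frac) x * stats::runif(1, 1 - frac, 1 + frac)
  anchor_params(
    shaft_length = j(14, 0.20), shaft_curvature = j(0.55, 0.30),
    point_length = j(7.5, 0.20), point_curl = j(1.9, 0.20),
    inner_root_length = j(4, 0.25), inner_root_width = j(2.6, 0.20),
    outer_root_length = j(3.2, 0.25), outer_root_width = j(2.0, 0.30),
    ear = seed %% 2L == 0L, ear_size = j(1.6, 0.25),
    seed = seed
  )
}
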