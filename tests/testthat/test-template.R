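# Template generation, annotation, snapping and strip layout.

test_that("synthetic anchor generation is valid, deterministic, and parameter-sensitive", {
  p <- anchor_params(ear = FALSE, ornament_bumps = 0, seed = 1)
  tpl <- generate_synthetic_anchor(p)
  expect_s3_class(tpl, "template2d")
  expect_gte(nrow(tpl$outline), 8)
  # simple + CCW are enforced invariants
  expect_silent(validate_template(tpl))
  expect_gt(oracle_polygon_area(tpl$outline), 0)

  # determinism: same params and seed give identical vertex lists
  tpl2 <- generate_synthetic_anchor(p)
  expect_identical(tpl$outline, tpl2$outline)
  expect_identical(tpl$medial_path, tpl2$medial_path)

  # a different seed with ornament ripples changes the outline
  p3 <- anchor_params(ornament_bumps = 3, seed = 5)
  p4 <- anchor_params(ornament_bumps = 3, seed = 6)
  expect_false(identical(generate_synthetic_anchor(p3)$outline,
                         generate_synthetic_anchor(p4)$outline))
})

test_that("invalid anchor parameters name the offending field", {
  expect_error(anchor_params(shaft_length = -1), "shaft_length",
               class = "anchor3d_parameter_error")
  expect_error(anchor_params(inner_root_width = 100), "inner_root_width",
               class = "anchor3d_parameter_error")
  expect_error(anchor_params(ornament_bumps = -2), "ornament_bumps",
               class = "anchor3d_parameter_error")
})

test_that("the ear flag adds a lobe inside the site VI interval band", {
  off <- generate_synthetic_anchor(anchor_params(ear = FALSE, seed = 2))
  on <- generate_synthetic_anchor(anchor_params(ear = TRUE, seed = 2))
  a_off <- oracle_polygon_area(off$outline)
  a_on <- oracle_polygon_area(on$outline)
  expect_gt(a_on, a_off)
  # centroid of the added lobe from area-weighted centroid difference
  c_off <- anchor3d:::polygon_centroid(off$outline)
  c_on <- anchor3d:::polygon_centroid(on$outline)
  c_lobe <- (a_on * c_on - a_off * c_off) / (a_on - a_off)
  near <- anchor3d:::nearest_on_polyline(matrix(c_lobe, 1), off$medial_path,
                                         closed = FALSE)
  vi <- Filter(function(s) s$label == "VI", default_site_annotations())[[1]]
  expect_gte(near$s, vi$s_start - 0.05)
  expect_lte(near$s, vi$s_end + 0.05)
})

test_that("site annotation rejects overlaps and duplicate labels, accepts the packaged seven", {
  tpl <- generate_synthetic_anchor(anchor_params())
  expect_error(annotate_sites(tpl, list(site_annotation("I", 0.1, 0.3),
                                        site_annotation("II", 0.2, 0.4))),
               class = "anchor3d_annotation_error")
  expect_error(annotate_sites(tpl, list(site_annotation("I", 0.1, 0.2),
                                        site_annotation("I", 0.3, 0.4))),
               class = "anchor3d_annotation_error")
  expect_error(site_annotation("I", 0.5, 0.4), class = "anchor3d_parameter_error")
  # empty list: all-normal template
  plain <- annotate_sites(tpl, list())
  expect_length(plain$sites, 0)
  # packaged annotation: seven distinct high-variation labels
  ann <- annotate_sites(tpl, default_site_annotations())
  labs <- vapply(ann$sites, `[[`, "", "label")
  expect_setequal(labs, c("I", "II", "III", "IV", "V", "VI", "VII"))
  expect_length(labs, 7)
})

test_that("snap_to_grid rounds to the grid, preserves simplicity, and is idempotent", {
  tpl <- rect_template()
  # already on grid: unchanged
  s <- snap_to_grid(tpl, 0.5)
  expect_equal(s$outline, tpl$outline)
  # rounding: an off-grid dent vertex at (1.24, 3.76) snaps to (1.0, 4.0)
  big <- rect_template(L = 10, W = 4)
  out <- big$outline
  dent <- rbind(out[1:6, ], c(1.24, 3.76), out[7:8, ])
  t2 <- template2d("dent", dent, big$medial_path)
  s2 <- snap_to_grid(t2, 0.5)
  expect_true(any(s2$outline[, 1] == 1.0 & s2$outline[, 2] == 4.0))
  expect_false(any(s2$outline[, 1] == 1.24))
  # idempotence on the anchor at a fine grid
  a <- snap_to_grid(anchor_template(), 0.1)
  a2 <- snap_to_grid(a, 0.1)
  expect_equal(a$outline, a2$outline)
  expect_equal(a$medial_path, a2$medial_path)
  expect_true(all(a$outline %% 0.1 < 1e-9 | a$outline %% 0.1 > 0.1 - 1e-9))
})

test_that("snapping a fine shape at a coarse spacing raises a degeneracy error", {
  # comb with 0.2-wide teeth: a unit grid collapses the teeth
  teeth <- c(1, 3, 5, 7)
  top <- do.call(rbind, lapply(rev(teeth), function(x)
    rbind(c(x + 0.2, 0.5), c(x + 0.2, 3), c(x, 3), c(x, 0.5))))
  outline <- rbind(c(0, 0), c(5, 0), c(10, 0), c(10, 0.5), top, c(0, 0.5))
  med <- cbind(seq(0.3, 9.7, length.out = 30), 0.25)
  tpl <- template2d("comb", outline, med)
  expect_error(snap_to_grid(tpl, 1), class = "anchor3d_degeneracy_error")
})

test_that("layout_strip places stations per site counts with every point inside the outline", {
  # straight rectangle, all normal, 3 stations of 2 points
  lay <- layout_strip(rect_template(), preliminary_config(), n_normal_stations = 3)
  expect_length(lay$stations, 3)
  expect_true(all(vapply(lay$stations, function(s) nrow(s$points), 0L) == 2))

  # packaged template and configuration: site VI = 16 as 4 stations x 4
  tpl <- anchor_template()
  lay <- layout_strip(tpl, site_config(), n_normal_stations = 12)
  sVI <- Filter(function(s) s$site == "VI", lay$stations)
  expect_length(sVI, 4)
  expect_true(all(vapply(sVI, function(s) nrow(s$points), 0L) == 4))
  expect_equal(sum(vapply(sVI, function(s) nrow(s$points), 0L)), 16)

  # stations ordered by s; all points inside or on the outline
  ss <- vapply(lay$stations, `[[`, 0, "s")
  expect_true(all(diff(ss) > 0))
  pts <- do.call(rbind, lapply(lay$stations, `[[`, "points"))
  d <- anchor3d:::dist_to_polyline(pts, tpl$outline)
  inside <- pracma::inpolygon(pts[, 1], pts[, 2], tpl$outline[, 1], tpl$outline[, 2])
  expect_true(all(inside | d < 1e-9))
})

test_that("layout invariants hold across seeded synthetic anchors", {
  for (seed in c(3, 11, 27, 42)) {
    tpl <- annotate_sites(generate_synthetic_anchor(variant_params(seed)),
                          default_site_annotations())
    lay <- layout_strip(tpl, site_config(), n_normal_stations = 12)
    ss <- vapply(lay$stations, `[[`, 0, "s")
    expect_true(all(diff(ss) > 0))
    # per-site in-plane totals equal the configured counts
    for (lab in c("I", "IV", "V", "VI", "VII")) {
      tot <- sum(vapply(Filter(function(s) s$site == lab, lay$stations),
                        function(s) nrow(s$points), 0L))
      expect_equal(tot, unname(site_config()$counts[[lab]]))
    }
    pts <- do.call(rbind, lapply(lay$stations, `[[`, "points"))
    d <- anchor3d:::dist_to_polyline(pts, tpl$outline)
    inside <- pracma::inpolygon(pts[, 1], pts[, 2], tpl$outline[, 1], tpl$outline[, 2])
    expect_true(all(inside | d < 1e-9))
  }
})

test_that("template JSON round-trips", {
  tpl <- anchor_template()
  f <- withr::local_tempfile(fileext = ".json")
  write_template_json(tpl, f)
  back <- read_template_json(f)
  expect_equal(back$outline, tpl$outline)
  expect_equal(back$medial_path, tpl$medial_path)
  expect_equal(length(back$sites), length(tpl$sites))
  expect_equal(back$grid_spacing, tpl$grid_spacing)
  # the packaged plain-text template fixture loads too
  pk <- system.file("extdata", "synthetic-generic-anchor.json", package = "anchor3d")
  if (nzchar(pk)) expect_s3_class(read_template_json(pk), "template2d")
})
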