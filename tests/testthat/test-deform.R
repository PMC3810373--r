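# Silhouettes, fit metrics, correspondence and direct-manipulation
# deformation.

test_that("silhouette of one block at level 0 is its front rectangle", {
  ext <- extrude_strip(row_layout(1, L = 4, W = 2))
  mesh <- assemble_mesh(ext$vertices, ext$blocks)
  sil <- silhouette(mesh, levels = 0)
  expect_equal(nrow(sil), 4)
  front <- ext$vertices[ext$vertices$layer == "front", ]
  expect_equal(sort(sil[, 1]), sort(front$x))
  expect_equal(sort(sil[, 2]), sort(front$y))
  # translation in z does not change the silhouette
  shifted <- mesh
  shifted$vertices[, 3] <- shifted$vertices[, 3] + 5
  expect_equal(silhouette(shifted, 0), sil)
})

test_that("silhouette area is bounded by the projected convex hull", {
  mesh <- generic_model_fixture()$control_mesh
  sil <- silhouette(mesh, levels = 2)
  hull <- grDevices::chull(mesh$vertices[, 1], mesh$vertices[, 2])
  hull_area <- oracle_polygon_area(mesh$vertices[hull, 1:2])
  expect_lte(oracle_polygon_area(sil), hull_area)
  expect_true(anchor3d:::is_simple_polygon(sil))
})

test_that("fit_report matches closed-form cases", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  fr <- fit_report(sq, sq)
  expect_equal(fr$mean_sym_dist, 0, tolerance = 1e-12)
  expect_equal(fr$hausdorff, 0, tolerance = 1e-12)
  expect_equal(fr$iou, 1)
  # unit square against itself shifted by (1, 0): zero overlap
  fr2 <- fit_report(sq, sq + cbind(rep(1, 4), 0))
  expect_equal(fr2$iou, 0, tolerance = 0.02)
  # concentric double-size square: area ratio 1/4
  big <- (sq - 0.5) * 2 + 0.5
  fr3 <- fit_report(sq, big, grid_n = 320)
  expect_lt(abs(fr3$iou - 0.25), 0.01)
  expect_error(fit_report(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0)), sq),
               class = "anchor3d_geometry_error")
})

test_that("correspondence maps boundary pilots onto the target outline", {
  model <- generic_model_fixture()
  tpl <- model$template
  corr <- correspond_pilots(model, tpl)
  # every mapped point lies on the target outline polyline
  d <- anchor3d:::dist_to_polyline(as.matrix(corr$pairs[, c("tx", "ty")]),
                                   tpl$outline)
  expect_lt(max(d), 1e-9)
  # one pair per front-layer boundary pilot, each mapped once
  expect_equal(anyDuplicated(corr$pairs$id), 0L)
  vd <- model$control_mesh$vdata
  expect_true(all(vd$layer[match(corr$pairs$id, vd$id)] == "front"))
  # a half-turn of the target changes the chosen offset, not the fit cost
  rot <- tpl$outline %*% matrix(c(-1, 0, 0, -1), 2)
  corr2 <- anchor3d:::correspond_silhouette(
    model, silhouette(model$control_mesh, model$display_levels),
    anchor3d:::ensure_ccw(rot))
  expect_false(isTRUE(all.equal(corr$cyclic_offset, corr2$cyclic_offset)))
})

test_that("move_pilots displaces exactly the selection and never the topology", {
  model <- generic_model_fixture()
  expect_identical(move_pilots(model, integer(0), NULL), model)
  before <- validate_mesh(model$control_mesh)
  moved <- move_pilots(model, 0, c(1, 0, 0))
  expect_equal(moved$control_mesh$vertices[1, ] - model$control_mesh$vertices[1, ],
               c(1, 0, 0))
  expect_equal(moved$control_mesh$vertices[-1, ], model$control_mesh$vertices[-1, ])
  after <- validate_mesh(moved$control_mesh)
  expect_equal(before$V, after$V); expect_equal(before$E, after$E)
  expect_equal(before$F, after$F)
  expect_error(move_pilots(model, 99999, c(1, 0, 0)), class = "anchor3d_lookup_error")
})

test_that("fitting the model to its own silhouette converges immediately", {
  model <- generic_model_fixture()
  sil <- silhouette(model$control_mesh, model$display_levels)
  res <- fit_to_template(model, sil, max_iters = 10)
  expect_true(res$converged)
  expect_lte(res$iterations, 2)
  disp <- max(abs(res$model$control_mesh$vertices - model$control_mesh$vertices))
  expect_lt(disp, 0.05)
})

test_that("a uniformly scaled target is recovered at the right scale", {
  model <- generic_model_fixture()
  sil <- silhouette(model$control_mesh, model$display_levels)
  ctr <- colMeans(sil)
  target <- sweep(sweep(sil, 2, ctr) * 1.5, 2, ctr, `+`)
  res <- fit_to_template(model, target, max_iters = 50)
  expect_true(res$converged)
  fitted_sil <- silhouette(res$model$control_mesh, model$display_levels)
  ratio <- anchor3d:::polygon_bbox_diag(fitted_sil) / anchor3d:::polygon_bbox_diag(sil)
  expect_equal(ratio, 1.5, tolerance = 0.01)
})

test_that("a perturbed model's silhouette is recovered from the generic model", {
  model <- generic_model_fixture()
  set.seed(11)
  ids <- sample(model$pilots, 6)
  disp <- matrix(stats::rnorm(18, sd = 0.25), 6, 3)
  disp[, 3] <- 0
  bent <- move_pilots(model, ids, disp)
  target <- silhouette(bent$control_mesh, model$display_levels)
  res <- fit_to_template(model, target, max_iters = 60)
  expect_true(res$converged)
  expect_gte(res$fit$iou, 0.95)
})

test_that("fit traces never increase and topology is preserved through deformation", {
  model <- generic_model_fixture()
  tgt <- generate_synthetic_anchor(variant_params(5))
  res <- fit_to_template(model, tgt, max_iters = 60)
  expect_true(all(diff(res$trace$mean_sym_dist) <= 1e-12))
  b <- validate_mesh(model$control_mesh)
  a <- validate_mesh(res$model$control_mesh)
  expect_equal(unclass(b)[c("V", "E", "F")], unclass(a)[c("V", "E", "F")])
})

test_that("coordinate-route deformation reproduces a fitted mesh exactly", {
  model <- generic_model_fixture()
  # identity: applying a model's own coordinates changes nothing
  same <- deform_by_coordinates(model, coordinate_table(model))
  expect_equal(same$control_mesh$vertices, model$control_mesh$vertices)
  # round-trip from a converged fit
  tgt <- generate_synthetic_anchor(variant_params(3))
  res <- fit_to_template(model, tgt, max_iters = 60)
  tab <- coordinate_table(res$model)
  fresh <- build_final_model(anchor_template(), site_config())
  re <- deform_by_coordinates(fresh, tab)
  expect_lt(max(abs(re$control_mesh$vertices - res$model$control_mesh$vertices)), 1e-9)
  # one missing row is a table error
  short <- tab
  short$rows <- short$rows[-1, ]
  expect_error(deform_by_coordinates(model, short), class = "anchor3d_table_error")
})

test_that("rotation views preserve edge lengths and are periodic", {
  mesh <- generic_model_fixture()$control_mesh
  views <- rotate_views(mesh, "x", c(0, 45, 90, 135, 180, 225, 270, 315), levels = 1)
  expect_length(views, 8)
  sil0 <- silhouette(mesh, 1)
  expect_equal(views[[1]]$silhouette, sil0, tolerance = 1e-9)
  v360 <- rotate_views(mesh, "x", 360, levels = 1)
  expect_equal(v360[[1]]$silhouette, sil0, tolerance = 1e-6)
  # rigid rotation: edge lengths of the subdivided mesh unchanged
  sub <- catmull_clark(mesh, 1)
  we <- wireframe_edges(sub)
  len0 <- sqrt(rowSums((sub$vertices[we[, 1], ] - sub$vertices[we[, 2], ])^2))
  R <- anchor3d:::rotation_matrix_3d("x", 45)
  V2 <- sub$vertices %*% t(R)
  len1 <- sqrt(rowSums((V2[we[, 1], ] - V2[we[, 2], ])^2))
  expect_lt(max(abs(len0 - len1)), 1e-9)
})
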