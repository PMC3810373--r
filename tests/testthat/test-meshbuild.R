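# Extrusion, block welding, wireframes and mesh validation.

test_that("extruding one in-plane quad yields one hexahedron of 8 vertices", {
  lay <- row_layout(1)  # 2 stations x 2 points
  ext <- extrude_strip(lay, thickness = 1)
  expect_length(ext$blocks, 1)
  expect_equal(nrow(ext$vertices), 8)
  expect_length(unique(ext$blocks[[1]]), 8)
  # 4 in-plane primitives per quad face, split over the two z layers
  expect_equal(sum(ext$vertices$layer == "front"), 4)
  expect_equal(sort(unique(ext$vertices$z)), c(-0.5, 0.5))
})

test_that("strip extrusion satisfies the closed-form block and vertex counts", {
  for (n in c(1, 3, 7)) {
    ext <- extrude_strip(row_layout(n))
    expect_length(ext$blocks, n)
    expect_equal(nrow(ext$vertices), 4 * (n + 1))
    expect_equal(ext$vertices$id, seq_len(4 * (n + 1)) - 1L)
  }
  expect_error(extrude_strip(row_layout(1), thickness = -1),
               class = "anchor3d_parameter_error")
})

test_that("single blocks and rows weld to the closed-form V/E/F, matching brute force", {
  # one block: the cube combinatorics
  ext <- extrude_strip(row_layout(1))
  mesh <- assemble_mesh(ext$vertices, ext$blocks)
  rep <- validate_mesh(mesh)
  expect_equal(rep$V, 8); expect_equal(rep$F, 6); expect_equal(rep$E, 12)
  expect_equal(rep$euler, 2)
  # rows of n blocks: V = 4(n+1), F = 4n+2, E = 8n+4, checked against the
  # independent face-pairing oracle
  for (n in c(3, 10, 25, 50)) {
    ext <- extrude_strip(row_layout(n))
    mesh <- assemble_mesh(ext$vertices, ext$blocks)
    rep <- validate_mesh(mesh)
    oracle <- brute_force_weld_counts(lapply(ext$blocks, function(b) b + 1L))
    expect_equal(rep$V, 4 * (n + 1)); expect_equal(oracle$V, rep$V)
    expect_equal(rep$F, 4 * n + 2); expect_equal(oracle$F, rep$F)
    expect_equal(rep$E, 8 * n + 4); expect_equal(oracle$E, rep$E)
    expect_equal(rep$euler, 2)
  }
  expect_error(assemble_mesh(ext$vertices, list()), class = "anchor3d_build_error")
})

test_that("wireframe edges are unique and complete", {
  ext <- extrude_strip(row_layout(1))
  mesh <- assemble_mesh(ext$vertices, ext$blocks)
  we <- wireframe_edges(mesh)
  expect_equal(nrow(we), 12)
  key <- paste(pmin(we[, 1], we[, 2]), pmax(we[, 1], we[, 2]))
  expect_equal(anyDuplicated(key), 0L)
  for (n in c(4, 9)) {
    ext <- extrude_strip(row_layout(n))
    mesh <- assemble_mesh(ext$vertices, ext$blocks)
    expect_equal(nrow(wireframe_edges(mesh)), 8 * n + 4)
  }
})

test_that("validate_mesh reports instead of throwing, and euler is recomputed correctly", {
  ext <- extrude_strip(row_layout(2))
  mesh <- assemble_mesh(ext$vertices, ext$blocks)
  rep <- validate_mesh(mesh)
  expect_true(rep$is_closed); expect_true(rep$is_oriented)
  expect_equal(rep$euler, rep$V - rep$E + rep$F)
  # deleting a face opens the mesh but still only reports
  broken <- mesh
  broken$faces <- broken$faces[-1, , drop = FALSE]
  rep2 <- validate_mesh(broken)
  expect_false(rep2$is_closed)
  expect_equal(rep2$euler, rep2$V - rep2$E + rep2$F)
})

test_that("per-site primitive counts follow the configuration", {
  model <- generic_model_fixture()
  cfg <- site_config()
  for (lab in c("I", "II", "III", "IV", "V", "VI", "VII"))
    expect_equal(count_site_primitives(model, lab), unname(cfg$counts[[lab]]))
  # an all-normal model has no site-I primitives
  plain <- build_final_model(annotate_sites(generate_synthetic_anchor(anchor_params()), list()),
                             preliminary_config())
  expect_equal(count_site_primitives(plain, "I"), 0)
  expect_error(count_site_primitives(model, "XII"), class = "anchor3d_lookup_error")
})

test_that("assembled meshes are closed, oriented, euler-2 and z-symmetric across many seeds", {
  for (seed in 1:50) {
    tpl <- annotate_sites(generate_synthetic_anchor(variant_params(seed)),
                          default_site_annotations())
    lay <- layout_strip(tpl, site_config(), n_normal_stations = 12)
    ext <- extrude_strip(lay)
    mesh <- assemble_mesh(ext$vertices, ext$blocks)
    rep <- validate_mesh(mesh)
    expect_true(rep$is_closed)
    expect_true(rep$is_oriented)
    expect_equal(rep$euler, 2)
    expect_equal(rep$degenerate_faces, 0)
  }
  # extrusion symmetry: reflecting through z = 0 maps the vertex set to itself
  mesh <- generic_model_fixture()$control_mesh
  refl <- mesh$vertices
  refl[, 3] <- -refl[, 3]
  ord1 <- order(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  ord2 <- order(refl[, 1], refl[, 2], refl[, 3])
  expect_lt(max(abs(mesh$vertices[ord1, ] - refl[ord2, ])), 1e-9)
})
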