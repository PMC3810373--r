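# Catmull-Clark subdivision: combinatorics, equivariance, hull
# containment, smoothing behavior.

test_that("subdividing the unit cube gives the classic counts", {
  cube <- unit_cube_mesh()
  s1 <- catmull_clark(cube, 1)
  r1 <- validate_mesh(s1)
  expect_equal(r1$V, 26); expect_equal(r1$F, 24); expect_equal(r1$E, 48)
  expect_equal(r1$euler, 2)
  expect_true(r1$is_closed); expect_true(r1$is_oriented)
  s2 <- catmull_clark(cube, 2)
  r2 <- validate_mesh(s2)
  expect_equal(r2$V, 98); expect_equal(r2$F, 96); expect_equal(r2$E, 192)
  expect_equal(r2$euler, 2)
  # level 0 is the identity
  expect_identical(catmull_clark(cube, 0), cube)
})

test_that("one level always yields V+E+F vertices, 4F faces and 2E+4F edges", {
  for (seed in c(2, 9, 21)) {
    tpl <- annotate_sites(generate_synthetic_anchor(variant_params(seed)),
                          default_site_annotations())
    mesh <- build_final_model(tpl, site_config())$control_mesh
    r0 <- validate_mesh(mesh)
    r1 <- validate_mesh(catmull_clark(mesh, 1))
    expect_equal(r1$V, r0$V + r0$E + r0$F)
    expect_equal(r1$F, 4 * r0$F)
    expect_equal(r1$E, 2 * r0$E + 4 * r0$F)
    expect_equal(r1$euler, r0$euler)
  }
})

test_that("subdivision commutes with affine maps", {
  set.seed(7)
  mesh <- generic_model_fixture()$control_mesh
  for (rep in 1:3) {
    A <- matrix(stats::rnorm(9, sd = 0.6), 3, 3) + diag(3)
    b <- stats::rnorm(3)
    mapped <- mesh
    mapped$vertices <- sweep(mesh$vertices %*% t(A), 2, b, `+`)
    lhs <- catmull_clark(mapped, 1)$vertices
    rhs0 <- catmull_clark(mesh, 1)$vertices
    rhs <- sweep(rhs0 %*% t(A), 2, b, `+`)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("subdivided vertices stay in the control hull; displaced ones are caught", {
  cube <- unit_cube_mesh()
  expect_true(limit_check(cube, catmull_clark(cube, 1)))
  model <- generic_model_fixture()
  sub <- catmull_clark(model$control_mesh, 2)
  expect_true(limit_check(model$control_mesh, sub))
  # hull containment across 50 seeded control meshes at level 1
  for (seed in 1:50) {
    tpl <- annotate_sites(generate_synthetic_anchor(variant_params(seed)),
                          default_site_annotations())
    mesh <- build_final_model(tpl, site_config())$control_mesh
    expect_true(limit_check(mesh, catmull_clark(mesh, 1)))
  }
  bad <- sub
  bad$vertices[5, ] <- bad$vertices[5, ] + c(100, 0, 0)
  expect_false(limit_check(model$control_mesh, bad))
})

test_that("surface area decreases monotonically on the convex cube", {
  cube <- unit_cube_mesh()
  area <- function(m) {
    n <- anchor3d:::face_normals(m$vertices, m$faces)
    sum(sqrt(rowSums(n^2)))
  }
  a <- vapply(0:3, function(l) area(catmull_clark(cube, l)), 0)
  expect_true(all(diff(a) < 0))
})

test_that("subdivision refuses open meshes", {
  cube <- unit_cube_mesh()
  open <- cube
  open$faces <- open$faces[-1, , drop = FALSE]
  expect_error(catmull_clark(open, 1), class = "anchor3d_topology_error")
})
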