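# Platelet surface mesh: generation, geometry, receptor placement.

test_that("default mesh has the published vertex count and valid topology", {
  mesh <- make_platelet_mesh()
  expect_identical(nrow(mesh$vertices), 958L)
  nv <- nrow(mesh$vertices); ne <- nrow(mesh$edges); nf <- nrow(mesh$triangles)
  expect_identical(nv - ne + nf, 2L)           # Euler characteristic
  expect_true(all(mesh$rest_length > 0))
  expect_gt(mesh$V0, 0)                        # outward orientation
  # vertices on the ellipsoid to 1e-6 relative
  r <- mesh$vertices
  val <- r[, 1]^2 / 1e-12 + r[, 2]^2 / 1e-12 + r[, 3]^2 / (0.25e-6)^2
  expect_lt(max(abs(val - 1)), 1e-6)
})

test_that("triangulation admits arbitrary vertex counts with Euler char 2", {
  for (n in c(86, 258, 555, 958)) {
    for (lam in c(0.25, 0.6, 1)) {
      m <- make_platelet_mesh(1e-6, lam, n)
      expect_identical(nrow(m$vertices), as.integer(n))
      expect_identical(nrow(m$vertices) - nrow(m$edges) + nrow(m$triangles), 2L)
    }
  }
})

test_that("mesh area and volume approach the spheroid closed forms", {
  m <- make_platelet_mesh(1e-6, 0.25, 958)
  av <- mesh_area_volume(m)
  expect_equal(av$area, oblate_spheroid_area(1e-6, 0.25), tolerance = 0.015)
  expect_equal(av$volume, 4 / 3 * pi * 1e-18 * 0.25, tolerance = 0.02)
  # sphere special case at the published example resolution
  s <- make_platelet_mesh(1e-6, 1, 642)
  expect_equal(mesh_area_volume(s)$area, 4 * pi * 1e-12, tolerance = 0.01)
})

test_that("area/volume computed two ways agree to 1e-12", {
  m <- make_platelet_mesh(1e-6, 0.25, 400)
  av <- mesh_area_volume(m)
  expect_equal(av$area, av$area_div, tolerance = 1e-12)
  expect_equal(av$volume, av$volume_div, tolerance = 1e-12)
})

test_that("area and volume are translation invariant", {
  m <- make_platelet_mesh(1e-6, 0.25, 300)
  av0 <- mesh_area_volume(m)
  m$vertices <- sweep(m$vertices, 2, c(3e-6, -2e-6, 7e-6), "+")
  av1 <- mesh_area_volume(m)
  expect_equal(av0$area, av1$area, tolerance = 1e-12)
  expect_equal(av0$volume, av1$volume, tolerance = 1e-10)
})

test_that("receptor placement hits the published surface density", {
  mesh <- place_receptors(make_platelet_mesh(), 5344, seed = 1)
  expect_identical(sum(mesh$receptors$n_receptors), 10688L)
  dens <- 10688 / (mesh_area_volume(mesh)$area * 1e12)   # per um^2
  expect_lt(abs(dens - 1500) / 1500, 0.05)
  # determinism and zero-site edge case
  mesh2 <- place_receptors(make_platelet_mesh(), 5344, seed = 1)
  expect_identical(mesh$receptors, mesh2$receptors)
  mesh3 <- place_receptors(make_platelet_mesh(), 5344, seed = 2)
  expect_false(identical(mesh$receptors$triangle, mesh3$receptors$triangle))
  empty <- place_receptors(make_platelet_mesh(), 0)
  expect_identical(nrow(empty$receptors), 0L)
})

test_that("receptor sites lie on the surface with valid barycentrics", {
  mesh <- place_receptors(make_platelet_mesh(1e-6, 0.25, 200), 600, seed = 3)
  r <- mesh$receptors
  expect_true(all(r$u >= 0 & r$v >= 0 & r$u + r$v <= 1))
  pos <- receptor_positions(mesh)
  # positions are inside (slightly under) the ellipsoid surface
  val <- pos[, 1]^2 / 1e-12 + pos[, 2]^2 / 1e-12 + pos[, 3]^2 / (0.25e-6)^2
  expect_true(all(val <= 1 + 1e-9))
})

test_that("vertex normals point outward", {
  m <- make_platelet_mesh(1e-6, 0.5, 300)
  n <- vertex_normals(m)
  expect_equal(rowSums(n^2), rep(1, 300), tolerance = 1e-12)
  expect_true(all(rowSums(n * m$vertices) > 0))
})
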