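# Synthetic test-asset generators.

test_that("icosphere hits the analytic sphere at increasing refinement", {
  s3 <- make_sphere_mesh(3)
  expect_identical(nrow(s3$vertices), 642L)
  expect_equal(mesh_area_volume(s3)$area, 4 * pi, tolerance = 0.01)
  expect_equal(mesh_area_volume(s3)$volume, 4 * pi / 3, tolerance = 0.02)
  # refinement halves the mean curvature error (second-order in the mean;
  # the 12 valence-5 vertices keep the max-norm from contracting as fast)
  err <- sapply(3:4, function(l) {
    m <- make_sphere_mesh(l, radius = 1e-6)
    mean(abs(curvature_field(m)$K * 1e-6 - 1))
  })
  expect_lt(err[2], 0.6 * err[1])
  # deterministic construction
  expect_identical(make_sphere_mesh(2)$vertices, make_sphere_mesh(2)$vertices)
})

test_that("synthetic trajectories move only when not stopped", {
  tr <- make_synthetic_trajectory(stops = list(c(0.2, 0.3)), speed = 10e-6,
                                  t_end = 1, dt = 1e-3)
  v <- diff(tr$cy) / diff(tr$t)
  expect_equal(max(tr$cy), 10e-6 * (1 - 0.3), tolerance = 1e-2)
  expect_true(all(v >= -1e-12))
  expect_identical(nrow(make_synthetic_trajectory(t_end = 1, dt = 1e-2)), 101L)
})

test_that("exponential duration fixture matches its rate", {
  d <- make_exponential_durations(3.45, 1e4, seed = 2)
  se <- 1 / 3.45 / sqrt(1e4)
  expect_lt(abs(mean(d) - 1 / 3.45), 3 * se)
  expect_identical(make_exponential_durations(5, 0), numeric(0))
  expect_identical(make_exponential_durations(5, 100, seed = 9),
                   make_exponential_durations(5, 100, seed = 9))
})
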