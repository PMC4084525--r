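# Immersed boundary coupling: kernel, spreading, interpolation, coupled step.

test_that("delta kernel satisfies partition of unity at random offsets", {
  set.seed(12)
  off <- matrix(runif(3000, -0.5, 0.5), ncol = 3)   # 1000 offsets
  grid <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3))
  worst <- 0
  for (i in seq_len(nrow(off))) {
    s <- sum(delta_kernel(off[i, 1] - grid[, 1], off[i, 2] - grid[, 2],
                          off[i, 3] - grid[, 3]))
    worst <- max(worst, abs(s - 1))
  }
  expect_lt(worst, 1e-12)
  # compact support and positivity
  r <- seq(-3, 3, by = 0.01)
  expect_true(all(delta_kernel_1d(r) >= 0))
  expect_true(all(delta_kernel_1d(r[abs(r) >= 2]) == 0))
})

test_that("force spreading conserves momentum to 1e-12", {
  set.seed(13)
  X <- cbind(runif(20, 2, 9), runif(20, 2, 9), runif(20, 3, 8))
  F <- matrix(rnorm(60), ncol = 3)
  g <- spread_forces(F, X, c(12, 12, 12))
  expect_equal(colSums(g), colSums(F), tolerance = 1e-12)
})

test_that("spreading matches the dense kernel-evaluation oracle", {
  X <- matrix(c(4.37, 5.91, 6.23), 1, 3)
  F <- matrix(c(1.5, -2, 0.7), 1, 3)
  nx <- 10; ny <- 10; nz <- 12
  g <- spread_forces(F, X, c(nx, ny, nz))
  grid <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1), z = 0:(nz - 1))
  w <- delta_kernel(grid$x - X[1], grid$y - X[2], grid$z - X[3])
  for (d in 1:3) expect_equal(g[, d], w * F[1, d], tolerance = 1e-14)
})

test_that("interpolation is exact for uniform and O(h^2) for linear fields", {
  nx <- 8; ny <- 8; nz <- 16
  ncell <- nx * ny * nz
  X <- cbind(runif(30, 1, 7), runif(30, 1, 7), runif(30, 3, 12))
  u0 <- matrix(rep(c(0.01, -0.02, 0.005), each = ncell), ncell, 3)
  U <- interpolate_velocity(u0, X, c(nx, ny, nz))
  expect_equal(U, matrix(rep(c(0.01, -0.02, 0.005), each = 30), 30, 3),
               tolerance = 1e-13)
  expect_equal(interpolate_velocity(u0 * 0, X, c(nx, ny, nz)),
               matrix(0, 30, 3))
  # linear shear u_y = gamma z: the cosine kernel carries a small residual
  # first moment (unlike the Peskin 4-point delta), so a linear field
  # interpolates with a sub-0.12-lattice-unit positional ripple
  z <- rep(0:(nz - 1), each = nx * ny)
  ushear <- cbind(0, 1e-3 * z, 0)
  U2 <- interpolate_velocity(ushear, X, c(nx, ny, nz))
  expect_lt(max(abs(U2[, 2] - 1e-3 * X[, 3])), 1e-3 * 0.12)
})

test_that("coupled step with no platelet reduces to the pure LBM module", {
  params <- platelet_params(gamma_shear = 1e4)
  sim <- platelet_simulation(params, elastic_params(), meshes = NULL,
                             dims = c(6, 8, 10), h = 0.4e-6, tau_relax = 1.0)
  ref <- lbm_init(6, 8, 10, 1.0, v_top = sim$v_top)
  # seed the reference with the same sheared initial condition
  ref$f <- sim$f
  sim <- sim_step(sim, 50, frame_every = 50)
  ref <- collide_stream(ref, 50)
  expect_equal(sim$f, ref$f, tolerance = 1e-13)
})

test_that("a force-free platelet advects with a uniform flow", {
  # both walls moving at U: uniform flow; relaxed platelet must ride along
  params <- platelet_params(gamma_shear = 1)       # shear unused below
  mesh <- make_platelet_mesh(0.8e-6, 0.5, 120)
  sim <- platelet_simulation(params, elastic_params(), mesh,
                             dims = c(10, 16, 14), h = 0.4e-6,
                             tau_relax = 1.0)
  U <- 0.02
  sim$v_bottom <- c(0, U, 0); sim$v_top <- c(0, U, 0)
  ncell <- 10 * 16 * 14
  sim$f <- plateletsim:::lbm_equilibrium_cpp(
    rep(1, ncell), matrix(rep(c(0, U, 0), each = ncell), ncell, 3))
  sim <- sim_step(sim, 400, frame_every = 40)
  fr <- sim$frames
  v_measured <- (fr$cy[nrow(fr)] - fr$cy[1]) / (fr$t[nrow(fr)] - fr$t[1])
  U_phys <- U * sim$sc$h / sim$sc$dt
  expect_equal(v_measured, U_phys, tolerance = 1e-3)
})

test_that("platelet volume drifts less than 2% over a long coupled run", {
  p <- reduced_preset()
  params <- platelet_params(a = p$a, lambda_ar = p$lambda_ar,
                            gamma_shear = 2e3)
  mesh <- make_platelet_mesh(p$a, p$lambda_ar, p$n_vertices)
  sim <- platelet_simulation(params, elastic_params(), mesh,
                             dims = p$dims, h = p$h, tau_relax = p$tau_relax,
                             H = 1.2e-6)
  sim <- sim_step(sim, 10000, frame_every = 2000)
  av <- plateletsim:::.area_volume(sim_vertices(sim), mesh$triangles)
  expect_lt(abs(av$volume / mesh$V0 - 1), 0.02)
  expect_lt(abs(av$area / mesh$area0 - 1), 0.02)
})

test_that("coupled runs are deterministic end to end", {
  p <- reduced_preset(max_steps = 1500L)
  run <- function() {
    sim <- plateletsim:::.run_tether_once(p, 2.5e3, 200, 1, seed = 5)
    list(f = sim$frames, b = sim$bonds$wall[[1]])
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$f, r2$f)
  expect_identical(r1$b, r2$b)
})
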