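# D3Q19 lattice Boltzmann: equilibrium, collision, boundaries, transport.

d3 <- lattice_d3q19()

test_that("lattice table has the D3Q19 structure", {
  expect_identical(dim(d3$c), c(19L, 3L))
  expect_equal(sum(d3$w), 1, tolerance = 1e-15)
  expect_equal(sort(unique(d3$w)), sort(c(1/36, 1/18, 1/3)))
  expect_equal(colSums(d3$c * d3$w), c(0, 0, 0), tolerance = 1e-15)
})

test_that("equilibrium reduces to the weights at rest and keeps moments", {
  f0 <- equilibrium(1, c(0, 0, 0))
  expect_equal(drop(f0), d3$w, tolerance = 1e-15)
  set.seed(3)
  rho <- runif(6, 0.9, 1.1)
  v <- matrix(runif(18, -0.05, 0.05), 6, 3)
  f <- equilibrium(rho, v)
  m <- macroscopic(list(f = f, nx = 6, ny = 1, nz = 1))
  expect_equal(m$rho, rho, tolerance = 1e-14)
  expect_equal(m$v, v, tolerance = 1e-14)
  # against the independently coded polynomial oracle
  for (j in 1:6) {
    expect_equal(f[, j], eq_oracle(rho[j], v[j, ], d3$c, d3$w),
                 tolerance = 1e-14)
  }
  expect_error(equilibrium(1, c(1.2, 0, 0)), "unstable")
})

test_that("uniform quiescent fluid is a fixed point", {
  st <- lbm_init(6, 6, 8, 1.0, wall_z = FALSE)
  f0 <- st$f
  st <- collide_stream(st, 25)
  expect_equal(st$f, f0, tolerance = 1e-13)
})

test_that("uniform body force accelerates the fluid by F/rho per step", {
  st <- lbm_init(4, 4, 4, 1.0, wall_z = FALSE)
  Fy <- 1e-5
  n <- 40
  st <- collide_stream(st, n, force = c(0, Fy, 0))
  m <- macroscopic(st, force = c(0, Fy, 0))
  expect_equal(mean(m$v[, 2]), n * Fy, tolerance = 1e-3)
})

test_that("mass is conserved with periodic boundaries", {
  set.seed(4)
  st <- lbm_init(6, 6, 6, 0.9, rho = 1 + runif(216, -0.01, 0.01),
                 v = matrix(runif(648, -0.02, 0.02), 216, 3), wall_z = FALSE)
  m0 <- sum(macroscopic(st)$rho)
  st <- collide_stream(st, 1000)
  expect_equal(sum(macroscopic(st)$rho), m0, tolerance = 1e-10)
})

test_that("velocity-wall reconstruction is moment-exact", {
  # random post-streaming state: after the BC the wall-node velocity must
  # equal the imposed wall velocity exactly
  set.seed(8)
  nx <- 4; ny <- 4; nz <- 6
  st <- lbm_init(nx, ny, nz, 1.0, rho = 1 + runif(nx * ny * nz, -0.05, 0.05),
                 v = matrix(runif(3 * nx * ny * nz, -0.03, 0.03),
                            ncol = 3))
  vw <- c(0.012, -0.02, 0)
  st <- apply_velocity_bc(st, "bottom", vw)
  st <- apply_velocity_bc(st, "top", c(-0.01, 0.03, 0))
  m <- macroscopic(st)
  bot <- 1:(nx * ny)
  top <- (nx * ny * (nz - 1) + 1):(nx * ny * nz)
  for (d in 1:3) {
    expect_equal(m$v[bot, d], rep(vw[d], nx * ny), tolerance = 1e-12)
    expect_equal(m$v[top, d], rep(c(-0.01, 0.03, 0)[d], nx * ny),
                 tolerance = 1e-12)
  }
  # quiescent equilibrium + resting wall: reconstruction returns equilibrium
  st2 <- lbm_init(2, 2, 4, 1.0)
  f0 <- st2$f
  st2 <- apply_velocity_bc(st2, "bottom", c(0, 0, 0))
  expect_equal(st2$f, f0, tolerance = 1e-14)
})

test_that("Couette flow converges to the linear profile", {
  U <- 0.05
  st <- lbm_init(3, 3, 32, 1.0, v_top = c(0, U, 0))
  st <- collide_stream(st, 6000)
  prof <- velocity_profile(st)
  expect_lt(max(abs(prof$v - U * prof$z / 31)) / U, 1e-3)
})

test_that("Poiseuille-measured viscosity matches the BGK relation", {
  for (tau in c(0.8, 1.0, 1.379)) {
    nz <- 32
    st <- lbm_init(3, 3, nz, tau)
    Fb <- 1e-6
    st <- collide_stream(st, 12000, force = c(0, Fb, 0))
    prof <- velocity_profile(st, force = c(0, Fb, 0))
    fit <- stats::lm(v ~ z + I(z^2), data = prof)
    nu_meas <- -Fb / (2 * coef(fit)[[3]])           # u'' = -F/(rho nu)
    expect_equal(nu_meas, (tau - 0.5) / 3, tolerance = 0.02)
  }
})

test_that("VTK snapshot writer emits a parseable structured-points file", {
  st <- lbm_init(3, 4, 5, 1.0)
  p <- tempfile(fileext = ".vtk")
  write_vtk_snapshot(st, p)
  lines <- readLines(p)
  expect_true(any(grepl("DIMENSIONS 3 4 5", lines)))
  expect_true(any(grepl("VECTORS velocity", lines)))
})
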