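# Stochastic adhesive dynamics: rate laws, probabilities, Monte Carlo rules.

kp <- kinetic_params()

test_that("Bell off-rate anchors and identities", {
  expect_equal(bell_off_rate(0, kp), 3.45)
  # doubling force scale: F = kBT ln2 / gamma -> exactly 2 koff0
  F_half <- kp$kBT * log(2) / kp$gamma_rc
  expect_equal(bell_off_rate(F_half, kp), 2 * 3.45, tolerance = 1e-12)
  expect_equal(bell_off_rate(2 * kp$kBT / kp$gamma_rc, kp),
               3.45 * exp(2), tolerance = 1e-12)
  expect_error(bell_off_rate(-1e-12, kp))
})

test_that("Dembo on-rate is maximal at l_b, symmetric, Gaussian", {
  expect_equal(dembo_on_rate(kp$l_b, kp), kp$kon0)
  d <- 15e-9
  expect_equal(dembo_on_rate(kp$l_b + d, kp), dembo_on_rate(kp$l_b - d, kp),
               tolerance = 1e-14)
  x_half <- kp$l_b + sqrt(2 * kp$kBT * log(2) / kp$sigma_bond)
  expect_equal(dembo_on_rate(x_half, kp), kp$kon0 / 2, tolerance = 1e-12)
})

test_that("binding probabilities are exact Poisson complements", {
  expect_equal(binding_probabilities(0, 1, 1e-4)$P_f, 0)
  expect_equal(binding_probabilities(log(2) / 1e-4, 0, 1e-4)$P_f, 0.5)
  expect_equal(binding_probabilities(0, 3.45, 1e-4)$P_r,
               3.4494e-4, tolerance = 1e-4)
})

test_that("bond force is a linear spring along the bond", {
  k <- kinetic_params(sigma_bond = 1e-3)            # 1 pN/nm
  r <- c(0, 0, k$l_b + 10e-9)
  l <- c(0, 0, 0)
  bf <- bond_force(r, l, k)
  expect_equal(bf$magnitude, 10e-12, tolerance = 1e-9)   # 10 pN tensile
  expect_equal(drop(bf$force), c(0, 0, -10e-12), tolerance = 1e-9)
  expect_equal(drop(bond_force(l, r, k)$force), c(0, 0, 10e-12),
               tolerance = 1e-9)                    # mirrored geometry
  expect_equal(bond_force(c(0, 0, k$l_b), l, k)$magnitude, 0)
})

test_that("wall repulsion follows the exponential law with clamp", {
  # identities probed at tau = 2e7 1/m so the test separations sit above
  # the 1 nm contact clamp
  tau <- 2e7; F0 <- 5e-19
  expect_equal(wall_repulsion(log(2) / tau, F0, tau), F0 * tau,
               tolerance = 1e-12)
  expect_equal(wall_repulsion(2 / tau, F0, tau),
               F0 * tau * exp(-2) / (1 - exp(-2)), tolerance = 1e-12)
  # monotone decay to zero
  eps <- seq(2e-9, 500e-9, by = 10e-9)
  v <- wall_repulsion(eps, F0, tau)
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1e-3 * F0 * tau)
  # clamp below eps_min
  expect_equal(wall_repulsion(1e-12, F0, tau), wall_repulsion(1e-9, F0, tau))
})

test_that("no bonds form beyond the binding radius", {
  mesh <- place_receptors(make_platelet_mesh(1e-6, 0.25, 100), 200, seed = 1)
  mesh$vertices[, 3] <- mesh$vertices[, 3] + 2e-6   # far above the wall
  lig <- ligand_field(4e-6, 4e-6, 25e12)
  bonds <- bond_state(200, lig)
  k <- kinetic_params(kon0 = 1e6)
  set.seed(1)
  for (i in 1:20) bonds <- mc_update(bonds, mesh, lig, k, 1e-4)
  expect_identical(sum(!is.na(bonds$site_bond)), 0L)
})

test_that("steric rules hold through crowded Monte Carlo updates", {
  # many sites over few ligands: rule (i) one bond per site, rule (ii)
  # at most four sites per vWF
  mesh <- place_receptors(make_platelet_mesh(1e-6, 0.25, 150), 400, seed = 2)
  mesh$vertices[, 3] <- mesh$vertices[, 3] + 0.3e-6
  lig <- ligand_field(2.2e-6, 2.2e-6, 4e12)         # ~16 ligands
  lig$positions[, 1:2] <- lig$positions[, 1:2] - 1.1e-6   # centre on platelet
  bonds <- bond_state(400, lig)
  k <- kinetic_params(kon0 = 1e5, koff0 = 100, sigma_bond = 1e-5)
  set.seed(42)
  for (i in 1:30) {
    bonds <- mc_update(bonds, mesh, lig, k, 1e-3)
    occ <- table(bonds$site_bond)
    expect_true(all(occ <= 4))
    expect_identical(as.integer(sum(occ)), sum(bonds$occupancy))
  }
  expect_gt(sum(!is.na(bonds$site_bond)), 0)        # something bound
  # saturated vWF takes no fifth site
  expect_true(all(bonds$occupancy <= 4))
})

test_that("bond histories are reproducible under a fixed seed", {
  mesh <- place_receptors(make_platelet_mesh(1e-6, 0.25, 120), 150, seed = 5)
  mesh$vertices[, 3] <- mesh$vertices[, 3] + 0.3e-6
  lig <- ligand_field(3e-6, 3e-6, 25e12)
  k <- kinetic_params(kon0 = 1e5, koff0 = 1e3, sigma_bond = 1e-5)
  run <- function() {
    bonds <- bond_state(150, lig)
    set.seed(99)
    for (i in 1:15) bonds <- mc_update(bonds, mesh, lig, k, 1e-3, t = i * 1e-3)
    bonds
  }
  b1 <- run(); b2 <- run()
  expect_identical(b1$site_bond, b2$site_bond)
  expect_identical(b1$events, b2$events)
})

test_that("per-step breakage reproduces exponential lifetimes", {
  # empirical mean lifetime -> 1/koff(F) within 3 standard errors
  k <- kinetic_params()
  Fb <- 10e-12
  koff <- bell_off_rate(Fb, k)
  dt <- 0.002 / koff
  set.seed(7)
  lt <- simulate_bond_lifetimes(1e4, Fb, k, dt)
  se <- 1 / koff / sqrt(1e4)
  expect_lt(abs(mean(lt) - 1 / koff), 3 * se + dt)
})

test_that("survival matches the Gillespie oracle distribution", {
  # per-step geometric scheme vs exact exponential sampling at koff dt < 0.01
  k <- kinetic_params()
  koff <- bell_off_rate(0, k)
  dt <- 0.005 / koff
  set.seed(11)
  lt <- simulate_bond_lifetimes(5000, 0, k, dt)
  exact <- rexp(5000, koff)                          # Gillespie for 1 bond
  expect_gt(suppressWarnings(stats::ks.test(lt, exact))$p.value, 0.01)
})
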