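# Experiments: Jeffery reference, pause detection, off-rate estimation,
# reduced-scale tether pipeline.

test_that("Jeffery closed form has the right period and limits", {
  expect_equal(jeffery_period(1, 300), 4 * pi / 300)       # sphere
  expect_equal(jeffery_period(0.25, 300), 0.0890, tolerance = 1e-3)
  # periodicity mod 2pi
  t <- seq(0, 0.2, by = 1e-3)
  T_orb <- jeffery_period(0.25, 300)
  a1 <- jeffery_orbit_reference(0.25, 300, t)
  a2 <- jeffery_orbit_reference(0.25, 300, t + T_orb)
  expect_equal(unclass(a1), unclass(a2), tolerance = 1e-9)
  # zero shear: no rotation
  expect_equal(unclass(jeffery_orbit_reference(0.25, 0, t)), rep(0, length(t)),
               ignore_attr = TRUE)
})

test_that("pause detector recovers constructed stops", {
  tr <- make_synthetic_trajectory(stops = list(c(0.5, 0.5)), speed = 50e-6,
                                  t_end = 2, dt = 1e-3)
  ev <- detect_pause_events(tr, free_speed = 50e-6)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$duration, 0.5, tolerance = 2e-3)
  expect_true(ev$released)
  # two separated stops
  tr2 <- make_synthetic_trajectory(stops = list(c(0.3, 0.2), c(1.2, 0.4)),
                                   speed = 50e-6, t_end = 2, dt = 1e-3)
  ev2 <- detect_pause_events(tr2, free_speed = 50e-6)
  expect_identical(nrow(ev2), 2L)
  expect_equal(ev2$duration, c(0.2, 0.4), tolerance = 2e-3)
  # free motion: no events
  tr3 <- make_synthetic_trajectory(speed = 50e-6, t_end = 1)
  expect_identical(nrow(detect_pause_events(tr3, free_speed = 50e-6)), 0L)
  # unreleased stop at the end is censored
  tr4 <- make_synthetic_trajectory(stops = list(c(1.5, 1)), speed = 50e-6,
                                   t_end = 2, dt = 1e-3)
  ev4 <- detect_pause_events(tr4, free_speed = 50e-6)
  expect_false(ev4$released[nrow(ev4)])
})

test_that("min_pause threshold includes/excludes at the boundary", {
  tr <- make_synthetic_trajectory(stops = list(c(0.5, 0.10)), speed = 50e-6,
                                  t_end = 1.5, dt = 1e-3)
  expect_identical(nrow(detect_pause_events(tr, min_pause = 0.0999,
                                            free_speed = 50e-6)), 1L)
  expect_identical(nrow(detect_pause_events(tr, min_pause = 0.15,
                                            free_speed = 50e-6)), 0L)
  expect_error(detect_pause_events(tr[1:2, ]), "too short")
})

test_that("pause detection is stable under 2x resampling", {
  stops <- list(c(0.4, 0.25), c(1.1, 0.5))
  tr1 <- make_synthetic_trajectory(stops, 50e-6, 2, dt = 2e-3)
  tr2 <- make_synthetic_trajectory(stops, 50e-6, 2, dt = 1e-3)
  ev1 <- detect_pause_events(tr1, free_speed = 50e-6, min_pause = 0.05)
  ev2 <- detect_pause_events(tr2, free_speed = 50e-6, min_pause = 0.05)
  expect_identical(nrow(ev1), nrow(ev2))
  expect_equal(ev1$duration, ev2$duration, tolerance = 2e-3 / 0.2)
})

test_that("off-rate estimator recovers synthetic exponential rates", {
  d <- make_exponential_durations(3.45, 2000, seed = 7)
  fit <- estimate_koff(d)
  expect_gt(fit$koff, 3.2)
  expect_lt(fit$koff, 3.7)
  expect_gt(glance(fit)$r.squared, 0.98)
  # the published comparison rate
  d2 <- make_exponential_durations(5.18, 2000, seed = 8)
  expect_equal(estimate_koff(d2)$koff, 5.18, tolerance = 0.08)
})

test_that("off-rate estimator is consistent as n grows", {
  errs <- sapply(c(100, 1000, 10000), function(n) {
    mean(sapply(1:3, function(s) {
      abs(estimate_koff(make_exponential_durations(3.45, n, seed = s))$koff -
            3.45) / 3.45
    }))
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("off-rate estimator flags degenerate and insufficient input", {
  expect_error(estimate_koff(rexp(5, 1)), "insufficient")
  expect_warning(fit <- estimate_koff(rep(0.5, 50)), "degenerate")
  expect_true(fit$degenerate)
  expect_true(is.na(glance(fit)$koff))
})

test_that("tidy/glance/autoplot methods work on fits and experiments", {
  fit <- estimate_koff(make_exponential_durations(3.45, 500, seed = 1))
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "koff"))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("reduced-scale tether experiment records pauses and censoring", {
  ex <- run_adhesion_experiment("smoke", n_seeds = 3, base_seed = 7,
                                preset = reduced_preset(max_steps = 8000L))
  res <- tidy(ex)
  expect_identical(nrow(res), 3L)
  expect_true(all(c("first_pause", "mean_pause", "released", "n_events")
                  %in% names(res)))
  expect_true(all(res$n_events >= res$released))
  g <- glance(ex)
  expect_identical(g$n_seeds, 3L)
  expect_identical(g$n_censored, sum(!res$released))
  # single seed: SD undefined, surfaced as NA
  ex1 <- run_adhesion_experiment("one", n_seeds = 1, base_seed = 3,
                                 preset = reduced_preset(max_steps = 6000L))
  expect_true(is.na(glance(ex1)$sd_pause) || glance(ex1)$n_censored == 1)
})

test_that("flipping near the wall is slower than far-field flipping", {
  # cheap matched configurations; only the height differs
  far <- run_flipping(h = 1e-6 / 4, dims = c(12, 24, 40), n_vertices = 162,
                      U_lattice = 0.04, n_half_periods = 1.2)
  near <- run_flipping(h = 1e-6 / 4, dims = c(12, 24, 40), n_vertices = 162,
                       U_lattice = 0.04, H_over_a = 2.4, n_half_periods = 1.3)
  expect_gt(near$period, far$period)      # wall retardation
  expect_identical(near$H_over_a, 2.4)
})

test_that("zero shear raises an error in the flipping driver", {
  expect_error(run_flipping(U_lattice = 0), "zero shear")
})
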