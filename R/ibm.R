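# Immersed-boundary coupling: delta-kernel spreading/interpolation and the
# coupled fluid-membrane-adhesion time loop.

#' Smoothed delta kernel (4-point cosine)
#'
#' One-dimensional kernel `phi(r) = (1/(4h)) (1 + cos(pi r / (2h)))` for
#' `|r| <= 2h`, zero outside; the 3-D kernel is the product of three 1-D
#' factors. Satisfies the discrete partition of unity exactly: summed over
#' any lattice-aligned sampling with spacing `h`, `sum h^3 delta_h = 1`.
#'
#' @param r Signed distance(s).
#' @param h Lattice spacing (same units as `r`; default 1 = lattice units).
#' @return Kernel value(s), units 1/length.
#' @export
delta_kernel_1d <- function(r, h = 1) {
  ifelse(abs(r) < 2 * h, (1 + cos(pi * r / (2 * h))) / (4 * h), 0)
}

#' @rdname delta_kernel_1d
#' @param rx,ry,rz Component offsets.
#' @export
delta_kernel <- function(rx, ry, rz, h = 1) {
  delta_kernel_1d(rx, h) * delta_kernel_1d(ry, h) * delta_kernel_1d(rz, h)
}

#' Spread Lagrangian point forces onto the fluid grid
#'
#' `f_ijk = sum_m F_m delta_h(x_ijk - X_m)` (lattice units, h = 1, so the
#' force density equals force per cell). Periodic in x and y; kernel
#' support crossing a z-face is truncated -- the wall absorbs that share of
#' the force. Total momentum is conserved away from the z-faces:
#' `sum_ijk f_ijk = sum_m F_m` to machine precision.
#'
#' @param vertex_forces m x 3 matrix of point forces (lattice units).
#' @param positions m x 3 matrix of positions (lattice coordinates).
#' @param grid Integer c(nx, ny, nz).
#' @return ncell x 3 force-density field (x-fastest ordering).
#' @export
spread_forces <- function(vertex_forces, positions, grid) {
  ibm_spread_cpp(positions, vertex_forces, grid[1], grid[2], grid[3])
}

#' Interpolate fluid velocity at Lagrangian points
#'
#' `U_m = sum_ijk u_ijk delta_h(x_ijk - X_m)` (lattice units). A uniform
#' field interpolates exactly (partition of unity); smooth fields to
#' O(h^2).
#'
#' @param fluid_v ncell x 3 velocity field (lattice units).
#' @param positions m x 3 matrix of positions (lattice coordinates).
#' @param grid Integer c(nx, ny, nz).
#' @return m x 3 velocities.
#' @export
interpolate_velocity <- function(fluid_v, positions, grid) {
  ibm_interp_cpp(fluid_v, positions, grid[1], grid[2], grid[3])
}

# Build the lattice-unit platelet struct handed to the C++ loop.
.platelet_struct <- function(mesh, center, sc) {
  h <- sc$h
  list(X = sweep(mesh$vertices, 2, center, "+") / h,
       tris = mesh$triangles - 1L,
       edges = mesh$edges - 1L,
       rest = mesh$rest_length / h,
       S0 = mesh$S0 / h^2, area0 = mesh$area0 / h^2, V0 = mesh$V0 / h^3,
       site_tri = matrix(mesh$receptors$triangle - 1L, ncol = 1),
       site_u = mesh$receptors$u, site_v = mesh$receptors$v)
}

#' Assemble a coupled platelet-flow simulation
#'
#' Builds the full coupled state: D3Q19 fluid in a channel with a resting
#' bottom wall (z = 0, the injured vessel wall carrying vWF) and a moving
#' top wall driving simple shear; one or two platelet meshes immersed via
#' the 4-point delta kernel; and the stochastic adhesion model. All
#' physical parameters are converted to lattice units internally.
#'
#' @param params A [platelet_params()] (fluid + adhesion physical values).
#' @param ep An [elastic_params()] (membrane mechanics).
#' @param meshes A `platelet_mesh` or list of 1-2 meshes (receptors placed
#'   if adhesion is wanted).
#' @param centers List of length-3 initial centroid positions (m); default
#'   places platelet 1 at mid-domain x/y at height `H`, platelet 2 one
#'   platelet diameter (2a) above it.
#' @param H Initial centroid height of platelet 1 (m).
#' @param dims Grid c(nx, ny, nz).
#' @param h Lattice spacing (m).
#' @param tau_relax BGK relaxation time.
#' @param wall_motion `"top"`: bottom wall at rest, top moving at
#'   `gamma * Lz` (tether geometry); `"symmetric"`: walls at -U/2 and +U/2
#'   (keeps a suspended platelet from advecting; flipping geometry).
#' @param kinetics A [kinetic_params()]; default [as_kinetic_params()] of
#'   `params`. Ligands are laid out from `params$rho_vwf` unless `ligands`
#'   is given.
#' @param ligands Optional [ligand_field()].
#' @param n_sub Fluid steps per adhesion Monte Carlo update (default 100).
#' @param stack_offset Vertical centre-to-centre offset of platelet 2 above
#'   platelet 1 (m); default one platelet diameter (2a).
#' @return List of class `platelet_sim`.
#' @export
platelet_simulation <- function(params, ep, meshes, centers = NULL,
                                H = NULL, dims = c(16, 64, 16),
                                h = 0.2e-6, tau_relax = 1.379,
                                wall_motion = c("top", "symmetric"),
                                kinetics = NULL, ligands = NULL,
                                n_sub = 100L, stack_offset = NULL) {
  wall_motion <- match.arg(wall_motion)
  if (inherits(meshes, "platelet_mesh")) meshes <- list(meshes)
  if (is.null(meshes)) meshes <- list()
  stopifnot(length(meshes) %in% 0:2)
  sc <- lattice_scaling(h, tau_relax, params)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  Lz <- (nz - 1) * h
  U <- params$gamma_shear * Lz / (sc$h / sc$dt)   # lattice wall speed
  if (abs(U) > 0.2) stop("wall speed ", U, " lattice units: reduce shear or refine")
  if (wall_motion == "top") {
    v_bottom <- c(0, 0, 0); v_top <- c(0, U, 0)
  } else {
    v_bottom <- c(0, -U / 2, 0); v_top <- c(0, U / 2, 0)
  }
  if (is.null(H)) H <- Lz / 2
  if (is.null(centers)) {
    centers <- list(c(nx / 2 * h, ny / 2 * h, H))
    if (length(meshes) == 2) {
      centers[[2]] <- centers[[1]] +
        c(0, 0, stack_offset %||% (2 * params$a))
    }
  }
  kinetics <- kinetics %||% as_kinetic_params(params)
  ligands <- ligands %||% ligand_field(nx * h, ny * h, params$rho_vwf)

  # initial fluid: linear shear profile consistent with the walls
  ncell <- nx * ny * nz
  zfrac <- rep(0:(nz - 1), each = nx * ny) / (nz - 1)
  v0 <- cbind(0, v_bottom[2] + (v_top[2] - v_bottom[2]) * zfrac, 0)
  f <- lbm_equilibrium_cpp(rep(1, ncell), v0)

  plats <- lapply(seq_along(meshes), function(i) {
    .platelet_struct(meshes[[i]], centers[[i]], sc)
  })
  n_sites <- vapply(plats, function(p) nrow(p$site_tri), integer(1))
  F0 <- .unit_factor(sc, "force")
  sim <- structure(list(
    f = f, nx = nx, ny = ny, nz = nz, tau = tau_relax,
    v_bottom = v_bottom, v_top = v_top,
    platelets = plats, meshes = meshes, sc = sc, params = params, ep = ep,
    kinetics = kinetics,
    mech_lat = list(k_spring = ep$k_spring * sc$h / F0,
                    ks = ep$k_s * sc$h / F0, kt = ep$k_t * sc$h / F0,
                    kv = ep$k_v * sc$h^2 / F0,
                    k0_bend = ep$k0_bend / (F0 * sc$h)),
    adh_lat = list(kon0 = kinetics$kon0 * sc$dt,
                   koff0 = kinetics$koff0 * sc$dt,
                   gbell = kinetics$gamma_rc / kinetics$kBT * F0,
                   sigma = kinetics$sigma_bond * sc$h / F0,
                   sigma_on = kinetics$sigma_bond / kinetics$kBT * sc$h^2,
                   lb = kinetics$l_b / sc$h,
                   rbind = kinetics$bind_radius / sc$h,
                   n_sub = as.integer(n_sub), max_per_lig = 4L),
    rep_lat = list(F0tau = params$F0_rep * params$tau_rep / F0,
                   taurep = params$tau_rep * sc$h,
                   eps_min = 1e-9 / sc$h,
                   cutoff = 20e-9 / sc$h),
    ligands_lat = ligands$positions / sc$h,
    lig_count = ligands$occupancy,
    bonds = list(wall = lapply(n_sites, function(n) rep(-1L, n)),
                 pp = rep(-1L, if (length(n_sites)) n_sites[1] else 0L),
                 pp_busy = integer(if (length(n_sites) > 1) n_sites[2] else 0)),
    step_count = 0L,
    frames = NULL, events = NULL
  ), class = "platelet_sim")
  sim
}

#' Advance the coupled simulation
#'
#' Executes the master loop: (1) membrane + bond + wall-repulsion nodal
#' forces; (2) spread to the fluid; (3) lattice Boltzmann collide/stream
#' with wall reconstruction; (4) interpolate vertex velocities;
#' (5) forward-Euler vertex advection; (6) every `n_sub` steps, the
#' stochastic adhesion update. Appends centroid/orientation/bond-count
#' frames (physical units) and optionally the bond event log.
#'
#' @param sim A `platelet_sim`.
#' @param n_steps Number of coupled steps.
#' @param frame_every Record a frame every this many steps.
#' @param record_events Keep the full bond form/break event log.
#' @param seed Optional RNG seed (applied via a local RNG scope).
#' @return Updated `platelet_sim`.
#' @export
sim_step <- function(sim, n_steps, frame_every = 100L, record_events = FALSE,
                     seed = NULL) {
  run <- function() {
    run_coupled_cpp(sim$f, sim$nx, sim$ny, sim$nz, sim$tau,
                    sim$v_bottom, sim$v_top,
                    sim$platelets, sim$mech_lat, sim$adh_lat, sim$rep_lat,
                    sim$ligands_lat, sim$lig_count,
                    list(wall = sim$bonds$wall, pp = sim$bonds$pp,
                         pp_busy = sim$bonds$pp_busy),
                    as.integer(n_steps), as.integer(frame_every),
                    record_events, as.double(sim$step_count))
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  sim$f <- res$f
  for (p in seq_along(sim$platelets)) {
    sim$platelets[[p]]$X <- res$platelets[[p]]$X
    sim$bonds$wall[[p]] <- as.integer(res$platelets[[p]]$site_bond)
  }
  sim$lig_count <- as.integer(res$lig_count)
  sim$bonds$pp <- as.integer(res$pp_bond)
  sim$bonds$pp_busy <- as.integer(res$pp_busy)
  fr <- res$frames
  np <- length(sim$platelets)
  cols <- c("t", "bonds")
  for (p in seq_len(np)) {
    cols <- c(cols, paste0(c("cx", "cy", "cz", "ax", "ay", "az", "fbond"),
                           if (np > 1) p else ""))
  }
  colnames(fr) <- cols
  fr <- tibble::as_tibble(fr)
  fr$t <- fr$t * sim$sc$dt
  for (p in seq_len(np)) {
    sfx <- if (np > 1) p else ""
    for (cc in c("cx", "cy", "cz")) {
      fr[[paste0(cc, sfx)]] <- fr[[paste0(cc, sfx)]] * sim$sc$h
    }
    fr[[paste0("fbond", sfx)]] <-
      fr[[paste0("fbond", sfx)]] * .unit_factor(sim$sc, "force")
  }
  # avoid duplicating the overlap frame on consecutive calls
  if (!is.null(sim$frames) && nrow(sim$frames) > 0) {
    fr <- fr[fr$t > max(sim$frames$t) + 1e-15 * max(fr$t, 1e-30), , drop = FALSE]
  }
  sim$frames <- if (is.null(sim$frames)) fr else dplyr::bind_rows(sim$frames, fr)
  if (record_events && nrow(res$events) > 0) {
    ev <- tibble::tibble(
      t = res$events[, 1] * sim$sc$dt,
      event = ifelse(res$events[, 2] > 0, "form", "break"),
      site = as.integer(res$events[, 3]),
      ligand = as.integer(res$events[, 4]),
      length = res$events[, 5] * sim$sc$h,
      force = res$events[, 6] * .unit_factor(sim$sc, "force"))
    sim$events <- if (is.null(sim$events)) ev else dplyr::bind_rows(sim$events, ev)
  }
  sim$step_count <- sim$step_count + as.integer(n_steps)
  sim
}

#' Current vertex positions of a simulated platelet (physical units)
#' @param sim A `platelet_sim`. @param which Platelet index.
#' @return N x 3 matrix (m).
#' @export
sim_vertices <- function(sim, which = 1) {
  sim$platelets[[which]]$X * sim$sc$h
}

#' Number of currently formed wall bonds
#' @param sim A `platelet_sim`.
#' @return Integer count (all platelets).
#' @export
sim_bond_count <- function(sim) {
  sum(vapply(sim$bonds$wall, function(b) sum(b >= 0), integer(1))) +
    sum(sim$bonds$pp >= 0)
}

#' @export
print.platelet_sim <- function(x, ...) {
  cat(sprintf("<platelet_sim> %dx%dx%d lattice (h = %.3g m, dt = %.3g s)\n",
              x$nx, x$ny, x$nz, x$sc$h, x$sc$dt))
  cat(sprintf("  %d platelet(s), %d steps elapsed (t = %.4g s), %d bonds\n",
              length(x$platelets), x$step_count,
              x$step_count * x$sc$dt, sim_bond_count(x)))
  invisible(x)
}

#' @export
tidy.platelet_sim <- function(x, ...) {
  x$frames %||% tibble::tibble()
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs facet_wrap
#' @export
autoplot.platelet_sim <- function(object, ...) {
  fr <- object$frames
  if (is.null(fr)) stop("no frames recorded yet; run sim_step() first")
  ggplot(fr, aes(x = .data$t)) +
    geom_line(aes(y = .data$cy * 1e6)) +
    labs(x = "time (s)", y = "centroid flow position (um)",
         title = "Platelet trajectory")
}
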