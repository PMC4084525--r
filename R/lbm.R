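# D3Q19 lattice Boltzmann fluid: BGK collision with Guo forcing, periodic
# x/y boundaries, Hecht-Harting on-site velocity walls at the z-faces.
# All lattice-state quantities are in lattice units (h = dt = rho0 = 1);
# use to_lattice()/to_physical() at the interface.

#' D3Q19 lattice vectors and weights
#'
#' Fixed direction table: index 1 is the rest vector (weight 1/3), 2-7 the
#' six axis vectors (1/18), 8-19 the twelve face diagonals (1/36). The
#' "unknown population" sets at the z-walls are derived from this table.
#'
#' @return List with `c` (19 x 3 integer matrix) and `w` (weights).
#' @export
lattice_d3q19 <- function() {
  tb <- d3q19_tables()
  list(c = tb$c, w = drop(tb$w))
}

#' Initialize a D3Q19 lattice state
#'
#' @param nx,ny,nz Grid dimensions (nodes). x and y are periodic; the two
#'   z-faces are on-site velocity walls when `wall_z = TRUE` (wall nodes sit
#'   exactly on z = 0 and z = nz-1).
#' @param tau_relax BGK relaxation time (> 0.5).
#' @param rho Initial density (scalar or per-node vector), lattice units.
#' @param v Initial velocity (length-3 vector or ncell x 3 matrix), lattice
#'   units.
#' @param wall_z Logical: velocity walls at the z-faces (default TRUE).
#' @param v_bottom,v_top Wall velocities (length-3, lattice units).
#' @return List of class `lattice_state`: `f` (19 x ncell), dims, `tau`,
#'   boundary spec.
#' @export
lbm_init <- function(nx, ny, nz, tau_relax = 1.379, rho = 1, v = c(0, 0, 0),
                     wall_z = TRUE, v_bottom = c(0, 0, 0),
                     v_top = c(0, 0, 0)) {
  stopifnot(tau_relax > 0.5, nx >= 1, ny >= 1, nz >= 3)
  ncell <- nx * ny * nz
  rho <- rep_len(rho, ncell)
  if (is.null(dim(v))) v <- matrix(v, ncell, 3, byrow = TRUE)
  f <- lbm_equilibrium_cpp(rho, v)
  structure(list(f = f, nx = nx, ny = ny, nz = nz, tau = tau_relax,
                 wall_z = wall_z, v_bottom = v_bottom, v_top = v_top),
            class = "lattice_state")
}

#' D3Q19 equilibrium distribution
#'
#' Standard second-order equilibrium
#' `f_i^eq = w_i rho (1 + 3 c.v + 9/2 (c.v)^2 - 3/2 v^2)` (lattice units,
#' sound speed `1/sqrt(3)`). Moments reproduce `rho` and `rho v` exactly.
#'
#' @param rho Density (scalar or vector), lattice units.
#' @param v Velocity (length-3 or n x 3), lattice units; must be below the
#'   lattice speed.
#' @return 19 x n matrix of equilibrium populations.
#' @export
equilibrium <- function(rho, v) {
  if (is.null(dim(v))) v <- matrix(v, length(rho), 3, byrow = TRUE)
  stopifnot(all(rho > 0))
  if (any(rowSums(v^2) >= 1)) stop("velocity at or above lattice speed: unstable")
  lbm_equilibrium_cpp(rho, v)
}

#' Collide and stream the lattice
#'
#' BGK relaxation toward the equilibrium evaluated at the force-corrected
#' velocity `v = u + F/(2 rho)`, plus the Guo forcing term with its
#' `(1 - 1/(2 tau))` prefactor, then streaming and wall reconstruction.
#'
#' @param state A `lattice_state`.
#' @param n_steps Number of steps.
#' @param force Optional body-force field (ncell x 3 or length-3 uniform),
#'   lattice units.
#' @return Updated `lattice_state`.
#' @export
collide_stream <- function(state, n_steps = 1, force = NULL) {
  ncell <- state$nx * state$ny * state$nz
  fmat <- if (is.null(force)) matrix(0, 0, 3)
          else if (is.null(dim(force))) matrix(force, ncell, 3, byrow = TRUE)
          else force
  state$f <- lbm_run_cpp(state$f, state$nx, state$ny, state$nz, state$tau,
                         fmat, n_steps, state$wall_z,
                         state$v_bottom, state$v_top)
  state
}

#' Apply the on-site velocity boundary to one z-face
#'
#' Reconstructs the five unknown (wall-inward) populations from the known
#' ones so the post-BC node moments equal the wall density (computed from
#' known populations, not imposed) and the prescribed wall velocity.
#'
#' @param state A `lattice_state`.
#' @param face `"bottom"` (z = 0) or `"top"` (z = nz-1).
#' @param v_wall Wall velocity, length-3 (lattice units).
#' @return Updated `lattice_state`.
#' @export
apply_velocity_bc <- function(state, face = c("bottom", "top"),
                              v_wall = c(0, 0, 0)) {
  face <- match.arg(face)
  state$f <- hh_apply_cpp(state$f, state$nx, state$ny, state$nz,
                          face == "bottom", v_wall)
  if (face == "bottom") state$v_bottom <- v_wall else state$v_top <- v_wall
  state
}

#' Macroscopic fields of a lattice state
#'
#' `rho = sum_i f_i`, `u = sum_i c_i f_i / rho`, and the force-corrected
#' (Navier-Stokes) velocity `v = u + F/(2 rho)`.
#'
#' @param state A `lattice_state`.
#' @param force Optional body-force field as in [collide_stream()].
#' @return List: `rho` (vector), `v` (ncell x 3), both lattice units;
#'   index order is x fastest, then y, then z.
#' @export
macroscopic <- function(state, force = NULL) {
  ncell <- state$nx * state$ny * state$nz
  fmat <- if (is.null(force)) matrix(0, 0, 3)
          else if (is.null(dim(force))) matrix(force, ncell, 3, byrow = TRUE)
          else force
  m <- lbm_macroscopic_cpp(state$f, fmat)
  list(rho = drop(m$rho), v = m$v)
}

#' Velocity profile along z (averaged over x, y)
#' @param state A `lattice_state`. @param component 1 (x), 2 (y) or 3 (z).
#' @param force Optional body force for the velocity correction.
#' @return Tibble with `z` (lattice index, 0-based) and `v`.
#' @export
velocity_profile <- function(state, component = 2, force = NULL) {
  m <- macroscopic(state, force)
  vz <- matrix(m$v[, component], state$nx * state$ny, state$nz)
  tibble::tibble(z = 0:(state$nz - 1), v = colMeans(vz))
}

#' Write a velocity/density snapshot as VTK legacy structured points
#' @param state A `lattice_state`. @param path Output path.
#' @export
write_vtk_snapshot <- function(state, path) {
  m <- macroscopic(state)
  n <- state$nx * state$ny * state$nz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0", "lattice snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", state$nx, state$ny, state$nz),
               "ORIGIN 0 0 0", "SPACING 1 1 1",
               sprintf("POINT_DATA %d", n),
               "SCALARS density double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(m$rho, digits = 12), con)
  writeLines("VECTORS velocity double", con)
  writeLines(paste(format(m$v[, 1], digits = 12),
                   format(m$v[, 2], digits = 12),
                   format(m$v[, 3], digits = 12)), con)
  invisible(path)
}
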