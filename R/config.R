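#' Physical parameters of the platelet-adhesion model
#'
#' Returns the full set of physical parameters used by the simulator, with
#' defaults equal to the published values for human platelets tethering to a
#' vWF-coated wall: platelet radius `a` = 1 um, aspect ratio `lambda_ar` =
#' 0.25, plasma density 1.0239 g/cm^3, plasma viscosity 1.2 cP, membrane
#' elastic modulus 25 kPa, bending modulus 200 kBT, unstressed GPIb-alpha/vWF
#' off-rate 3.45 1/s.
#'
#' Three bond-level parameters (reactive compliance `gamma_rc`, bond spring
#' constant `sigma_bond`, equilibrium bond length `l_b`) are required by the
#' Bell/Dembo rate laws but are not part of the published table; the defaults
#' (0.71 nm, 1 pN/nm, 128 nm) come from the flow-chamber literature on this
#' bond and are plain config values. The intrinsic on-rate default `kon0` =
#' 1e-5 1/s is the published value; it is implausibly small for an on-rate
#' and real studies override it (see the methods vignette).
#'
#' @param a Platelet major radius (m).
#' @param lambda_ar Aspect ratio (minor/major, dimensionless, <= 1).
#' @param gamma_shear Wall shear rate (1/s).
#' @param wall_shear_stress Optional wall shear stress (Pa). When supplied,
#'   `gamma_shear` is derived as `wall_shear_stress / mu` (experiments are
#'   reported by stress in the source data).
#' @param rho Plasma density (kg/m^3).
#' @param mu Plasma dynamic viscosity (Pa s).
#' @param E Membrane elastic modulus (Pa).
#' @param l0 Average initial spring length (m).
#' @param dx_unit Unit link length used in the stiffness relation
#'   `k_spring = E * dx_unit / 5` (m).
#' @param k_s,k_t,k_v Global-area, local-area and volume constraint
#'   coefficients (energy per unit reference measure; see vignette on units).
#' @param k0_bend Bending modulus (J); default 200 kBT at 300 K.
#' @param T Temperature (K).
#' @param kon0 Intrinsic bond formation rate (1/s).
#' @param koff0 Unstressed bond dissociation rate (1/s).
#' @param gamma_rc Reactive compliance of the Bell model (m).
#' @param sigma_bond Bond spring constant (N/m).
#' @param l_b Equilibrium bond length (m).
#' @param bind_radius Maximum receptor--ligand separation at which bond
#'   formation is attempted (m); default equals `l_b` = 128 nm.
#' @param F0_rep Wall repulsion amplitude (N m); the repulsive force is
#'   `F0_rep * tau_rep * exp(-tau_rep*eps) / (1 - exp(-tau_rep*eps))`.
#' @param tau_rep Wall repulsion decay constant (1/m).
#' @param rho_vwf Wall vWF surface density (1/m^2); default 25 per um^2.
#' @param n_receptors GPIb-alpha receptors per platelet; default 10688.
#' @param n_receptor_sites Surface sites carrying receptors (2 receptors per
#'   site); default 5344.
#'
#' @return A list of class `platelet_params`.
#' @export
#' @examples
#' p <- platelet_params()
#' reynolds_number(400, p$rho, p$a, p$mu)  # O(1e-4): Stokes regime
platelet_params <- function(a = 1e-6,
                            lambda_ar = 0.25,
                            gamma_shear = 300,
                            wall_shear_stress = NULL,
                            rho = 1023.9,
                            mu = 1.2e-3,
                            E = 25e3,
                            l0 = 75e-9,
                            dx_unit = 0.1e-6,
                            k_s = 6000,
                            k_t = 6000,
                            k_v = 6000,
                            k0_bend = 200 * 1.380649e-23 * 300,
                            T = 300,
                            kon0 = 1e-5,
                            koff0 = 3.45,
                            gamma_rc = 0.71e-9,
                            sigma_bond = 1e-3,
                            l_b = 128e-9,
                            bind_radius = 128e-9,
                            F0_rep = 5e-19,
                            tau_rep = 2000e6,
                            rho_vwf = 25e12,
                            n_receptors = 10688,
                            n_receptor_sites = 5344) {
  if (!is.null(wall_shear_stress)) {
    stopifnot(wall_shear_stress > 0)
    gamma_shear <- wall_shear_stress / mu
  }
  p <- list(
    a = a, lambda_ar = lambda_ar, gamma_shear = gamma_shear,
    rho = rho, mu = mu, E = E, l0 = l0, dx_unit = dx_unit,
    k_s = k_s, k_t = k_t, k_v = k_v, k0_bend = k0_bend, T = T,
    kon0 = kon0, koff0 = koff0, gamma_rc = gamma_rc,
    sigma_bond = sigma_bond, l_b = l_b, bind_radius = bind_radius,
    F0_rep = F0_rep, tau_rep = tau_rep, rho_vwf = rho_vwf,
    n_receptors = n_receptors, n_receptor_sites = n_receptor_sites
  )
  num <- vapply(p, is.numeric, logical(1))
  if (any(vapply(p[num], function(x) any(x <= 0), logical(1)))) {
    stop("all physical parameters must be strictly positive")
  }
  if (lambda_ar > 1) stop("lambda_ar must be <= 1 (oblate or spherical)")
  p$kBT <- 1.380649e-23 * T
  class(p) <- "platelet_params"
  p
}

#' @export
print.platelet_params <- function(x, ...) {
  cat("<platelet_params>\n")
  cat(sprintf("  a = %.3g m, lambda = %.3g, shear rate = %.4g 1/s\n",
              x$a, x$lambda_ar, x$gamma_shear))
  cat(sprintf("  rho = %.1f kg/m^3, mu = %.3g Pa s, E = %.3g Pa\n",
              x$rho, x$mu, x$E))
  cat(sprintf("  koff0 = %.3g 1/s, kon0 = %.3g 1/s, %d receptors (%d sites)\n",
              x$koff0, x$kon0, x$n_receptors, x$n_receptor_sites))
  invisible(x)
}

#' Lattice Boltzmann timestep from the BGK stability relation
#'
#' The timestep follows from the kinematic-viscosity relation of the BGK
#' collision operator, `nu = cs^2 (tau - 1/2) dt` with `cs^2 = h^2/(3 dt^2)`,
#' solved for `dt`:
#' \deqn{\Delta t = (\tau - 0.5)\, h^2 / (3 \nu).}
#' With the default plasma viscosity, `tau = 1.379` and `h = 0.2` um this
#' gives 1e-8 s.
#'
#' @param tau_relax Dimensionless BGK relaxation time (> 0.5).
#' @param h Lattice spacing (m).
#' @param nu Kinematic viscosity (m^2/s).
#' @return Timestep (s).
#' @export
#' @examples
#' compute_timestep(1.379, 0.2e-6, 1.2e-3 / 1023.9)  # 1e-8 s
compute_timestep <- function(tau_relax, h, nu) {
  stopifnot(h > 0, nu > 0)
  if (tau_relax <= 0.5) {
    stop("tau_relax must exceed 0.5 for a stable (positive-viscosity) BGK fluid")
  }
  (tau_relax - 0.5) * h^2 / (3 * nu)
}

#' Particle Reynolds number of a platelet in shear flow
#'
#' `Re = gamma * rho * a^2 / mu`; around 3e-4 at physiological shear, so the
#' flow around a platelet is effectively inertialess.
#'
#' @param gamma_shear Shear rate (1/s). @param rho Fluid density (kg/m^3).
#' @param a Particle radius (m). @param mu Dynamic viscosity (Pa s).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(gamma_shear, rho, a, mu) {
  stopifnot(gamma_shear >= 0, rho > 0, a > 0, mu > 0)
  gamma_shear * rho * a^2 / mu
}

#' Lattice scaling: unit conversion between physical (SI) and lattice units
#'
#' Builds the conversion system for a D3Q19 lattice with spacing `h`,
#' relaxation time `tau_relax` and fluid of kinematic viscosity `mu/rho`.
#' The mass unit is chosen so the quiescent fluid has lattice density 1.
#'
#' @param h Lattice spacing (m).
#' @param tau_relax BGK relaxation time (dimensionless, > 0.5).
#' @param params A [platelet_params()] object (supplies `mu`, `rho`).
#' @return A list of class `lattice_scaling` with fields `h`, `dt`,
#'   `tau_relax`, and conversion factors `L0` (m), `T0` (s), `M0` (kg).
#' @export
#' @examples
#' sc <- lattice_scaling(0.2e-6, 1.379, platelet_params())
#' sc$dt  # 1e-8 s
lattice_scaling <- function(h, tau_relax, params = platelet_params()) {
  nu <- params$mu / params$rho
  dt <- compute_timestep(tau_relax, h, nu)
  sc <- list(
    h = h, dt = dt, tau_relax = tau_relax,
    L0 = h, T0 = dt, M0 = params$rho * h^3,
    nu_lattice = (tau_relax - 0.5) / 3
  )
  class(sc) <- "lattice_scaling"
  sc
}

.unit_factor <- function(sc, kind) {
  switch(kind,
    length   = sc$L0,
    time     = sc$T0,
    velocity = sc$L0 / sc$T0,
    force    = sc$M0 * sc$L0 / sc$T0^2,
    density  = sc$M0 / sc$L0^3,
    rate     = 1 / sc$T0,
    stop("unknown unit kind: ", kind)
  )
}

#' Convert a physical quantity to lattice units (and back)
#'
#' @param x Numeric quantity in SI units (`to_lattice`) or lattice units
#'   (`to_physical`).
#' @param kind One of `"length"`, `"time"`, `"velocity"`, `"force"`,
#'   `"density"`, `"rate"`.
#' @param scaling A [lattice_scaling()] object.
#' @return Converted quantity; round trips are exact to machine precision.
#' @export
to_lattice <- function(x, kind, scaling) x / .unit_factor(scaling, kind)

#' @rdname to_lattice
#' @export
to_physical <- function(x, kind, scaling) x * .unit_factor(scaling, kind)

#' Read / write a simulation configuration file
#'
#' YAML with sections `physical`, `lattice`, `adhesion` and `experiment`.
#' Keys in `physical` and `adhesion` override the matching arguments of
#' [platelet_params()]; `lattice` holds `h`, `tau_relax` and grid dimensions;
#' `experiment` is passed through untouched.
#'
#' @param path File path.
#' @return `read_config()`: a list with elements `params`
#'   ([platelet_params()]), `lattice` (list) and `experiment` (list).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  phys <- c(raw$physical, raw$adhesion)
  keep <- intersect(names(phys), names(formals(platelet_params)))
  params <- do.call(platelet_params, phys[keep])
  list(params = params, lattice = raw$lattice, experiment = raw$experiment)
}

#' @rdname read_config
#' @param config List as returned by [read_config()] (or of the same shape).
#' @export
write_config <- function(config, path) {
  p <- unclass(config$params)
  p$kBT <- NULL
  adh_keys <- c("kon0", "koff0", "gamma_rc", "sigma_bond", "l_b",
                "bind_radius", "rho_vwf", "n_receptors", "n_receptor_sites")
  out <- list(
    physical = p[setdiff(names(p), adh_keys)],
    adhesion = p[adh_keys],
    lattice = config$lattice,
    experiment = config$experiment
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
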