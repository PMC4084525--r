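# Stochastic adhesive dynamics: GPIb-alpha/vWF bond kinetics (Bell
# dissociation, Dembo association), Monte Carlo bond updates, bond spring
# forces, and the short-range wall repulsion.

#' Kinetic parameters of the receptor-ligand bond
#'
#' @param kon0 Intrinsic formation rate (1/s).
#' @param koff0 Unstressed dissociation rate (1/s); default 3.45.
#' @param gamma_rc Reactive compliance (m).
#' @param sigma_bond Bond spring constant (N/m).
#' @param l_b Equilibrium bond length (m); default 128 nm.
#' @param bind_radius Formation cutoff distance (m); default `l_b`.
#' @param T Temperature (K).
#' @return List of class `kinetic_params` (includes `kBT`).
#' @export
kinetic_params <- function(kon0 = 1e-5, koff0 = 3.45, gamma_rc = 0.71e-9,
                           sigma_bond = 1e-3, l_b = 128e-9,
                           bind_radius = l_b, T = 300) {
  stopifnot(kon0 >= 0, koff0 >= 0, gamma_rc > 0, sigma_bond > 0,
            l_b > 0, bind_radius > 0, T > 0)
  structure(list(kon0 = kon0, koff0 = koff0, gamma_rc = gamma_rc,
                 sigma_bond = sigma_bond, l_b = l_b,
                 bind_radius = bind_radius, T = T,
                 kBT = 1.380649e-23 * T),
            class = "kinetic_params")
}

#' @rdname kinetic_params
#' @param params A [platelet_params()] object to take the kinetic subset from.
#' @export
as_kinetic_params <- function(params) {
  kinetic_params(params$kon0, params$koff0, params$gamma_rc,
                 params$sigma_bond, params$l_b, params$bind_radius, params$T)
}

#' Bell force-dependent dissociation rate
#'
#' `koff(F) = koff0 * exp(gamma_rc * F / kBT)`: the dissociation rate grows
#' exponentially with the tensile force on the bond (pure slip bond; no
#' catch regime).
#'
#' @param F_b Applied bond force (N), >= 0; vectorized.
#' @param kp A [kinetic_params()] object.
#' @return Dissociation rate (1/s).
#' @export
#' @examples
#' bell_off_rate(0, kinetic_params())           # 3.45 1/s (unstressed)
#' bell_off_rate(20e-12, kinetic_params())      # a few-fold faster at 20 pN
bell_off_rate <- function(F_b, kp) {
  stopifnot(all(F_b >= 0))
  kp$koff0 * exp(kp$gamma_rc * F_b / kp$kBT)
}

#' Dembo separation-dependent formation rate
#'
#' `kon(x) = kon0 * exp(-sigma_bond * (x - l_b)^2 / (2 kBT))`: a Gaussian
#' in the deviation of the receptor-ligand distance from the equilibrium
#' bond length, maximal at `x = l_b` and symmetric about it.
#'
#' @param x_b Receptor-ligand separation (m), >= 0; vectorized.
#' @param kp A [kinetic_params()] object.
#' @return Formation rate (1/s).
#' @export
dembo_on_rate <- function(x_b, kp) {
  stopifnot(all(x_b >= 0))
  kp$kon0 * exp(-kp$sigma_bond * (x_b - kp$l_b)^2 / (2 * kp$kBT))
}

#' Per-step binding/unbinding probabilities
#'
#' `P_f = 1 - exp(-kon dt)`, `P_r = 1 - exp(-koff dt)`: the exact
#' probabilities of at least one Poisson event in a step of length `dt`.
#'
#' @param kon,koff Rates (1/s). @param dt Step length (s).
#' @return List with `P_f` and `P_r`.
#' @export
binding_probabilities <- function(kon, koff, dt) {
  stopifnot(all(kon >= 0), all(koff >= 0), dt > 0)
  list(P_f = 1 - exp(-kon * dt), P_r = 1 - exp(-koff * dt))
}

#' Bond spring force
#'
#' Linear-spring force of magnitude `sigma_bond * (x_b - l_b)` directed
#' along the bond: tensile (pulling the receptor toward the ligand) when
#' stretched, compressive when shorter than `l_b`. The wall is rigid, so
#' the reaction on the ligand is discarded (but equal and opposite).
#'
#' @param receptor n x 3 matrix of receptor positions (m).
#' @param ligand n x 3 matrix of ligand positions (m).
#' @param kp A [kinetic_params()] object.
#' @return List: `force` (n x 3, N, acting on the receptor side), `length`
#'   (m), `magnitude` (signed, N; positive = tension).
#' @export
bond_force <- function(receptor, ligand, kp) {
  receptor <- rbind(receptor); ligand <- rbind(ligand)
  d <- ligand - receptor
  x_b <- unname(sqrt(rowSums(d^2)))
  mag <- kp$sigma_bond * (x_b - kp$l_b)
  dir <- d / ifelse(x_b > 0, x_b, 1)
  list(force = unname(dir * mag), length = x_b, magnitude = mag)
}

#' Short-range wall repulsion
#'
#' Empirical repulsive force between the membrane and the vessel wall,
#' `F_rep(eps) = F0 * tau * exp(-tau * eps) / (1 - exp(-tau * eps))`,
#' directed away from the wall; `eps` is the membrane-wall separation.
#' Separations below `eps_min` (default 1 nm) are clamped to avoid the
#' divergence at contact.
#'
#' @param eps Separation distance(s) (m).
#' @param F0_rep Amplitude (N m); default 500 pN um.
#' @param tau_rep Decay constant (1/m); default 2000 per um.
#' @param eps_min Clamp distance (m).
#' @return Force magnitude(s) (N), acting in +z on the platelet.
#' @export
#' @examples
#' wall_repulsion(log(2) / 2000e6)  # = F0 * tau exactly
wall_repulsion <- function(eps, F0_rep = 5e-19, tau_rep = 2000e6,
                           eps_min = 1e-9) {
  eps <- pmax(eps, eps_min)
  e <- exp(-tau_rep * eps)
  F0_rep * tau_rep * e / (1 - e)
}

#' Wall vWF ligand field
#'
#' Immobilized vWF molecules on the wall plane z = 0, on a uniform grid at
#' the requested surface density (default 25 per um^2, the flow-chamber
#' coating density).
#'
#' @param Lx,Ly Domain extent in x and y (m).
#' @param density Surface density (1/m^2).
#' @return List of class `ligand_field`: `positions` (L x 3 matrix, z = 0),
#'   `density`, and `occupancy` (integer bond count per ligand, all zero).
#' @export
ligand_field <- function(Lx, Ly, density = 25e12) {
  spacing <- 1 / sqrt(density)
  if (spacing > Lx || spacing > Ly) {       # domain too small for even one
    g <- data.frame(x = double(), y = double())
  } else {
    xs <- seq(spacing / 2, Lx - spacing / 2, by = spacing)
    ys <- seq(spacing / 2, Ly - spacing / 2, by = spacing)
    g <- expand.grid(x = xs, y = ys)
  }
  structure(list(positions = cbind(g$x, g$y, 0), density = density,
                 occupancy = integer(nrow(g))),
            class = "ligand_field")
}

#' Initialize an empty bond state
#'
#' @param n_sites Number of receptor sites on the platelet.
#' @param ligands A [ligand_field()].
#' @return List of class `bond_state`: `site_bond` (ligand index per site,
#'   NA when free), `occupancy` (bonds per ligand), `events` (tibble).
#' @export
bond_state <- function(n_sites, ligands) {
  structure(list(site_bond = rep(NA_integer_, n_sites),
                 occupancy = ligands$occupancy,
                 events = tibble::tibble(t = double(), event = character(),
                                         site = integer(), ligand = integer(),
                                         length = double(), force = double())),
            class = "bond_state")
}

#' Monte Carlo adhesion update
#'
#' One stochastic update of the bond population: (1) every free
#' receptor-site/ligand pair closer than `bind_radius` attempts formation
#' with probability `P_f = 1 - exp(-kon(x) dt)`, subject to the steric
#' rules -- a site holds at most one bond, a vWF binds at most
#' `max_per_ligand` (4) sites; (2) every existing bond breaks with
#' probability `P_r = 1 - exp(-koff(F) dt)`. Candidate pairs are processed
#' in a uniformly shuffled order so competition for ligand slots carries no
#' index bias. Driven by R's RNG: identical seed and inputs give an
#' identical bond history.
#'
#' @param bonds A [bond_state()].
#' @param mesh A `platelet_mesh` with receptors placed (site positions are
#'   taken from the current vertex positions).
#' @param ligands A [ligand_field()].
#' @param kp A [kinetic_params()] object.
#' @param dt Monte Carlo step length (s).
#' @param t Current simulation time (s), recorded in the event log.
#' @param max_per_ligand Steric cap per vWF (default 4).
#' @return Updated `bond_state` (events appended).
#' @export
mc_update <- function(bonds, mesh, ligands, kp, dt, t = 0,
                      max_per_ligand = 4L) {
  sitepos <- receptor_positions(mesh)
  sb <- ifelse(is.na(bonds$site_bond), -1L, bonds$site_bond - 1L)
  res <- mc_update_cpp(sitepos, sb, bonds$occupancy, ligands$positions,
                       kp$kon0, kp$koff0, kp$gamma_rc / kp$kBT,
                       kp$sigma_bond, kp$sigma_bond / kp$kBT,
                       kp$l_b, kp$bind_radius, dt, max_per_ligand)
  bonds$site_bond <- ifelse(res$site_bond < 0, NA_integer_,
                            as.integer(res$site_bond) + 1L)
  bonds$occupancy <- as.integer(res$lig_count)
  ev <- res$events
  if (nrow(ev) > 0) {
    bonds$events <- dplyr::bind_rows(
      bonds$events,
      tibble::tibble(t = t, event = ifelse(ev[, 2] > 0, "form", "break"),
                     site = as.integer(ev[, 3]), ligand = as.integer(ev[, 4]),
                     length = ev[, 5], force = ev[, 6]))
  }
  bonds
}

#' Vertex forces from the current wall bonds
#'
#' Maps each bond's spring force at its receptor site to the site's
#' triangle vertices by barycentric weights.
#'
#' @param bonds A [bond_state()]. @param mesh Platelet mesh.
#' @param ligands A [ligand_field()]. @param kp Kinetic parameters.
#' @return N x 3 matrix of vertex forces (N).
#' @export
bond_vertex_forces <- function(bonds, mesh, ligands, kp) {
  Fv <- matrix(0, nrow(mesh$vertices), 3)
  bound <- which(!is.na(bonds$site_bond))
  if (length(bound) == 0) return(Fv)
  sitepos <- receptor_positions(mesh)
  bf <- bond_force(sitepos[bound, , drop = FALSE],
                   ligands$positions[bonds$site_bond[bound], , drop = FALSE],
                   kp)
  r <- mesh$receptors[bound, ]
  tri <- mesh$triangles[r$triangle, , drop = FALSE]
  w <- cbind(r$u, r$v, 1 - r$u - r$v)
  for (corner in 1:3) {
    for (d in 1:3) {
      Fv[, d] <- Fv[, d] + tabulate2(tri[, corner],
                                     w[, corner] * bf$force[, d],
                                     nrow(Fv))
    }
  }
  Fv
}

#' Sample bond lifetimes under constant force
#'
#' Repeated per-step breakage trials (`P_r = 1 - exp(-koff(F) dt)`) for `n`
#' independent bonds held at constant force; the resulting lifetime
#' distribution should match the exponential with rate `koff(F)` whenever
#' `koff * dt` is small. This is the validation path for the Monte Carlo
#' breakage scheme.
#'
#' @param n Number of bonds.
#' @param F_b Constant applied force (N).
#' @param kp A [kinetic_params()] object.
#' @param dt Monte Carlo step (s).
#' @param max_steps Safety cap per bond.
#' @return Vector of lifetimes (s).
#' @export
simulate_bond_lifetimes <- function(n, F_b, kp, dt, max_steps = 1e7) {
  koff <- bell_off_rate(F_b, kp)
  drop(bond_lifetimes_cpp(n, koff, dt, as.integer(max_steps)))
}
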