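# Synthetic test assets, all generated in code (pure functions of their
# arguments; nothing is downloaded or bundled).

#' Icosphere test mesh
#'
#' Recursively subdivided icosahedron projected to a sphere: the standard
#' analytic-curvature test asset. Subdivision levels 0..4 give 12, 42, 162,
#' 642, 2562 vertices. Deterministic (no RNG).
#'
#' @param level Subdivision level (0-5).
#' @param radius Sphere radius (m).
#' @return A `platelet_mesh` (reference geometry = the generated sphere).
#' @export
#' @examples
#' mesh_area_volume(make_sphere_mesh(3))$area / (4 * pi)  # ~1 (radius 1)
make_sphere_mesh <- function(level = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    key <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      id <- key[[k]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1]] <<- m
      id <- nv + length(newv)
      key[[k]] <- id
      id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(cc, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  .finish_mesh(v * radius, matrix(as.integer(f), nrow(f), 3),
               a = radius, lambda_ar = 1)
}

#' Synthetic centroid trajectory with constructed stops
#'
#' A platelet translating at constant speed along the flow direction,
#' interrupted by full stops at given times -- the ground-truth input for
#' the pause-event detector.
#'
#' @param stops List of c(t_start, duration) pairs (s); may be empty.
#' @param speed Free translation speed (m/s).
#' @param t_end Total duration (s).
#' @param dt Sampling interval (s).
#' @return Tibble with `t` (s) and `cy` (flow coordinate, m).
#' @export
make_synthetic_trajectory <- function(stops = list(), speed = 50e-6,
                                      t_end = 2, dt = 1e-3) {
  t <- seq(0, t_end, by = dt)
  moving <- rep(TRUE, length(t))
  for (s in stops) {
    moving[t >= s[1] & t < s[1] + s[2]] <- FALSE
  }
  cy <- cumsum(c(0, speed * dt * moving[-1]))
  tibble::tibble(t = t, cy = cy)
}

#' Exponential pause-duration sample
#'
#' I.i.d. exponential durations at the given rate; the recovery asset for
#' the off-rate estimator.
#'
#' @param rate Rate (1/s). @param n Sample size. @param seed RNG seed.
#' @return Vector of durations (s).
#' @export
make_exponential_durations <- function(rate, n, seed = 1) {
  if (n == 0) return(numeric(0))
  with_seed(seed, rexp(n, rate))
}
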