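# Triangulated platelet surface: generation, geometry, receptor placement.

#' @importFrom stats runif rexp setNames coef lm quantile sd approx
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Meridian arc length of the ellipse (a*sin(theta), c*cos(theta)), theta in
# [0, pi], tabulated for numeric inversion.
.meridian_arc <- function(a, c, n = 4096) {
  theta <- seq(0, pi, length.out = n)
  ds <- sqrt((a * cos(theta))^2 + (c * sin(theta))^2)
  s <- c(0, cumsum((ds[-1] + ds[-n]) / 2 * diff(theta)))
  list(theta = theta, s = s, total = s[n])
}

#' Generate a triangulated oblate-spheroid platelet surface
#'
#' Builds a closed, outward-oriented triangular mesh with exactly `n_target`
#' vertices on the ellipsoid `x^2/a^2 + y^2/a^2 + z^2/(lambda_ar*a)^2 = 1`
#' (symmetry axis along z, matching the convention of a platelet lying above
#' the wall plane z = 0). Vertices are placed on latitude rings spaced
#' uniformly in meridian arc length, with per-ring counts proportional to
#' ring circumference, plus the two poles; adjacent rings are zippered into
#' triangle strips. The construction is deterministic and admits any
#' `n_target >= 8`; the default 958 matches the published discretization.
#'
#' The generated state is recorded as the unstressed reference: per-edge rest
#' lengths, per-triangle reference areas, total reference area and volume.
#'
#' @param a Major (equatorial) radius (m).
#' @param lambda_ar Aspect ratio (polar/equatorial, 0 < lambda_ar <= 1).
#' @param n_target Exact number of vertices.
#' @param seed Unused for generation (the triangulation is deterministic);
#'   kept so fixture specs are uniform.
#' @return A list of class `platelet_mesh` with elements `vertices` (N x 3,
#'   m), `triangles` (F x 3 integer), `edges` (E x 2 integer),
#'   `rest_length` (E), `S0` (per-triangle reference area), `area0`, `V0`,
#'   `a`, `lambda_ar`, and `receptors` (empty until [place_receptors()]).
#' @export
#' @examples
#' mesh <- make_platelet_mesh()
#' nrow(mesh$vertices)              # 958
#' mesh_area_volume(mesh)$area      # ~7.1e-12 m^2 (7.1 um^2)
make_platelet_mesh <- function(a = 1e-6, lambda_ar = 0.25, n_target = 958,
                               seed = NULL) {
  stopifnot(a > 0, lambda_ar > 0, lambda_ar <= 1, n_target >= 8)
  c_pol <- lambda_ar * a
  arc <- .meridian_arc(a, c_pol)

  # choose ring count so band spacing ~ in-ring spacing (isotropic triangles)
  n_int <- n_target - 2
  # total area ~ sum over rings of circumference * ds; solve m from
  # ds = total_arc/(m+1) and sum(n_j) = n_int with n_j = circ_j / ds
  circ_at <- function(theta) 2 * pi * a * sin(theta)
  m <- max(3L, round(sqrt(n_int * arc$total /
                            (2 * pi * a * 2 / pi))))  # initial guess
  # refine: pick m minimizing anisotropy ds/dl
  best <- NULL
  for (mm in max(3L, m - 8L):(m + 8L)) {
    ds <- arc$total / (mm + 1)
    s_rings <- ds * seq_len(mm)
    th <- approx(arc$s, arc$theta, xout = s_rings)$y
    w <- circ_at(th)
    nj <- pmax(3L, round(w / sum(w) * n_int))
    # fix rounding to hit n_int exactly: adjust largest rings
    diff_n <- n_int - sum(nj)
    ord <- order(w, decreasing = TRUE)
    i <- 1L
    while (diff_n != 0L) {
      j <- ord[(i - 1L) %% mm + 1L]
      step <- sign(diff_n)
      if (nj[j] + step >= 3L) {
        nj[j] <- nj[j] + step
        diff_n <- diff_n - step
      }
      i <- i + 1L
    }
    dl <- w / nj
    aniso <- max(ds / dl, dl / ds)
    if (is.null(best) || aniso < best$aniso) {
      best <- list(m = mm, theta = th, nj = nj, aniso = aniso)
    }
  }
  m <- best$m; theta_rings <- best$theta; nj <- best$nj

  # vertices: north pole, rings (staggered), south pole
  verts <- matrix(0, n_target, 3)
  verts[1, ] <- c(0, 0, c_pol)
  idx <- 1L
  ring_start <- integer(m)
  for (j in seq_len(m)) {
    ring_start[j] <- idx + 1L
    phi <- 2 * pi * ((seq_len(nj[j]) - 1) + 0.5 * (j %% 2)) / nj[j]
    st <- sin(theta_rings[j]); ct <- cos(theta_rings[j])
    verts[idx + seq_len(nj[j]), ] <- cbind(a * st * cos(phi),
                                           a * st * sin(phi),
                                           c_pol * ct)
    idx <- idx + nj[j]
  }
  verts[n_target, ] <- c(0, 0, -c_pol)

  # triangles: pole fans + zippered bands; winding chosen for outward normals
  tris <- vector("list", m + 1L)
  r1 <- ring_start[1]; n1 <- nj[1]
  tris[[1]] <- cbind(1L, r1 + (seq_len(n1) %% n1), r1 + seq_len(n1) - 1L)
  for (j in seq_len(m - 1L)) {
    tris[[j + 1L]] <- .zipper(ring_start[j], nj[j],
                              ring_start[j + 1L], nj[j + 1L],
                              (j %% 2) * 0.5, ((j + 1L) %% 2) * 0.5)
  }
  rm_ <- ring_start[m]; nm_ <- nj[m]
  tris[[m + 1L]] <- cbind(n_target, rm_ + seq_len(nm_) - 1L,
                          rm_ + (seq_len(nm_) %% nm_))
  triangles <- do.call(rbind, tris)
  storage.mode(triangles) <- "integer"

  mesh <- .finish_mesh(verts, triangles, a = a, lambda_ar = lambda_ar)
  mesh
}

# Zipper two rings into a triangle strip. Ring 1 is the upper (smaller
# colatitude) ring. Vertices are at azimuth (i + off)/n (fractions of 2*pi).
.zipper <- function(s1, n1, s2, n2, off1, off2) {
  u1 <- ((seq_len(n1) - 1) + off1) / n1
  u2 <- ((seq_len(n2) - 1) + off2) / n2
  i1 <- 0L; i2 <- 0L
  out <- matrix(0L, n1 + n2, 3)
  k <- 0L
  nxt <- function(u, i, n) u[(i %% n) + 1L] + (i %/% n)
  while (i1 < n1 || i2 < n2) {
    k <- k + 1L
    a1 <- s1 + (i1 %% n1); a2 <- s2 + (i2 %% n2)
    adv1 <- if (i1 >= n1) FALSE
            else if (i2 >= n2) TRUE
            else nxt(u1, i1 + 1L, n1) <= nxt(u2, i2 + 1L, n2)
    if (adv1) {
      b <- s1 + ((i1 + 1L) %% n1)
      out[k, ] <- c(a1, b, a2)
      i1 <- i1 + 1L
    } else {
      b <- s2 + ((i2 + 1L) %% n2)
      out[k, ] <- c(a1, b, a2)
      i2 <- i2 + 1L
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Assemble derived mesh quantities, fix orientation, validate closedness.
.finish_mesh <- function(verts, triangles, a = NA_real_, lambda_ar = NA_real_) {
  av <- .area_volume(verts, triangles)
  if (av$volume < 0) {  # flip winding to outward
    triangles <- triangles[, c(1, 3, 2), drop = FALSE]
    av <- .area_volume(verts, triangles)
  }
  ek <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  ek <- cbind(pmin(ek[, 1], ek[, 2]), pmax(ek[, 1], ek[, 2]))
  key <- paste(ek[, 1], ek[, 2])
  cnt <- table(key)
  if (any(cnt != 2)) stop("mesh is not a closed 2-manifold (edge shared by != 2 triangles)")
  edges <- unique(ek)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  dimnames(triangles) <- NULL
  dimnames(verts) <- NULL
  rest <- sqrt(rowSums((verts[edges[, 1], , drop = FALSE] -
                          verts[edges[, 2], , drop = FALSE])^2))
  nv <- nrow(verts); ne <- nrow(edges); nf <- nrow(triangles)
  if (nv - ne + nf != 2L) stop("mesh Euler characteristic != 2")
  structure(list(
    vertices = verts, triangles = triangles, edges = edges,
    rest_length = rest, S0 = av$S_tri, area0 = av$area, V0 = av$volume,
    a = a, lambda_ar = lambda_ar,
    receptors = tibble::tibble(site = integer(), triangle = integer(),
                               u = double(), v = double(),
                               n_receptors = integer())
  ), class = "platelet_mesh")
}

.area_volume <- function(verts, triangles) {
  p1 <- verts[triangles[, 1], , drop = FALSE]
  p2 <- verts[triangles[, 2], , drop = FALSE]
  p3 <- verts[triangles[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  S_tri <- 0.5 * sqrt(rowSums(cr^2))
  vol <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
             p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
             p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  list(S_tri = S_tri, area = sum(S_tri), volume = vol, face_normal2 = cr)
}

#' Surface area and enclosed volume of a closed mesh
#'
#' Area is the sum of triangle areas; volume the sum of signed tetrahedron
#' volumes against the origin (positive for outward orientation). The
#' divergence-theorem forms (`area_div`, `volume_div`) are also returned as
#' an internal consistency check.
#'
#' @param mesh A `platelet_mesh`.
#' @return List with `area`, `volume`, `area_div`, `volume_div` (SI units).
#' @export
mesh_area_volume <- function(mesh) {
  av <- .area_volume(mesh$vertices, mesh$triangles)
  # divergence theorem: V = (1/3) sum centroid . n_hat * S ; area via vector
  # norm of the summed per-face area vectors recomputed componentwise
  p1 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  p2 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  p3 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  cent <- (p1 + p2 + p3) / 3
  nvec <- 0.5 * av$face_normal2          # area-weighted normals
  vol_div <- sum(rowSums(cent * nvec)) / 3
  area_div <- sum(sqrt(rowSums(nvec^2)))
  list(area = av$area, volume = av$volume,
       area_div = area_div, volume_div = vol_div)
}

#' Area-weighted outward vertex normals
#' @param mesh A `platelet_mesh`.
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  av <- .area_volume(mesh$vertices, mesh$triangles)
  nv <- nrow(mesh$vertices)
  n <- matrix(0, nv, 3)
  for (k in 1:3) {
    for (cc in 1:3) {
      n[, cc] <- n[, cc] + tabulate2(mesh$triangles[, k],
                                     av$face_normal2[, cc], nv)
    }
  }
  n / sqrt(rowSums(n^2))
}

# sum `w` into bins `i` of length n (sparse accumulation)
tabulate2 <- function(i, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, i)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Place GPIb-alpha receptor sites on the platelet surface
#'
#' Receptor sites are independent surface points (not mesh vertices): the
#' published model carries 5344 sites on a 958-vertex mesh, so sites must
#' outnumber vertices. Each site is sampled uniformly over the surface
#' (triangle chosen with probability proportional to area, then uniform
#' barycentric position) and stores its triangle id and barycentric
#' coordinates; each site represents two GPIb-alpha receptors (the receptor
#' pair of one GPV complex). Bond forces at a site are later distributed to
#' the triangle's vertices by barycentric weight.
#'
#' @param mesh A `platelet_mesh`.
#' @param n_sites Number of receptor sites (default 5344, i.e. 10688
#'   receptors).
#' @param seed RNG seed; the same seed reproduces the same site list.
#' @return The mesh with its `receptors` tibble filled in.
#' @export
#' @examples
#' mesh <- place_receptors(make_platelet_mesh(), 5344, seed = 1)
#' sum(mesh$receptors$n_receptors) / (mesh_area_volume(mesh)$area * 1e12)
#' # ~1500 receptors per um^2
place_receptors <- function(mesh, n_sites = 5344, seed = 1) {
  stopifnot(n_sites >= 0)
  if (n_sites == 0) {
    mesh$receptors <- mesh$receptors[0, ]
    return(mesh)
  }
  probs <- mesh$S0 / sum(mesh$S0)
  dat <- with_seed(seed, {
    tri <- sample.int(nrow(mesh$triangles), n_sites, replace = TRUE,
                      prob = probs)
    r1 <- sqrt(runif(n_sites)); r2 <- runif(n_sites)
    list(tri = tri, u = 1 - r1, v = r1 * (1 - r2))
  })
  mesh$receptors <- tibble::tibble(
    site = seq_len(n_sites), triangle = dat$tri,
    u = dat$u, v = dat$v, n_receptors = 2L
  )
  mesh
}

#' World positions of receptor sites
#' @param mesh A `platelet_mesh` with receptors placed.
#' @return n_sites x 3 matrix (m).
#' @export
receptor_positions <- function(mesh) {
  r <- mesh$receptors
  if (nrow(r) == 0) return(matrix(0, 0, 3))
  tri <- mesh$triangles[r$triangle, , drop = FALSE]
  p1 <- mesh$vertices[tri[, 1], , drop = FALSE]
  p2 <- mesh$vertices[tri[, 2], , drop = FALSE]
  p3 <- mesh$vertices[tri[, 3], , drop = FALSE]
  w3 <- 1 - r$u - r$v
  p1 * r$u + p2 * r$v + p3 * w3
}

#' @export
print.platelet_mesh <- function(x, ...) {
  cat(sprintf("<platelet_mesh> %d vertices, %d triangles, %d edges\n",
              nrow(x$vertices), nrow(x$triangles), nrow(x$edges)))
  cat(sprintf("  a = %.3g m, lambda = %.3g, area0 = %.4g m^2, V0 = %.4g m^3\n",
              x$a, x$lambda_ar, x$area0, x$V0))
  if (nrow(x$receptors) > 0) {
    cat(sprintf("  %d receptor sites (%d receptors)\n",
                nrow(x$receptors), sum(x$receptors$n_receptors)))
  }
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.platelet_mesh <- function(x, ...) {
  tibble::tibble(vertex = seq_len(nrow(x$vertices)),
                 x = x$vertices[, 1], y = x$vertices[, 2],
                 z = x$vertices[, 3])
}

#' Closed-form surface area of an oblate spheroid
#'
#' `S = 2 pi a^2 (1 + ((1 - e^2)/e) artanh(e))`, `e = sqrt(1 - lambda^2)`.
#' Used as the analytic oracle for mesh area checks.
#' @param a Equatorial radius (m). @param lambda_ar Aspect ratio.
#' @return Area (m^2).
#' @export
oblate_spheroid_area <- function(a, lambda_ar) {
  if (lambda_ar == 1) return(4 * pi * a^2)
  e <- sqrt(1 - lambda_ar^2)
  2 * pi * a^2 * (1 + (1 - e^2) / e * atanh(e))
}
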