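# Shared fixtures and small independent oracles used across test files.

table2 <- platelet_params()        # published defaults
nu_plasma <- table2$mu / table2$rho

# independently coded D3Q19 equilibrium (the oracle for the C++ version)
eq_oracle <- function(rho, v, ci, wi) {
  sapply(seq_len(19), function(i) {
    cv <- sum(ci[i, ] * v)
    wi[i] * rho * (1 + 3 * cv + 4.5 * cv^2 - 1.5 * sum(v^2))
  })
}

# central-difference gradient of a scalar energy over vertex coordinates
fd_gradient <- function(mesh, energy_fn, delta = 1e-11) {
  g <- matrix(0, nrow(mesh$vertices), 3)
  for (i in seq_len(nrow(mesh$vertices))) {
    for (d in 1:3) {
      mp <- mesh; mp$vertices[i, d] <- mp$vertices[i, d] + delta
      mm <- mesh; mm$vertices[i, d] <- mm$vertices[i, d] - delta
      g[i, d] <- (energy_fn(mp) - energy_fn(mm)) / (2 * delta)
    }
  }
  g
}

# random smooth perturbation of a mesh (fraction of its radius scale)
perturb_mesh <- function(mesh, frac = 0.02, seed = 1) {
  scale <- frac * mean(sqrt(rowSums(mesh$vertices^2)))
  mesh$vertices <- mesh$vertices +
    plateletsim:::with_seed(seed,
      matrix(runif(length(mesh$vertices), -scale, scale), ncol = 3))
  mesh
}

# planar triangulated patch (open mesh) for curvature edge cases
flat_patch <- function(n = 8, spacing = 1e-7) {
  g <- expand.grid(x = 0:n, y = 0:n)
  verts <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) i + 1 + (n + 1) * j
  tris <- list()
  for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
    tris[[length(tris) + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    tris[[length(tris) + 1]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  list(vertices = verts, triangles = do.call(rbind, tris),
       interior = which(g$x > 1 & g$x < n - 1 & g$y > 1 & g$y < n - 1))
}
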