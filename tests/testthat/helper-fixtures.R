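# Shared fixtures.  Heavier objects are built lazily and memoized so single
# test files stay cheap to run interactively.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

ref_geom <- function() memo("geom", function() vf_geometry())

ref_mesh <- function(n = 120) {
  memo(paste0("mesh", n), function() vf_triangulate(vf_geometry(), n))
}

ref_cache <- function(n = 120, nu = 0.4995) {
  memo(paste0("cache", n), function()
    vfbayes:::assembly_cache(ref_mesh(n), nu))
}

# short reference simulation with trajectories, used by the contact and
# observation tests (350 ms keeps several post-transient cycles)
ref_sim_traj <- function() {
  memo("sim_traj", function()
    vf_simulate(vf_props(), ref_mesh(), duration_ms = 350, h_ms = 0.05,
                cache = ref_cache(), store_trajectories = TRUE))
}

# full-length reference simulation without trajectories
ref_sim <- function() {
  memo("sim_full", function()
    vf_simulate(vf_props(), ref_mesh(), duration_ms = 550, h_ms = 0.05,
                cache = ref_cache()))
}

# a tiny two-triangle rectangular mesh in vf_mesh form (single layer)
rect_mesh <- function(Lx = 2, Lz = 1) {
  nodes <- rbind(c(0, 0), c(Lx, 0), c(Lx, Lz), c(0, Lz))
  tri <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  structure(list(
    nodes = nodes, triangles = tri,
    layer = factor(rep("body", 2), levels = c("body", "ligament", "cover")),
    fixed_nodes = integer(0), free_surface = integer(0),
    patch = c(1L, 1L)), class = "vf_mesh")
}

# independent 3-point Gauss quadrature of the element integrands, used as
# the oracle for the closed-form element matrices
quad_element <- function(coords_mm, E, nu, rho, eta_poise) {
  p <- coords_mm * 1e-3
  # midpoint rule points (degree-2 exact on triangles)
  gp <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
  w <- rep(1 / 3, 3)
  detJ <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
    (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
  A <- detJ / 2
  b <- c(p[2, 2] - p[3, 2], p[3, 2] - p[1, 2], p[1, 2] - p[2, 2]) / detJ
  cc <- c(p[3, 1] - p[2, 1], p[1, 1] - p[3, 1], p[2, 1] - p[1, 1]) / detJ
  B <- rbind(c(b, 0, 0, 0), c(0, 0, 0, cc), c(cc, b))
  cm <- constitutive(E, nu)
  Ke <- matrix(0, 6, 6); De <- matrix(0, 6, 6); Me <- matrix(0, 6, 6)
  for (g in seq_len(3)) {
    N <- gp[g, ]
    Phi <- rbind(c(N, 0, 0, 0), c(0, 0, 0, N))
    Ke <- Ke + w[g] * A * t(B) %*% cm$C %*% B
    De <- De + w[g] * A * t(B) %*% (0.1 * eta_poise * cm$S) %*% B
    Me <- Me + w[g] * A * rho * t(Phi) %*% Phi
  }
  list(Me = Me, De = De, Ke = Ke)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  scale <- max(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(actual - expected)) / scale, rel_tol)
}
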