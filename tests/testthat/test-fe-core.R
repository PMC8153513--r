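test_that("Lame parameters match their closed forms", {
  expect_equal(lame_parameters(1234, 0), list(mu = 617, lambda = 0))
  lp <- lame_parameters(600, 0.4995)
  expect_equal(lp$mu, 600 / (2 * 1.4995))          # ~200.07 Pa
  expect_equal(lp$lambda, 0.4995 * 600 / (1.4995 * 0.001))  # ~1.999e5 Pa
  expect_equal(lp$mu, 200.0667, tolerance = 1e-6)
  expect_equal(lp$lambda, 1.998666e5, tolerance = 1e-6)
  expect_error(lame_parameters(600, 0.5), "constitutive-domain")
  expect_error(lame_parameters(-5, 0.3), "constitutive-domain")
})

test_that("constitutive matrix is the plane-strain law and S = C/mu", {
  cm0 <- constitutive(700, 0)
  expect_equal(cm0$C, 350 * diag(c(2, 2, 1)))
  cm <- constitutive(600, 0.4995)
  expect_equal(cm$C[1, 1], cm$lambda + 2 * cm$mu)
  expect_equal(cm$C[1, 1], 2.0027e5, tolerance = 1e-4)
  expect_equal(cm$C, cm$mu * cm$S, tolerance = 1e-12)
  # positive definiteness across admissible parameters
  for (E in c(1, 600, 1e5)) for (nu in c(-0.9, 0, 0.3, 0.4995)) {
    ev <- eigen(constitutive(E, nu)$C, symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), 0)
  }
})

test_that("element matrices match the quadrature oracle", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))     # unit right triangle, mm
  em <- element_matrices(tri, 600, 0.3, 1050, 3)
  qr <- quad_element(tri, 600, 0.3, 1050, 3)
  expect_rel_equal(em$Ke, qr$Ke, 1e-10)
  expect_rel_equal(em$De, qr$De, 1e-10)
  expect_rel_equal(em$Me, qr$Me, 1e-10)
  # consistent-mass row sum: total mass rho * A per coordinate block
  A <- 0.5e-6
  expect_equal(sum(em$Me[1:3, 1:3]), 1050 * A)
  # rigid-body modes are annihilated by Ke
  r1 <- c(1, 1, 1, 0, 0, 0)
  r2 <- c(0, 0, 0, 1, 1, 1)
  rot <- c(-tri[, 2], tri[, 1]) * 1e-3
  for (r in list(r1, r2, rot))
    expect_lt(max(abs(em$Ke %*% r)), 1e-9 * max(abs(em$Ke)))
  expect_error(element_matrices(rbind(c(0, 0), c(1, 0), c(2, 0)), 600, 0.3,
                                1050, 3), "singular-element")
})

test_that("assembly conserves mass and preserves symmetry", {
  mesh <- ref_mesh()
  props <- vf_props()
  sys <- vf_assemble(mesh, props)
  nN <- nrow(mesh$nodes)
  asym <- function(S) max(abs(S - Matrix::t(S))) / max(abs(S))
  expect_lt(asym(sys$M), 1e-10)
  expect_lt(asym(sys$D), 1e-10)
  expect_lt(asym(sys$K), 1e-10)
  area_m2 <- sum(triangle_areas(mesh)) * 1e-6
  expect_rel_equal(sum(sys$M[1:nN, 1:nN]), props$rho * area_m2, 1e-9)
  expect_rel_equal(sum(sys$M[-(1:nN), -(1:nN)]), props$rho * area_m2, 1e-9)
})

test_that("assembled operators scale linearly in their coefficients", {
  mesh <- rect_mesh()
  p1 <- vf_props(E_bdy = 1000, rho = 1000, eta = 2, nu = 0.3)
  p2 <- vf_props(E_bdy = 3000, rho = 2000, eta = 6, nu = 0.3)
  s1 <- vf_assemble(mesh, p1)
  s2 <- vf_assemble(mesh, p2)
  expect_rel_equal(as.matrix(s2$K), 3 * as.matrix(s1$K), 1e-12)
  expect_rel_equal(as.matrix(s2$M), 2 * as.matrix(s1$M), 1e-12)
  expect_rel_equal(as.matrix(s2$D), 3 * as.matrix(s1$D), 1e-12)
})

test_that("mesh-dependence of a 2-element square is bounded", {
  # same square split along the two diagonals
  mk <- function(tri) structure(list(
    nodes = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), triangles = tri,
    layer = factor(rep("body", 2), levels = c("body", "ligament", "cover")),
    fixed_nodes = integer(0), free_surface = integer(0),
    patch = c(1L, 1L)), class = "vf_mesh")
  mA <- mk(rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  mB <- mk(rbind(c(1L, 2L, 4L), c(2L, 3L, 4L)))
  props <- vf_props(E_bdy = 1000, nu = 0.3)
  tip <- function(mesh) {
    sys <- vf_constrain(vf_assemble(mesh, props), fixed_nodes = c(1L, 4L))
    F <- numeric(nrow(sys$K))
    F[sys$dof_of_node[3, 1]] <- 1e-3   # point load at the free corner
    solve(as.matrix(sys$K), F)[sys$dof_of_node[3, 1]]
  }
  tA <- tip(mA); tB <- tip(mB)
  expect_rel_equal(sum(triangle_areas(mA)), sum(triangle_areas(mB)), 1e-12)
  expect_lt(abs(tA - tB) / max(abs(tA), abs(tB)), 0.2)
})

test_that("constraint elimination controls the stiffness nullspace", {
  mesh <- rect_mesh()
  props <- vf_props(E_bdy = 1000, nu = 0.3)
  sys <- vf_assemble(mesh, props)
  K <- as.matrix(sys$K)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  # free-floating: exactly the three rigid-body modes
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 3L)
  # a single fixed node leaves the rotation about it
  s1 <- vf_constrain(sys, fixed_nodes = 1L)
  e1 <- eigen(as.matrix(s1$K), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(sum(abs(e1) < 1e-8 * max(e1)), 1L)
  # an edge fixed: positive definite
  s2 <- vf_constrain(sys, fixed_nodes = c(1L, 4L))
  e2 <- eigen(as.matrix(s2$K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(e2), 0)
  expect_error(vf_constrain(sys, fixed_nodes = 1:4), "degenerate-system")
})

test_that("a uniaxial traction patch reproduces the plane-strain field", {
  # rectangle under uniform traction t on the x = Lx face, rollers on
  # x = 0 (u_x = 0) and z = 0 (u_z = 0), nu = 0.3, full integration.
  Lx <- 2; Lz <- 1; t_mag <- 100; E <- 1000; nu <- 0.3
  mesh <- rect_mesh(Lx, Lz)
  sys <- vf_assemble(mesh, vf_props(E_bdy = E, nu = nu),
                     formulation = "full")
  K <- as.matrix(sys$K)
  nN <- 4L
  # dofs: x = node, z = nN + node
  F <- numeric(2 * nN)
  F[c(2, 3)] <- t_mag * (Lz * 1e-3) / 2   # right-edge nodes 2,3
  fixed <- c(1L, 4L, nN + 1L, nN + 2L)    # u_x = 0 on left, u_z = 0 on bottom
  keep <- setdiff(seq_len(2 * nN), fixed)
  u <- numeric(2 * nN)
  u[keep] <- solve(K[keep, keep], F[keep])
  lp <- lame_parameters(E, nu)
  lam <- lp$lambda; mu <- lp$mu
  a <- t_mag * (lam + 2 * mu) / ((lam + 2 * mu)^2 - lam^2)  # eps_xx
  b <- -lam * a / (lam + 2 * mu)                            # eps_zz
  u_exact <- c(a * mesh$nodes[, 1], b * mesh$nodes[, 2]) * 1e-3
  expect_rel_equal(u, u_exact, 1e-8)
})
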