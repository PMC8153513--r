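sysc_for <- function(x0 = 8.4, eta = 3, p_sub = 1000) {
  props <- vf_props(eta = eta, p_sub = p_sub, x0 = x0)
  vf_constrain(vf_assemble(ref_mesh(), props, cache = ref_cache()))
}

max_node_x <- function(sys, theta) {
  cn <- vfbayes:::contact_candidates(sys)
  max(cn$X + 1e3 * theta[cn$dof0 + 1])
}

test_that("pre-stress solve respects the compression constraint", {
  sys <- sysc_for()
  # flush geometry: no compression, zero state
  p0 <- vf_prestress(sys, 8.4)
  expect_equal(p0$theta0, rep(0, nrow(sys$K)))
  expect_equal(p0$energy, 0)
  # compressed: every node at or behind x0, contact set engaged
  p1 <- vf_prestress(sys, 8.27)
  expect_lte(max_node_x(sys, p1$theta0), 8.27 + 1e-4)
  expect_gt(p1$energy, 0)
  expect_gt(p1$n_active, 0)
  # stored energy grows monotonically with compression
  en <- vapply(c(8.40, 8.35, 8.30, 8.25), function(x0)
    vf_prestress(sys, x0)$energy, numeric(1))
  expect_true(all(diff(en) > 0))
  expect_error(vf_prestress(sys, 9.0), "x0")
})

test_that("the zero state is a fixed point of the step", {
  M <- diag(2); D <- 0.1 * diag(2); K <- 5 * diag(2)
  th <- vf_step(M, D, K, c(0, 0), c(0, 0), c(0, 0), 1e-3)
  expect_equal(th, c(0, 0))
})

test_that("single-dof reduction matches the harmonic oscillator period", {
  m <- 1; f <- 100; k <- (2 * pi * f)^2 * m
  run <- function(h) {
    n <- round(0.2 / h)
    res <- vfbayes:::integrate_fe(
      matrix(m), matrix(0), matrix(k), h, n, 1e-3, 0,
      integer(0), integer(0), numeric(0), numeric(0),
      integer(0), numeric(0), 1e9, 17, 0, 0, 1e-3, 1.14,
      FALSE, TRUE, 2L, FALSE, 0.25, 0.5)
    x <- res$trajectories[1, ]
    up <- which(x[-length(x)] < 0 & x[-1] >= 0)
    # linear interpolation of the crossing instants
    tc <- (up - 1 + x[up] / (x[up] - x[up + 1])) * h
    mean(diff(tc))
  }
  T_exact <- 2 * pi * sqrt(m / k)
  e1 <- abs(run(0.05e-3) - T_exact) / T_exact
  e2 <- abs(run(0.025e-3) - T_exact) / T_exact
  expect_lt(e1, ((2 * pi * f * 0.05e-3)^2))   # O(h^2) bound
  expect_gt(e1 / e2, 2.5)                     # second-order convergence
  expect_lt(e1 / e2, 6)
})

test_that("undamped free vibration conserves energy to 1 percent", {
  props <- vf_props(eta = 0, p_sub = 0, x0 = 8.3)
  sim <- vf_simulate(props, ref_mesh(), duration_ms = 50.05, h_ms = 0.05,
                     cache = ref_cache(), contact = FALSE,
                     store_trajectories = TRUE)
  en <- trajectory_energy(sim)     # 1000 interior samples
  expect_gt(min(en), 0)
  expect_lt(diff(range(en)) / en[1], 0.01)
})

test_that("viscous damping makes the free energy decay", {
  props <- vf_props(eta = 3, p_sub = 0, x0 = 8.3)
  sim <- vf_simulate(props, ref_mesh(), duration_ms = 30, h_ms = 0.05,
                     cache = ref_cache(), contact = FALSE,
                     store_trajectories = TRUE)
  en <- trajectory_energy(sim)
  expect_lt(en[length(en)], 0.5 * en[1])
  expect_lt(max(en), en[1] * 1.001)
})

test_that("no node ever penetrates the midline and contact is compressive", {
  sim <- ref_sim_traj()
  sys <- sim$system
  cn <- vfbayes:::contact_candidates(sys)
  xmax <- apply(sim$trajectories, 2, function(th)
    max(cn$X + 1e3 * th[cn$dof0 + 1]))
  expect_lte(max(xmax), 8.4 + 1e-9)
  expect_gte(min(sim$contact_force), 0)
  expect_gt(max(sim$contact_force), 0)   # collisions do occur
})

test_that("stored contact forces equal the discrete momentum residual", {
  sim <- ref_sim_traj()
  sys <- sim$system
  M <- as.matrix(sys$M); D <- as.matrix(sys$D); K <- as.matrix(sys$K)
  h <- sim$h_ms * 1e-3
  th <- sim$trajectories
  Fst <- sim$forces
  sd_ <- vfbayes:::surface_dofs(sys)
  checked <- 0L
  for (k in seq(3, ncol(th), by = 17)) {
    in_contact <- which(sim$contact_force[, k] > 0)
    if (!length(in_contact)) next
    thdd <- (th[, k] - 2 * th[, k - 1] + th[, k - 2]) / h^2
    thd <- (th[, k] - th[, k - 2]) / (2 * h)
    thbar <- (th[, k] + 2 * th[, k - 1] + th[, k - 2]) / 4
    r <- M %*% thdd + D %*% thd + K %*% thbar - Fst[, k]
    for (i in in_contact) {
      dof <- sd_$x_dof0[i] + 1
      expect_equal(-r[dof], sim$contact_force[i, k],
                   tolerance = 1e-8)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("contact pressure is force over tributary edge area", {
  # 1 mN over a 0.5 mm tributary length and 17 mm depth -> 117.6 Pa
  f_per_depth <- 1e-3 / 17e-3            # N per metre depth
  expect_equal(f_per_depth / 0.5e-3, 117.6, tolerance = 1e-3)
  sim <- ref_sim_traj()
  trib <- vfbayes:::tributary_lengths(sim$mesh)
  expect_equal(sim$contact_pressure,
               sim$contact_force / (trib * 1e-3), tolerance = 1e-12)
  cs <- contact_stats(sim, from_ms = 150)
  expect_gt(cs$max_cp, cs$mean_cp)
})

test_that("the reference configuration self-oscillates sustainably", {
  sim <- ref_sim()
  expect_true(sustained_oscillation(sim))
  a <- sim$gaw$area
  expect_gt(max(a), 10)
  expect_true(all(a >= 0))
  # peak-to-peak amplitude in the final 100 ms is at least half of that in
  # the preceding 100 ms
  w2 <- a[sim$times >= 0.45]
  w1 <- a[sim$times >= 0.35 & sim$times < 0.45]
  expect_gte(diff(range(w2)), 0.5 * diff(range(w1)))
})

test_that("without driving pressure the fold settles to rest", {
  props <- vf_props(p_sub = 0)
  sim <- vf_simulate(props, ref_mesh(), duration_ms = 300,
                     cache = ref_cache())
  expect_false(sustained_oscillation(sim))
  late <- sim$gaw$area[sim$times > 0.25]
  expect_lt(diff(range(late)), 1e-6)
})

test_that("the fundamental frequency is converged in the time step", {
  f0_of <- function(h) {
    sim <- vf_simulate(vf_props(), ref_mesh(), duration_ms = 550, h_ms = h,
                       cache = ref_cache())
    g <- trim_transient(downsample(sim$gaw, 2000), 250)
    a <- g$area; eps <- 0.2 * max(a); op <- a > eps
    up <- which(!op[-length(op)] & op[-1]) + 1L
    1 / mean(diff(up) / 2000)
  }
  f1 <- f0_of(0.05); f2 <- f0_of(0.025)
  expect_lt(abs(f1 - f2) / f1, 0.02)
})

test_that("a non-finite state is reported as a failed integration", {
  res <- vfbayes:::integrate_fe(
    matrix(1), matrix(0), matrix(1), 1e-3, 10, NaN, 0,
    integer(0), integer(0), numeric(0), numeric(0),
    integer(0), numeric(0), 1e9, 17, 0, 0, 1e-3, 1.14,
    FALSE, FALSE, 2L, FALSE, 0.25, 0.5)
  expect_true(res$failed)
  expect_equal(res$fail_step, 1L)
})
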