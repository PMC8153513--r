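test_that("prior specification carries the study bounds and units", {
  pr <- vf_prior()
  expect_setequal(pr$param, c("E_bdy", "E_cvr", "E_lig", "p_sub", "rho", "eta"))
  expect_equal(pr$lower[pr$param == "E_cvr"], 250)
  expect_equal(pr$upper[pr$param == "E_cvr"], 950)
  expect_equal(pr$lower[pr$param == "p_sub"], 400)
  expect_equal(pr$upper[pr$param == "p_sub"], 1800)
  expect_equal(attr(pr, "fixed")$nu, 0.4995)
  expect_equal(attr(pr, "fixed")$p_sup, 0)
  prx <- vf_prior(estimate_x0 = TRUE)
  expect_true("x0" %in% prx$param)
  expect_equal(prx$lower[prx$param == "x0"], 7.4)
  expect_equal(prx$upper[prx$param == "x0"], 8.4)
  expect_error(vf_prior(bounds = list(E_cvr = c(900, 100))), "invalid prior")
  expect_error(vf_prior(bounds = list(bogus = c(0, 1))), "unknown")
})

test_that("prior sampling is uniform, seeded and degenerate-safe", {
  pr <- vf_prior()
  s1 <- sample_prior(pr, 50, seed = 42)
  s2 <- sample_prior(pr, 50, seed = 42)
  expect_identical(s1, s2)
  s3 <- sample_prior(pr, 50, seed = 43)
  expect_false(identical(s1, s3))
  # CLT check on the E_cvr mean: mean of U(250, 950) is 600
  big <- sample_prior(pr, 1e4, seed = 1)
  se <- (700 / sqrt(12)) / 100
  expect_lt(abs(mean(big$E_cvr) - 600), 3 * se)
  expect_true(all(big$E_cvr > 250 & big$E_cvr < 950))
  # collapsed bounds give a point mass
  prc <- vf_prior(bounds = list(E_cvr = c(600, 600 + 1e-12)))
  sc <- sample_prior(prc, 10, seed = 1)
  expect_equal(sc$E_cvr, rep(600, 10), tolerance = 1e-9)
})

test_that("log-likelihood follows the Gaussian error model", {
  g1 <- gaw_series((0:599) / 2000, rep(5, 600), fps = 2000)
  expect_equal(log_likelihood(g1, g1), 0)
  g2 <- gaw_series((0:599) / 2000, rep(6, 600), fps = 2000)
  expect_equal(log_likelihood(g1, g2, sigma_e = 1), -300)
  expect_equal(log_likelihood(g1, g2, sigma_e = 2), -75)   # 1/c^2 scaling
  expect_equal(log_likelihood(g1, NULL), -Inf)
  g3 <- gaw_series((0:9) / 2000, rep(5, 10), fps = 2000)
  expect_error(log_likelihood(g1, g3), "comparison error")
})

test_that("importance weights are log-sum-exp stabilized", {
  expect_equal(importance_weights(rep(-12345, 4)), rep(0.25, 4))
  expect_equal(importance_weights(c(0, -log(3))), c(0.75, 0.25))
  w <- importance_weights(c(-1e6, -1e6 + 2, -Inf))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[3], 0)
  expect_true(all(w >= 0))
  expect_error(importance_weights(c(-Inf, -Inf)), "total-failure")
})

test_that("multinomial resampling tracks the weights", {
  draws <- tibble::tibble(x = c(1, 2))
  expect_equal(resample_ensemble(draws, c(1, 0), seed = 5), rep(1L, 2))
  # binomial oracle: count of index 1 within 3 sd of N p
  drawsN <- tibble::tibble(x = seq_len(1e4))
  w <- c(0.75, 0.25, rep(0, 1e4 - 2))
  idx <- resample_ensemble(drawsN, w, seed = 7)
  n1 <- sum(idx == 1L)
  expect_lt(abs(n1 - 7500), 3 * sqrt(1e4 * 0.75 * 0.25))
  expect_identical(idx, resample_ensemble(drawsN, w, seed = 7))
})

test_that("weighted and resampled means agree within resampling error", {
  set.seed(31)
  n <- 1e5
  draws <- tibble::tibble(x = rnorm(n))
  ll <- -(draws$x - 0.5)^2
  w <- importance_weights(ll)
  mu_w <- sum(w * draws$x)
  idx <- resample_ensemble(draws, w, seed = 8)
  mu_r <- mean(draws$x[idx])
  se <- sqrt(sum(w * (draws$x - mu_w)^2) / n)
  expect_lt(abs(mu_r - mu_w), 3 * se)
})

test_that("importance sampling reproduces a linear-Gaussian toy posterior", {
  # scalar model y = chi + eps, eps ~ N(0, s); prior chi ~ U(a, b).
  # Posterior: N(y, s^2) truncated to [a, b]; closed-form mean below.
  a <- -4; b <- 6; s <- 1; y <- 0.8
  set.seed(123)
  n <- 1e4
  chi <- runif(n, a, b)
  ll <- -(y - chi)^2 / (2 * s^2)
  w <- importance_weights(ll)
  mu_is <- sum(w * chi)
  al <- (a - y) / s; be <- (b - y) / s
  mu_exact <- y + s * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  se_is <- sqrt(sum(w^2 * (chi - mu_is)^2))
  expect_lt(abs(mu_is - mu_exact), 3 * se_is)
  # posterior sd never exceeds the prior sd
  sd_is <- sqrt(sum(w * (chi - mu_is)^2))
  expect_lt(sd_is, (b - a) / sqrt(12))
})

test_that("a one-parameter estimate contracts around the truth", {
  # priors collapsed to the truth except the cover modulus; noise-free
  # observation from the same forward model
  mesh <- ref_mesh()
  obs <- generate_observation(noise_sd = 0, seed = 1, mesh = mesh,
                              cache = ref_cache())
  pr <- vf_prior(bounds = list(
    E_bdy = c(11.8, 11.8 + 1e-9), E_lig = c(2, 2 + 1e-9),
    p_sub = c(1000, 1000 + 1e-9), rho = c(1049.75, 1049.75 + 1e-9),
    eta = c(3, 3 + 1e-9)))
  post <- vf_estimate(obs$gaw, pr,
                      vf_config(n_ens = 48, seed = 21, mesh_target = 120),
                      mesh = mesh)
  i <- match("E_cvr", post$summary$param)
  prior_mean <- 600; prior_sd <- 700 / sqrt(12)
  expect_lt(abs(post$summary$mean[i] - 600), abs(prior_mean - 600) + 120)
  expect_lt(post$summary$sd[i], prior_sd)
  expect_equal(post$failures, 0)
  expect_equal(sum(post$ensemble$weight), 1, tolerance = 1e-12)
})

test_that("estimation is deterministic and worker-count invariant", {
  mesh <- vf_triangulate(vf_geometry(), 60)
  obs <- generate_observation(noise_sd = 1, seed = 3, mesh_target = 120,
                              duration_ms = 400)
  cfg <- vf_config(n_ens = 6, seed = 9, mesh_target = 60, duration_ms = 400)
  p1 <- vf_estimate(obs$gaw, vf_prior(), cfg, mesh = mesh)
  p2 <- vf_estimate(obs$gaw, vf_prior(), cfg, mesh = mesh)
  expect_identical(p1$summary, p2$summary)
  cfg$workers <- 2
  p3 <- vf_estimate(obs$gaw, vf_prior(), cfg, mesh = mesh)
  expect_equal(p3$summary, p1$summary, tolerance = 1e-12)
  expect_equal(p3$ensemble$log_likelihood, p1$ensemble$log_likelihood)
  # tidy/glance accessors
  expect_identical(tidy(p1), p1$summary)
  expect_equal(glance(p1)$n_ens, 6)
})

test_that("inflating the error scale whitens the weights", {
  # the effective sample size is non-decreasing in sigma_e: log-likelihoods
  # scale as 1/sigma_e^2, so a larger assumed error spreads the weights
  ll1 <- -c(715, 847, 1064, 1086, 1137, 1345, 1521, 1860, 2154, 2440)
  ess <- vapply(c(1, 4, 16, 64), function(s) {
    w <- importance_weights(ll1 / s^2)
    1 / sum(w^2)
  }, numeric(1))
  expect_true(all(diff(ess) > 0))
  expect_lt(ess[1], 1.01)   # at sigma_e = 1 a single draw dominates
  expect_gt(ess[4], 2)
})

test_that("the two-sample t statistic matches its definition", {
  mk <- function(mean, sd) tibble::tibble(param = "x0", mean = mean, sd = sd,
                                          relative_uncertainty = sd / mean)
  same <- welch_t(mk(8.3, 0.03), mk(8.3, 0.03), "x0")
  expect_equal(same$t, 0)
  expect_false(same$significant)
  # printed means/sds of the two compression cases give t ~ 2.97
  tt <- welch_t(mk(8.39, 8.39 * 0.0038), mk(8.27, 8.27 * 0.0030), "x0")
  expect_equal(tt$t, 2.97, tolerance = 0.01)
  expect_true(tt$significant)
  # invariance under common rescaling
  tt2 <- welch_t(mk(83.9, 83.9 * 0.0038), mk(82.7, 82.7 * 0.0030), "x0")
  expect_equal(tt2$t, tt$t)
  expect_error(welch_t(mk(1, 0), mk(1, 0), "x0"), "undefined-t")
  expect_error(welch_t(mk(1, 1), mk(1, 1), "nope"), "not present")
})

test_that("degenerate sweep grids reduce to a single estimate", {
  mesh <- vf_triangulate(vf_geometry(), 60)
  obs <- generate_observation(noise_sd = 1, seed = 3, mesh_target = 120,
                              duration_ms = 400)
  cfg <- vf_config(n_ens = 6, seed = 9, mesh_target = 60, duration_ms = 400)
  post <- vf_estimate(obs$gaw, vf_prior(), cfg, mesh = mesh)
  sw <- sensitivity_sweep(obs$gaw, truth = reference_truth(),
                          axis = "ensemble_size", grid = 6,
                          prior = vf_prior(), config = cfg)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$avg_rel_unc,
               100 * mean(abs(post$summary$relative_uncertainty)),
               tolerance = 1e-10)
  expect_true(all(c("avg_rel_error", "max_rel_error") %in% names(sw)))
})
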