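#' Uniform prior specification for the estimated parameters
#'
#' Independent uniform priors per parameter.  Default bounds: E_bdy (9, 15) kPa; E_cvr (250, 950) Pa; E_lig (0.5, 3) kPa;
#' p_sub (400, 1800) Pa; rho (950, 1200) kg/m^3; eta (1, 7) Poise;
#' x0 (7.4, 8.4) mm.  The Poisson ratio (0.4995) and supraglottal pressure
#' (0 Pa) are fixed, not estimated.  The medial-compression offset `x0` is
#' excluded from the estimated set by default and can be switched on.
#'
#' @param estimate_x0 Include `x0` in the estimated set (default `FALSE`).
#' @param bounds Optional named list overriding `(lower, upper)` pairs, in
#'   the native units above (e.g. `list(E_bdy = c(10, 14))`).
#' @param nu,p_sup Fixed values.
#' @return A tibble of class `vf_prior` with columns `param`, `lower`,
#'   `upper`, `unit`, and attributes `fixed` and `estimate_x0`.
#' @examples
#' vf_prior()
#' @export
vf_prior <- function(estimate_x0 = FALSE, bounds = NULL,
                     nu = 0.4995, p_sup = 0) {
  def <- tibble::tribble(
    ~param,   ~lower,  ~upper,  ~unit,
    "E_bdy",  9,       15,      "kPa",
    "E_cvr",  250,     950,     "Pa",
    "E_lig",  0.5,     3,       "kPa",
    "p_sub",  400,     1800,    "Pa",
    "rho",    950,     1200,    "kg/m^3",
    "eta",    1,       7,       "Poise",
    "x0",     7.4,     8.4,     "mm")
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      i <- match(nm, def$param)
      if (is.na(i)) stop("unknown prior parameter: ", nm, call. = FALSE)
      def$lower[i] <- bounds[[nm]][1]
      def$upper[i] <- bounds[[nm]][2]
    }
  }
  if (!estimate_x0) def <- def[def$param != "x0", ]
  if (any(def$lower >= def$upper))
    stop("invalid prior: lower bound must be below upper bound", call. = FALSE)
  structure(def, class = c("vf_prior", class(def)),
            fixed = list(nu = nu, p_sup = p_sup), estimate_x0 = estimate_x0)
}

# run fn() under a temporary RNG state seeded with `seed`
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Draw independent samples from the prior
#'
#' Each coordinate is uniform on its interval; draws are reproducible by
#' seed and independent across parameters.
#'
#' @param prior A [vf_prior()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A tibble with one column per estimated parameter (native units)
#'   and `n` rows.
#' @export
sample_prior <- function(prior, n, seed = 1) {
  stopifnot(inherits(prior, "vf_prior"), n >= 1)
  with_seed(seed, function() {
    draws <- purrr::map2(prior$lower, prior$upper, ~ runif(n, .x, .y))
    tibble::as_tibble(setNames(draws, prior$param))
  })
}

# one row of prior draws (native units) -> vf_props (SI-ish internal units)
props_from_draw <- function(draw, prior) {
  fx <- attr(prior, "fixed")
  vf_props(
    rho = draw$rho, eta = draw$eta,
    E_bdy = draw$E_bdy * 1000,   # kPa -> Pa
    E_cvr = draw$E_cvr,
    E_lig = draw$E_lig * 1000,   # kPa -> Pa
    nu = fx$nu, p_sub = draw$p_sub, p_sup = fx$p_sup,
    x0 = if ("x0" %in% names(draw)) draw[["x0"]] else 8.4)
}

#' Gaussian log-likelihood of a simulated GAW
#'
#' Unnormalized log-density of the additive white-noise error model:
#' `-||A_m - A_s||^2 / (2 sigma_e^2)`.  A failed (unstable) simulation is
#' passed as `NULL` and maps to `-Inf`.
#'
#' @param meas,sim [gaw_series()] objects of equal length (after
#'   downsampling, trimming and alignment), or `NULL` for `sim` if the
#'   forward run failed.
#' @param sigma_e Measurement-error standard deviation, mm^2 (default 1).
#' @return Log-likelihood (scalar, unnormalized).
#' @export
log_likelihood <- function(meas, sim, sigma_e = 1) {
  if (is.null(sim)) return(-Inf)
  if (nrow(meas) != nrow(sim))
    stop("comparison error: series lengths differ", call. = FALSE)
  -sum((meas$area - sim$area)^2) / (2 * sigma_e^2)
}

#' Normalized importance weights from log-likelihoods
#'
#' Log-sum-exp stabilized: `w_l = exp(ll_l - max) / sum exp(ll - max)`;
#' `-Inf` maps to weight zero.
#'
#' @param ll Vector of log-likelihoods.
#' @return Normalized weights summing to one.
#' @export
importance_weights <- function(ll) {
  fin <- is.finite(ll)
  if (!any(fin))
    stop(paste("total-failure error: no finite log-likelihood",
               "(prior too wide or model unstable)"), call. = FALSE)
  m <- max(ll[fin])
  w <- ifelse(fin, exp(ll - m), 0)
  w / sum(w)
}

#' Multinomial resampling of an ensemble
#'
#' Draws `nrow(samples)` indices with replacement, with probability equal to
#' the importance weights; reproducible by seed.
#'
#' @param samples Tibble of prior draws.
#' @param weights Normalized importance weights.
#' @param seed Integer seed.
#' @return Integer vector of resampled row indices.
#' @export
resample_ensemble <- function(samples, weights, seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  n <- nrow(samples)
  with_seed(seed, function() sample.int(n, n, replace = TRUE, prob = weights))
}

#' Configuration for an estimation run
#'
#' @param n_ens Ensemble size (prior draws).
#' @param seed Master seed; all randomness (prior draws, resampling, noise)
#'   derives from it, so a run is reproducible bit for bit and independent
#'   of the worker count.
#' @param mesh_target Triangulation element-count target.
#' @param h_ms Solver time step, ms.
#' @param duration_ms Simulated duration, ms.
#' @param trim_ms Transient trim, ms.
#' @param fps Observation rate, frames/s.
#' @param sigma_e Likelihood noise scale, mm^2.
#' @param workers Parallel workers for the forward sweeps (forked; results
#'   are worker-count invariant).
#' @return A list of class `vf_config`.
#' @export
vf_config <- function(n_ens = 2000, seed = 1, mesh_target = 120, h_ms = 0.05,
                      duration_ms = 550, trim_ms = 250, fps = 2000,
                      sigma_e = 1, workers = 1) {
  structure(list(n_ens = n_ens, seed = seed, mesh_target = mesh_target,
                 h_ms = h_ms, duration_ms = duration_ms, trim_ms = trim_ms,
                 fps = fps, sigma_e = sigma_e, workers = workers),
            class = "vf_config")
}

# forward model for one draw: simulate -> observe; NULL if unstable.
# pad_ms of extra signal on both sides of the nominal comparison window
# lets phase alignment shift by up to +-pad_ms while always comparing the
# same number of samples (a variable-length overlap would bias the
# likelihood toward large shifts).
forward_gaw <- function(props, mesh, cache, config, pad_ms = 0) {
  sim <- vf_simulate(props, mesh,
                     duration_ms = config$duration_ms + 2 * pad_ms,
                     h_ms = config$h_ms, cache = cache,
                     error_on_blowup = FALSE)
  if (sim$failed) return(NULL)
  trim_transient(downsample(sim$gaw, config$fps), config$trim_ms - pad_ms)
}

# log-likelihood of a padded simulated series against the measurement:
# integer-shift alignment on the nominal window, fixed-length comparison
aligned_loglik <- function(sim_padded, meas, pad, sigma_e) {
  n <- nrow(meas)
  core <- gaw_series(meas$t, sim_padded$area[pad + seq_len(n)],
                     fps = attr(meas, "fps"))
  s <- tryCatch(alignment_shift(core, meas), error = function(e) 0L)
  s <- max(-pad, min(pad, s))
  -sum((meas$area - sim_padded$area[pad + s + seq_len(n)])^2) /
    (2 * sigma_e^2)
}

# map over indices, optionally forked; deterministic for any worker count
run_map <- function(idx, fn, workers) {
  if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, fn, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(idx, fn)
  }
}

#' Importance-sampling estimation of material properties from a GAW
#'
#' The full inverse pipeline: draw `n_ens` parameter vectors from the prior;
#' for each, run the finite-element forward model, extract the GAW at the
#' observation rate, trim the transient, phase-align to the measurement and
#' evaluate the Gaussian log-likelihood; convert to normalized importance
#' weights; resample with replacement in proportion to the weights; report
#' the resampled ensemble's mean and standard deviation per parameter.
#' Unstable prior draws receive weight zero and are reported as failures.
#'
#' @param meas A measured [gaw_series()] at `config$fps`.
#' @param prior A [vf_prior()].
#' @param config A [vf_config()].
#' @param mesh Optional `vf_mesh` (default built from `config$mesh_target`).
#' @return An object of class `vf_posterior`: `summary` (per-parameter
#'   mean/sd/relative uncertainty), `ensemble` (draws, log-likelihoods,
#'   weights, resample counts), `ess` (effective sample size), `failures`,
#'   and the config echo.  Methods: [tidy()], [glance()], `autoplot()`.
#' @export
vf_estimate <- function(meas, prior = vf_prior(), config = vf_config(),
                        mesh = NULL) {
  stopifnot(inherits(meas, "gaw_series"))
  if (is.null(mesh)) mesh <- vf_triangulate(vf_geometry(), config$mesh_target)
  cache <- assembly_cache(mesh, attr(prior, "fixed")$nu)
  draws <- sample_prior(prior, config$n_ens, seed = config$seed)
  ll <- compute_loglik_sweep(draws, meas, prior, config, mesh, cache)
  finish_estimate(draws, ll, meas, prior, config)
}

# the expensive part, shared with the sensitivity sweeps
compute_loglik_sweep <- function(draws, meas, prior, config, mesh, cache) {
  pad_ms <- 40
  pad <- as.integer(round(pad_ms * 1e-3 * config$fps))
  fn <- function(l) {
    props <- props_from_draw(draws[l, ], prior)
    sim <- tryCatch(forward_gaw(props, mesh, cache, config, pad_ms = pad_ms),
                    error = function(e) NULL)
    if (is.null(sim) || nrow(sim) < nrow(meas) + 2 * pad) return(-Inf)
    aligned_loglik(sim, meas, pad, config$sigma_e)
  }
  unlist(run_map(seq_len(nrow(draws)), fn, config$workers))
}

# weights, resampling and summaries for precomputed log-likelihoods
finish_estimate <- function(draws, ll, meas, prior, config) {
  w <- importance_weights(ll)
  rs <- resample_ensemble(draws, w, seed = config$seed + 1L)
  res <- draws[rs, ]
  summ <- purrr::map_dfr(names(draws), function(p) {
    v <- res[[p]]
    tibble::tibble(param = p, mean = mean(v), sd = stats::sd(v),
                   relative_uncertainty = stats::sd(v) / mean(v))
  })
  summ$unit <- prior$unit[match(summ$param, prior$param)]
  structure(list(
    summary = summ,
    ensemble = dplyr::mutate(draws, log_likelihood = ll, weight = w,
                             n_resampled = tabulate(rs, nbins = nrow(draws))),
    ess = 1 / sum(w^2),
    failures = sum(!is.finite(ll)),
    config = config,
    resample_idx = rs
  ), class = "vf_posterior")
}

#' @export
print.vf_posterior <- function(x, ...) {
  cat(sprintf("<vf_posterior> N = %d draws, ESS = %.1f, %d failed runs\n",
              x$config$n_ens, x$ess, x$failures))
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' @rdname vf_estimate
#' @param x A `vf_posterior`.
#' @param ... Unused.
#' @export
tidy.vf_posterior <- function(x, ...) x$summary

#' @rdname vf_estimate
#' @export
glance.vf_posterior <- function(x, ...) {
  tibble::tibble(n_ens = x$config$n_ens, ess = x$ess, failures = x$failures,
                 max_log_likelihood = max(x$ensemble$log_likelihood),
                 seed = x$config$seed)
}

#' Two-sample comparison of posterior estimates
#'
#' `t = |mean_a - mean_b| / sqrt(sd_a^2 + sd_b^2)` for one parameter across
#' two posterior summaries, with a significance flag at the 95 percent level
#' under the normal approximation (|t| > 1.96).
#'
#' @param a,b `vf_posterior` objects (or their `tidy()` summaries).
#' @param parameter Parameter name, e.g. `"x0"`.
#' @return A tibble with the two means, sds, `t` and `significant`.
#' @export
welch_t <- function(a, b, parameter) {
  sa <- if (inherits(a, "vf_posterior")) a$summary else a
  sb <- if (inherits(b, "vf_posterior")) b$summary else b
  ia <- match(parameter, sa$param); ib <- match(parameter, sb$param)
  if (is.na(ia) || is.na(ib))
    stop("parameter not present in both summaries", call. = FALSE)
  s2 <- sa$sd[ia]^2 + sb$sd[ib]^2
  if (s2 <= 0) stop("undefined-t error: zero combined sd", call. = FALSE)
  t <- abs(sa$mean[ia] - sb$mean[ib]) / sqrt(s2)
  tibble::tibble(param = parameter, mean_a = sa$mean[ia], mean_b = sb$mean[ib],
                 sd_a = sa$sd[ia], sd_b = sb$sd[ib], t = t,
                 significant = t > stats::qnorm(0.975))
}

#' Sensitivity sweeps over sampler and solver fidelity
#'
#' Recomputes the estimate along one numerical axis and reports, per grid
#' point, the average and maximum relative error against a supplied truth
#' and the average and maximum relative uncertainty across parameters.
#'
#' For `axis = "ensemble_size"` the sweep nests the ensembles: the largest
#' grid value is drawn once and smaller ensembles are its leading subsets,
#' mirroring estimation with progressively fewer draws and keeping the
#' comparison free of independent-redraw noise.  For `"timestep"` and
#' `"mesh_density"` the same prior draws (same seed) are pushed through the
#' altered forward model, so differences reflect solver fidelity only.
#'
#' @param meas Measured [gaw_series()].
#' @param truth Named list or `vf_props` with true parameter values in prior
#'   units (for the relative-error column); `NULL` skips error columns.
#' @param axis One of `"ensemble_size"`, `"timestep"`, `"mesh_density"`.
#' @param grid Numeric grid (ensemble sizes, h in ms, or element targets).
#' @param prior A [vf_prior()].
#' @param config Base [vf_config()].
#' @return A tibble of class `vf_sweep`, one row per grid point with columns
#'   `avg_rel_error`, `max_rel_error`, `avg_rel_unc`, `max_rel_unc` (percent).
#' @export
sensitivity_sweep <- function(meas, truth = NULL,
                              axis = c("ensemble_size", "timestep",
                                       "mesh_density"),
                              grid, prior = vf_prior(), config = vf_config()) {
  axis <- match.arg(axis)
  stopifnot(length(grid) >= 1)
  posteriors <- list()
  if (axis == "ensemble_size") {
    n_max <- max(grid)
    cfg <- config; cfg$n_ens <- n_max
    mesh <- vf_triangulate(vf_geometry(), cfg$mesh_target)
    cache <- assembly_cache(mesh, attr(prior, "fixed")$nu)
    draws <- sample_prior(prior, n_max, seed = cfg$seed)
    ll <- compute_loglik_sweep(draws, meas, prior, cfg, mesh, cache)
    for (n in grid) {
      cfg_n <- config; cfg_n$n_ens <- n
      posteriors[[as.character(n)]] <-
        finish_estimate(draws[seq_len(n), ], ll[seq_len(n)], meas, prior, cfg_n)
    }
  } else {
    for (g in grid) {
      cfg <- config
      if (axis == "timestep") cfg$h_ms <- g else cfg$mesh_target <- g
      posteriors[[as.character(g)]] <- vf_estimate(meas, prior, cfg)
    }
  }
  rows <- purrr::map2_dfr(posteriors, as.numeric(names(posteriors)),
                          function(p, g) {
    s <- p$summary
    out <- tibble::tibble(
      value = g,
      avg_rel_unc = 100 * mean(abs(s$relative_uncertainty)),
      max_rel_unc = 100 * max(abs(s$relative_uncertainty)),
      ess = p$ess, failures = p$failures)
    names(out)[1] <- axis
    if (!is.null(truth)) {
      tv <- truth_in_prior_units(truth, s$param)
      rel_err <- 100 * abs(s$mean - tv) / tv
      out$avg_rel_error <- mean(rel_err)
      out$max_rel_error <- max(rel_err)
    }
    out
  })
  structure(rows, class = c("vf_sweep", class(rows)), axis = axis,
            posteriors = posteriors)
}

# truth (vf_props in SI or named list in prior units) -> prior units
truth_in_prior_units <- function(truth, params) {
  if (inherits(truth, "vf_props")) {
    conv <- c(E_bdy = 1e-3, E_cvr = 1, E_lig = 1e-3, p_sub = 1, rho = 1,
              eta = 1, x0 = 1)
    vapply(params, function(p) truth[[p]] * conv[[p]], numeric(1))
  } else {
    vapply(params, function(p) truth[[p]], numeric(1))
  }
}
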