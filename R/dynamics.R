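#' Static medial-compression pre-stress solve
#'
#' Solves the zero-velocity equilibrium `K theta0 = f_c` under the constraint
#' that no node's x-position exceed the compression offset `x0` (mm).  The
#' constrained equilibrium is found by active-set iteration on the contact
#' complementarity conditions: violating nodes are pinned at `x0`, the
#' remaining dofs relax elastically, and pinned nodes whose reaction turns
#' tensile are released.  `x0 = midline_x` (no compression) yields the zero
#' state.
#'
#' @param sys A constrained `vf_system` (see [vf_constrain()]).
#' @param x0 Compression offset, mm, in `[0, midline_x]`.
#' @return List with `theta0` (reduced displacement vector, m), stored elastic
#'   `energy` (J per metre depth) and the number of pinned nodes `n_active`.
#' @export
vf_prestress <- function(sys, x0) {
  stopifnot(inherits(sys, "vf_system"), isTRUE(sys$constrained))
  mid <- sys$mesh$geom$midline_x %||% max(sys$mesh$nodes[, 1])
  if (x0 < 0 || x0 > mid + 1e-9)
    stop("x0 must lie in [0, midline_x] (mm)", call. = FALSE)
  cn <- contact_candidates(sys)
  res <- prestress_cpp(as.matrix(sys$K), cn$dof0, cn$X, x0)
  if (!isTRUE(res$converged))
    stop("prestress error: active-set iteration did not converge", call. = FALSE)
  res$theta0 <- drop(res$theta0)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# x-dofs (0-based, reduced numbering) and rest x-positions of all free nodes
contact_candidates <- function(sys) {
  free_nodes <- which(!is.na(sys$dof_of_node[, 1]))
  list(dof0 = as.integer(sys$dof_of_node[free_nodes, 1] - 1L),
       X = sys$mesh$nodes[free_nodes, 1])
}

surface_dofs <- function(sys) {
  chain <- sys$mesh$free_surface
  xd <- sys$dof_of_node[chain, 1]
  zd <- sys$dof_of_node[chain, 2]
  if (anyNA(xd) || anyNA(zd))
    stop("free-surface chain contains fixed nodes", call. = FALSE)
  list(x_dof0 = as.integer(xd - 1L), z_dof0 = as.integer(zd - 1L),
       X = sys$mesh$nodes[chain, 1], Z = sys$mesh$nodes[chain, 2])
}

#' One implicit-Newmark step (reference implementation)
#'
#' Advances `M theta'' + D theta' + K theta = F` by one step of the
#' average-acceleration Newmark scheme in three-term form:
#' `(M/h^2 + D/2h + K/4) theta_next = F + (2M/h^2 - K/2) theta +
#'  (-M/h^2 + D/2h - K/4) theta_prev`.
#' This mirrors the compiled integrator step exactly and exists for testing
#' and single-step experimentation.
#'
#' @param M,D,K Dense system matrices (SI units).
#' @param theta,theta_prev Current and previous displacement vectors.
#' @param F External force vector.
#' @param h Time step, s.
#' @return The next displacement vector.
#' @export
vf_step <- function(M, D, K, theta, theta_prev, F, h) {
  A <- M / h^2 + D / (2 * h) + K / 4
  b <- F + (2 * M / h^2 - K / 2) %*% theta +
    (-M / h^2 + D / (2 * h) - K / 4) %*% theta_prev
  drop(solve(A, b))
}

#' Simulate vocal-fold self-oscillation
#'
#' Full forward model: assemble, constrain, pre-stress at `props$x0`, then
#' time-integrate with Bernoulli surface loading and midline contact.  The
#' solver rate is `1/h` (h = 0.05 ms gives 20,000 samples/s).
#'
#' @param props A [vf_props()].
#' @param mesh A `vf_mesh` (default: 205-element default geometry).
#' @param duration_ms Simulated duration, ms; the output has
#'   `round(duration_ms / h_ms)` uniform samples starting at t = 0.
#' @param h_ms Time step, ms (default 0.05).
#' @param cache Optional [assembly cache][vf_assemble()] for ensemble reuse.
#' @param store_trajectories Keep full node trajectories and force vectors
#'   (memory-heavy; off by default).
#' @param contact Enable midline collision (on by default).
#' @param a_floor Contact floor for the Bernoulli areas, mm^2.
#' @param rho_air Air density, kg/m^3.
#' @param error_on_blowup If `TRUE` (default) an unstable integration raises
#'   an error naming the failing step; if `FALSE` a result with
#'   `failed = TRUE` is returned (used by the sampler, whose wide priors
#'   include unstable corners).
#' @param separation_mode `"closed_phase"` (default): the separation law
#'   applies while there is flow; during full closure the profile switches to
#'   stagnation pressure below the contact region and supraglottal pressure
#'   at and above it (the Bernoulli law is undefined without flow, and its
#'   naive continuation seals the glottis permanently).  `"verbatim"` applies
#'   the printed branch rule to the floored areas unconditionally.
#' @param follower_loads If `TRUE`, pressures act on the deformed surface
#'   edges; default `FALSE` integrates tractions over the reference surface,
#'   the consistent small-strain treatment (a follower load on a very soft
#'   cover feeds back through the stretched edge length and can balloon).
#' @return Object of class `vf_simulation`: `gaw` ([gaw_series()] at solver
#'   rate), `a_min`, `q` (mL/s), `contact_pressure` (stations x samples, Pa),
#'   `times` (s), the inputs, and optionally trajectories.
#' @export
vf_simulate <- function(props, mesh = vf_triangulate(vf_geometry(), 205),
                        duration_ms = 550, h_ms = 0.05, cache = NULL,
                        store_trajectories = FALSE, contact = TRUE,
                        a_floor = 1e-3, rho_air = 1.14,
                        error_on_blowup = TRUE,
                        separation_mode = c("jet", "smooth", "verbatim",
                                            "closed_phase"),
                        follower_loads = FALSE,
                        newmark_gamma = 0.5,
                        newmark_beta = (newmark_gamma + 0.5)^2 / 4) {
  separation_mode <- match.arg(separation_mode)
  stopifnot(inherits(props, "vf_props"))
  sys <- vf_constrain(vf_assemble(mesh, props, cache))
  pre <- vf_prestress(sys, props$x0)
  h <- h_ms * 1e-3
  nsamp <- round(duration_ms / h_ms)
  sd_ <- surface_dofs(sys)
  cn <- contact_candidates(sys)
  geom <- mesh$geom
  res <- integrate_fe(as.matrix(sys$M), as.matrix(sys$D), as.matrix(sys$K),
                      h, nsamp - 1L, pre$theta0, numeric(nrow(sys$K)),
                      sd_$x_dof0, sd_$z_dof0, sd_$X, sd_$Z,
                      cn$dof0, cn$X,
                      geom$midline_x, geom$length_ap,
                      props$p_sub, props$p_sup, a_floor, rho_air,
                      contact, store_trajectories,
                      switch(separation_mode, verbatim = 0L,
                             closed_phase = 1L, jet = 2L, smooth = 3L),
                      follower_loads, newmark_beta, newmark_gamma)
  if (isTRUE(res$failed) && error_on_blowup)
    stop(sprintf(paste0("integration-blowup error at step %d ",
                        "(E_bdy=%.3g, E_cvr=%.3g, E_lig=%.3g, p_sub=%.3g, ",
                        "rho=%.3g, eta=%.3g, x0=%.3g)"),
                 res$fail_step, props$E_bdy, props$E_cvr, props$E_lig,
                 props$p_sub, props$rho, props$eta, props$x0),
         call. = FALSE)
  fps <- 1 / h
  times <- (seq_len(nsamp) - 1) * h
  trib <- tributary_lengths(mesh)
  out <- list(
    gaw = gaw_series(times, res$gaw, fps = fps, meta = "simulated"),
    a_min = drop(res$a_min), q = drop(res$q),
    contact_pressure = res$contact_force / (trib * 1e-3),  # Pa
    contact_force = res$contact_force,                     # N per m depth
    times = times, h_ms = h_ms, fps = fps,
    props = props, mesh = mesh, prestress = pre,
    failed = isTRUE(res$failed), fail_step = res$fail_step
  )
  if (store_trajectories) {
    out$trajectories <- res$trajectories
    out$forces <- res$forces
    out$system <- sys
  }
  structure(out, class = "vf_simulation")
}

#' @export
print.vf_simulation <- function(x, ...) {
  cat("<vf_simulation>\n")
  cat(sprintf("  %d samples at %g fps (h = %g ms)%s\n", length(x$times),
              x$fps, x$h_ms, if (x$failed) " [FAILED: unstable]" else ""))
  cat(sprintf("  GAW range %.3f..%.3f mm^2\n", min(x$gaw$area), max(x$gaw$area)))
  invisible(x)
}

# tributary free-surface edge length per chain station, mm
tributary_lengths <- function(mesh) {
  chain <- mesh$free_surface
  xy <- mesh$nodes[chain, , drop = FALSE]
  el <- sqrt(rowSums(diff(xy)^2))
  trib <- numeric(length(chain))
  trib[1] <- el[1] / 2
  trib[length(chain)] <- el[length(el)] / 2
  if (length(chain) > 2)
    trib[2:(length(chain) - 1)] <- (el[-length(el)] + el[-1]) / 2
  trib
}

#' Sustained-oscillation check
#'
#' A simulation sustains oscillation if the glottal-area peak-to-peak
#' amplitude over the final 100 ms is at least half of that over the
#' preceding 100 ms, and non-zero.
#'
#' @param sim A `vf_simulation`.
#' @param window_ms Comparison window length, ms (default 100).
#' @return Logical.
#' @export
sustained_oscillation <- function(sim, window_ms = 100) {
  t_end <- max(sim$times)
  w <- window_ms * 1e-3
  a_last <- sim$gaw$area[sim$times > t_end - w]
  a_prev <- sim$gaw$area[sim$times > t_end - 2 * w & sim$times <= t_end - w]
  pp_last <- diff(range(a_last))
  pp_prev <- diff(range(a_prev))
  pp_last > 0 && pp_last >= 0.5 * pp_prev
}

#' Contact-pressure statistics per oscillation cycle
#'
#' Splits the analysis window into cycles of the glottal area waveform and
#' reports, per cycle, the maximum and the mean contact pressure over all
#' in-contact station-samples, then averages across cycles.
#'
#' @param sim A `vf_simulation`.
#' @param from_ms Discard samples before this time (transient), default 250.
#' @return A tibble with `mean_cp` and `max_cp` in Pa (0 if no contact).
#' @export
contact_stats <- function(sim, from_ms = 250) {
  stopifnot(inherits(sim, "vf_simulation"))
  keep <- sim$times >= from_ms * 1e-3
  cp <- sim$contact_pressure[, keep, drop = FALSE]
  area <- sim$gaw$area[keep]
  cyc <- tryCatch(cycle_bounds(area), error = function(e) NULL)
  if (is.null(cyc) || nrow(cyc) == 0) {
    any_c <- any(cp > 0)
    return(tibble::tibble(
      mean_cp = if (any_c) mean(cp[cp > 0]) else 0,
      max_cp = if (any_c) max(cp) else 0))
  }
  per <- purrr::map_dfr(seq_len(nrow(cyc)), function(i) {
    blk <- cp[, cyc$start[i]:cyc$end[i], drop = FALSE]
    v <- blk[blk > 0]
    tibble::tibble(mean_cp = if (length(v)) mean(v) else 0,
                   max_cp = if (length(v)) max(v) else 0)
  })
  dplyr::summarise(per, mean_cp = mean(.data$mean_cp),
                   max_cp = mean(.data$max_cp))
}

#' Discrete energy of a stored trajectory
#'
#' `E_n = 1/2 v' M v + 1/2 theta' K theta` with centred-difference velocity;
#' used for conservation and decay diagnostics.
#'
#' @param sim A `vf_simulation` run with `store_trajectories = TRUE`.
#' @return Numeric vector (J per metre depth), one value per interior sample.
#' @export
trajectory_energy <- function(sim) {
  if (is.null(sim$trajectories))
    stop("run vf_simulate(store_trajectories = TRUE)", call. = FALSE)
  th <- sim$trajectories
  h <- sim$h_ms * 1e-3
  M <- as.matrix(sim$system$M); K <- as.matrix(sim$system$K)
  n <- ncol(th)
  vapply(2:(n - 1), function(i) {
    v <- (th[, i + 1] - th[, i - 1]) / (2 * h)
    0.5 * sum(v * (M %*% v)) + 0.5 * sum(th[, i] * (K %*% th[, i]))
  }, numeric(1))
}
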