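#' Reference ground-truth material properties
#'
#' The silicone-fold manufacturing values: E_bdy = 11.8 kPa, E_cvr = 600 Pa,
#' E_lig = 2 kPa, p_sub = 1000 Pa, rho = 1049.75 kg/m^3, nu = 0.4995,
#' p_sup = 0, x0 = 8.4 mm (no compression).  No ground-truth viscosity is
#' available for the silicone; eta = 3 Poise is used, the value the
#' estimates consistently recover.
#'
#' @return A [vf_props()].
#' @export
reference_truth <- function() {
  vf_props(rho = 1049.75, eta = 3, E_bdy = 11800, E_cvr = 600, E_lig = 2000,
           nu = 0.4995, p_sub = 1000, p_sup = 0, x0 = 8.4)
}

#' Generate a synthetic "measured" GAW with known ground truth
#'
#' Runs the forward model at the true properties, extracts the GAW at the
#' solver rate, decimates to the camera rate, trims the start-up transient,
#' then adds i.i.d. Gaussian noise to every area sample (the additive
#' unbiased error model) and floors negative areas at zero.  Noise is added
#' after downsampling: measurement noise lives at the camera rate.
#'
#' The generator refuses configurations that do not sustain oscillation
#' (peak-to-peak amplitude in the final fifth of the waveform below half of
#' that in the preceding fifth, or no opening at all), since a silent
#' waveform carries no information about the parameters.
#'
#' @param truth True [vf_props()] (default [reference_truth()]).
#' @param noise_sd Noise standard deviation, mm^2 (default 1).
#' @param fps Observation rate, frames/s (default 2000).
#' @param duration_ms Simulated duration, ms (default 550).
#' @param trim_ms Transient trim, ms (default 250; the returned series is
#'   `duration_ms - trim_ms` long, 300 ms by default).
#' @param seed Integer seed for the noise.
#' @param mesh_target Element-count target (default 205, the full-scale
#'   finite-element representation of the folds).
#' @param h_ms Solver step, ms (default 0.05).
#' @param mesh Optional prebuilt mesh (overrides `mesh_target`).
#' @param cache Optional assembly cache.
#' @return A list with `gaw` (the noisy [gaw_series()], meta "measured"),
#'   `clean` (the noise-free series), and `truth` (a record of all inputs
#'   plus the realized noise-to-peak ratio).
#' @export
generate_observation <- function(truth = reference_truth(), noise_sd = 1,
                                 fps = 2000, duration_ms = 550, trim_ms = 250,
                                 seed = 1, mesh_target = 205, h_ms = 0.05,
                                 mesh = NULL, cache = NULL) {
  stopifnot(noise_sd >= 0, duration_ms - trim_ms >= 100)
  if (is.null(mesh)) mesh <- vf_triangulate(vf_geometry(), mesh_target)
  sim <- vf_simulate(truth, mesh, duration_ms = duration_ms, h_ms = h_ms,
                     cache = cache)
  clean <- trim_transient(downsample(sim$gaw, fps), trim_ms)
  if (!sustained_oscillation(sim))
    stop("generation error: no sustained oscillation at these properties",
         call. = FALSE)
  a <- clean$area
  n <- length(a)
  noisy <- with_seed(seed, function() pmax(a + rnorm(n, 0, noise_sd), 0))
  gaw <- gaw_series(clean$t, noisy, fps = fps, meta = "measured")
  list(
    gaw = gaw,
    clean = clean,
    truth = list(props = truth, noise_sd = noise_sd, fps = fps,
                 duration_ms = duration_ms, trim_ms = trim_ms, seed = seed,
                 mesh_target = mesh_target, h_ms = h_ms,
                 noise_to_peak = noise_sd / max(a))
  )
}
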