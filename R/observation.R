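#' Glottal area waveform series
#'
#' A uniformly sampled glottal area time series: a tibble with columns `t`
#' (seconds) and `area` (mm^2), plus attributes `fps` (frames per second),
#' `meta` (provenance, `"measured"` or `"simulated"`) and, for measured
#' series, the pixel calibration (`pixels_per_mm`).
#'
#' @param t Sample times, s (uniform).
#' @param area Areas, mm^2 (non-negative).
#' @param fps Sampling rate, frames/s.
#' @param meta Provenance string.
#' @param pixels_per_mm Optional calibration for measured series.
#' @return A tibble of class `gaw_series`.
#' @export
gaw_series <- function(t, area, fps, meta = "simulated", pixels_per_mm = NULL) {
  if (length(t) != length(area)) stop("t and area lengths differ", call. = FALSE)
  if (any(area < -1e-12)) stop("areas must be non-negative", call. = FALSE)
  if (length(t) > 1 && max(abs(diff(t) - 1 / fps)) > 1e-9)
    stop("non-uniform sampling: max |dt - 1/fps| exceeds 1e-9 s", call. = FALSE)
  out <- tibble::tibble(t = as.numeric(t), area = pmax(as.numeric(area), 0))
  attr(out, "fps") <- fps
  attr(out, "meta") <- meta
  attr(out, "pixels_per_mm") <- pixels_per_mm
  class(out) <- c("gaw_series", class(out))
  out
}

#' @export
print.gaw_series <- function(x, ...) {
  cat(sprintf("<gaw_series> %d samples at %g fps (%s), %.1f ms\n",
              nrow(x), attr(x, "fps"), attr(x, "meta"),
              1e3 * (max(x$t) - min(x$t))))
  NextMethod()
}

#' Extract the glottal area waveform from a simulation
#'
#' The glottal half-width at each sample is `midline_x` minus the largest
#' medial position over the free-surface nodes, floored at zero; the glottal
#' width is twice that, and the area is `l_gl` times the width.
#'
#' For `vf_simulate()` results the waveform is already computed in the
#' integration loop; this accessor recomputes it from stored trajectories
#' when available (and is tested against the loop's output).
#'
#' @param sim A `vf_simulation`.
#' @return A [gaw_series()] at the solver rate.
#' @export
compute_gaw <- function(sim) {
  stopifnot(inherits(sim, "vf_simulation"))
  if (is.null(sim$trajectories)) return(sim$gaw)
  sys <- sim$system
  chain <- sim$mesh$free_surface
  xd <- sys$dof_of_node[chain, 1]
  X <- sim$mesh$nodes[chain, 1]
  mid <- sim$mesh$geom$midline_x
  area <- apply(sim$trajectories, 2, function(th) {
    w <- mid - max(X + 1e3 * th[xd])
    2 * max(w, 0) * sim$mesh$geom$length_ap
  })
  gaw_series(sim$times, area, fps = sim$fps, meta = "simulated")
}

#' Physical area of one camera pixel
#'
#' @param resolution Spatial resolution, pixels/mm.
#' @return Area per pixel, mm^2: `(1/resolution)^2`.
#' @examples
#' pixel_area(24.4)  # 1.680e-3 mm^2
#' @export
pixel_area <- function(resolution) {
  if (any(resolution <= 0)) stop("resolution must be positive", call. = FALSE)
  (1 / resolution)^2
}

#' Downsample a GAW by integer decimation
#'
#' Keeps every k-th sample, `k = fps / target_fps`, which must be an integer
#' (e.g. 20,000 -> 2,000 fps keeps every 10th sample).  No interpolation or
#' anti-alias filtering is applied; the source is a smooth simulated signal.
#'
#' @param gaw A [gaw_series()].
#' @param target_fps Target rate, frames/s.
#' @return Decimated `gaw_series`.
#' @export
downsample <- function(gaw, target_fps) {
  fps <- attr(gaw, "fps")
  k <- fps / target_fps
  if (abs(k - round(k)) > 1e-9)
    stop("resampling error: fps must be an integer multiple of target_fps",
         call. = FALSE)
  k <- as.integer(round(k))
  idx <- seq(1, nrow(gaw), by = k)
  gaw_series(gaw$t[idx], gaw$area[idx], fps = target_fps,
             meta = attr(gaw, "meta"), pixels_per_mm = attr(gaw, "pixels_per_mm"))
}

#' Trim the initial transient of a GAW
#'
#' Removes all samples with `t < trim_ms` and resets the time origin to zero.
#'
#' @param gaw A [gaw_series()].
#' @param trim_ms Transient length to discard, ms (default 250).
#' @return Trimmed `gaw_series`.
#' @export
trim_transient <- function(gaw, trim_ms = 250) {
  keep <- gaw$t >= trim_ms * 1e-3 - 1e-12
  if (!any(keep))
    stop("window error: trim leaves no samples", call. = FALSE)
  gaw_series(gaw$t[keep] - gaw$t[keep][1], gaw$area[keep],
             fps = attr(gaw, "fps"), meta = attr(gaw, "meta"),
             pixels_per_mm = attr(gaw, "pixels_per_mm"))
}

# cycle boundaries via upward crossings of eps = 1% of max area.
# Returns a tibble start/end (sample indices), plus open/close info.
cycle_bounds <- function(area, eps_frac = 0.01) {
  eps <- eps_frac * max(area)
  if (max(area) <= 0) stop("metrics error: empty waveform", call. = FALSE)
  open <- area > eps
  up <- which(!open[-length(open)] & open[-1]) + 1L
  if (length(up) < 2) stop("metrics error: no complete cycle", call. = FALSE)
  tibble::tibble(start = up[-length(up)], end = up[-1] - 1L)
}

#' Waveform metrics of a GAW
#'
#' Cycles are delimited by upward crossings of a threshold at 1 percent of
#' the maximum area.  Per cycle: the open quotient is open time over period;
#' the speed quotient is opening time over closing time, with the cycle peak
#' splitting the open phase; f0 is the reciprocal of the mean period.
#' Per-cycle values are averaged.
#'
#' @param gaw A [gaw_series()] containing at least 3 cycles.
#' @return A tibble with `f0` (Hz), `max_area` (mm^2), `open_quotient`,
#'   `speed_quotient` and `n_cycles`.
#' @export
gaw_metrics <- function(gaw) {
  area <- gaw$area
  fps <- attr(gaw, "fps")
  eps <- 0.01 * max(area)
  cyc <- cycle_bounds(area)
  if (nrow(cyc) < 2) stop("metrics error: need >= 3 cycles", call. = FALSE)
  per <- purrr::map_dfr(seq_len(nrow(cyc)), function(i) {
    seg <- area[cyc$start[i]:cyc$end[i]]
    period <- length(seg) / fps
    open_idx <- which(seg > eps)
    open_len <- if (length(open_idx)) max(open_idx) else 0L
    pk <- which.max(seg)
    opening <- pk - 1L
    closing <- open_len - pk
    tibble::tibble(period = period,
                   oq = open_len / length(seg),
                   sq = if (closing > 0) opening / closing else NA_real_,
                   peak = max(seg))
  })
  tibble::tibble(
    f0 = 1 / mean(per$period),
    max_area = mean(per$peak),
    open_quotient = mean(per$oq),
    speed_quotient = mean(per$sq, na.rm = TRUE),
    n_cycles = nrow(per))
}

# integer shift (in samples) maximizing the centred cross-correlation of the
# first-two-cycle windows; positive shift means sim lags meas by that many
# samples (sim must be advanced).
alignment_shift <- function(sim, meas) {
  w_len <- function(g) {
    # offset-robust cycle detection for the correlation window
    cyc <- cycle_bounds(g$area - min(g$area))
    cyc$end[min(2L, nrow(cyc))]
  }
  n_win <- min(w_len(sim), w_len(meas))
  a <- sim$area[seq_len(n_win)] - mean(sim$area[seq_len(n_win)])
  b <- meas$area[seq_len(n_win)] - mean(meas$area[seq_len(n_win)])
  max_lag <- n_win - 1L
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(a[seq_len(n_win - k) + k] * b[seq_len(n_win - k)])
    else sum(a[seq_len(n_win + k)] * b[seq_len(n_win + k) - k])
  }, numeric(1))
  lags[which.max(cc)]
}

#' Phase-align a simulated GAW to a measured one
#'
#' Cross-correlates the first two cycles of both signals (mean-removed) and
#' applies the maximizing integer-sample shift to the simulated series; the
#' overlap is cropped to the common length.  If fewer than two cycles can be
#' detected in either signal, the shift falls back to zero with a warning and
#' the result carries `attr(, "alignment_failed") = TRUE`.
#'
#' @param sim,meas [gaw_series()] objects at the same fps.
#' @return The shifted and cropped simulated series, with `attr(, "shift")`.
#' @export
phase_align <- function(sim, meas) {
  if (abs(attr(sim, "fps") - attr(meas, "fps")) > 1e-9)
    stop("alignment error: series must share a sampling rate", call. = FALSE)
  shift <- tryCatch(alignment_shift(sim, meas), error = function(e) NA_integer_)
  failed <- is.na(shift)
  if (failed) {
    warning("alignment error: fewer than two cycles detected; using zero shift")
    shift <- 0L
  }
  n <- nrow(sim)
  idx <- if (shift >= 0) (1L + shift):n else 1L:(n + shift)
  out <- gaw_series((seq_along(idx) - 1) / attr(sim, "fps"), sim$area[idx],
                    fps = attr(sim, "fps"), meta = attr(sim, "meta"))
  attr(out, "shift") <- as.integer(shift)
  # for a negative shift the aligned simulated series corresponds to the
  # measured series starting this many samples in
  attr(out, "meas_offset") <- max(0L, -as.integer(shift))
  attr(out, "alignment_failed") <- failed
  out
}

#' Read / write a GAW as two-column CSV
#'
#' Plain CSV with columns `time_s, area_mm2` and comment header lines
#' (`# fps: `, `# meta: `, `# pixels_per_mm: `) carrying the sampling rate
#' and calibration.  Round-trips losslessly to 12 significant digits.  A
#' missing fps header is inferred from the median time step with a warning;
#' non-uniform timestamps are a parse error.
#'
#' @param gaw A [gaw_series()].
#' @param path File path.
#' @return `read_gaw_csv` returns a `gaw_series`; `write_gaw_csv` returns
#'   `path` invisibly.
#' @export
write_gaw_csv <- function(gaw, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps: %.12g", attr(gaw, "fps")), con)
  writeLines(sprintf("# meta: %s", attr(gaw, "meta")), con)
  if (!is.null(attr(gaw, "pixels_per_mm")))
    writeLines(sprintf("# pixels_per_mm: %.12g", attr(gaw, "pixels_per_mm")), con)
  writeLines("time_s,area_mm2", con)
  writeLines(sprintf("%.15g,%.15g", gaw$t, gaw$area), con)
  invisible(path)
}

#' @rdname write_gaw_csv
#' @export
read_gaw_csv <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#")]
  body <- body[nzchar(trimws(body))]
  if (!identical(trimws(body[1]), "time_s,area_mm2"))
    stop("parse error: expected 'time_s,area_mm2' header", call. = FALSE)
  fields <- strsplit(body[-1], ",", fixed = TRUE)
  if (any(lengths(fields) != 2))
    stop("parse error: ragged rows", call. = FALSE)
  tv <- as.numeric(vapply(fields, `[`, "", 1))
  av <- as.numeric(vapply(fields, `[`, "", 2))
  if (anyNA(tv) || anyNA(av)) stop("parse error: non-numeric values", call. = FALSE)
  if (any(diff(tv) <= 0)) stop("parse error: non-monotone time", call. = FALSE)
  get_hdr <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(sprintf("^# %s:\\s*", key), "", m[1])) else NULL
  }
  fps <- get_hdr("fps")
  if (is.null(fps)) {
    fps <- 1 / stats::median(diff(tv))
    warning("missing fps header; inferred from median time step")
  }
  if (max(abs(diff(tv) - 1 / fps)) > 1e-9)
    stop("parse error: non-uniform timestamps", call. = FALSE)
  meta_m <- grep("^# meta:", hdr, value = TRUE)
  meta <- if (length(meta_m)) trimws(sub("^# meta:", "", meta_m[1])) else "measured"
  gaw_series(tv, av, fps = fps, meta = meta, pixels_per_mm = get_hdr("pixels_per_mm"))
}
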