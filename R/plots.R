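#' Plot a glottal area waveform
#'
#' @param object A [gaw_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaw_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t * 1e3, y = .data$area)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = expression(area ~ (mm^2)),
                  title = sprintf("GAW (%s, %g fps)", attr(object, "meta"),
                                  attr(object, "fps"))) +
    ggplot2::theme_minimal()
}

#' Plot marginal posteriors of an estimate
#'
#' Histograms of the resampled ensemble per parameter, with the posterior
#' mean marked.
#'
#' @param object A `vf_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vf_posterior <- function(object, ...) {
  res <- object$ensemble[object$resample_idx,
                         setdiff(names(object$ensemble),
                                 c("log_likelihood", "weight", "n_resampled"))]
  long <- tidyr_pivot(res)
  means <- object$summary
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = NULL, y = "resampled count") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  purrr::map_dfr(names(df), function(p)
    tibble::tibble(param = p, value = df[[p]]))
}

#' Plot a sensitivity sweep
#'
#' @param object A `vf_sweep` from [sensitivity_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vf_sweep <- function(object, ...) {
  axis <- attr(object, "axis")
  df <- tibble::as_tibble(object)
  long <- purrr::map_dfr(intersect(c("avg_rel_unc", "avg_rel_error"),
                                   names(df)), function(m)
    tibble::tibble(x = df[[axis]], metric = m, value = df[[m]]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = axis, y = "percent") +
    ggplot2::theme_minimal()
}

#' Plot a triangulated vocal-fold mesh
#'
#' @param mesh A `vf_mesh`.
#' @return A ggplot colour-coded by layer.
#' @export
plot_mesh <- function(mesh) {
  tri <- mesh$triangles
  df <- tibble::tibble(
    id = rep(seq_len(nrow(tri)), each = 3L),
    layer = rep(as.character(mesh$layer), each = 3L),
    x = mesh$nodes[as.vector(t(tri)), 1],
    z = mesh$nodes[as.vector(t(tri)), 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   group = .data$id, fill = .data$layer)) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.15) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)") +
    ggplot2::theme_minimal()
}
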