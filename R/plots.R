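# ggplot2 visualization: scalp topographies, tuning curves, latency lags.

# azimuthal-equidistant projection of unit-sphere sensor positions
# (vertex at the origin, nose up)
.project_2d <- function(pos) {
  theta <- acos(pmin(1, pmax(-1, pos[, 3])))   # polar angle from vertex
  az <- atan2(pos[, 1], pos[, 2])              # 0 = nose (+y), + = right
  data.frame(px = theta * sin(az), py = theta * cos(az))
}

#' Plot sensor values as a scalp topography
#'
#' Flat (azimuthal-equidistant) projection of the montage with one point
#' per sensor colored by `values`; electrodes of interest can be
#' highlighted.
#'
#' @param values Numeric 128-vector (e.g. a forward topography column or
#'   per-channel amplitude).
#' @param montage An `eeg_montage`.
#' @param title Plot title.
#' @param highlight Sensor ids to outline.
#' @return A ggplot object.
#' @export
plot_topography <- function(values, montage = load_montage(), title = NULL,
                            highlight = integer(0)) {
  pos <- montage_positions(montage)
  df <- cbind(.project_2d(pos), value = values,
              sensor = montage$sensors$sensor)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py,
                                        color = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, color = "weight")
  if (length(highlight)) {
    p <- p + ggplot2::geom_point(
      data = df[df$sensor %in% highlight, ],
      shape = 1, size = 5, color = "red"
    )
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.eeg_montage <- function(object, ...) {
  pos <- montage_positions(object)
  df <- cbind(.project_2d(pos), sensor = object$sensors$sensor)
  ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sensor),
                       size = 2, vjust = -1) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rca_model <- function(object, montage = load_montage(), ...) {
  pos <- montage_positions(montage)
  proj <- .project_2d(pos)
  df <- do.call(rbind, lapply(seq_len(object$n_components), function(j) {
    cbind(proj, value = object$A[, j], component = paste0("RC", j))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py,
                                   color = .data$value)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~component) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "topography")
}

#' Plot per-component tuning curves
#'
#' Amplitude (with the neighbor-bin noise floor shaded) or phase as a
#' function of logMAR, per component.
#'
#' @param tuning Tuning tibble from [component_tuning()] (components may
#'   be row-bound).
#' @param what `"amplitude"`, `"phase"` or `"snr"`.
#' @return A ggplot object.
#' @export
plot_tuning <- function(tuning, what = c("amplitude", "phase", "snr")) {
  what <- match.arg(what)
  y <- switch(what, amplitude = "amplitude", phase = "phase_deg",
              snr = "snr_db")
  p <- ggplot2::ggplot(tuning, ggplot2::aes(.data$logmar, .data[[y]],
                                            color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "logMAR",
                  y = switch(what, amplitude = "amplitude (uV ASD)",
                             phase = "phase (deg)", snr = "SNR (dB)"))
  if (what == "amplitude") {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 0, ymax = .data$noise_amp,
                   group = .data$component),
      alpha = 0.15, color = NA
    )
  }
  p
}

#' Plot per-level latency lags
#'
#' @param latency Tibble from [component_latency_lag()] (optionally with a
#'   `task` column for faceting).
#' @return A ggplot object.
#' @export
plot_latency <- function(latency) {
  p <- ggplot2::ggplot(latency, ggplot2::aes(.data$logmar,
                                             .data$latency_ms)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "logMAR", y = "RC2 - RC1 latency (ms)")
  if ("task" %in% names(latency)) {
    p <- p + ggplot2::facet_wrap(~task)
  }
  p
}
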