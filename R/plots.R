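#' Scalp and spectrum plots
#'
#' Topographies use the montage's azimuthal-equidistant 2-D projection
#' with inverse-distance-weighted interpolation onto a disc grid -- the
#' conventional flat scalp map. Cluster results are shown as
#' channel-by-frequency heat maps of the paired-t statistic with
#' significant cluster members marked.
#'
#' @name plots
NULL

# inverse-distance-weighted interpolation of per-channel values onto a
# disc-shaped grid in the 2-D projection
.topo_grid <- function(montage, values, n_grid = 67, power = 2) {
  r_max <- max(sqrt(montage$x2d^2 + montage$y2d^2)) * 1.05
  ax <- seq(-r_max, r_max, length.out = n_grid)
  grid <- expand.grid(x = ax, y = ax)
  grid <- grid[grid$x^2 + grid$y^2 <= r_max^2, ]
  pos <- montage[match(names(values), montage$label), ]
  z <- vapply(seq_len(nrow(grid)), function(i) {
    d2 <- (pos$x2d - grid$x[i])^2 + (pos$y2d - grid$y[i])^2
    if (any(d2 < 1e-12)) return(values[which.min(d2)])
    w <- 1 / d2^(power / 2)
    sum(w * values) / sum(w)
  }, 0)
  tibble::tibble(x = grid$x, y = grid$y, value = z)
}

#' Band-power scalp topographies
#'
#' @param band_maps Tibble from [band_topography()] (optionally with a
#'   `condition` column, as produced by [run_pipeline()]).
#' @param montage The `eeg_montage` giving sensor positions.
#' @param interpolate Fill the scalp disc by inverse-distance weighting
#'   (TRUE) or show per-sensor points only.
#' @return A ggplot: one panel per band (and condition, if present).
#' @export
plot_band_topography <- function(band_maps, montage = build_montage(),
                                 interpolate = TRUE) {
  has_cond <- "condition" %in% names(band_maps)
  groups <- if (has_cond) {
    dplyr::group_split(band_maps, .data$condition, .data$band)
  } else {
    dplyr::group_split(band_maps, .data$band)
  }
  layers <- purrr::map_dfr(groups, function(g) {
    vals <- stats::setNames(g$value, g$channel)
    out <- if (interpolate) .topo_grid(montage, vals) else
      tibble::tibble(x = montage$x2d[match(names(vals), montage$label)],
                     y = montage$y2d[match(names(vals), montage$label)],
                     value = vals)
    out$band <- g$band[1]
    if (has_cond) out$condition <- g$condition[1]
    out
  })
  p <- ggplot2::ggplot(layers, ggplot2::aes(.data$x, .data$y)) +
    (if (interpolate) ggplot2::geom_raster(ggplot2::aes(fill = .data$value))
     else ggplot2::geom_point(ggplot2::aes(color = .data$value), size = 4)) +
    ggplot2::geom_point(
      data = montage, ggplot2::aes(.data$x2d, .data$y2d),
      shape = 21, size = 0.8, stroke = 0.3, inherit.aes = FALSE) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "z") +
    ggplot2::scale_color_gradient2(low = "#2166ac", mid = "white",
                                   high = "#b2182b", name = "z") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (has_cond) {
    p + ggplot2::facet_grid(condition ~ band)
  } else {
    p + ggplot2::facet_wrap(~band, nrow = 1)
  }
}

#' @export
autoplot.grand_average <- function(object, montage = build_montage(), ...) {
  plot_band_topography(band_topography(object), montage, ...)
}

#' @export
autoplot.cluster_result <- function(object, ...) {
  stat_long <- tibble::as_tibble(object$stat_map, rownames = "channel") |>
    tidyr::pivot_longer(-"channel", names_to = "freq", values_to = "t") |>
    dplyr::mutate(freq = as.numeric(.data$freq),
                  channel = factor(.data$channel,
                                   levels = rev(object$channels)))
  sig <- object$clusters[object$clusters$significant, , drop = FALSE]
  members <- if (nrow(sig) > 0) {
    purrr::map_dfr(seq_len(nrow(sig)), function(i) {
      tibble::tibble(channel = factor(sig$channel[[i]],
                                      levels = rev(object$channels)),
                     freq = sig$freq[[i]])
    })
  } else NULL
  p <- ggplot2::ggplot(stat_long,
                       ggplot2::aes(.data$freq, .data$channel,
                                    fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "paired t") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL)
  if (!is.null(members)) {
    p <- p + ggplot2::geom_point(
      data = members, ggplot2::aes(.data$freq, .data$channel),
      inherit.aes = FALSE, shape = 4, size = 1)
  }
  p
}

#' Motion vs rest spectra at selected channels
#'
#' Line plot of epoch-averaged power spectra for the two conditions of a
#' paired comparison, averaged across subjects, at the given channels.
#'
#' @param ps A `paired_spectra`.
#' @param channels Channel labels (default: all common channels, averaged).
#' @return A ggplot.
#' @export
plot_pair_spectra <- function(ps, channels = NULL) {
  if (is.null(channels)) channels <- ps$channels
  sel <- match(channels, ps$channels)
  mk <- function(lst, cond) {
    avg <- Reduce(`+`, lst) / length(lst)
    tibble::tibble(freq = ps$freqs,
                   power = colMeans(avg[sel, , drop = FALSE]),
                   condition = cond)
  }
  df <- dplyr::bind_rows(mk(ps$motion, "motion"), mk(ps$rest, "rest"))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$power,
                                   color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (uV^2/Hz)")
}
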