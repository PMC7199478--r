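#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster test result
#'
#' One row per cluster with its sign, mass, extent, peak frequency and
#' Monte-Carlo p-value.
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cluster_result <- function(x, ...) {
  dplyr::select(x$clusters, "sign", "mass", "n_points", "n_sensors",
                "peak_freq_hz", "p", "significant")
}

#' @rdname tidy.cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subjects),
    n_channels = length(x$channels),
    n_bins = length(x$freqs),
    n_perm = x$n_perm,
    exact = x$exact,
    threshold = x$threshold,
    alpha = x$alpha,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters) > 0) min(x$clusters$p) else NA_real_
  )
}

#' Tidy a grand-averaged z-spectrum
#'
#' @param x A `grand_average`.
#' @param ... Unused.
#' @return A long tibble `condition`, `channel`, `freq`, `mean_z`.
#' @export
tidy.grand_average <- function(x, ...) {
  tibble::as_tibble(x$mean_z, rownames = "channel") |>
    tidyr::pivot_longer(-"channel", names_to = "freq",
                        values_to = "mean_z") |>
    dplyr::mutate(freq = as.numeric(.data$freq),
                  condition = x$condition, .before = 1)
}
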