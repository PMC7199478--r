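#' Spectral estimation and z-normalized topographies
#'
#' Two distinct spectral paths are kept apart in the data model: plain
#' per-epoch FFT power feeds the z-normalized topographies (scale-free
#' scalp maps averaged across infants), while DPSS multitaper spectra in
#' raw uV^2/Hz feed the cluster permutation test. Both operate on 1-s
#' epochs, so the native frequency grid is 1 Hz.
#'
#' @name spectral
NULL

#' Infant frequency band definitions
#'
#' Downward-shifted relative to adult conventions: delta 1-3, theta 3-6,
#' alpha 6-9, low beta 9-13, high beta 13-20 Hz. Band membership is
#' low-inclusive / high-exclusive so that shared edges belong to the upper
#' band and the bands partition 1-20 Hz (the 20 Hz bin closes high beta).
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @export
infant_bands <- function() {
  tibble::tibble(
    band = factor(c("delta", "theta", "alpha", "low beta", "high beta"),
                  levels = c("delta", "theta", "alpha", "low beta",
                             "high beta")),
    low_hz = c(1, 3, 6, 9, 13),
    high_hz = c(3, 6, 9, 13, 20)
  )
}

.epoched_power <- function(pow, freqs, cd, channels) {
  structure(
    list(pow = pow, freqs = freqs, infant_id = cd$infant_id,
         condition = cd$condition, channels = channels),
    class = "epoched_power"
  )
}

#' @export
print.epoched_power <- function(x, ...) {
  cat(sprintf("<epoched_power> %s/%s: %d epochs x %d ch x %d bins (%g-%g Hz)\n",
              x$infant_id, x$condition, dim(x$pow)[1], dim(x$pow)[2],
              dim(x$pow)[3], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Per-epoch FFT power
#'
#' One-sided power spectral density of every epoch and retained channel,
#' rectangular window, Parseval-consistent scaling: the one-sided PSD
#' integrated over the full frequency axis equals the epoch's mean square
#' amplitude. With 1-s epochs the bin spacing is 1 Hz.
#'
#' @param cd A `condition_data` with epochs cut ([epoch_1s()]).
#' @param fmin,fmax Frequency range to retain (Hz). Defaults keep every
#'   positive-frequency bin through 20 Hz; `fmax = NULL` keeps up to
#'   Nyquist.
#' @return An `epoched_power`: `pow` is an epochs x channels x bins array
#'   in uV^2/Hz, `freqs` the bin centers, `channels` the retained labels.
#'   Zero epochs gives an empty (0-epoch) result.
#' @export
fft_power <- function(cd, fmin = 1, fmax = 20) {
  stopifnot(!is.null(cd$epochs))
  fs <- cd$fs
  n <- dim(cd$epochs)[3]
  keep_ch <- which(cd$retained)
  freqs_all <- seq(0, floor(n / 2)) * fs / n
  if (is.null(fmax)) fmax <- fs / 2
  sel <- which(freqs_all >= fmin & freqs_all <= fmax)
  n_ep <- dim(cd$epochs)[1]
  # stack (epoch, channel) columns so one FFT call covers the whole object
  x <- aperm(cd$epochs[, keep_ch, , drop = FALSE], c(3, 2, 1))
  dim(x) <- c(n, length(keep_ch) * n_ep)
  ft <- stats::mvfft(x)
  psd <- (Mod(ft[sel, , drop = FALSE])^2) * (2 / (fs * n))
  psd[freqs_all[sel] == 0, ] <- psd[freqs_all[sel] == 0, ] / 2
  if (n %% 2 == 0) {
    psd[freqs_all[sel] == fs / 2, ] <- psd[freqs_all[sel] == fs / 2, ] / 2
  }
  pow <- aperm(array(psd, dim = c(length(sel), length(keep_ch), n_ep)),
               c(3, 2, 1))
  .epoched_power(pow, freqs_all[sel], cd, cd$labels[keep_ch])
}

#' DPSS multitaper power spectral density
#'
#' Per-epoch multitaper PSD with time-bandwidth product
#' `NW = T * smoothing_hz` and `K = floor(2 NW - 1)` Slepian tapers (for
#' 1-s epochs and the default 2 Hz smoothing: NW = 2, K = 3), averaged
#' over tapers. This is the spectral estimate consumed by the cluster
#' permutation test, in raw uV^2/Hz.
#'
#' @param cd A `condition_data` with epochs cut.
#' @param smoothing_hz Half-bandwidth of spectral smoothing (Hz, default 2).
#' @param fmin,fmax Frequency range of interest (default 0.1-20 Hz; with
#'   1-s epochs the 0.1 Hz bound excludes only the DC bin).
#' @return An `epoched_power` (epochs x channels x bins, uV^2/Hz).
#' @export
multitaper_psd <- function(cd, smoothing_hz = 2, fmin = 0.1, fmax = 20) {
  stopifnot(!is.null(cd$epochs))
  fs <- cd$fs
  n <- dim(cd$epochs)[3]
  if (fmax > fs / 2) {
    stop(sprintf("fmax = %g Hz exceeds the Nyquist frequency %g Hz",
                 fmax, fs / 2), call. = FALSE)
  }
  nw <- (n / fs) * smoothing_hz
  k <- max(1L, floor(2 * nw - 1))
  tapers <- dpss_tapers(n, nw, k)
  keep_ch <- which(cd$retained)
  freqs_all <- seq(0, floor(n / 2)) * fs / n
  sel <- which(freqs_all >= fmin & freqs_all <= fmax)
  n_ep <- dim(cd$epochs)[1]
  x <- aperm(cd$epochs[, keep_ch, , drop = FALSE], c(3, 2, 1))
  dim(x) <- c(n, length(keep_ch) * n_ep)
  acc <- matrix(0, length(sel), ncol(x))
  for (j in seq_len(k)) {
    ft <- stats::mvfft(x * tapers[, j])
    psd <- (Mod(ft[sel, , drop = FALSE])^2) * (2 / fs)
    psd[freqs_all[sel] == 0, ] <- psd[freqs_all[sel] == 0, ] / 2
    if (n %% 2 == 0) {
      psd[freqs_all[sel] == fs / 2, ] <- psd[freqs_all[sel] == fs / 2, ] / 2
    }
    acc <- acc + psd
  }
  pow <- aperm(array(acc / k, dim = c(length(sel), length(keep_ch), n_ep)),
               c(3, 2, 1))
  .epoched_power(pow, freqs_all[sel], cd, cd$labels[keep_ch])
}

#' Average an epoched power object over epochs
#'
#' @param ep An `epoched_power`.
#' @return A channels x bins matrix (dimnames: channel, frequency).
#' @export
epoch_average <- function(ep) {
  out <- apply(ep$pow, c(2, 3), mean)
  dimnames(out) <- list(ep$channels, ep$freqs)
  out
}

#' Z-normalize power spectra within an infant and condition
#'
#' Standardizes each channel's epoch-averaged power, per frequency bin,
#' against the epoch-wise distribution of the channel-averaged power:
#'
#'   z(c, f) = ( mean_e pow(c, f, e) - mean_e m(f, e) ) / sd_e( m(f, e) )
#'
#' where m(f, e) is the mean over retained channels and sd is the sample
#' (n - 1) standard deviation over epochs. This makes topographies
#' dimensionless and comparable across infants; by construction the mean
#' of z over channels is exactly 0 at every bin, and z is invariant under
#' positive rescaling of the raw signal.
#'
#' An alternative normalization that divides by the standard deviation
#' pooled over all epochs and channels is available via
#' `denominator = "pooled"`.
#'
#' @param ep An `epoched_power` with at least 2 epochs.
#' @param denominator `"epoch_mean"` (default; sd over epochs of the
#'   channel mean) or `"pooled"` (sd over all epochs and channels).
#' @return A `z_spectra`: `z` is a channels x bins matrix, plus `freqs`,
#'   `channels`, `infant_id`, `condition`.
#' @export
znormalize <- function(ep, denominator = c("epoch_mean", "pooled")) {
  denominator <- match.arg(denominator)
  n_ep <- dim(ep$pow)[1]
  if (n_ep < 2) {
    stop("z-normalization needs at least 2 epochs", call. = FALSE)
  }
  chan_mean <- apply(ep$pow, c(2, 3), mean)      # mean over epochs, per c,f
  m <- apply(ep$pow, c(1, 3), mean)              # mean over channels: e x f
  center <- colMeans(m)
  s <- switch(denominator,
    epoch_mean = apply(m, 2, stats::sd),
    pooled = apply(ep$pow, 3, stats::sd)
  )
  degenerate <- which(s == 0)
  if (length(degenerate) > 0) {
    stop(sprintf(
      "z-score undefined: zero epoch variance of channel-mean power at %g Hz",
      ep$freqs[degenerate[1]]), call. = FALSE)
  }
  z <- sweep(sweep(chan_mean, 2, center), 2, s, "/")
  dimnames(z) <- list(ep$channels, ep$freqs)
  structure(
    list(z = z, freqs = ep$freqs, channels = ep$channels,
         infant_id = ep$infant_id, condition = ep$condition),
    class = "z_spectra"
  )
}

#' Grand-average z-spectra across infants
#'
#' Aligns channels by label and averages each (channel, bin) over the
#' infants that retained that channel; per-channel contributor counts are
#' recorded. All inputs must share one condition and frequency grid.
#'
#' @param zs List of `z_spectra` (one per infant).
#' @return A `grand_average`: `mean_z` (channels x bins), `n_infants`
#'   (total), `n_by_channel`, `freqs`, `channels`, `condition`.
#' @export
grand_average <- function(zs) {
  if (length(zs) == 0) stop("no infants to average", call. = FALSE)
  cond <- unique(vapply(zs, function(z) z$condition, ""))
  stopifnot(length(cond) == 1)
  freqs <- zs[[1]]$freqs
  channels <- unique(unlist(lapply(zs, function(z) z$channels)))
  acc <- matrix(0, length(channels), length(freqs),
                dimnames = list(channels, freqs))
  cnt <- matrix(0L, length(channels), length(freqs),
                dimnames = list(channels, freqs))
  for (z in zs) {
    stopifnot(isTRUE(all.equal(z$freqs, freqs)))
    acc[z$channels, ] <- acc[z$channels, ] + z$z
    cnt[z$channels, ] <- cnt[z$channels, ] + 1L
  }
  structure(
    list(mean_z = acc / cnt, n_infants = length(zs),
         n_by_channel = cnt[, 1], freqs = freqs, channels = channels,
         condition = cond),
    class = "grand_average"
  )
}

#' Band-averaged topography
#'
#' Averages grand-average z-power over the bins of each frequency band
#' (low-inclusive, high-exclusive) to produce one scalp value per channel
#' and band.
#'
#' @param ga A `grand_average`.
#' @param bands Band definition tibble (default [infant_bands()]).
#' @return A tibble `channel`, `band`, `value`.
#' @export
band_topography <- function(ga, bands = infant_bands()) {
  purrr::pmap_dfr(bands, function(band, low_hz, high_hz) {
    sel <- ga$freqs >= low_hz & ga$freqs < high_hz
    # the top band's upper edge is the last analyzed bin; close it
    if (high_hz >= max(ga$freqs)) sel <- sel | ga$freqs == high_hz
    if (!any(sel)) {
      stop(sprintf("band %s (%g-%g Hz) not covered by available bins",
                   band, low_hz, high_hz), call. = FALSE)
    }
    tibble::tibble(
      channel = ga$channels,
      band = band,
      value = unname(rowMeans(ga$mean_z[, sel, drop = FALSE]))
    )
  })
}

#' Long-format tidy export of spectra
#'
#' @param ep An `epoched_power` (epoch-averaged on export) or `z_spectra`.
#' @return A tibble `infant_id`, `condition`, `channel`, `freq`, and
#'   `power` (uV^2/Hz) or `z`.
#' @export
spectra_to_tibble <- function(ep) {
  if (inherits(ep, "z_spectra")) {
    mat <- ep$z
    value_name <- "z"
  } else {
    mat <- epoch_average(ep)
    value_name <- "power"
  }
  out <- tibble::as_tibble(mat, rownames = "channel") |>
    tidyr::pivot_longer(-"channel", names_to = "freq",
                        values_to = value_name) |>
    dplyr::mutate(freq = as.numeric(.data$freq),
                  infant_id = ep$infant_id, condition = ep$condition,
                  .before = 1)
  out[, c("infant_id", "condition", "channel", "freq", value_name)]
}
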