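#' EEG recordings and per-condition preprocessing
#'
#' A recording is a matrix-backed S3 object: `data` is channels x samples in
#' microvolts, `fs` the sampling rate in Hz (500 by default), `labels` the
#' channel names (matching the montage), and `retained` a per-channel
#' logical mask maintained by bad-channel rejection. Sample indexing is
#' 0-based with half-open `[start, stop)` intervals and floor quantization
#' of second-valued onsets/offsets; that convention is used everywhere.
#'
#' The pipeline order is fixed: reject noisy channels on the raw signal,
#' re-reference to the average of the retained channels, extract and
#' concatenate per-condition segments, excise high-amplitude windows, cut
#' 1-s epochs. Rejection must precede re-referencing because a bad channel
#' contaminates the average reference.
#'
#' @name preprocessing
NULL

#' Construct an EEG recording object
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param labels Channel names, one per row of `data`.
#' @param infant_id Subject identifier.
#' @param retained Optional logical mask of retained channels.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels, infant_id = "infant",
                          retained = rep(TRUE, nrow(data))) {
  stopifnot(is.matrix(data), nrow(data) == length(labels),
            length(retained) == nrow(data), fs > 0)
  if (!all(is.finite(data))) stop("recording contains non-finite samples",
                                  call. = FALSE)
  structure(
    list(infant_id = infant_id, data = data, fs = fs,
         labels = labels, retained = retained),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d ch x %d samples @ %g Hz (%.1f s), %d retained\n",
              x$infant_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, sum(x$retained)))
  invisible(x)
}

#' Reject noisy channels
#'
#' A channel is rejected iff its raw amplitude deviates from the rest of the
#' channels by more than `amp_threshold` microvolts for strictly more than
#' `fraction` of the samples. "The rest of the channels" is operationalized
#' as the instantaneous median of the other channels, which is robust to the
#' offending channel itself. Data are not modified; only the retained mask.
#'
#' @param rec An `eeg_recording` with at least 3 channels.
#' @param amp_threshold Deviation threshold in microvolts (default 100).
#' @param fraction Fraction of samples that must exceed the threshold for
#'   rejection (default 0.25, exceeded strictly).
#' @return The recording with an updated `retained` mask.
#' @export
reject_noisy_channels <- function(rec, amp_threshold = 100, fraction = 0.25) {
  x <- rec$data
  n_ch <- nrow(x)
  if (n_ch < 3) stop("channel rejection needs at least 3 channels",
                     call. = FALSE)
  # leave-one-out median from the two central order statistics per sample:
  # with n channels, the median of the other n-1 is the k-th or (k+1)-th
  # order statistic of all n depending on the rank of the removed value,
  # where k = floor((n-1+1)/2) for odd n-1 (general case handled for both
  # parities via the two relevant order statistics).
  sorted <- apply(x, 2, sort, method = "quick")
  m <- n_ch - 1 # size of the leave-one-out set
  exceed <- matrix(FALSE, n_ch, ncol(x))
  for (c in seq_len(n_ch)) {
    med_others <- apply_colmed_wo(sorted, x[c, ], m)
    exceed[c, ] <- abs(x[c, ] - med_others) > amp_threshold
  }
  frac_exceed <- rowMeans(exceed)
  rec$retained <- frac_exceed <= fraction
  if (sum(rec$retained) < n_ch / 2) {
    stop(sprintf("recording unusable: %d of %d channels rejected",
                 sum(!rec$retained), n_ch), call. = FALSE)
  }
  rec
}

# median of the leave-one-out set per sample, given the column-sorted data
# (all channels) and the removed channel's values. m = n_ch - 1.
apply_colmed_wo <- function(sorted, removed, m) {
  if (m %% 2 == 1) {
    # odd leave-one-out size: median is a single order statistic, the
    # ((m+1)/2)-th of the remaining. Relative to the full sorted column it
    # is sorted[k+1] when the removed value ranks <= k, else sorted[k].
    k <- (m + 1) / 2
    lo <- sorted[k, ]
    hi <- sorted[k + 1, ]
    ifelse(removed <= lo, hi, lo)
  } else {
    # even leave-one-out size: average of the (m/2)-th and (m/2+1)-th order
    # statistics of the remaining values.
    k <- m / 2
    a <- sorted[k, ]; b <- sorted[k + 1, ]; cc <- sorted[k + 2, ]
    low <- removed <= a
    high <- removed >= cc
    mid <- !low & !high
    out <- numeric(length(removed))
    out[low] <- (b[low] + cc[low]) / 2
    out[high] <- (a[high] + b[high]) / 2
    # removed value lies strictly between sorted[k] and sorted[k+2]: it is
    # sorted[k+1] itself (ties broken arbitrarily); remaining middle pair is
    # (sorted[k], sorted[k+2])
    out[mid] <- (a[mid] + cc[mid]) / 2
    out
  }
}

#' Re-reference to the average of retained channels
#'
#' Subtracts the instantaneous mean over retained channels from every
#' retained channel; rejected channels are left untouched (they are excluded
#' from all later stages). After this the retained-channel sum is zero at
#' every sample up to floating-point error.
#'
#' @param rec An `eeg_recording` (rejection already applied).
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  keep <- which(rec$retained)
  ref <- colMeans(rec$data[keep, , drop = FALSE])
  rec$data[keep, ] <- sweep(rec$data[keep, , drop = FALSE], 2, ref)
  rec
}

#' Extract and concatenate a condition's segments
#'
#' Collects the samples inside each of the condition's annotated intervals
#' (floor-quantized, half-open `[floor(onset * fs), floor(offset * fs))`)
#' and concatenates them in temporal order. An absent condition yields an
#' empty result (the infant is simply a non-contributor), not an error.
#'
#' @param rec An `eeg_recording`.
#' @param events Validated annotation tibble for this infant.
#' @param condition Condition label to extract.
#' @return An object of class `condition_data`: `infant_id`, `condition`,
#'   `segments` (tibble of onsets/offsets used), `data` (channels x samples),
#'   `fs`, `labels`, `retained`, `epochs` (NULL until [epoch_1s()]).
#' @export
extract_concatenate <- function(rec, events, condition) {
  ev <- events[events$label == condition &
                 events$infant_id == rec$infant_id, , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  n_total <- ncol(rec$data)
  idx <- integer(0)
  if (nrow(ev) > 0) {
    starts <- pmax(0L, as.integer(floor(ev$onset_s * rec$fs)))
    stops <- pmin(n_total, as.integer(floor(ev$offset_s * rec$fs)))
    pieces <- Map(function(a, b) if (b > a) seq.int(a + 1L, b) else integer(0),
                  starts, stops)
    idx <- unlist(pieces, use.names = FALSE)
  }
  structure(
    list(infant_id = rec$infant_id, condition = condition,
         segments = tibble::tibble(onset_s = ev$onset_s,
                                   offset_s = ev$offset_s),
         data = rec$data[, idx, drop = FALSE],
         fs = rec$fs, labels = rec$labels, retained = rec$retained,
         epochs = NULL),
    class = "condition_data"
  )
}

#' @export
print.condition_data <- function(x, ...) {
  cat(sprintf("<condition_data> %s/%s: %d segments, %.2f s concatenated%s\n",
              x$infant_id, x$condition, nrow(x$segments),
              ncol(x$data) / x$fs,
              if (is.null(x$epochs)) "" else
                sprintf(", %d epochs", dim(x$epochs)[1])))
  invisible(x)
}

#' Excise high-amplitude windows
#'
#' Deterministic surrogate for manual inspection of eye-blinks and large
#' amplitude excursions: consecutive 1-s windows of the concatenated stream
#' whose peak-to-peak amplitude on any retained channel exceeds the
#' threshold are removed before epoching. A trailing partial window is
#' screened with the same rule.
#'
#' @param cd A `condition_data`.
#' @param p2p_threshold Peak-to-peak threshold in microvolts (default 200,
#'   applied after average re-referencing).
#' @return The `condition_data` with offending windows removed. If nothing
#'   survives, an empty result with a warning.
#' @export
clean_amplitude <- function(cd, p2p_threshold = 200) {
  n <- ncol(cd$data)
  if (n == 0 || is.infinite(p2p_threshold)) return(cd)
  fs <- cd$fs
  keep_rows <- which(cd$retained)
  n_win <- ceiling(n / fs)
  keep_idx <- integer(0)
  n_kept <- 0L
  for (w in seq_len(n_win)) {
    a <- (w - 1L) * fs + 1L
    b <- min(w * fs, n)
    seg <- cd$data[keep_rows, a:b, drop = FALSE]
    p2p <- apply(seg, 1, function(v) max(v) - min(v))
    if (all(p2p <= p2p_threshold)) {
      keep_idx <- c(keep_idx, a:b)
      n_kept <- n_kept + 1L
    }
  }
  if (n_kept == 0L) {
    warning(sprintf("all %d windows of %s/%s exceeded %g uV peak-to-peak",
                    n_win, cd$infant_id, cd$condition, p2p_threshold))
  }
  cd$data <- cd$data[, keep_idx, drop = FALSE]
  cd
}

#' Cut non-overlapping 1-s epochs
#'
#' Divides the cleaned concatenated stream into `floor(n_samples / fs)`
#' epochs of exactly `fs` samples; the trailing remainder is dropped. By
#' default epochs may span concatenation boundaries (the concatenated
#' stream is treated as continuous); `span_boundaries = FALSE` restarts
#' epoching at each segment boundary instead, for sensitivity analysis.
#'
#' @param cd A `condition_data` after [clean_amplitude()].
#' @param span_boundaries Allow epochs to straddle segment joins
#'   (default TRUE).
#' @return The `condition_data` with `epochs` set to an
#'   epochs x channels x fs array.
#' @export
epoch_1s <- function(cd, span_boundaries = TRUE) {
  fs <- cd$fs
  if (span_boundaries) {
    n_ep <- floor(ncol(cd$data) / fs)
    use <- seq_len(n_ep * fs)
    dat <- cd$data[, use, drop = FALSE]
  } else {
    seg_len <- as.integer(floor(cd$segments$offset_s * fs) -
                            floor(cd$segments$onset_s * fs))
    ends <- cumsum(seg_len)
    starts <- c(0L, utils::head(ends, -1L))
    use <- unlist(Map(function(a, b) {
      k <- floor((b - a) / fs)
      if (k > 0) seq.int(a + 1L, a + k * fs) else integer(0)
    }, starts, pmin(ends, ncol(cd$data))), use.names = FALSE)
    dat <- cd$data[, use, drop = FALSE]
    n_ep <- ncol(dat) / fs
  }
  ep <- array(0, dim = c(n_ep, nrow(dat), fs))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- dat[, ((e - 1L) * fs + 1L):(e * fs)]
  }
  cd$epochs <- ep
  cd
}

#' Write / read a recording as a plain-text table
#'
#' Tab-separated matrix with a `# fs=<Hz> infant=<id>` header line and one
#' row per channel (label then samples). Intended for small fixtures and
#' interchange, not long recordings.
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @return `read_recording` returns an `eeg_recording`;
#'   `write_recording` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g infant=%s", rec$fs, rec$infant_id), con)
  utils::write.table(
    data.frame(label = rec$labels, rec$data, check.names = FALSE),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs=([0-9.]+).*", "\\1", header))
  infant_id <- sub(".*infant=(\\S+).*", "\\1", header)
  tab <- utils::read.table(path, sep = "\t", skip = 1,
                           colClasses = "character")
  data <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  eeg_recording(data, fs = fs, labels = tab[[1]], infant_id = infant_id)
}
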