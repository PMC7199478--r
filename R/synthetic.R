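#' Synthetic infant EEG cohort
#'
#' Generates continuous multichannel recordings with the statistical
#' structure the analysis assumes -- a 1/f background with band-limited
#' oscillatory prominences (posterior delta/theta, centro-parietal alpha),
#' sparse isolated motion events with per-infant presence patterns, motion
#' artifact signatures injected as band-limited power changes with spatial
#' falloff from seed channels, and occasional bad channels -- together with
#' ground-truth annotations. Everything is driven by a single integer seed
#' with per-infant substreams, so cohorts are bit-reproducible.
#'
#' @name synthetic_data
NULL

#' Default synthetic cohort configuration
#'
#' All tunable generator parameters with defaults emulating a naturalistic
#' infant recording session: 12 infants, 500 Hz, 274-448 s recordings,
#' ~15% incidental rest, five spontaneous motion types with per-infant
#' presence probabilities and log-normal event durations, beta-band
#' (~15 Hz) artifact power increases that are frontal/fronto-temporal for
#' jaw and posterior parietal/occipital for arm, an optional central
#' theta/alpha attenuation for every motion type, and occasional
#' high-offset bad channels.
#'
#' @param n_infants Number of infants.
#' @param fs Sampling rate (Hz).
#' @param duration_range Recording length range in seconds (drawn
#'   uniformly).
#' @param seed Master integer seed.
#' @param beta_gain Multiplicative beta-band power gain at artifact seed
#'   channels for jaw and arm (types with no reliable artifact keep
#'   gain 1).
#' @param thetaalpha_gain Multiplicative central theta/alpha gain during
#'   motion (< 1 attenuates; 1 disables).
#' @param bad_channel_prob Per-infant probability of one bad channel.
#' @return A nested list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_infants = 12, fs = 500,
                             duration_range = c(274, 448), seed = 1,
                             beta_gain = 2.5, thetaalpha_gain = 0.9,
                             bad_channel_prob = 0.25) {
  cfg <- list(
    n_infants = n_infants,
    fs = fs,
    duration_range = duration_range,
    seed = seed,
    background = list(
      one_over_f_exponent = 1,
      broadband_scale_uv = 15, # RMS of the 1/f component per channel
      band_bumps = list(
        delta = list(center_hz = 2, width_hz = 1, amplitude_uv = 10,
                     seed_channels = c("O1", "Oz", "O2", "PO9", "PO10"),
                     spatial_falloff = 0.7),
        theta = list(center_hz = 4.5, width_hz = 1.2, amplitude_uv = 8,
                     seed_channels = c("O1", "Oz", "O2", "P3", "Pz", "P4"),
                     spatial_falloff = 0.7),
        alpha = list(center_hz = 7.5, width_hz = 1.2, amplitude_uv = 7,
                     seed_channels = c("C3", "Cz", "C4", "CP1", "CP2"),
                     spatial_falloff = 0.7)
      )
    ),
    artifact_specs = list(
      jaw = list(beta_center_hz = 15, beta_width_hz = 3.5,
                 beta_gain = beta_gain,
                 seed_channels = c("Fp1", "Fp2", "F3", "F4", "F7", "F8",
                                   "FC5", "FC6"),
                 spatial_falloff = 0.6,
                 central_thetaalpha_gain = thetaalpha_gain),
      hand = list(beta_center_hz = 15, beta_width_hz = 3.5, beta_gain = 1,
                  seed_channels = c("C3", "C4"), spatial_falloff = 0.6,
                  central_thetaalpha_gain = thetaalpha_gain),
      arm = list(beta_center_hz = 15, beta_width_hz = 3.5,
                 beta_gain = beta_gain,
                 seed_channels = c("P3", "Pz", "P4", "P7", "P8",
                                   "O1", "Oz", "O2"),
                 spatial_falloff = 0.6,
                 central_thetaalpha_gain = thetaalpha_gain),
      foot = list(beta_center_hz = 15, beta_width_hz = 3.5, beta_gain = 1,
                  seed_channels = c("Cz", "CP1", "CP2"),
                  spatial_falloff = 0.6,
                  central_thetaalpha_gain = thetaalpha_gain),
      leg = list(beta_center_hz = 15, beta_width_hz = 3.5, beta_gain = 1,
                 seed_channels = c("Cz", "CP1", "CP2"),
                 spatial_falloff = 0.6,
                 central_thetaalpha_gain = thetaalpha_gain)
    ),
    event_model = list(
      rest_fraction = 0.15,
      rest_duration = list(meanlog = log(5), sdlog = 0.5,
                           min_s = 0.6, max_s = 20),
      types = list(
        jaw = list(presence_prob = 0.5, rate_per_min = 1.3,
                   meanlog = log(1.3), sdlog = 0.5, min_s = 0.3,
                   max_s = 15),
        hand = list(presence_prob = 0.67, rate_per_min = 1.7,
                    meanlog = log(2.2), sdlog = 0.6, min_s = 0.3,
                    max_s = 15),
        arm = list(presence_prob = 0.83, rate_per_min = 1.1,
                   meanlog = log(1.8), sdlog = 0.5, min_s = 0.3,
                   max_s = 15),
        foot = list(presence_prob = 0.33, rate_per_min = 1.0,
                    meanlog = log(2.5), sdlog = 1.0, min_s = 0.3,
                    max_s = 40),
        leg = list(presence_prob = 0.83, rate_per_min = 1.6,
                   meanlog = log(2.2), sdlog = 0.6, min_s = 0.3,
                   max_s = 15)
      )
    ),
    bad_channel_model = list(
      probability = bad_channel_prob,
      offset_uv = 150,
      affected_fraction = 0.3
    )
  )
  .validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_synthetic_config <- function(cfg) {
  gains <- c(vapply(cfg$artifact_specs, `[[`, 0, "beta_gain"),
             vapply(cfg$artifact_specs, `[[`, 0, "central_thetaalpha_gain"))
  if (any(gains <= 0)) stop("all gains must be > 0", call. = FALSE)
  centers <- vapply(cfg$background$band_bumps, `[[`, 0, "center_hz")
  if (cfg$fs <= 2 * max(centers)) {
    stop("fs must exceed twice the highest band-bump center", call. = FALSE)
  }
  durs <- unlist(lapply(cfg$event_model$types, `[[`, "min_s"))
  if (any(durs <= 0)) stop("event durations must be positive", call. = FALSE)
  invisible(cfg)
}

#' Read / write a synthetic configuration as YAML
#'
#' @param cfg A `synthetic_config`.
#' @param path File path.
#' @return `read_synthetic_config` returns a `synthetic_config`.
#' @export
write_synthetic_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

# spatial amplitude profile: Gaussian falloff in 3-D chord distance from
# the nearest seed channel (1 at a seed channel)
.spatial_profile <- function(montage, seed_channels, falloff) {
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  seed_xyz <- xyz[montage$label %in% seed_channels, , drop = FALSE]
  d2 <- vapply(seq_len(nrow(xyz)), function(i) {
    min(colSums((t(seed_xyz) - xyz[i, ])^2))
  }, 0)
  exp(-d2 / (2 * falloff^2))
}

# real noise with a prescribed amplitude spectrum shape, unit RMS, n x k
.shaped_noise <- function(n, k, shape_fun, fs) {
  freqs <- c(0, seq_len(floor(n / 2)), # one-sided bin frequencies (cycles)
             if (n %% 2 == 0) NULL else NULL)
  n_pos <- floor((n - 1) / 2)
  f_pos <- seq_len(n_pos) * fs / n
  has_nyq <- n %% 2 == 0
  amp_pos <- shape_fun(f_pos)
  amp <- c(0, amp_pos,
           if (has_nyq) shape_fun(fs / 2) else NULL)
  # Hermitian spectrum with random phases
  re <- matrix(stats::rnorm((n_pos + 1 + has_nyq) * k), ncol = k)
  im <- matrix(stats::rnorm((n_pos + 1 + has_nyq) * k), ncol = k)
  half <- (re + 1i * im) * amp
  if (has_nyq) half[nrow(half), ] <- Re(half[nrow(half), ])
  full <- rbind(half,
                Conj(half[rev(seq_len(n_pos) + 1L), , drop = FALSE]))
  x <- Re(stats::mvfft(full, inverse = TRUE)) / n
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  sweep(x, 2, rms, "/")
}

#' Simulate one infant's background EEG
#'
#' Each channel is unit-RMS 1/f-shaped noise scaled to the configured
#' broadband RMS, plus spatially-weighted band-limited oscillations: every
#' bump contributes a common Gaussian-spectrum waveform whose amplitude
#' decays with 3-D distance from its seed channels, so band power is
#' maximal at the seeds.
#'
#' @param cfg A `synthetic_config`.
#' @param infant_index Infant number (used for the id).
#' @param duration_s Recording length in seconds (drawn from
#'   `cfg$duration_range` when NULL).
#' @param montage An `eeg_montage` (defaults to [build_montage()]).
#' @return An `eeg_recording`. Uses the current RNG stream.
#' @export
simulate_background <- function(cfg, infant_index = 1, duration_s = NULL,
                                montage = build_montage()) {
  fs <- cfg$fs
  if (is.null(duration_s)) {
    duration_s <- stats::runif(1, cfg$duration_range[1],
                               cfg$duration_range[2])
  }
  n <- as.integer(round(duration_s * fs))
  n_ch <- nrow(montage)
  bg <- cfg$background
  expo <- bg$one_over_f_exponent

  # 1/f background, independent across channels
  pink <- .shaped_noise(n, n_ch, function(f) f^(-expo / 2), fs)
  data <- t(pink) * bg$broadband_scale_uv

  # band bumps: one common source waveform each, spatial Gaussian weights
  for (bump in bg$band_bumps) {
    src <- .shaped_noise(n, 1, function(f) {
      exp(-(f - bump$center_hz)^2 / (2 * bump$width_hz^2))
    }, fs)[, 1]
    w <- .spatial_profile(montage, bump$seed_channels, bump$spatial_falloff)
    data <- data + outer(w * bump$amplitude_uv, src)
  }
  eeg_recording(data, fs = fs, labels = montage$label,
                infant_id = sprintf("infant%02d", infant_index))
}

# truncated log-normal duration sampler for one event type spec
.sample_durations <- function(n, spec) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
    d <- d[d >= spec$min_s & d <= spec$max_s]
    out <- c(out, d)
  }
  out[seq_len(n)]
}

#' Sample event durations for one motion type or rest
#'
#' Exposes the configured truncated log-normal duration sampler (positive
#' and right-skewed, matching the heavy-tailed totals spontaneous motion
#' produces).
#'
#' @param cfg A `synthetic_config`.
#' @param type One of the motion types or `"rest"`.
#' @param n Number of draws.
#' @return Numeric vector of durations in seconds.
#' @export
sample_event_duration <- function(cfg, type, n) {
  spec <- if (type == "rest") cfg$event_model$rest_duration
          else cfg$event_model$types[[type]]
  if (is.null(spec)) stop("unknown event type: ", type, call. = FALSE)
  .sample_durations(n, spec)
}

#' Schedule rest and motion events for one recording
#'
#' Draws per-type presence (so some infants lack some motion types), event
#' counts (Poisson at the configured rate, at least one when present) and
#' truncated log-normal durations, then packs all events into the
#' recording in shuffled order with random gaps and quantizes to the 1/30 s
#' video-frame grid. With `rest_fraction = 1` the whole recording is one
#' rest interval.
#'
#' @param cfg A `synthetic_config`.
#' @param duration_s Recording length (seconds, positive).
#' @param infant_id Identifier for the emitted events.
#' @return Annotation tibble (`infant_id`, `label`, `onset_s`,
#'   `offset_s`), non-overlapping, within `[0, duration_s]`.
#' @export
schedule_events <- function(cfg, duration_s, infant_id = "infant01") {
  stopifnot(duration_s > 0)
  em <- cfg$event_model
  if (em$rest_fraction >= 1) {
    frames <- floor(duration_s * 30)
    return(tibble::tibble(infant_id = infant_id, label = "rest",
                          onset_s = 0, offset_s = frames / 30))
  }
  labels <- character(0)
  durs <- numeric(0)
  for (type in names(em$types)) {
    spec <- em$types[[type]]
    if (stats::runif(1) > spec$presence_prob) next
    n_ev <- max(1L, stats::rpois(1, spec$rate_per_min * duration_s / 60))
    labels <- c(labels, rep(type, n_ev))
    durs <- c(durs, .sample_durations(n_ev, spec))
  }
  rest_total <- em$rest_fraction * duration_s
  rest_durs <- numeric(0)
  while (sum(rest_durs) < rest_total) {
    rest_durs <- c(rest_durs, .sample_durations(1, em$rest_duration))
  }
  labels <- c(labels, rep("rest", length(rest_durs)))
  durs <- c(durs, rest_durs)

  if (sum(durs) > 0.9 * duration_s) {
    stop(sprintf(
      paste0("scheduling infeasible: %.1f s of events requested for a ",
             "%.1f s recording"), sum(durs), duration_s), call. = FALSE)
  }
  ord <- sample.int(length(durs))
  labels <- labels[ord]
  durs <- durs[ord]
  free <- duration_s - sum(durs)
  gaps <- free * {g <- stats::runif(length(durs) + 1); g / sum(g)}
  onsets <- cumsum(gaps[seq_along(durs)] +
                     c(0, durs[-length(durs)]))
  # snap to the video frame grid, keeping events disjoint and in bounds
  frame <- 1 / 30
  onsets_q <- round(onsets / frame) * frame
  offsets_q <- round((onsets + durs) / frame) * frame
  for (i in seq_along(onsets_q)) {
    if (i > 1 && onsets_q[i] < offsets_q[i - 1]) {
      onsets_q[i] <- offsets_q[i - 1]
    }
    if (offsets_q[i] <= onsets_q[i]) offsets_q[i] <- onsets_q[i] + frame
  }
  keep <- offsets_q <= duration_s
  tibble::tibble(infant_id = infant_id, label = labels,
                 onset_s = onsets_q, offset_s = offsets_q)[keep, ]
}

#' Inject motion-artifact signatures into a recording
#'
#' Within each motion interval, beta-band power is multiplied by the
#' type's `beta_gain` with a Gaussian spatial profile decaying from its
#' seed channels, realized as added independent band-limited noise whose
#' variance per channel is `(gain_c - 1)` times the channel's measured
#' in-interval beta power, with 10 ms Hann-tapered onsets/offsets to avoid
#' edge clicks. An optional theta/alpha attenuation
#' (`central_thetaalpha_gain` < 1) multiplicatively scales 3-9 Hz content
#' at central channels via frequency-domain masking of the interval.
#' Signal outside motion intervals is untouched, and unit gains are exact
#' no-ops.
#'
#' @param rec An `eeg_recording`.
#' @param events Annotation tibble for this infant.
#' @param cfg A `synthetic_config`.
#' @param montage The montage used for spatial profiles.
#' @return The modified `eeg_recording`.
#' @export
inject_artifacts <- function(rec, events, cfg, montage = build_montage()) {
  fs <- rec$fs
  ev <- events[events$label != "rest", , drop = FALSE]
  unknown <- setdiff(unique(ev$label), names(cfg$artifact_specs))
  if (length(unknown) > 0) {
    stop("no artifact spec for motion type(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  central_seed <- c("C3", "Cz", "C4", "CP1", "CP2")
  for (i in seq_len(nrow(ev))) {
    spec <- cfg$artifact_specs[[ev$label[i]]]
    a <- as.integer(floor(ev$onset_s[i] * fs)) + 1L
    b <- min(as.integer(floor(ev$offset_s[i] * fs)), ncol(rec$data))
    if (b - a + 1L < fs / 10) next # sub-100 ms remnant: nothing to shape
    seg <- rec$data[, a:b, drop = FALSE]
    len <- ncol(seg)
    taper <- .edge_taper(len, fs)

    if (spec$beta_gain != 1) {
      w <- .spatial_profile(montage, spec$seed_channels,
                            spec$spatial_falloff)
      gain_c <- 1 + (spec$beta_gain - 1) * w
      band_p <- .band_power(seg, fs, spec$beta_center_hz - spec$beta_width_hz,
                            spec$beta_center_hz + spec$beta_width_hz)
      noise <- .shaped_noise(len, nrow(seg), function(f) {
        exp(-(f - spec$beta_center_hz)^2 / (2 * (spec$beta_width_hz / 2)^2))
      }, fs)
      add <- t(noise) * sqrt(pmax(gain_c - 1, 0) * band_p)
      rec$data[, a:b] <- seg + sweep(add, 2, taper, "*")
      seg <- rec$data[, a:b, drop = FALSE]
    }

    ta_gain <- spec$central_thetaalpha_gain
    if (!is.null(ta_gain) && ta_gain != 1) {
      w <- .spatial_profile(montage, central_seed, spec$spatial_falloff)
      gain_c <- 1 - (1 - ta_gain) * w
      shaped <- .scale_band(seg, fs, 3, 9, sqrt(gain_c))
      blended <- sweep(seg, 2, 1 - taper, "*") +
        sweep(shaped, 2, taper, "*")
      rec$data[, a:b] <- blended
    }
  }
  rec
}

# 10 ms raised-cosine on/off ramps
.edge_taper <- function(len, fs) {
  ramp_n <- max(1L, round(0.01 * fs))
  taper <- rep(1, len)
  if (2 * ramp_n < len) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    taper[seq_len(ramp_n)] <- r
    taper[len - ramp_n + seq_len(ramp_n)] <- rev(r)
  }
  taper
}

# mean band power (uV^2) per channel of a segment
.band_power <- function(seg, fs, lo, hi) {
  n <- ncol(seg)
  ft <- stats::mvfft(t(seg))
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f <= hi
  2 * colSums(Mod(ft[sel, , drop = FALSE])^2) / n^2
}

# multiply spectral content in [lo, hi] Hz by per-channel factors
.scale_band <- function(seg, fs, lo, hi, factor_c) {
  n <- ncol(seg)
  ft <- stats::mvfft(t(seg))
  f <- (seq_len(n) - 1) * fs / n
  f_mirror <- pmin(f, fs - f)
  mask <- as.numeric(f_mirror >= lo & f_mirror <= hi)
  out <- matrix(0, nrow(seg), n)
  for (c in seq_len(nrow(seg))) {
    g <- 1 + (factor_c[c] - 1) * mask
    out[c, ] <- Re(stats::fft(ft[, c] * g, inverse = TRUE)) / n
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Composes background simulation, event scheduling, artifact injection
#' and the bad-channel model per infant, each on its own RNG substream
#' derived from `cfg$seed`, so the cohort is bit-reproducible and infants
#' are statistically independent.
#'
#' @param cfg A `synthetic_config`.
#' @param montage An `eeg_montage`.
#' @return A list of class `synthetic_cohort`: `recordings` (list of
#'   `eeg_recording`), `annotations` (one tibble over all infants),
#'   `truth_effects` (the artifact specs injected), `config`.
#' @export
simulate_cohort <- function(cfg, montage = build_montage()) {
  set.seed(cfg$seed)
  infant_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_infants)
  recordings <- vector("list", cfg$n_infants)
  annotations <- vector("list", cfg$n_infants)
  for (i in seq_len(cfg$n_infants)) {
    set.seed(infant_seeds[i])
    duration_s <- stats::runif(1, cfg$duration_range[1],
                               cfg$duration_range[2])
    rec <- simulate_background(cfg, i, duration_s, montage)
    events <- schedule_events(cfg, duration_s, rec$infant_id)
    rec <- inject_artifacts(rec, events, cfg, montage)
    rec <- .apply_bad_channels(rec, cfg)
    recordings[[i]] <- rec
    annotations[[i]] <- events
  }
  names(recordings) <- vapply(recordings, function(r) r$infant_id, "")
  structure(
    list(recordings = recordings,
         annotations = dplyr::bind_rows(annotations),
         truth_effects = cfg$artifact_specs,
         config = cfg),
    class = "synthetic_cohort"
  )
}

# with the configured probability, add a large square offset to one random
# channel for a contiguous stretch of the recording, enough to trip the
# rejection rule downstream
.apply_bad_channels <- function(rec, cfg) {
  bc <- cfg$bad_channel_model
  if (stats::runif(1) >= bc$probability) return(rec)
  ch <- sample.int(nrow(rec$data), 1)
  n <- ncol(rec$data)
  len <- round(bc$affected_fraction * n)
  start <- sample.int(n - len + 1, 1)
  rec$data[ch, start:(start + len - 1)] <-
    rec$data[ch, start:(start + len - 1)] + bc$offset_uv
  rec
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d infants @ %g Hz, %d annotated events\n",
              length(x$recordings), x$config$fs, nrow(x$annotations)))
  invisible(x)
}
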