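test_that("background PSD follows the configured 1/f exponent", {
  cfg <- small_config(fs = 250, duration_range = c(80, 80))
  set.seed(1)
  rec <- simulate_background(cfg, 1, duration_s = 80)
  events <- tibble::tibble(infant_id = rec$infant_id, label = "rest",
                           onset_s = 0, offset_s = 80)
  cd <- epoch_1s(extract_concatenate(rec, events, "rest"))
  pw <- fft_power(cd, fmin = 1, fmax = 100)
  psd <- colMeans(epoch_average(pw))
  # fit above the oscillatory bumps, where the background is pure 1/f
  sel <- pw$freqs >= 15 & pw$freqs <= 80
  slope <- stats::coef(stats::lm(log(psd[sel]) ~ log(pw$freqs[sel])))[2]
  expect_lt(abs(slope - (-cfg$background$one_over_f_exponent)), 0.3)
})

test_that("background amplitude is physiological and zero when configured off", {
  cfg <- small_config(duration_range = c(30, 30))
  set.seed(2)
  rec <- simulate_background(cfg, 1, duration_s = 30)
  rms <- sqrt(rowMeans(rec$data^2))
  expect_true(all(rms > 5 & rms < 50))
  cfg0 <- cfg
  cfg0$background$broadband_scale_uv <- 0
  for (b in names(cfg0$background$band_bumps)) {
    cfg0$background$band_bumps[[b]]$amplitude_uv <- 0
  }
  set.seed(2)
  expect_true(all(simulate_background(cfg0, 1, duration_s = 30)$data == 0))
})

test_that("alpha bump power is maximal at its seed channels", {
  cfg <- small_config(fs = 250, duration_range = c(60, 60))
  set.seed(3)
  rec <- simulate_background(cfg, 1, duration_s = 60)
  events <- tibble::tibble(infant_id = rec$infant_id, label = "rest",
                           onset_s = 0, offset_s = 60)
  cd <- epoch_1s(extract_concatenate(rec, events, "rest"))
  pw <- epoch_average(fft_power(cd))
  alpha_band <- colnames(pw) %in% as.character(6:8)
  alpha_pow <- rowSums(pw[, alpha_band])
  mon <- build_montage()
  seed_ch <- "Cz"
  d <- montage_distances(mon)[seed_ch, ]
  farthest <- names(which.max(d))
  expect_gt(alpha_pow[seed_ch], alpha_pow[farthest])
})

test_that("schedule honors rest_fraction = 1 and per-type sparsity", {
  cfg <- small_config()
  cfg$event_model$rest_fraction <- 1
  set.seed(4)
  ev <- schedule_events(cfg, 120)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$label, "rest")
  expect_equal(ev$onset_s, 0)
  expect_equal(ev$offset_s, floor(120 * 30) / 30)

  # default presence probabilities leave some types missing in a 12-infant
  # cohort (spontaneous motion is sparse)
  cfg2 <- small_config()
  set.seed(5)
  present <- sapply(1:12, function(i) {
    ev <- schedule_events(cfg2, 300, sprintf("infant%02d", i))
    motion_conditions() %in% ev$label
  })
  expect_true(any(rowSums(present) < 12))
})

test_that("scheduled events are disjoint, in bounds, and frame-aligned", {
  cfg <- small_config()
  set.seed(6)
  for (rep_i in 1:5) {
    ev <- schedule_events(cfg, 200)
    ev <- dplyr::arrange(ev, onset_s)
    expect_true(all(ev$onset_s >= 0 & ev$offset_s <= 200))
    expect_true(all(diff(c(rbind(ev$onset_s, ev$offset_s))) >= -1e-9))
    expect_true(all(abs(ev$onset_s * 30 - round(ev$onset_s * 30)) < 1e-6))
  }
})

test_that("scheduled durations match the configured sampler (KS)", {
  cfg <- small_config()
  set.seed(7)
  sched <- numeric(0)
  while (length(sched) < 2000) {
    ev <- schedule_events(cfg, 400)
    sched <- c(sched, with(ev[ev$label == "leg", ],
                           offset_s - onset_s))
  }
  ref <- sample_event_duration(cfg, "leg", length(sched))
  ref <- round(ref * 30) / 30 # same frame quantization as the scheduler
  ks <- suppressWarnings(stats::ks.test(sched, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("infeasible packing raises a scheduling error", {
  cfg <- small_config()
  cfg$event_model$rest_fraction <- 0.95
  set.seed(8)
  expect_error(schedule_events(cfg, 50), "infeasible")
})

test_that("unit gains make artifact injection an exact no-op", {
  cfg <- small_config(beta_gain = 1, thetaalpha_gain = 1,
                      duration_range = c(30, 30))
  set.seed(9)
  rec <- simulate_background(cfg, 1, duration_s = 30)
  ev <- tibble::tibble(infant_id = rec$infant_id, label = "jaw",
                       onset_s = 5, offset_s = 10)
  out <- inject_artifacts(rec, ev, cfg)
  expect_identical(out$data, rec$data)
})

test_that("unknown motion type in the track is a labeling error", {
  cfg <- small_config(duration_range = c(10, 10))
  cfg$artifact_specs$leg <- NULL
  set.seed(10)
  rec <- simulate_background(cfg, 1, duration_s = 10)
  ev <- tibble::tibble(infant_id = rec$infant_id, label = "leg",
                       onset_s = 1, offset_s = 3)
  expect_error(inject_artifacts(rec, ev, cfg), "leg")
})

test_that("jaw injection at gain 3 doubles frontal beta power vs rest", {
  cfg <- small_config(beta_gain = 3, thetaalpha_gain = 1, fs = 250,
                      duration_range = c(60, 60))
  set.seed(11)
  rec <- simulate_background(cfg, 1, duration_s = 60)
  ev <- tibble::tibble(infant_id = rec$infant_id,
                       label = c("jaw", "rest"),
                       onset_s = c(5, 35), offset_s = c(25, 55))
  out <- inject_artifacts(rec, ev, cfg)
  band_pow <- function(cd) {
    pw <- epoch_average(fft_power(cd))
    rowSums(pw[, colnames(pw) %in% as.character(13:20)])
  }
  jaw <- band_pow(epoch_1s(extract_concatenate(out, ev, "jaw")))
  rest <- band_pow(epoch_1s(extract_concatenate(out, ev, "rest")))
  expect_gt(jaw["Fp1"] / rest["Fp1"], 2)
  # signal outside motion intervals unchanged
  expect_equal(out$data[, 1:(5 * 250 - 1)], rec$data[, 1:(5 * 250 - 1)])
})

test_that("arm injection is posterior-dominant, jaw anterior-dominant", {
  cfg <- small_config(beta_gain = 3, thetaalpha_gain = 1, fs = 250,
                      duration_range = c(60, 60))
  set.seed(12)
  rec <- simulate_background(cfg, 1, duration_s = 60)
  ev <- tibble::tibble(infant_id = rec$infant_id,
                       label = c("arm", "jaw"),
                       onset_s = c(5, 35), offset_s = c(25, 55))
  out <- inject_artifacts(rec, ev, cfg)
  beta_gain_by_channel <- function(cond) {
    pre <- epoch_average(fft_power(epoch_1s(extract_concatenate(rec, ev, cond))))
    post <- epoch_average(fft_power(epoch_1s(extract_concatenate(out, ev, cond))))
    sel <- colnames(pre) %in% as.character(13:20)
    rowSums(post[, sel]) / rowSums(pre[, sel])
  }
  arm <- beta_gain_by_channel("arm")
  expect_gt(arm["Oz"], max(arm[c("Fp1", "Fp2", "F7", "F8")]))
  jaw <- beta_gain_by_channel("jaw")
  expect_gt(jaw["Fp1"], max(jaw[c("O1", "Oz", "O2")]))
})

test_that("theta/alpha attenuation reduces central 3-9 Hz power", {
  cfg <- small_config(beta_gain = 1, thetaalpha_gain = 0.5, fs = 250,
                      duration_range = c(60, 60))
  set.seed(13)
  rec <- simulate_background(cfg, 1, duration_s = 60)
  ev <- tibble::tibble(infant_id = rec$infant_id, label = "hand",
                       onset_s = 5, offset_s = 45)
  out <- inject_artifacts(rec, ev, cfg)
  ta <- function(r) {
    pw <- epoch_average(fft_power(epoch_1s(extract_concatenate(r, ev, "hand"))))
    rowSums(pw[, colnames(pw) %in% as.character(3:8)])
  }
  ratio <- ta(out) / ta(rec)
  expect_lt(ratio["Cz"], 0.6)
  expect_gt(ratio["Cz"], 0.15)
  expect_gt(min(ratio[c("Fp1", "O1")]), ratio["Cz"]) # falls off centrally
})

test_that("cohorts are bit-reproducible and sized as configured", {
  cfg <- small_config(n_infants = 3, duration_range = c(60, 80), seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$annotations, b$annotations)
  expect_equal(length(a$recordings), 3)
  durs <- sapply(a$recordings, function(r) ncol(r$data) / r$fs)
  expect_true(all(durs >= 60 & durs <= 80))
  # annotations lie within recording bounds
  for (r in a$recordings) {
    ev <- a$annotations[a$annotations$infant_id == r$infant_id, ]
    expect_true(all(ev$onset_s >= 0 & ev$offset_s <= ncol(r$data) / r$fs))
  }
})

test_that("forced bad channels trip the downstream rejection rule", {
  cfg <- small_config(n_infants = 3, duration_range = c(60, 70),
                      bad_channel_prob = 1, seed = 5)
  coh <- simulate_cohort(cfg)
  for (rec in coh$recordings) {
    rej <- reject_noisy_channels(rec)
    expect_gte(sum(!rej$retained), 1)
  }
})

test_that("config validation and YAML round-trip work", {
  expect_error(synthetic_config(beta_gain = 0), "gains")
  expect_error(synthetic_config(fs = 10), "twice the highest")
  cfg <- small_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-9)
})
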