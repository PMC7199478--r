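# condition_data wrapper around a raw epochs array
as_condition <- function(epochs, fs, infant_id = "i1", condition = "rest",
                         labels = paste0("c", seq_len(dim(epochs)[2]))) {
  structure(
    list(infant_id = infant_id, condition = condition,
         segments = tibble::tibble(onset_s = 0, offset_s = 0),
         data = matrix(0, dim(epochs)[2], 0), fs = fs, labels = labels,
         retained = rep(TRUE, dim(epochs)[2]), epochs = epochs),
    class = "condition_data"
  )
}

test_that("a pure tone concentrates FFT power in its own bin", {
  fs <- 500
  t_ax <- seq_len(fs) / fs
  x <- 3 * sin(2 * pi * 10 * t_ax)
  ep <- array(0, dim = c(1, 1, fs)); ep[1, 1, ] <- x
  pw <- fft_power(as_condition(ep, fs))
  peak <- pw$pow[1, 1, pw$freqs == 10]
  off <- pw$pow[1, 1, abs(pw$freqs - 10) >= 2]
  expect_true(all(off < 0.01 * peak))
  # all-zero epoch: all-zero spectrum
  ep0 <- array(0, dim = c(1, 1, fs))
  expect_true(all(fft_power(as_condition(ep0, fs))$pow == 0))
})

test_that("one-sided PSD integrates to the signal variance (Parseval)", {
  set.seed(21)
  fs <- 250
  sigma <- 4
  ep <- array(rnorm(100 * 2 * fs, sd = sigma), dim = c(100, 2, fs))
  pw <- fft_power(as_condition(ep, fs), fmin = 0, fmax = NULL)
  integral <- mean(apply(pw$pow, c(1, 2), sum)) # delta-f = 1 Hz
  expect_equal(integral, sigma^2, tolerance = 0.05)
})

test_that("z-scores match hand evaluation on a 2-channel fixture", {
  # epoch powers c1 = (1, 3), c2 = (3, 5); channel means m = (2, 4),
  # sd(m) = sqrt(2); chan means (2, 4) - mean(m) = -+1 => z = -+1/sqrt(2)
  pow <- array(0, dim = c(2, 2, 1))
  pow[, 1, 1] <- c(1, 3); pow[, 2, 1] <- c(3, 5)
  ep <- structure(list(pow = pow, freqs = 5, infant_id = "i1",
                       condition = "rest", channels = c("c1", "c2")),
                  class = "epoched_power")
  z <- znormalize(ep)
  expect_equal(as.vector(z$z), c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("z-scores have zero channel mean and are scale invariant", {
  set.seed(8)
  ep <- fake_epoched_power(matrix(runif(5 * 7, 1, 4), 5,
                                  dimnames = list(paste0("c", 1:5), NULL)),
                           n_epochs = 6, infant_id = "i1",
                           condition = "rest", sd = 0.3)
  z <- znormalize(ep)
  expect_lt(max(abs(colMeans(z$z))), 1e-9)
  # multiplying raw power by a positive constant leaves z unchanged
  ep2 <- ep; ep2$pow <- ep$pow * 7.3
  expect_equal(znormalize(ep2)$z, z$z, tolerance = 1e-9)
})

test_that("degenerate z-scores are reported, not fabricated", {
  pow <- array(1, dim = c(3, 2, 4)) # no epoch variance anywhere
  ep <- structure(list(pow = pow, freqs = c(3, 4), infant_id = "i1",
                       condition = "rest", channels = paste0("c", 1:2)),
                  class = "epoched_power")
  expect_error(znormalize(ep), "3 Hz")
})

test_that("identical channels give z = 0 everywhere", {
  pow <- array(0, dim = c(4, 3, 2))
  for (e in 1:4) pow[e, , ] <- matrix(rep(c(1, 2), each = 3) * e, 3)
  ep <- structure(list(pow = pow, freqs = c(1, 2), infant_id = "i1",
                       condition = "rest", channels = paste0("c", 1:3)),
                  class = "epoched_power")
  expect_true(all(abs(znormalize(ep)$z) < 1e-12))
})

test_that("grand averaging aligns channels and averages contributors", {
  z1 <- structure(list(z = matrix(1, 2, 2, dimnames = list(c("a", "b"), 1:2)),
                       freqs = 1:2, channels = c("a", "b"),
                       infant_id = "i1", condition = "rest"),
                  class = "z_spectra")
  z2 <- z1; z2$infant_id <- "i2"; z2$z[] <- -1
  ga <- grand_average(list(z1, z2))
  expect_true(all(ga$mean_z == 0))
  # single infant: identity
  expect_equal(grand_average(list(z1))$mean_z, z1$z)
  # three infants with a channel missing from one
  z3 <- structure(list(z = matrix(4, 1, 2, dimnames = list("a", 1:2)),
                       freqs = 1:2, channels = "a",
                       infant_id = "i3", condition = "rest"),
                  class = "z_spectra")
  ga3 <- grand_average(list(z1, z2, z3))
  expect_equal(ga3$mean_z["a", ], c(`1` = 4 / 3, `2` = 4 / 3))
  expect_equal(ga3$mean_z["b", ], c(`1` = 0, `2` = 0))
  expect_equal(unname(ga3$n_by_channel), c(3L, 2L))
})

test_that("band averages follow the low-inclusive high-exclusive convention", {
  freqs <- 1:20
  mean_z <- matrix(rep(freqs, each = 2), 2,
                   dimnames = list(c("a", "b"), freqs))
  ga <- structure(list(mean_z = mean_z, n_infants = 1,
                       n_by_channel = c(a = 1L, b = 1L), freqs = freqs,
                       channels = c("a", "b"), condition = "rest"),
                  class = "grand_average")
  bt <- band_topography(ga)
  alpha <- bt$value[bt$band == "alpha" & bt$channel == "a"]
  expect_equal(alpha, mean(c(6, 7, 8))) # bins 6-8; 9 belongs to low beta
  lowbeta <- bt$value[bt$band == "low beta" & bt$channel == "a"]
  expect_equal(lowbeta, mean(9:12))
  highbeta <- bt$value[bt$band == "high beta" & bt$channel == "a"]
  expect_equal(highbeta, mean(13:20)) # top band closes at the last bin
  # flat spectrum: identical value in every band
  ga$mean_z[] <- 2
  expect_true(all(band_topography(ga)$value == 2))
})

test_that("1-s epochs with 2 Hz smoothing use exactly 3 DPSS tapers", {
  v <- dpss_tapers(250, 2)
  expect_equal(ncol(v), 3)
  expect_equal(crossprod(v), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("multitaper variance across bins is below the periodogram's", {
  set.seed(31)
  fs <- 250
  ep <- array(rnorm(60 * 1 * fs), dim = c(60, 1, fs))
  cd <- as_condition(ep, fs)
  mt <- multitaper_psd(cd)
  pg <- fft_power(cd, fmin = 1, fmax = 20)
  var_mt <- mean(apply(mt$pow[, 1, mt$freqs >= 1], 1, stats::var))
  var_pg <- mean(apply(pg$pow[, 1, ], 1, stats::var))
  expect_lt(var_mt, var_pg)
})

test_that("a 15 Hz tone yields a multitaper peak at 15 Hz with ~2 Hz half-width", {
  fs <- 250
  t_ax <- seq_len(fs) / fs
  ep <- array(0, dim = c(1, 1, fs))
  ep[1, 1, ] <- sin(2 * pi * 15 * t_ax)
  mt <- multitaper_psd(as_condition(ep, fs))
  expect_equal(mt$freqs[which.max(mt$pow[1, 1, ])], 15)
  inside <- sum(mt$pow[1, 1, abs(mt$freqs - 15) <= 2])
  total <- sum(mt$pow[1, 1, ])
  expect_gt(inside / total, 0.95)
})

test_that("fmax beyond Nyquist is a range error", {
  ep <- array(rnorm(2 * 1 * 30), dim = c(2, 1, 30))
  expect_error(multitaper_psd(as_condition(ep, 30), fmax = 20), "Nyquist")
})

test_that("FFT and multitaper spectra agree on smooth 1/f-like spectra", {
  set.seed(77)
  cfg <- small_config(n_infants = 1, duration_range = c(60, 60))
  set.seed(1)
  rec <- simulate_background(cfg, 1, duration_s = 60)
  events <- tibble::tibble(infant_id = rec$infant_id, label = "rest",
                           onset_s = 0, offset_s = 60)
  cd <- epoch_1s(extract_concatenate(rec, events, "rest"))
  a <- colMeans(epoch_average(fft_power(cd)))
  b <- colMeans(epoch_average(multitaper_psd(cd, fmin = 1)))
  expect_gt(stats::cor(log(a), log(b)), 0.95)
})
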