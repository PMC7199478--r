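nb32 <- build_neighbors(build_montage())

test_that("paired t map matches hand arithmetic and is antisymmetric", {
  set.seed(2)
  ps <- null_paired_spectra(3, n_bins = 4)
  # overwrite one point with known differences (1, 2, 3)
  for (i in 1:3) {
    ps$motion[[i]][1, 1] <- ps$rest[[i]][1, 1] + i
  }
  tmap <- pointwise_paired_t(ps)
  expect_equal(tmap[1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  # swapping conditions negates the map
  swapped <- ps
  swapped$motion <- ps$rest; swapped$rest <- ps$motion
  expect_equal(pointwise_paired_t(swapped), -tmap, tolerance = 1e-12)
})

test_that("constant differences hit the zero-variance branch", {
  ps <- null_paired_spectra(4, n_bins = 2)
  for (s in ps$subjects) ps$motion[[s]] <- ps$rest[[s]] + 1
  expect_warning(tmap <- pointwise_paired_t(ps), "zero variance")
  expect_true(all(tmap == 0))
})

test_that("cluster formation respects connectivity, sign and min_sensors", {
  mon <- build_montage()
  channels <- mon$label
  stat_map <- matrix(0, 32, 6, dimnames = list(channels, 1:6))
  # a 4-channel mutually-connected set straddling 3 adjacent bins at t = 5
  clique <- c("Cz", "FC1", "FC2", "C3")
  stat_map[clique, 2:4] <- 5
  cl <- form_clusters(stat_map, threshold = 2, nb32)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$mass, 60) # 4 channels x 3 bins x t = 5
  expect_equal(cl$n_sensors, 4)
  # only 2 channels supra-threshold: discarded at min_sensors = 3
  stat_map2 <- matrix(0, 32, 6, dimnames = list(channels, 1:6))
  stat_map2[c("Cz", "FC1"), 3] <- 5
  expect_equal(nrow(form_clusters(stat_map2, 2, nb32)), 0)
  expect_equal(nrow(form_clusters(stat_map2, 2, nb32, min_sensors = 2)), 1)
  # empty supra-threshold set: no clusters
  expect_equal(nrow(form_clusters(matrix(0, 32, 6,
                                         dimnames = list(channels, 1:6)),
                                  2, nb32)), 0)
})

test_that("opposite-sign points never join one cluster", {
  channels <- build_montage()$label
  stat_map <- matrix(0, 32, 4, dimnames = list(channels, 1:4))
  stat_map[c("Cz", "FC1", "FC2"), 2] <- 5
  stat_map[c("C3", "CP1", "CP2"), 2] <- -5 # sensor-adjacent to the positives
  cl <- form_clusters(stat_map, 2, nb32)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$sign, c(1, -1))
})

test_that("same-channel clusters only bridge adjacent frequency bins", {
  channels <- build_montage()$label
  stat_map <- matrix(0, 32, 8, dimnames = list(channels, 1:8))
  stat_map[c("Cz", "FC1", "FC2"), c(2, 3)] <- 5
  stat_map[c("Cz", "FC1", "FC2"), c(6, 7)] <- 5 # gap at bins 4-5
  cl <- form_clusters(stat_map, 2, nb32)
  expect_equal(nrow(cl), 2)
})

test_that("exact mode enumerates all sign patterns", {
  set.seed(4)
  ps <- null_paired_spectra(5, n_bins = 6)
  null <- permutation_null(ps, n_perm = 10000, neighbors = nb32, seed = 1,
                           exact = "always")
  expect_true(null$exact)
  expect_equal(null$n_perm, 32)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration within 3 SE", {
  set.seed(6)
  ps <- null_paired_spectra(5, n_bins = 8,
                            shift = matrix(c(rep(2, 32 * 4), rep(0, 32 * 4)),
                                           32, 8))
  stat_map <- pointwise_paired_t(ps)
  exact <- permutation_null(ps, neighbors = nb32, exact = "always")
  mc <- permutation_null(ps, n_perm = 2000, neighbors = nb32, seed = 3,
                         exact = "never")
  cl <- form_clusters(stat_map, exact$threshold, nb32)
  expect_gt(nrow(cl), 0)
  p_ex <- cluster_pvalues(cl, exact)$clusters$p[1]
  p_mc <- cluster_pvalues(cl, mc)$clusters$p[1]
  se <- sqrt(p_ex * (1 - p_ex) / mc$n_perm)
  expect_lt(abs(p_mc - p_ex), 3 * se + 1 / mc$n_perm)
})

test_that("p-value estimator bounds hold", {
  set.seed(10)
  ps <- null_paired_spectra(6, n_bins = 6, shift = 5)
  null <- permutation_null(ps, n_perm = 500, neighbors = nb32, seed = 2,
                           exact = "never")
  stat_map <- pointwise_paired_t(ps)
  cl <- form_clusters(stat_map, null$threshold, nb32)
  res <- cluster_pvalues(cl, null)
  expect_true(all(res$clusters$p > 0 & res$clusters$p <= 1))
  # a uniform shift at every point: the observed max cluster is also the
  # best achievable, so Monte-Carlo p is bounded below by 1/(n_perm + 1)
  expect_gte(min(res$clusters$p), 1 / (null$n_perm + 1))
})

test_that("negating all inputs mirrors cluster signs with identical mass and p", {
  set.seed(12)
  shift <- matrix(0, 32, 8)
  shift[1:10, 3:6] <- 3
  ps <- null_paired_spectra(6, n_bins = 8, shift = shift)
  neg <- ps
  for (s in ps$subjects) {
    neg$motion[[s]] <- -ps$motion[[s]]
    neg$rest[[s]] <- -ps$rest[[s]]
  }
  r1 <- cluster_test(ps, nb32, n_perm = 300, seed = 5)
  r2 <- cluster_test(neg, nb32, n_perm = 300, seed = 5)
  expect_equal(r1$clusters$mass, -r2$clusters$mass)
  expect_equal(r1$clusters$p, r2$clusters$p)
})

test_that("detected positive cluster mass is monotone in injected gain", {
  masses <- vapply(c(0.5, 1.5, 3), function(g) {
    set.seed(99) # same noise at every gain
    shift <- matrix(0, 32, 8)
    shift[25:32, 4:7] <- g
    ps <- null_paired_spectra(6, n_bins = 8, shift = shift)
    stat_map <- pointwise_paired_t(ps)
    thr <- stats::qt(0.975, 5)
    cl <- form_clusters(stat_map, thr, nb32)
    pos <- cl[cl$sign > 0, ]
    if (nrow(pos) == 0) 0 else max(pos$mass)
  }, 0)
  expect_true(all(diff(masses) >= 0))
})

test_that("stratified rerun equates epoch counts and preserves strong effects", {
  set.seed(14)
  mon <- build_montage()
  shift <- matrix(0, 32, 8, dimnames = list(mon$label, NULL))
  posterior <- c("P3", "Pz", "P4", "P7", "P8", "O1", "Oz", "O2")
  shift[posterior, 4:7] <- 4
  subjects <- sprintf("s%02d", 1:6)
  mk <- function(s, cond, n_ep, delta) {
    base <- matrix(10, 32, 8, dimnames = list(mon$label, NULL))
    fake_epoched_power(base + delta + matrix(rnorm(32 * 8, sd = 0.5), 32),
                       n_epochs = n_ep, infant_id = s, condition = cond,
                       freqs = 1:8, sd = 0.05)
  }
  ps <- pair_spectra(
    motion = lapply(subjects, mk, cond = "arm", n_ep = 4, delta = shift),
    rest = lapply(subjects, mk, cond = "rest", n_ep = 11, delta = 0))
  both <- stratified_rerun(ps, nb32, seed = 2, n_perm = 300)
  expect_true(all(both$epoch_counts$n_motion == 4))
  expect_true(all(both$epoch_counts$n_rest == 11))
  top_full <- both$full$clusters[1, ]
  top_strat <- both$stratified$clusters[1, ]
  expect_equal(top_full$sign, top_strat$sign)
  expect_gt(length(intersect(top_full$channel[[1]],
                             top_strat$channel[[1]])), 0)
  # equal counts: subsampling is a no-op on the spectra
  ps_eq <- pair_spectra(
    motion = lapply(subjects, mk, cond = "arm", n_ep = 5, delta = shift),
    rest = lapply(subjects, mk, cond = "rest", n_ep = 5, delta = 0))
  both_eq <- stratified_rerun(ps_eq, nb32, seed = 2, n_perm = 100)
  expect_equal(both_eq$full$stat_map, both_eq$stratified$stat_map)
})

test_that("subjects missing a condition are dropped from the pairing", {
  set.seed(16)
  mon <- build_montage()
  mk <- function(s, cond) {
    fake_epoched_power(matrix(10, 32, 4, dimnames = list(mon$label, NULL)),
                       n_epochs = 3, infant_id = s, condition = cond,
                       freqs = 1:4)
  }
  motion <- lapply(c("a", "b", "c"), mk, cond = "jaw")
  rest <- lapply(c("b", "c", "d"), mk, cond = "rest")
  ps <- pair_spectra(motion, rest)
  expect_setequal(ps$subjects, c("b", "c"))
  expect_error(pair_spectra(motion[1], rest), "at least 2 subjects")
})
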