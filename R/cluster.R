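#' Within-subject cluster-based permutation test
#'
#' Compares motion against resting-state power over the channel x frequency
#' plane with family-wise error control: a paired t statistic is computed at
#' every (channel, bin) point, supra-threshold points of equal sign are
#' grouped into clusters connected through the sensor neighbor graph (same
#' bin) or adjacent frequency bins (same channel), each cluster is scored by
#' its mass (sum of member t values), and observed masses are referred to
#' the permutation distribution of the maximum absolute cluster mass under
#' within-subject condition exchange (independent sign flips of each
#' subject's difference). Two-tailed control at level alpha follows from
#' using the single max-|mass| null: a cluster of either sign is significant
#' iff its Monte-Carlo p-value is at most alpha.
#'
#' @name cluster_stats
NULL

#' Pair per-subject motion and rest spectra
#'
#' Retains only subjects possessing both conditions, and only channels
#' retained in both conditions for every contributing subject (rejected
#' channels are excluded from the statistic map, the conservative choice).
#' Epoch-level power is kept so the stratified rerun can subsample epochs.
#'
#' @param motion,rest Named lists of `epoched_power` objects (names or
#'   `infant_id`s identify subjects), one condition each.
#' @return A `paired_spectra`: per-subject epoch arrays and epoch-averaged
#'   channels x bins matrices for both conditions, aligned to the common
#'   `channels` and `freqs`, plus `subjects`.
#' @export
pair_spectra <- function(motion, rest) {
  sid <- function(lst) vapply(lst, function(e) e$infant_id, "")
  names(motion) <- sid(motion)
  names(rest) <- sid(rest)
  subjects <- intersect(names(motion), names(rest))
  # a subject contributes only with >= 1 epoch in both conditions
  subjects <- subjects[vapply(subjects, function(s) {
    dim(motion[[s]]$pow)[1] > 0 && dim(rest[[s]]$pow)[1] > 0
  }, TRUE)]
  if (length(subjects) < 2) {
    stop("paired comparison needs at least 2 subjects with both conditions",
         call. = FALSE)
  }
  freqs <- motion[[subjects[1]]]$freqs
  channels <- Reduce(intersect, c(
    lapply(motion[subjects], function(e) e$channels),
    lapply(rest[subjects], function(e) e$channels)
  ))
  if (length(channels) == 0) stop("no common retained channels",
                                  call. = FALSE)
  take <- function(e) {
    stopifnot(isTRUE(all.equal(e$freqs, freqs)))
    e$pow[, match(channels, e$channels), , drop = FALSE]
  }
  motion_ep <- lapply(motion[subjects], take)
  rest_ep <- lapply(rest[subjects], take)
  avg <- function(a) {
    out <- apply(a, c(2, 3), mean)
    dimnames(out) <- list(channels, freqs)
    out
  }
  structure(
    list(subjects = subjects, channels = channels, freqs = freqs,
         motion_epochs = motion_ep, rest_epochs = rest_ep,
         motion = lapply(motion_ep, avg), rest = lapply(rest_ep, avg)),
    class = "paired_spectra"
  )
}

# subjects x (channels*bins) matrix of paired differences (motion - rest)
.difference_matrix <- function(ps) {
  t(vapply(ps$subjects, function(s) as.vector(ps$motion[[s]] - ps$rest[[s]]),
           numeric(length(ps$channels) * length(ps$freqs))))
}

# paired t over rows of the difference matrix; zero-variance points -> 0
.t_from_diff <- function(d_mat, warn = FALSE) {
  n <- nrow(d_mat)
  m <- colMeans(d_mat)
  v <- (colSums(d_mat^2) - n * m^2) / (n - 1)
  zero <- v <= max(v, 1) * 1e-14
  if (warn && any(zero & m != 0)) {
    warning(sprintf(
      "%d point(s) with zero variance of differences; statistic set to 0",
      sum(zero & m != 0)))
  }
  t_stat <- m / sqrt(v / n)
  t_stat[zero] <- 0
  t_stat
}

#' Pointwise paired t-statistic map
#'
#' Dependent-samples t across subjects of (motion - rest) at every
#' (channel, bin) point, n - 1 degrees of freedom. Points with zero
#' variance of the differences cannot seed a cluster and get statistic 0
#' (with a warning).
#'
#' @param ps A `paired_spectra`.
#' @return A channels x bins matrix of t values.
#' @export
pointwise_paired_t <- function(ps) {
  t_flat <- .t_from_diff(.difference_matrix(ps), warn = TRUE)
  matrix(t_flat, length(ps$channels), length(ps$freqs),
         dimnames = list(ps$channels, ps$freqs))
}

# integer adjacency (channel index -> neighbor channel indices) for a label set
.neighbor_index <- function(neighbors, channels) {
  adjacency <- attr(neighbors, "adjacency")
  lapply(channels, function(ch) {
    which(channels %in% adjacency[[ch]])
  })
}

# Flood-fill clustering over the flattened t map. Points p = (f-1)*C + c.
# Connectivity: same bin + neighboring channels, or same channel +
# adjacent bin, within one sign. Returns list of integer point vectors.
.connected_components <- function(supra_idx, n_ch, nb_idx) {
  comp <- list()
  if (length(supra_idx) == 0) return(comp)
  member <- integer(max(supra_idx))
  member[supra_idx] <- 1L
  visited <- logical(max(supra_idx))
  for (p0 in supra_idx) {
    if (visited[p0]) next
    queue <- p0
    visited[p0] <- TRUE
    pts <- integer(0)
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pts <- c(pts, p)
      c_i <- ((p - 1L) %% n_ch) + 1L
      f_i <- ((p - 1L) %/% n_ch) + 1L
      cand <- c(
        (f_i - 1L) * n_ch + nb_idx[[c_i]],       # sensor neighbors, same bin
        p - n_ch, p + n_ch                       # adjacent bins, same channel
      )
      cand <- cand[cand >= 1L & cand <= length(member)]
      cand <- cand[member[cand] == 1L & !visited[cand]]
      visited[cand] <- TRUE
      queue <- c(queue, cand)
    }
    comp[[length(comp) + 1L]] <- pts
  }
  comp
}

#' Form signed clusters from a statistic map
#'
#' Thresholds the map at `+/- threshold`, groups supra-threshold points of
#' equal sign by connectivity (sensor neighbors within a bin, adjacent bins
#' within a sensor), and discards clusters spanning fewer than
#' `min_sensors` distinct channels.
#'
#' @param stat_map Channels x bins matrix (rows named by channel).
#' @param threshold Cluster-forming threshold on |t| (> 0).
#' @param neighbors A `neighbor_graph`.
#' @param min_sensors Minimum distinct channels per cluster (default 3).
#' @return A tibble with one row per cluster: `sign`, `mass`, `n_points`,
#'   `n_sensors`, and list-columns `channel` and `freq` of member points.
#' @export
form_clusters <- function(stat_map, threshold, neighbors, min_sensors = 3) {
  stopifnot(threshold > 0)
  channels <- rownames(stat_map)
  freqs <- as.numeric(colnames(stat_map))
  nb_idx <- .neighbor_index(neighbors, channels)
  n_ch <- nrow(stat_map)
  t_flat <- as.vector(stat_map)
  rows <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * t_flat > threshold)
    for (pts in .connected_components(supra, n_ch, nb_idx)) {
      ch_i <- ((pts - 1L) %% n_ch) + 1L
      if (length(unique(ch_i)) < min_sensors) next
      f_i <- ((pts - 1L) %/% n_ch) + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sign = sgn,
        mass = sum(t_flat[pts]),
        n_points = length(pts),
        n_sensors = length(unique(ch_i)),
        channel = list(channels[ch_i]),
        freq = list(freqs[f_i]),
        point_stat = list(t_flat[pts])
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      sign = numeric(0), mass = numeric(0), n_points = integer(0),
      n_sensors = integer(0), channel = list(), freq = list(),
      point_stat = list()
    ))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(abs(.data$mass)))
}

# max |cluster mass| of one flattened t map (0 when no qualifying cluster)
.max_cluster_mass <- function(t_flat, threshold, n_ch, nb_idx, min_sensors) {
  best <- 0
  for (sgn in c(1, -1)) {
    supra <- which(sgn * t_flat > threshold)
    if (length(supra) == 0) next
    for (pts in .connected_components(supra, n_ch, nb_idx)) {
      ch_i <- ((pts - 1L) %% n_ch) + 1L
      if (length(unique(ch_i)) < min_sensors) next
      best <- max(best, abs(sum(t_flat[pts])))
    }
  }
  best
}

#' Permutation null distribution of the maximum cluster mass
#'
#' Each cycle flips the sign of every subject's (motion - rest) difference
#' independently (the within-subject condition exchange), recomputes the
#' paired-t map and its clusters, and records the maximum absolute cluster
#' mass (0 if no qualifying cluster). With `exact = "auto"` (default) all
#' `2^n` sign patterns are enumerated whenever the subject count is at most
#' 13 and `2^n <= n_perm`; otherwise `n_perm` random sign vectors are drawn.
#'
#' @param ps A `paired_spectra`.
#' @param n_perm Number of Monte-Carlo cycles (default 10000; fewer than
#'   100 triggers a warning).
#' @param threshold Cluster-forming threshold on |t|; default the
#'   two-tailed paired-t critical value at `cluster_alpha` with n - 1 df.
#' @param neighbors A `neighbor_graph`.
#' @param min_sensors Minimum distinct channels per cluster.
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param exact `"auto"`, `"never"` or `"always"` (exhaustive sign-pattern
#'   enumeration).
#' @param cluster_alpha Point-level alpha defining the default threshold.
#' @return A list: `null` (vector of max |mass| values), `exact` (logical),
#'   `n_perm` (effective cycle count), `threshold`.
#' @export
permutation_null <- function(ps, n_perm = 10000, threshold = NULL,
                             neighbors, min_sensors = 3, seed = 1,
                             exact = c("auto", "never", "always"),
                             cluster_alpha = 0.05) {
  exact <- match.arg(exact)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value grid")
  d_mat <- .difference_matrix(ps)
  n <- nrow(d_mat)
  if (is.null(threshold)) {
    threshold <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  }
  use_exact <- switch(exact,
    always = TRUE,
    never = FALSE,
    auto = n <= 13 && 2^n <= n_perm
  )
  n_ch <- length(ps$channels)
  nb_idx <- .neighbor_index(neighbors, ps$channels)
  s2 <- colSums(d_mat^2)
  scale_zero <- max(s2 / (n - 1), 1) * 1e-14

  if (use_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    rng <- local({set.seed(seed); matrix(sample(c(-1, 1), n_perm * n,
                                                replace = TRUE),
                                         n_perm, n)})
    signs <- rng
  }
  m_all <- (signs %*% d_mat) / n
  null <- numeric(nrow(signs))
  for (i in seq_len(nrow(signs))) {
    m <- m_all[i, ]
    v <- (s2 - n * m^2) / (n - 1)
    t_flat <- m / sqrt(v / n)
    t_flat[v <= scale_zero] <- 0
    null[i] <- .max_cluster_mass(t_flat, threshold, n_ch, nb_idx,
                                 min_sensors)
  }
  list(null = null, exact = use_exact, n_perm = nrow(signs),
       threshold = threshold)
}

#' Monte-Carlo cluster p-values
#'
#' For each observed cluster, `p = (1 + #\{null >= |mass|\}) / (1 + n_perm)`
#' under Monte-Carlo sampling (the add-one estimator, so p > 0), or the
#' plain exceedance fraction over all enumerated sign patterns in exact
#' mode (the identity pattern guarantees p > 0 there). A cluster of either
#' sign is significant iff `p <= alpha`: the single max-|mass| reference
#' distribution delivers two-tailed family-wise control at `alpha`.
#'
#' @param clusters Tibble from [form_clusters()].
#' @param null Result of [permutation_null()].
#' @param alpha Two-tailed significance level (default 0.05).
#' @return A `cluster_result`: the cluster tibble gains `p`,
#'   `significant`, and `peak_freq_hz` (bin with the largest summed
#'   |statistic| over the cluster's member channels).
#' @export
cluster_pvalues <- function(clusters, null, alpha = 0.05) {
  p <- vapply(clusters$mass, function(mass) {
    if (mass == 0) return(1)
    # tolerance so the identity pattern's own mass counts as an exceedance
    k <- sum(null$null >= abs(mass) * (1 - 1e-10))
    if (null$exact) k / null$n_perm else (1 + k) / (1 + null$n_perm)
  }, 0)
  peak <- vapply(seq_len(nrow(clusters)), function(i) {
    f <- clusters$freq[[i]]
    s <- abs(clusters$point_stat[[i]])
    sums <- tapply(s, f, sum)
    as.numeric(names(sums)[which.max(sums)])
  }, 0)
  out <- dplyr::mutate(clusters, p = p,
                       significant = p <= alpha,
                       peak_freq_hz = peak)
  structure(
    list(clusters = out, n_perm = null$n_perm, exact = null$exact,
         alpha = alpha, threshold = null$threshold, null = null$null),
    class = "cluster_result"
  )
}

#' Run the full cluster permutation test
#'
#' Convenience wrapper: statistic map, cluster formation, permutation null,
#' p-values.
#'
#' @inheritParams permutation_null
#' @param alpha Two-tailed significance level.
#' @return A `cluster_result` (see [cluster_pvalues()]); also carries the
#'   observed `stat_map`, `subjects`, `channels` and `freqs`.
#' @export
cluster_test <- function(ps, neighbors, n_perm = 10000, threshold = NULL,
                         min_sensors = 3, alpha = 0.05, seed = 1,
                         exact = c("auto", "never", "always")) {
  stat_map <- pointwise_paired_t(ps)
  null <- permutation_null(ps, n_perm = n_perm, threshold = threshold,
                           neighbors = neighbors, min_sensors = min_sensors,
                           seed = seed, exact = exact)
  clusters <- form_clusters(stat_map, null$threshold, neighbors,
                            min_sensors)
  res <- cluster_pvalues(clusters, null, alpha)
  res$stat_map <- stat_map
  res$subjects <- ps$subjects
  res$channels <- ps$channels
  res$freqs <- ps$freqs
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d subjects, %d x %d map, %s null (%d cycles), alpha %g\n",
    length(x$subjects), length(x$channels), length(x$freqs),
    if (x$exact) "exact" else "Monte-Carlo", x$n_perm, x$alpha))
  cl <- x$clusters
  if (nrow(cl) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(cl))) {
      cat(sprintf(
        "  %s cluster: mass %8.2f, %2d sensors, peak %g Hz, p = %.4g%s\n",
        if (cl$sign[i] > 0) "positive" else "negative", cl$mass[i],
        cl$n_sensors[i], cl$peak_freq_hz[i], cl$p[i],
        if (cl$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

#' Stratified rerun equating data quantity across conditions
#'
#' Per subject, the condition with more epochs is randomly subsampled
#' (without replacement) to the other condition's epoch count before
#' spectral averaging, removing duration imbalance; the full test is then
#' rerun on the stratified spectra. Both results are returned side by side.
#'
#' @param ps A `paired_spectra` (epoch-level data retained).
#' @param neighbors A `neighbor_graph`.
#' @param seed Integer seed (drives the subsample and both permutation
#'   runs).
#' @param ... Passed on to [cluster_test()].
#' @return A list with elements `full` and `stratified`, both
#'   `cluster_result`s, plus `epoch_counts` (tibble per subject).
#' @export
stratified_rerun <- function(ps, neighbors, seed = 1, ...) {
  full <- cluster_test(ps, neighbors, seed = seed, ...)
  counts <- tibble::tibble(
    subject = ps$subjects,
    n_motion = vapply(ps$motion_epochs, function(a) dim(a)[1], 0L),
    n_rest = vapply(ps$rest_epochs, function(a) dim(a)[1], 0L)
  )
  set.seed(seed)
  strat <- ps
  for (s in ps$subjects) {
    k <- min(dim(ps$motion_epochs[[s]])[1], dim(ps$rest_epochs[[s]])[1])
    for (cond in c("motion_epochs", "rest_epochs")) {
      a <- ps[[cond]][[s]]
      if (dim(a)[1] > k) {
        sel <- sort(sample.int(dim(a)[1], k))
        strat[[cond]][[s]] <- a[sel, , , drop = FALSE]
      }
    }
  }
  reavg <- function(a) {
    out <- apply(a, c(2, 3), mean)
    dimnames(out) <- list(ps$channels, ps$freqs)
    out
  }
  strat$motion <- lapply(strat$motion_epochs, reavg)
  strat$rest <- lapply(strat$rest_epochs, reavg)
  stratified <- cluster_test(strat, neighbors, seed = seed, ...)
  list(full = full, stratified = stratified, epoch_counts = counts)
}
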