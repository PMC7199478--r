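#' End-to-end analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate annotations -> preprocess ->
#' spectra -> cluster tests -> report as one seeded, reproducible run.
#'
#' @name pipeline
NULL

#' Run the full motion-artifact characterization pipeline
#'
#' Stages, in fixed order, for each infant: bad-channel rejection, average
#' re-referencing, per-condition segment extraction and concatenation,
#' amplitude cleaning, 1-s epoching; then z-normalized FFT topographies
#' (grand-averaged across infants) and DPSS multitaper spectra feeding one
#' within-subject cluster permutation test per motion type against rest.
#' Infants lacking a condition are non-contributors for it; comparisons
#' with fewer than 2 contributing subjects are skipped with a note.
#'
#' @param cohort A `synthetic_cohort`, or a list with elements
#'   `recordings` (list of `eeg_recording`) and `annotations` (tibble).
#' @param montage An `eeg_montage`.
#' @param neighbors A `neighbor_graph` (default built from `montage`).
#' @param n_perm Permutation cycles per comparison (default 10000).
#' @param seed Integer seed for permutation draws.
#' @param amp_threshold,fraction Bad-channel rejection parameters.
#' @param p2p_threshold Amplitude-cleaning peak-to-peak threshold (uV).
#' @param min_sensors,alpha Cluster test parameters.
#' @param stratify Also rerun each comparison on duration-equated
#'   (epoch-subsampled) data.
#' @return A list of class `squirm_report`: `rejected_channels` (tibble),
#'   `durations` (per-infant and summary tibbles of clean epoched
#'   seconds), `grand_averages` (per condition), `band_maps` (tibble),
#'   `cluster_results` (per motion type; each a `cluster_result` or a
#'   skip note), `stratified` (optional), `config`/`seed` provenance.
#' @export
run_pipeline <- function(cohort, montage = build_montage(),
                         neighbors = build_neighbors(montage),
                         n_perm = 10000, seed = 1,
                         amp_threshold = 100, fraction = 0.25,
                         p2p_threshold = 200, min_sensors = 3,
                         alpha = 0.05, stratify = FALSE) {
  events <- validate_events(cohort$annotations)
  conditions <- all_conditions()

  fftpow <- list()
  mtpow <- list()
  rejected <- list()
  dur_rows <- list()
  for (rec in cohort$recordings) {
    rec <- reject_noisy_channels(rec, amp_threshold, fraction)
    rejected[[rec$infant_id]] <- tibble::tibble(
      infant_id = rec$infant_id,
      rejected = paste(rec$labels[!rec$retained], collapse = ", ")
    )
    rec <- rereference_average(rec)
    for (cond in conditions) {
      cd <- extract_concatenate(rec, events, cond)
      if (ncol(cd$data) == 0) next
      cd <- clean_amplitude(cd, p2p_threshold)
      cd <- epoch_1s(cd)
      n_ep <- dim(cd$epochs)[1]
      if (n_ep == 0) next
      dur_rows[[length(dur_rows) + 1L]] <- tibble::tibble(
        infant_id = rec$infant_id, condition = cond, total_s = n_ep)
      if (n_ep >= 2) {
        fftpow[[cond]][[rec$infant_id]] <- fft_power(cd)
        mtpow[[cond]][[rec$infant_id]] <- multitaper_psd(cd)
      }
    }
  }

  per_infant <- dplyr::bind_rows(dur_rows)
  durations <- list(
    per_infant = per_infant,
    summary = per_infant |>
      dplyr::mutate(condition = factor(.data$condition,
                                       levels = conditions)) |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        mean_s = mean(.data$total_s),
        sd_s = if (dplyr::n() > 1) stats::sd(.data$total_s) else NA_real_,
        n_contributing = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(condition = as.character(.data$condition))
  )

  grand_averages <- list()
  for (cond in names(fftpow)) {
    zs <- lapply(fftpow[[cond]], znormalize)
    grand_averages[[cond]] <- grand_average(zs)
  }
  band_maps <- purrr::imap_dfr(grand_averages, function(ga, cond) {
    dplyr::mutate(band_topography(ga), condition = cond, .before = 1)
  })

  cluster_results <- list()
  stratified <- if (stratify) list() else NULL
  for (type in motion_conditions()) {
    if (is.null(mtpow[[type]])) {
      cluster_results[[type]] <- paste0("skipped: no infant contributed ",
                                        "usable '", type, "' epochs")
      next
    }
    common <- intersect(names(mtpow[[type]]), names(mtpow[["rest"]]))
    if (length(common) < 2) {
      cluster_results[[type]] <- paste0(
        "skipped: fewer than 2 subjects with both '", type, "' and rest")
      next
    }
    ps <- pair_spectra(mtpow[[type]][common], mtpow[["rest"]][common])
    if (stratify) {
      both <- stratified_rerun(ps, neighbors, seed = seed, n_perm = n_perm,
                               min_sensors = min_sensors, alpha = alpha)
      cluster_results[[type]] <- both$full
      stratified[[type]] <- both$stratified
    } else {
      cluster_results[[type]] <- cluster_test(
        ps, neighbors, n_perm = n_perm, min_sensors = min_sensors,
        alpha = alpha, seed = seed)
    }
  }

  structure(
    list(rejected_channels = dplyr::bind_rows(rejected),
         durations = durations,
         grand_averages = grand_averages,
         band_maps = band_maps,
         cluster_results = cluster_results,
         stratified = stratified,
         seed = seed, n_perm = n_perm,
         config = if (inherits(cohort, "synthetic_cohort")) cohort$config),
    class = "squirm_report"
  )
}

#' @export
print.squirm_report <- function(x, ...) {
  cat(sprintf("<squirm_report> %d infants, %d comparisons (seed %d)\n",
              nrow(x$rejected_channels), length(x$cluster_results), x$seed))
  for (type in names(x$cluster_results)) {
    res <- x$cluster_results[[type]]
    if (is.character(res)) {
      cat(sprintf("  %-5s %s\n", type, res))
    } else {
      sig <- res$clusters[res$clusters$significant, , drop = FALSE]
      cat(sprintf("  %-5s vs rest: %d cluster(s), %d significant%s\n",
                  type, nrow(res$clusters), nrow(sig),
                  if (nrow(sig) > 0) sprintf(
                    " (top: %s, peak %g Hz, p = %.4g)",
                    if (sig$sign[1] > 0) "increase" else "decrease",
                    sig$peak_freq_hz[1], sig$p[1]) else ""))
    }
  }
  invisible(x)
}

#' Report tables in the published shapes
#'
#' Emits the rejected-channels table (one row per infant, dash when
#' nothing was rejected) and the clean-durations table (infants x
#' conditions with an `Average(SD)` summary row). With `out_dir` set, both
#' are also written as CSV.
#'
#' @param report A `squirm_report`.
#' @param out_dir Optional output directory.
#' @return A list of tibbles `rejected` and `durations`.
#' @export
report_tables <- function(report, out_dir = NULL) {
  rejected <- dplyr::mutate(
    report$rejected_channels,
    rejected = ifelse(.data$rejected == "", "-", .data$rejected))
  durations <- duration_table(report$durations)
  durations[is.na(durations)] <- "-"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(rejected, file.path(out_dir, "rejected_channels.csv"))
    readr::write_csv(durations, file.path(out_dir, "durations.csv"))
  }
  list(rejected = rejected, durations = durations)
}
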