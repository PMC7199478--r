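#' Video-coded annotations
#'
#' Annotations are plain tibbles with columns `infant_id`, `label` (one of
#' `rest`, `jaw`, `hand`, `arm`, `foot`, `leg`), `onset_s`, `offset_s`.
#' Onsets and offsets are quantized to the 1/30 s video-frame grid, the
#' synchronization resolution of video-coded EEG. Motion-condition labels in
#' the canonical order.
#'
#' @name annotations
NULL

#' @rdname annotations
#' @export
motion_conditions <- function() c("jaw", "hand", "arm", "foot", "leg")

#' @rdname annotations
#' @export
all_conditions <- function() c("rest", motion_conditions())

VIDEO_FRAME_S <- 1 / 30

.check_events_frame <- function(events) {
  req <- c("infant_id", "label", "onset_s", "offset_s")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(events$label), all_conditions())
  if (length(bad) > 0) {
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$offset_s <= events$onset_s)) {
    stop("annotation events must have offset_s > onset_s", call. = FALSE)
  }
  invisible(events)
}

#' Quantize event times to the video frame grid
#'
#' Rounds onsets/offsets to the nearest 1/30 s frame, the temporal
#' resolution of manual video-EEG synchronization (30 fps, 33 ms).
#'
#' @param events Annotation tibble.
#' @return The tibble with quantized `onset_s` / `offset_s`.
#' @export
quantize_events <- function(events) {
  dplyr::mutate(
    events,
    onset_s = round(.data$onset_s / VIDEO_FRAME_S) * VIDEO_FRAME_S,
    offset_s = round(.data$offset_s / VIDEO_FRAME_S) * VIDEO_FRAME_S
  )
}

#' Apply the inclusion criteria to coded events
#'
#' Implements the segment inclusion rules applied before any EEG analysis:
#' * motion events must last strictly longer than `min_motion_s`
#'   (default 0.25 s);
#' * rest events must last at least `min_rest_s` (default 0.5 s);
#' * any pair of temporally overlapping motion events of different types is
#'   removed entirely (both events), because only unambiguous single-motion
#'   segments are analyzable;
#' * a rest event overlapping a motion event is a coding contradiction and
#'   raises an error rather than being silently resolved.
#'
#' Overlap is strict interval overlap (shared interior); abutting events
#' sharing only an endpoint do not overlap.
#'
#' @param events Annotation tibble (may cover several infants).
#' @param min_motion_s Minimum motion duration, exclusive bound (seconds).
#' @param min_rest_s Minimum rest duration, inclusive bound (seconds).
#' @return The filtered tibble, sorted by infant and onset. Idempotent.
#' @export
validate_events <- function(events, min_motion_s = 0.25, min_rest_s = 0.5) {
  .check_events_frame(events)
  events <- dplyr::arrange(events, .data$infant_id, .data$onset_s)
  dur <- events$offset_s - events$onset_s
  is_rest <- events$label == "rest"

  keep <- ifelse(is_rest, dur >= min_rest_s, dur > min_motion_s)
  events <- events[keep, , drop = FALSE]

  drop <- rep(FALSE, nrow(events))
  for (id in unique(events$infant_id)) {
    idx <- which(events$infant_id == id)
    ev <- events[idx, ]
    n <- nrow(ev)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (ev$onset_s[j] >= ev$offset_s[i]) break
        overlap <- min(ev$offset_s[i], ev$offset_s[j]) -
          max(ev$onset_s[i], ev$onset_s[j])
        if (overlap <= 0) next
        ri <- ev$label[i] == "rest"
        rj <- ev$label[j] == "rest"
        if (xor(ri, rj)) {
          stop(sprintf(
            paste0("coding contradiction for infant %s: rest overlaps ",
                   "motion in [%.3f, %.3f] s"),
            ev$infant_id[i], max(ev$onset_s[i], ev$onset_s[j]),
            min(ev$offset_s[i], ev$offset_s[j])), call. = FALSE)
        }
        if (!ri && !rj) {
          drop[idx[i]] <- TRUE
          drop[idx[j]] <- TRUE
        }
      }
    }
  }
  events[!drop, , drop = FALSE]
}

#' Aggregate clean durations per infant and condition
#'
#' Totals event durations per (infant, condition), then summarizes each
#' condition over the infants that contributed any data to it: mean, sample
#' standard deviation (n - 1 denominator; reported as NA when only one
#' infant contributed), and the contributor count. Infants without a given
#' condition are non-contributors for it and are excluded from that
#' condition's mean/SD, mirroring how sparse spontaneous-motion tables are
#' summarized.
#'
#' @param events Validated annotation tibble.
#' @return A list with two tibbles: `per_infant` (`infant_id`, `condition`,
#'   `total_s` for every observed infant x condition with nonzero total) and
#'   `summary` (`condition`, `mean_s`, `sd_s`, `n_contributing`).
#' @export
aggregate_durations <- function(events) {
  .check_events_frame(events)
  if (nrow(events) == 0) {
    stop("no annotation events to aggregate", call. = FALSE)
  }
  per_infant <- events |>
    dplyr::mutate(duration = .data$offset_s - .data$onset_s) |>
    dplyr::group_by(.data$infant_id, condition = .data$label) |>
    dplyr::summarise(total_s = sum(.data$duration), .groups = "drop") |>
    dplyr::filter(.data$total_s > 0)

  summary <- per_infant |>
    dplyr::mutate(
      condition = factor(.data$condition, levels = all_conditions())
    ) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_s = mean(.data$total_s),
      sd_s = if (dplyr::n() > 1) stats::sd(.data$total_s) else NA_real_,
      n_contributing = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition) |>
    dplyr::mutate(condition = as.character(.data$condition))

  list(per_infant = per_infant, summary = summary)
}

#' Read / write annotation tables
#'
#' CSV dialect: header `infant_id,label,onset_s,offset_s`, UTF-8, `.`
#' decimal separator. Reading validates structure (labels, offset > onset)
#' and reports the offending line on failure.
#'
#' @param events Annotation tibble.
#' @param path File path.
#' @return `read_annotations` returns the annotation tibble;
#'   `write_annotations` returns `path` invisibly.
#' @export
write_annotations <- function(events, path) {
  .check_events_frame(events)
  readr::write_csv(events[, c("infant_id", "label", "onset_s", "offset_s")],
                   path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  events <- readr::read_csv(path, col_types = readr::cols(
    infant_id = readr::col_character(),
    label = readr::col_character(),
    onset_s = readr::col_double(),
    offset_s = readr::col_double()
  ), progress = FALSE)
  prob <- readr::problems(events)
  if (nrow(prob) > 0) {
    stop("malformed annotation file ", path, " at line ", prob$row[1] + 1,
         ": ", prob$expected[1], call. = FALSE)
  }
  bad_label <- which(!events$label %in% all_conditions())
  if (length(bad_label) > 0) {
    stop("malformed annotation file ", path, " at line ", bad_label[1] + 1,
         ": unknown label '", events$label[bad_label[1]], "'", call. = FALSE)
  }
  bad_time <- which(events$offset_s <= events$onset_s)
  if (length(bad_time) > 0) {
    stop("malformed annotation file ", path, " at line ", bad_time[1] + 1,
         ": offset_s <= onset_s", call. = FALSE)
  }
  events
}

#' Duration table in the published wide shape
#'
#' Pivots per-infant totals to an infants x conditions table with an
#' `Average(SD)` style summary row appended, and non-contributing cells
#' left as NA (rendered as dashes on export).
#'
#' @param durations Result of [aggregate_durations()].
#' @param digits Decimals for the summary row (default 1).
#' @return A tibble: one row per infant plus a final `Average(SD)` row.
#' @export
duration_table <- function(durations, digits = 1) {
  wide <- durations$per_infant |>
    dplyr::mutate(
      condition = factor(.data$condition, levels = all_conditions())
    ) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "total_s",
                       names_expand = TRUE) |>
    dplyr::arrange(.data$infant_id) |>
    dplyr::mutate(dplyr::across(-"infant_id", as.character))

  fmt <- function(m, s) {
    if (is.na(s)) return(sprintf("%.*f", digits, m))
    s_txt <- sub("\\.0+$", "", sprintf("%.*f", digits, s))
    sprintf("%.*f(%s)", digits, m, s_txt)
  }
  srow <- durations$summary
  summary_cells <- stats::setNames(
    mapply(fmt, srow$mean_s, srow$sd_s), srow$condition)
  out <- dplyr::bind_rows(
    wide,
    tibble::tibble(infant_id = "Average(SD)") |>
      dplyr::bind_cols(tibble::as_tibble_row(as.list(summary_cells)))
  )
  out
}
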