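# CSV interchange for tracks, events, segments and labels

check_columns <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0(what, " file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "courtsig_schema_error")
  }
  invisible(df)
}

#' Read / write two-fly pose tracks
#'
#' Tracks are stored as CSV with one row per (frame, fly, body part):
#' columns `frame`, `fly_id`, `part`, `x_mm`, `y_mm`, `confidence`.
#'
#' @param path file path.
#' @param frame_rate_hz frame rate to attach to the result.
#' @return `read_tracks`: a tibble with the `frame_rate_hz` attribute.
#' @export
read_tracks <- function(path, frame_rate_hz = 100) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("frame", "fly_id", "part", "x_mm", "y_mm", "confidence"),
                "tracks")
  df <- arrange(df, .data$frame, .data$fly_id, .data$part)
  attr(df, "frame_rate_hz") <- frame_rate_hz
  df
}

#' @rdname read_tracks
#' @param tracks tibble of tracks.
#' @export
write_tracks <- function(tracks, path) {
  check_columns(tracks, c("frame", "fly_id", "part", "x_mm", "y_mm", "confidence"),
                "tracks")
  readr::write_csv(tracks, path)
  invisible(path)
}

#' Read / write event and segment annotations
#'
#' Events are CSV with columns `time_s`, `event_type`; segments with
#' `onset_s`, `offset_s`, `seg_type`. Times are validated (finite,
#' nonnegative; offsets >= onsets; same-type segments non-overlapping)
#' and sorted on read.
#'
#' @param path file path.
#' @return A sorted, validated tibble.
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("time_s", "event_type"), "events")
  if (any(!is.finite(df$time_s)) || any(df$time_s < 0)) {
    abort("event times must be finite and nonnegative.",
          class = "courtsig_validation_error")
  }
  arrange(df, .data$time_s)
}

#' @rdname read_events
#' @param events events tibble.
#' @export
write_events <- function(events, path) {
  check_columns(events, c("time_s", "event_type"), "events")
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname read_events
#' @export
read_segments <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("onset_s", "offset_s", "seg_type"), "segments")
  if (any(!is.finite(df$onset_s)) || any(!is.finite(df$offset_s)) ||
      any(df$onset_s < 0) || any(df$offset_s < df$onset_s)) {
    abort("segment times must be finite, nonnegative, with offset >= onset.",
          class = "courtsig_validation_error")
  }
  df <- arrange(df, .data$onset_s)
  for (ty in unique(df$seg_type)) {
    sub <- df[df$seg_type == ty, ]
    if (nrow(sub) > 1 && any(sub$onset_s[-1] < sub$offset_s[-nrow(sub)])) {
      abort(paste0("overlapping segments of type ", ty, "."),
            class = "courtsig_validation_error")
    }
  }
  df
}

#' @rdname read_events
#' @param segments segments tibble.
#' @export
write_segments <- function(segments, path) {
  check_columns(segments, c("onset_s", "offset_s", "seg_type"), "segments")
  readr::write_csv(segments, path)
  invisible(path)
}

#' @rdname read_events
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("frame", "label"), "labels")
  mutate(arrange(df, .data$frame),
         label = factor(.data$label, levels = choice_classes()))
}

#' @rdname read_events
#' @param labels labels tibble (`frame`, `label`).
#' @export
write_labels <- function(labels, path) {
  check_columns(labels, c("frame", "label"), "labels")
  readr::write_csv(labels[c("frame", "label")], path)
  invisible(path)
}
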