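# interval-based pulse classification and train segmentation

#' Classify pulses into song vs vibration by inter-pulse interval
#'
#' Each pulse is typed by the intervals to its neighbors: song if a
#' neighbor interval falls in `song_range_ms` (the 30-45 ms inter-pulse
#' interval band of pulse song), vibration if one falls in `vib_range_ms`
#' (the 140-180 ms inter-vibration band), otherwise unclassified. When the
#' two neighbor intervals disagree, the tighter (shorter) interval wins,
#' which resolves ambiguity toward song. Isolated pulses have no interval
#' and stay unclassified.
#'
#' @param pulse_times_s sorted pulse times in seconds.
#' @param song_range_ms `(low, high)` song inter-pulse interval range, ms.
#' @param vib_range_ms `(low, high)` inter-vibration interval range, ms.
#' @return A tibble `time_s`, `event_type` with `event_type` one of
#'   `pulse_song`, `vibration`, `unclassified_pulse`.
#' @examples
#' classify_pulses(seq(0, 0.16, by = 0.04))
#' @export
classify_pulses <- function(pulse_times_s,
                            song_range_ms = c(30, 45),
                            vib_range_ms = c(140, 180)) {
  check_range(song_range_ms, "song_range_ms")
  check_range(vib_range_ms, "vib_range_ms")
  if (song_range_ms[2] > vib_range_ms[1] && vib_range_ms[2] > song_range_ms[1]) {
    abort("song and vibration interval ranges must be disjoint.",
          class = "courtsig_config_error")
  }
  t <- sort(pulse_times_s)
  n <- length(t)
  if (n == 0) return(tibble(time_s = numeric(), event_type = character()))
  iv <- diff(t) * 1000
  prev <- c(NA, iv)
  nxt <- c(iv, NA)
  in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  type_of <- function(x) {
    ifelse(in_range(x, song_range_ms), "pulse_song",
           ifelse(in_range(x, vib_range_ms), "vibration", NA))
  }
  tp <- type_of(prev)
  tn <- type_of(nxt)
  # tighter neighbor interval wins on disagreement; ties resolve to song
  pick <- ifelse(
    is.na(tp), tn,
    ifelse(is.na(tn), tp,
           ifelse(tp == tn, tp,
                  ifelse(prev < nxt, tp,
                         ifelse(nxt < prev, tn, "pulse_song")))))
  pick[is.na(pick)] <- "unclassified_pulse"
  tibble(time_s = t, event_type = pick)
}

#' Segment classified events into trains
#'
#' Groups maximal runs of same-type events whose consecutive gaps are below
#' a type-specific threshold (2-2.5 times the modal interval: 80 ms for
#' pulse song, 400 ms for vibration). A train's onset is its first event
#' and its offset the last.
#'
#' @param events tibble `time_s`, `event_type` as from [classify_pulses()].
#' @param gap_pulse_ms maximum within-train gap for song pulses, ms.
#' @param gap_vib_ms maximum within-train gap for vibrations, ms.
#' @return A tibble `onset_s`, `offset_s`, `seg_type`
#'   (`pulse_train`/`vibration_train`), `n_events`, ordered by onset.
#' @examples
#' ev <- classify_pulses(c(0, 0.04, 0.08, 0.5, 0.54))
#' segment_trains(ev)
#' @export
segment_trains <- function(events, gap_pulse_ms = 80, gap_vib_ms = 400) {
  gaps <- c(pulse_song = gap_pulse_ms, vibration = gap_vib_ms)
  out_type <- c(pulse_song = "pulse_train", vibration = "vibration_train")
  res <- map(names(gaps), function(ty) {
    t <- sort(events$time_s[events$event_type == ty])
    if (length(t) == 0) return(NULL)
    new_train <- c(TRUE, diff(t) * 1000 >= gaps[[ty]])
    id <- cumsum(new_train)
    tibble(
      onset_s = as.numeric(tapply(t, id, min)),
      offset_s = as.numeric(tapply(t, id, max)),
      seg_type = out_type[[ty]],
      n_events = as.integer(tapply(t, id, length))
    )
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(onset_s = numeric(), offset_s = numeric(),
                  seg_type = character(), n_events = integer()))
  }
  arrange(out, .data$onset_s)
}
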