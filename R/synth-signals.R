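# ground-truth-driven label sampling and pulse-event emission

#' Synthetic cue matrix of z-scored Gaussian series
#'
#' Generates independent standard-normal cue series (optionally smoothed and
#' re-standardized) on the analysis clock, as a controlled input for label
#' generation and model-recovery experiments.
#'
#' @param n_frames number of frames.
#' @param rate_hz analysis rate in Hz.
#' @param cue_names cue column names (default the 19 canonical cues).
#' @param seed integer seed.
#' @param smooth_s optional Gaussian smoothing sigma in seconds (0 = none).
#' @return A tibble with `frame`, `time_s` and one column per cue;
#'   attribute `rate_hz`.
#' @export
synth_cue_matrix <- function(n_frames, rate_hz = 50, cue_names = courtsig::cue_names(),
                             seed = 1, smooth_s = 0) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_frames * length(cue_names)), n_frames, length(cue_names))
  })
  if (smooth_s > 0) {
    m <- apply(m, 2, smooth_series, sigma_s = smooth_s, rate_hz = rate_hz)
    m <- scale(m)[, , drop = FALSE]
  }
  colnames(m) <- cue_names
  out <- as_tibble(m)
  out <- mutate(out, frame = seq_len(n_frames) - 1L,
                time_s = (seq_len(n_frames) - 1L) / rate_hz,
                .before = 1)
  attr(out, "rate_hz") <- rate_hz
  out
}

# linear predictors of a ground-truth model on a cue matrix: n x 3 matrix
ground_truth_eta <- function(cues, model) {
  missing <- setdiff(model$cue_names, names(cues))
  if (length(missing)) {
    abort(paste0("cue matrix lacks model cues: ", paste(missing, collapse = ", ")),
          class = "courtsig_schema_error")
  }
  n <- nrow(cues)
  L <- model$n_lags
  eta <- matrix(0, n, length(model$classes),
                dimnames = list(NULL, model$classes))
  for (cl in model$classes) {
    acc <- rep(model$intercepts[[cl]], n)
    fm <- model$filters[[cl]]
    for (j in seq_along(model$cue_names)) {
      f <- fm[, j]
      if (all(f == 0)) next
      # lag k contributes f[k] * cue[t - k]
      acc <- acc + as.numeric(stats::filter(cues[[model$cue_names[j]]],
                                            c(0, f), sides = 1))
    }
    eta[, cl] <- acc
  }
  eta[seq_len(min(L, n)), ] <- NA   # incomplete history
  eta
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' Sample per-frame signal labels from a ground-truth model
#'
#' For each frame, class probabilities are the softmax of the per-class
#' linear predictors (intercept plus the sum over cues and lags of filter
#' times cue history over the preceding window); the label is drawn from
#' that categorical distribution. Frames with incomplete history are
#' labeled `none` with zero stated probability mass elsewhere.
#'
#' @param cues cue matrix (tibble with the model's cue columns).
#' @param model a [ground_truth_glm()].
#' @param seed integer seed for the categorical draws.
#' @return A tibble `frame`, `label` (factor song/vibration/none), and the
#'   per-class probabilities `p_song`, `p_vibration`, `p_none`.
#' @export
sample_signals <- function(cues, model, seed = 1) {
  if (nrow(cues) <= model$n_lags) {
    abort("cue matrix must cover more than the lag window.",
          class = "courtsig_config_error")
  }
  eta <- ground_truth_eta(cues, model)
  p <- softmax_rows(eta)
  n <- nrow(p)
  withr::with_seed(seed, u <- runif(n))
  cum1 <- p[, 1]
  cum2 <- p[, 1] + p[, 2]
  lab <- ifelse(u < cum1, model$classes[1],
                ifelse(u < cum2, model$classes[2], model$classes[3]))
  incomplete <- is.na(eta[, 1])
  lab[incomplete] <- "none"
  p[incomplete, ] <- rep(c(0, 0, 1), each = sum(incomplete))
  tibble(
    frame = if ("frame" %in% names(cues)) cues$frame else seq_len(n) - 1L,
    label = factor(lab, levels = model$classes),
    p_song = p[, "song"], p_vibration = p[, "vibration"], p_none = p[, "none"]
  )
}

# contiguous spans of a given label: tibble(onset_idx, offset_idx) inclusive
label_spans <- function(lab, value) {
  r <- rle(as.character(lab) == value)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(onset_idx = starts[r$values], offset_idx = ends[r$values])
}

#' Emit pulse events from a per-frame label sequence
#'
#' Within each contiguous span labeled `song`, pulse events are placed at
#' intervals drawn uniformly from the configured song inter-pulse-interval
#' range; within `vibration` spans, from the inter-vibration-interval
#' range. No events are emitted in `none` spans.
#'
#' @param labels tibble with `frame` and `label` (as from
#'   [sample_signals()]), on the clock given by `rate_hz`.
#' @param config a [synth_config()] providing the interval ranges.
#' @param seed integer seed for the interval draws.
#' @param rate_hz frame rate of `labels`; defaults to the config's
#'   `frame_rate_hz`.
#' @return A tibble `time_s`, `event_type` (`pulse_song` / `vibration`),
#'   time-sorted.
#' @export
emit_pulse_events <- function(labels, config, seed = 1,
                              rate_hz = config$frame_rate_hz) {
  withr::with_seed(seed, {
    ev <- list(
      emit_spans(labels, "song", config$ipi_song_ms, rate_hz, "pulse_song"),
      emit_spans(labels, "vibration", config$ivi_vib_ms, rate_hz, "vibration")
    )
  })
  out <- bind_rows(ev)
  if (nrow(out) == 0) {
    return(tibble(time_s = numeric(), event_type = character()))
  }
  arrange(out, .data$time_s)
}

emit_spans <- function(labels, value, range_ms, rate_hz, type) {
  spans <- label_spans(labels$label, value)
  if (nrow(spans) == 0) return(NULL)
  t0_all <- (labels$frame[spans$onset_idx]) / rate_hz
  t1_all <- (labels$frame[spans$offset_idx]) / rate_hz
  times <- purrr::map2(t0_all, t1_all, function(t0, t1) {
    ts <- t0
    repeat {
      nxt <- ts[length(ts)] + runif(1, range_ms[1], range_ms[2]) / 1000
      if (nxt > t1) break
      ts <- c(ts, nxt)
    }
    ts
  })
  tibble(time_s = unlist(times), event_type = type)
}
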