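# fractions, overlap, transitions, trial/epoch probabilities, tests

#' Rasterize segments onto a frame clock
#'
#' @param segments tibble `onset_s`, `offset_s`, `seg_type`.
#' @param rate_hz frame rate of the raster.
#' @param n_frames number of frames (frame f covers time f/rate, 0-based).
#' @param types canonical signal types to rasterize (default: all present).
#' @return A tibble `frame`, `time_s`, one logical column per type.
#' @export
raster_segments <- function(segments, rate_hz, n_frames, types = NULL) {
  sig <- canonical_signal(segments$seg_type)
  if (is.null(types)) types <- setdiff(unique(sig), NA)
  t <- (seq_len(n_frames) - 1L) / rate_hz
  out <- tibble(frame = seq_len(n_frames) - 1L, time_s = t)
  for (ty in types) {
    on <- rep(FALSE, n_frames)
    rows <- which(sig == ty)
    for (i in rows) {
      i0 <- ceiling(segments$onset_s[i] * rate_hz - 1e-9) + 1L
      i1 <- floor(segments$offset_s[i] * rate_hz + 1e-9) + 1L
      if (i1 >= 1 && i0 <= n_frames) on[max(i0, 1):min(i1, n_frames)] <- TRUE
    }
    out[[ty]] <- on
  }
  out
}

#' Per-type signal fractions over masked frames
#'
#' Fraction of the masked (courtship) frames in which each signal type was
#' produced; `none` is the fraction of masked frames with no signal at all.
#' Because signals can overlap, the typed fractions plus `none` can exceed 1.
#'
#' @param segments tibble `onset_s`, `offset_s`, `seg_type`.
#' @param mask logical vector defining the denominator frames.
#' @param rate_hz frame rate of `mask`.
#' @return A tibble `signal`, `fraction`; attribute `undefined` is `TRUE`
#'   when the mask is empty.
#' @export
signal_fraction <- function(segments, mask, rate_hz) {
  types <- c("sine", "pulse", "vibration")
  ras <- raster_segments(segments, rate_hz, length(mask), types)
  denom <- sum(mask)
  any_sig <- ras$sine | ras$pulse | ras$vibration
  frac <- c(
    map_dbl(types, function(ty) sum(ras[[ty]] & mask) / denom),
    sum(!any_sig & mask) / denom
  )
  out <- tibble(signal = c(types, "none"), fraction = frac)
  attr(out, "undefined") <- denom == 0
  out
}

#' Overlap between two signal rasters
#'
#' Fraction of the frames covered by `a_segments` that are also covered by
#' `b_segments` (e.g. how much of the vibration time coincides with sine
#' song).
#'
#' @param a_segments,b_segments segment tibbles on a common clock.
#' @param rate_hz frame rate.
#' @param n_frames raster length; defaults to cover both sets.
#' @return A single number in `[0, 1]`; `NA` with attribute
#'   `undefined = TRUE` when `a_segments` cover no frames.
#' @export
overlap_fraction <- function(a_segments, b_segments, rate_hz, n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- ceiling(max(0, a_segments$offset_s, b_segments$offset_s) * rate_hz) + 1L
  }
  a <- raster_any(a_segments, rate_hz, n_frames)
  b <- raster_any(b_segments, rate_hz, n_frames)
  na <- sum(a)
  if (na == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  sum(a & b) / na
}

raster_any <- function(segments, rate_hz, n_frames) {
  if (nrow(segments) == 0) return(rep(FALSE, n_frames))
  ras <- raster_segments(segments, rate_hz, n_frames)
  cols <- setdiff(names(ras), c("frame", "time_s"))
  Reduce(`|`, ras[cols], rep(FALSE, n_frames))
}

#' Transition probabilities between signal trains
#'
#' Counts consecutive train-type pairs in onset order and row-normalizes to
#' the fraction of trains of one type followed by each other type. In
#' `"trains"` mode pauses are ignored regardless of duration (and
#' self-transitions counted). In `"sequence"` mode, pauses longer than
#' `pause_none_s` are inserted as a `none` state and self-transitions are
#' excluded.
#'
#' @param trains segment tibble from [segment_trains()] (optionally with
#'   sine segments appended), ordered or orderable by onset.
#' @param mode `"trains"` or `"sequence"`.
#' @param pause_none_s pause duration treated as "no signal" in sequence
#'   mode (default 0.5 s).
#' @return An object of class `courtsig_transitions`: list with `counts`
#'   and row-stochastic `P` (rows with zero counts are `NA` and listed in
#'   `undefined_rows`), `labels`, `mode`.
#' @export
transition_probabilities <- function(trains, mode = c("trains", "sequence"),
                                     pause_none_s = 0.5) {
  mode <- match.arg(mode)
  labels <- signal_levels()
  counts <- matrix(0L, 4, 4, dimnames = list(labels, labels))
  tr <- arrange(trains, .data$onset_s)
  sig <- canonical_signal(tr$seg_type)
  flagged <- nrow(tr) < 2
  if (!flagged) {
    seqv <- sig
    if (mode == "sequence") {
      gaps <- tr$onset_s[-1] - tr$offset_s[-nrow(tr)]
      seqv <- character(0)
      for (i in seq_along(sig)) {
        seqv <- c(seqv, sig[i])
        if (i < length(sig) && gaps[i] > pause_none_s) seqv <- c(seqv, "none")
      }
    }
    from <- seqv[-length(seqv)]
    to <- seqv[-1]
    if (mode == "sequence") {
      keep <- from != to
      from <- from[keep]; to <- to[keep]
    }
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, NA, rs)
  structure(
    list(counts = counts, P = P, labels = labels, mode = mode,
         undefined_rows = labels[rs == 0], empty = flagged),
    class = "courtsig_transitions"
  )
}

#' @param x a `courtsig_transitions` object.
#' @param ... unused.
#' @method tidy courtsig_transitions
#' @export
tidy.courtsig_transitions <- function(x, ...) {
  tibble(
    from = rep(x$labels, times = length(x$labels)),
    to = rep(x$labels, each = length(x$labels)),
    count = as.integer(t(x$counts)),
    probability = as.numeric(t(x$P))
  )
}

#' @method print courtsig_transitions
#' @export
print.courtsig_transitions <- function(x, ...) {
  cat("Signal transition matrix (", x$mode, " mode)\n", sep = "")
  print(round(x$P, 3))
  invisible(x)
}

#' Analysis epochs around a stimulus
#'
#' The four windows used to summarize signal probabilities relative to
#' optogenetic stimulus onset: before (-10-0 s), during (0-5 s), offset
#' (5-15 s) and after (15-35 s).
#'
#' @param before,during,offset,after `(start, end)` windows in seconds
#'   relative to stimulus onset.
#' @return A tibble `epoch`, `start_s`, `end_s`.
#' @export
trial_epochs <- function(before = c(-10, 0), during = c(0, 5),
                         offset = c(5, 15), after = c(15, 35)) {
  out <- tibble(
    epoch = factor(c("before", "during", "offset", "after"),
                   levels = c("before", "during", "offset", "after")),
    start_s = c(before[1], during[1], offset[1], after[1]),
    end_s = c(before[2], during[2], offset[2], after[2])
  )
  if (any(out$end_s <= out$start_s) || any(diff(out$start_s) < 0) ||
      any(out$start_s[-1] < out$end_s[-4])) {
    abort("epoch windows must be ordered and non-overlapping.",
          class = "courtsig_config_error")
  }
  out
}

#' Per-trial signal probabilities around stimulus onsets
#'
#' Aligns a signal raster to each stimulus onset and computes, per time
#' bin, the fraction of trials in which the signal was active, and per
#' epoch the per-trial probabilities (mean activity over epoch bins)
#' together with their across-trial mean. An optional courtship mask
#' restricts the evaluation to frames where the male courted.
#'
#' @param segments segment tibble (trains and/or sine segments).
#' @param stimulus_onsets_s stimulus onset times, seconds.
#' @param rate_hz frame rate of the raster.
#' @param window_s `(start, end)` analysis window around onset, seconds.
#' @param epochs epoch table from [trial_epochs()].
#' @param types canonical signal types to evaluate.
#' @param courtship optional logical vector on the global frame clock.
#' @param n_frames global raster length; defaults to cover window and data.
#' @return A list of class `courtsig_trials`: `bins` (tibble `time_rel_s`,
#'   `signal`, `probability`), `epochs` (per trial x epoch x signal),
#'   `epoch_summary` (across-trial means), `n_trials`.
#' @export
trial_probability <- function(segments, stimulus_onsets_s, rate_hz,
                              window_s = c(-10, 35), epochs = trial_epochs(),
                              types = c("pulse", "vibration", "sine"),
                              courtship = NULL, n_frames = NULL) {
  if (length(stimulus_onsets_s) == 0) {
    abort("no trials given.", class = "courtsig_config_error")
  }
  if (is.null(n_frames)) {
    n_frames <- ceiling((max(stimulus_onsets_s) + window_s[2]) * rate_hz) + 1L
    if (nrow(segments) > 0) {
      n_frames <- max(n_frames, ceiling(max(segments$offset_s) * rate_hz) + 1L)
    }
  }
  ras <- raster_segments(segments, rate_hz, n_frames, types)
  for (ty in setdiff(types, names(ras))) ras[[ty]] <- FALSE
  ras$any <- Reduce(`|`, ras[types], rep(FALSE, n_frames))
  use_types <- c(types, "any")
  rel <- as.integer(seq(round(window_s[1] * rate_hz), round(window_s[2] * rate_hz)))
  n_trials <- length(stimulus_onsets_s)
  trial_rows <- vapply(stimulus_onsets_s,
                       function(on) as.integer(round(on * rate_hz)) + 1L + rel,
                       integer(length(rel)))   # bins x trials
  valid_idx <- trial_rows >= 1 & trial_rows <= n_frames
  gate <- if (is.null(courtship)) rep(TRUE, n_frames) else courtship

  bins <- list(); ep <- list()
  for (ty in use_types) {
    v <- ras[[ty]]
    act <- matrix(NA, nrow(trial_rows), n_trials)
    act[valid_idx] <- v[trial_rows[valid_idx]]
    gt <- matrix(FALSE, nrow(trial_rows), n_trials)
    gt[valid_idx] <- gate[trial_rows[valid_idx]]
    act[!gt] <- NA
    bins[[ty]] <- tibble(time_rel_s = rel / rate_hz, signal = ty,
                         probability = rowMeans(act, na.rm = TRUE))
    for (k in seq_len(nrow(epochs))) {
      sel <- rel / rate_hz >= epochs$start_s[k] & rel / rate_hz < epochs$end_s[k]
      ep[[paste(ty, k)]] <- tibble(
        trial = seq_len(n_trials), epoch = epochs$epoch[k], signal = ty,
        probability = colMeans(act[sel, , drop = FALSE], na.rm = TRUE)
      )
    }
  }
  epochs_tb <- list_rbind(ep)
  summary_tb <- epochs_tb |>
    group_by(.data$epoch, .data$signal) |>
    summarise(probability = mean(.data$probability, na.rm = TRUE), .groups = "drop")
  structure(
    list(bins = list_rbind(bins), epochs = epochs_tb,
         epoch_summary = summary_tb, n_trials = n_trials),
    class = "courtsig_trials"
  )
}

#' Paired nonparametric test (Wilcoxon signed-rank)
#'
#' Exact distribution for n <= 25 with no zero differences or ties,
#' normal approximation with continuity correction otherwise. When all
#' differences are zero the test is undefined; the p-value is reported as
#' 1 and flagged degenerate.
#'
#' @param x,y paired samples of equal length.
#' @param alternative `"two-sided"`, `"less"` or `"greater"`.
#' @return A tibble `p_value`, `statistic`, `method`, `degenerate`.
#' @export
paired_test <- function(x, y, alternative = "two-sided") {
  alternative <- sub("two-sided", "two.sided", alternative)
  if (length(x) != length(y)) {
    abort("paired samples must have equal length.", class = "courtsig_config_error")
  }
  d <- x - y
  if (all(d == 0)) {
    return(tibble(p_value = 1, statistic = NA_real_,
                  method = "wilcoxon_signed_rank", degenerate = TRUE))
  }
  d_nz <- d[d != 0]
  exact <- length(d_nz) <= 25 && !any(duplicated(abs(d_nz)))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  tibble(p_value = res$p.value, statistic = unname(res$statistic),
         method = "wilcoxon_signed_rank", degenerate = FALSE)
}

#' Unpaired nonparametric test (Mann-Whitney U)
#'
#' Exact for both samples <= 25 without ties, normal approximation with
#' continuity correction otherwise. Ties are mid-ranked.
#'
#' @param x,y samples.
#' @param alternative `"two-sided"`, `"less"` or `"greater"`.
#' @return A tibble `p_value`, `statistic`, `method`, `degenerate`.
#' @export
unpaired_test <- function(x, y, alternative = "two-sided") {
  alternative <- sub("two-sided", "two.sided", alternative)
  exact <- length(x) <= 25 && length(y) <= 25 && !any(duplicated(c(x, y)))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  tibble(p_value = res$p.value, statistic = unname(res$statistic),
         method = "mann_whitney_u", degenerate = FALSE)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha familywise level (default 0.05).
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @examples
#' bonferroni(m = 5)  # 0.01
#' @export
bonferroni <- function(alpha = 0.05, m = 1) {
  check_positive(m, "m")
  alpha / m
}
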