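test_that("interval classification follows the song and vibration bands", {
  song <- classify_pulses(seq(0, by = 0.040, length.out = 5))
  expect_true(all(song$event_type == "pulse_song"))
  vib <- classify_pulses(seq(0, by = 0.160, length.out = 5))
  expect_true(all(vib$event_type == "vibration"))
  one <- classify_pulses(0.5)
  expect_identical(one$event_type, "unclassified_pulse")
  # out-of-band spacing stays unclassified
  odd <- classify_pulses(seq(0, by = 0.100, length.out = 4))
  expect_true(all(odd$event_type == "unclassified_pulse"))
  # disagreement resolves to the tighter neighbor interval
  mix <- classify_pulses(c(0, 0.04, 0.2))   # 40 ms then 160 ms
  expect_identical(mix$event_type, c("pulse_song", "pulse_song", "vibration"))
  expect_error(classify_pulses(c(0, 1), song_range_ms = c(30, 150)),
               class = "courtsig_config_error")
})

test_that("train segmentation matches the worked examples", {
  ev <- classify_pulses(c(0, 0.040, 0.080, 0.500, 0.540))
  tr <- segment_trains(ev)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$onset_s, c(0, 0.5))
  expect_equal(tr$offset_s, c(0.08, 0.54))
  expect_true(all(tr$seg_type == "pulse_train"))
  empty <- segment_trains(tibble::tibble(time_s = numeric(),
                                         event_type = character()))
  expect_equal(nrow(empty), 0)
})

test_that("segmentation equals the agglomerative oracle and is gap-monotone", {
  withr::with_seed(11, {
    for (i in 1:60) {
      n <- sample(2:120, 1)
      ev <- tibble::tibble(
        time_s = sort(runif(n, 0, 20)),
        event_type = sample(c("pulse_song", "vibration"), n, replace = TRUE)
      )
      got <- segment_trains(ev)
      ora <- oracle_trains(ev)
      expect_equal(got[c("onset_s", "offset_s", "seg_type")], ora)
      wider <- segment_trains(ev, gap_pulse_ms = 160, gap_vib_ms = 800)
      expect_lte(nrow(wider), nrow(got))
    }
  })
})

test_that("signal fractions equal direct frame counting", {
  rate <- 50
  mask <- rep(TRUE, 500)
  # one signal covering exactly half of the masked frames
  seg <- tibble::tibble(onset_s = 0, offset_s = 249 / rate, seg_type = "sine")
  fr <- signal_fraction(seg, mask, rate)
  expect_equal(fr$fraction[fr$signal == "sine"], 0.5)
  # no signals at all: none fraction 1
  fr0 <- signal_fraction(seg[0, ], mask, rate)
  expect_equal(fr0$fraction[fr0$signal == "none"], 1)
  expect_true(attr(signal_fraction(seg, rep(FALSE, 10), rate), "undefined"))
  withr::with_seed(21, {
    for (i in 1:20) {
      seg <- random_segments(sample(1:30, 1), 10)
      m <- runif(500) < 0.7
      got <- signal_fraction(seg, m, rate)
      ora <- oracle_fraction(seg, m, rate)
      expect_equal(setNames(got$fraction, got$signal), ora)
    }
  })
})

test_that("overlap fraction is a frame-set intersection ratio", {
  rate <- 50
  a <- tibble::tibble(onset_s = c(1, 3), offset_s = c(2, 4), seg_type = "vibration_train")
  expect_equal(overlap_fraction(a, a, rate), 1)
  b <- tibble::tibble(onset_s = 10, offset_s = 11, seg_type = "sine")
  expect_equal(overlap_fraction(a, b, rate), 0)
  expect_true(attr(overlap_fraction(a[0, ], b, rate), "undefined"))
  withr::with_seed(22, {
    for (i in 1:20) {
      sa <- random_segments(sample(1:20, 1), 10)
      sb <- random_segments(sample(1:20, 1), 10)
      n <- 10 * rate + 1
      fa <- function(s) {
        t <- (seq_len(n) - 1) / rate
        out <- rep(FALSE, n)
        for (j in seq_len(nrow(s))) {
          out <- out | (t >= s$onset_s[j] - 1e-9 & t <= s$offset_s[j] + 1e-9)
        }
        out
      }
      ora <- sum(fa(sa) & fa(sb)) / sum(fa(sa))
      expect_equal(as.numeric(overlap_fraction(sa, sb, rate, n)), ora)
    }
  })
})

test_that("transition matrices are row-stochastic and match hand counting", {
  # alternating pulse and sine trains
  alt <- tibble::tibble(
    onset_s = seq(0, by = 2, length.out = 8),
    offset_s = seq(0, by = 2, length.out = 8) + 1,
    seg_type = rep(c("pulse_train", "sine"), 4)
  )
  tm <- transition_probabilities(alt)
  expect_equal(tm$P["pulse", "sine"], 1)
  expect_equal(tm$P["sine", "pulse"], 1)
  # single-type sequence: diagonal row
  solo <- dplyr::mutate(alt, seg_type = "vibration_train")
  tms <- transition_probabilities(solo)
  expect_equal(tms$P["vibration", "vibration"], 1)
  # fewer than two trains: flagged empty
  expect_true(transition_probabilities(alt[1, ])$empty)
  # random sequences: counts equal a hand-count oracle; rows sum to one
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(2:60, 1)
      on <- cumsum(runif(n, 0.1, 2))
      tr <- tibble::tibble(onset_s = on, offset_s = on + 0.05,
                           seg_type = sample(c("pulse_train", "sine",
                                               "vibration_train"), n, TRUE))
      tm <- transition_probabilities(tr)
      lab <- courtsig:::canonical_signal(tr$seg_type)
      ora <- table(factor(lab[-n], levels = tm$labels),
                   factor(lab[-1], levels = tm$labels))
      expect_equal(unname(tm$counts), unname(as.matrix(unclass(ora))))
      rs <- rowSums(tm$P, na.rm = FALSE)
      expect_true(all(abs(rs[!is.na(rs)] - 1) < 1e-12))
    }
  })
})

test_that("sequence mode inserts no-signal pauses and drops self-transitions", {
  tr <- tibble::tibble(
    onset_s = c(0, 1.2, 1.5, 4),
    offset_s = c(1, 1.4, 2, 4.5),
    seg_type = c("pulse_train", "pulse_train", "sine", "sine")
  )
  tm <- transition_probabilities(tr, mode = "sequence", pause_none_s = 0.5)
  # pause 0->1.2 is short (0.2), 2->4 is long: pulse->pulse dropped (self),
  # pulse->sine kept, sine->none->sine becomes sine->none and none->sine
  expect_equal(tm$counts["pulse", "sine"], 1L)
  expect_equal(tm$counts["sine", "none"], 1L)
  expect_equal(tm$counts["none", "sine"], 1L)
  expect_equal(tm$counts["pulse", "pulse"], 0L)
})

test_that("trial probabilities match direct per-trial counting", {
  rate <- 50
  onsets <- c(20, 80, 140)
  seg <- tibble::tibble(onset_s = onsets, offset_s = onsets + 5,
                        seg_type = "vibration_train")
  tp <- trial_probability(seg, onsets, rate)
  s <- tp$epoch_summary
  expect_equal(s$probability[s$epoch == "during" & s$signal == "vibration"], 1)
  expect_equal(s$probability[s$epoch == "before" & s$signal == "vibration"], 0)
  # no signals: zero in all epochs
  tp0 <- trial_probability(seg[0, ], onsets, rate)
  expect_true(all(tp0$epoch_summary$probability == 0))
  expect_error(trial_probability(seg, numeric(0), rate),
               class = "courtsig_config_error")
  # random raster, 7 trials: equals direct counting
  withr::with_seed(24, {
    seg2 <- random_segments(40, 400, types = "vibration_train")
    on7 <- seq(50, 350, length.out = 7)
    tp2 <- trial_probability(seg2, on7, rate)
    n <- ceiling(400 * rate) + 1
    ras <- raster_segments(seg2, rate, n)$vibration
    rel <- seq(round(-10 * rate), round(35 * rate))
    ep <- trial_epochs()
    for (k in 1:4) {
      sel <- rel / rate >= ep$start_s[k] & rel / rate < ep$end_s[k]
      per_trial <- vapply(on7, function(o) {
        mean(ras[round(o * rate) + 1 + rel[sel]])
      }, numeric(1))
      got <- tp2$epochs
      got <- got$probability[got$epoch == ep$epoch[k] & got$signal == "vibration"]
      expect_equal(got, per_trial)
    }
  })
})

test_that("paired test matches exact enumeration at n = 6", {
  withr::with_seed(25, {
    for (i in 1:8) {
      x <- rnorm(6); y <- rnorm(6)
      for (alt in c("two-sided", "less", "greater")) {
        got <- paired_test(x, y, alt)$p_value
        ora <- oracle_signed_rank_p(x, y, sub("two-sided", "two.sided", alt))
        expect_equal(got, ora, tolerance = 1e-12,
                     label = paste("alt", alt, "rep", i))
      }
    }
  })
})

test_that("degenerate and large-sample test paths behave", {
  x <- c(1, 2, 3)
  r <- paired_test(x, x)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  expect_error(paired_test(1:3, 1:4), class = "courtsig_config_error")
  # large n switches to the normal approximation and still works
  withr::with_seed(26, {
    big <- paired_test(rnorm(40), rnorm(40))
    expect_true(big$p_value > 0 && big$p_value <= 1)
    u <- unpaired_test(rnorm(10), rnorm(10) + 2, "less")
    expect_lt(u$p_value, 0.05)
  })
})

test_that("bonferroni adjusts the familywise level", {
  expect_equal(bonferroni(m = 5), 0.01)
  expect_equal(bonferroni(alpha = 0.1, m = 4), 0.025)
})
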