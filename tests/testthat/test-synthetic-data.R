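test_that("generator is deterministic and respects the arena", {
  cfg <- synth_config(duration_s = 20, seed = 7)
  tr1 <- generate_tracks(cfg)
  tr2 <- generate_tracks(cfg)
  expect_identical(tr1, tr2)
  expect_true(all(sqrt(tr1$x_mm^2 + tr1$y_mm^2) <= cfg$arena_radius_mm + 2))
  expect_true(all(tr1$confidence >= 0 & tr1$confidence <= 1))
  tr3 <- generate_tracks(synth_config(duration_s = 20, seed = 8))
  expect_false(identical(tr1$x_mm, tr3$x_mm))
})

test_that("config validation rejects bad durations, rates and ranges", {
  expect_error(synth_config(duration_s = 0), class = "courtsig_config_error")
  expect_error(synth_config(frame_rate_hz = -1), class = "courtsig_config_error")
  expect_error(synth_config(ipi_song_ms = c(45, 30)), class = "courtsig_config_error")
  expect_error(synth_config(ipi_song_ms = c(100, 200), ivi_vib_ms = c(140, 180)),
               class = "courtsig_config_error")
})

test_that("female only stops when the stop process is on", {
  cfg <- synth_config(duration_s = 60, seed = 3, stationary_bout_rate = 0)
  cu <- extract_cues(generate_tracks(cfg))
  # no contiguous stationary bout longer than 1 s
  still <- rle(cu$female_velocity < 1e-9)
  expect_true(all(still$lengths[still$values] < attr(cu, "rate_hz")))
  cfg2 <- synth_config(duration_s = 60, seed = 3, stationary_bout_rate = 0.3)
  cu2 <- extract_cues(generate_tracks(cfg2))
  expect_gt(sum(cu2$female_velocity < 1e-6), sum(cu$female_velocity < 1e-6))
})

test_that("pursuit coupling makes male and female speeds correlate", {
  cu <- extract_cues(generate_tracks(synth_config(duration_s = 300, seed = 1)))
  expect_gt(cor(cu$male_velocity, cu$female_velocity), 0.3)
})

test_that("label sampling follows the ground-truth softmax", {
  nm <- cue_names()
  L <- 50
  zero <- matrix(0, L, length(nm), dimnames = list(NULL, nm))
  flat <- ground_truth_glm(nm, list(song = zero, vibration = zero, none = zero))
  cm <- synth_cue_matrix(1e5, seed = 4)
  lab <- sample_signals(cm, flat, seed = 5)
  freq <- table(lab$label[-(1:L)]) / (1e5 - L)
  expect_true(all(abs(freq - 1 / 3) < 0.01))

  # total-variation convergence to the per-frame softmax probabilities
  gt <- default_ground_truth()
  lab2 <- sample_signals(cm, gt, seed = 6)
  ok <- lab2$p_none < 1 | lab2$p_song > 0   # complete-history frames
  emp <- c(mean(lab2$label[-(1:L)] == "song"),
           mean(lab2$label[-(1:L)] == "vibration"),
           mean(lab2$label[-(1:L)] == "none"))
  thr <- c(mean(lab2$p_song[-(1:L)]), mean(lab2$p_vibration[-(1:L)]),
           mean(lab2$p_none[-(1:L)]))
  expect_lt(0.5 * sum(abs(emp - thr)), 0.02)
})

test_that("a strongly negative vibration filter concentrates vibration on low cue", {
  nm <- c("male_velocity", "distance")
  L <- 50
  zero <- matrix(0, L, 2, dimnames = list(NULL, nm))
  f <- list(song = zero, vibration = zero, none = zero)
  f$vibration[, "male_velocity"] <- -0.6      # strong negative flat filter
  f$song[, "male_velocity"] <- 0.3
  f$none[, "male_velocity"] <- 0.3
  gt <- ground_truth_glm(nm, f)
  cm <- synth_cue_matrix(4e4, cue_names = nm, seed = 8)
  lab <- sample_signals(cm, gt, seed = 9)
  trail <- as.numeric(stats::filter(cm$male_velocity, c(0, rep(1 / L, L)), sides = 1))
  vib <- which(lab$label == "vibration" & !is.na(trail))
  expect_gte(mean(trail[vib] < median(trail, na.rm = TRUE)), 0.8)
  # direct softmax check: sampled probabilities match manual evaluation
  eta_v <- as.numeric(stats::filter(cm$male_velocity, c(0, f$vibration[, 1]), sides = 1))
  eta_s <- as.numeric(stats::filter(cm$male_velocity, c(0, f$song[, 1]), sides = 1))
  i <- 1000
  man <- exp(eta_v[i]) / (exp(eta_v[i]) + 2 * exp(eta_s[i]))
  expect_equal(lab$p_vibration[i], man, tolerance = 1e-12)
})

test_that("a saturated model labels every frame with its class", {
  nm <- c("male_velocity")
  zero <- matrix(0, 50, 1, dimnames = list(NULL, nm))
  gt <- ground_truth_glm(nm, list(song = zero, vibration = zero, none = zero),
                         intercepts = c(song = 1e3, vibration = 0, none = 0))
  lab <- sample_signals(synth_cue_matrix(500, cue_names = nm, seed = 2), gt, seed = 3)
  expect_true(all(lab$label[-(1:50)] == "song"))
})

test_that("cue name mismatch raises a schema error", {
  nm <- c("not_a_cue")
  zero <- matrix(0, 50, 1, dimnames = list(NULL, nm))
  gt <- ground_truth_glm(nm, list(song = zero, vibration = zero, none = zero))
  expect_error(sample_signals(synth_cue_matrix(200, seed = 1), gt),
               class = "courtsig_schema_error")
})

test_that("pulse emission respects spans and interval ranges", {
  cfg <- synth_config(duration_s = 10, seed = 1)
  # all-none labels: no events
  lab0 <- tibble::tibble(frame = 0:499,
                         label = factor(rep("none", 500),
                                        levels = c("song", "vibration", "none")))
  expect_equal(nrow(emit_pulse_events(lab0, cfg, rate_hz = 50)), 0)

  # one 1 s song span at fixed 40 ms interval: 25 or 26 events
  lab1 <- lab0
  lab1$label[1:50] <- "song"
  cfg40 <- synth_config(duration_s = 10, ipi_song_ms = c(40, 40 + 1e-9))
  ev <- emit_pulse_events(lab1, cfg40, seed = 2, rate_hz = 50)
  expect_true(nrow(ev) %in% c(25, 26))
  expect_true(all(abs(diff(ev$time_s) - 0.04) < 1e-6))

  # default ranges: median intervals inside the configured bands
  gt <- default_ground_truth()
  cm <- synth_cue_matrix(2e4, seed = 3)
  lab <- sample_signals(cm, gt, seed = 4)
  ev2 <- emit_pulse_events(lab, cfg, seed = 5, rate_hz = 50)
  ivs <- function(ty) {
    t <- ev2$time_s[ev2$event_type == ty]
    1000 * diff(t)[diff(t) * 1000 < 3 * cfg$ivi_vib_ms[2]]
  }
  m_song <- median(ivs("pulse_song")[ivs("pulse_song") < 100])
  m_vib <- median(ivs("vibration")[ivs("vibration") > 100])
  expect_gt(m_song, 30); expect_lt(m_song, 45)
  expect_gt(m_vib, 140); expect_lt(m_vib, 180)
})

test_that("emitted events reclassify back to the generating span labels", {
  cfg <- synth_config(duration_s = 30, seed = 1)
  rate <- 50
  lab <- tibble::tibble(frame = 0:(30 * rate - 1), label = "none")
  # well-separated long spans
  spans <- list(c(2, 5, "song"), c(8, 13, "vibration"), c(16, 18, "song"),
                c(21, 27, "vibration"))
  for (s in spans) {
    i <- (as.numeric(s[1]) * rate):(as.numeric(s[2]) * rate)
    lab$label[i + 1] <- s[3]
  }
  lab$label <- factor(lab$label, levels = c("song", "vibration", "none"))
  ev <- emit_pulse_events(lab, cfg, seed = 2, rate_hz = rate)
  cl <- classify_pulses(ev$time_s)
  # classification recovers the emitted type for every pulse
  expect_identical(cl$event_type, ev$event_type)
  # rasterized trains agree with the generating labels on covered frames
  trains <- segment_trains(cl)
  ras <- raster_segments(trains, rate, nrow(lab))
  expect_true(all(lab$label[ras$pulse] == "song"))
  expect_true(all(lab$label[ras$vibration] == "vibration"))
})
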