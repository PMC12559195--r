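#' Configuration for the synthetic courtship generator
#'
#' Bundles every knob of the synthetic two-fly generator. The defaults encode
#' the study conditions the rest of the package is tested against: 100 Hz
#' video frame rate, song inter-pulse intervals of 30-45 ms, vibration
#' intervals of 140-180 ms, and a female that alternates walking with
#' stationary bouts inside a circular arena.
#'
#' @param duration_s recording duration in seconds.
#' @param frame_rate_hz video frame rate in Hz (default 100).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param stationary_bout_rate rate (events/s of walking time) at which the
#'   female initiates stationary bouts.
#' @param stationary_bout_mean_s mean duration of a stationary bout
#'   (exponentially distributed).
#' @param arena_radius_mm radius of the circular arena in mm.
#' @param chase_gain relaxation rate (1/s) of the male position toward a
#'   point behind the female; couples male speed to female speed.
#' @param ipi_song_ms `(low, high)` range of song inter-pulse intervals, ms.
#' @param ivi_vib_ms `(low, high)` range of inter-vibration intervals, ms.
#' @param low_conf_frac fraction of body-part samples whose tracking
#'   confidence is dropped below 0.5, to exercise exclusion rules.
#' @return A list of class `synth_config`.
#' @examples
#' cfg <- synth_config(duration_s = 60, seed = 1)
#' @export
synth_config <- function(duration_s = 600,
                         frame_rate_hz = 100,
                         seed = 1,
                         stationary_bout_rate = 0.1,
                         stationary_bout_mean_s = 3,
                         arena_radius_mm = 25,
                         chase_gain = 2,
                         ipi_song_ms = c(30, 45),
                         ivi_vib_ms = c(140, 180),
                         low_conf_frac = 0.02) {
  check_positive(duration_s, "duration_s")
  check_positive(frame_rate_hz, "frame_rate_hz")
  check_range(ipi_song_ms, "ipi_song_ms")
  check_range(ivi_vib_ms, "ivi_vib_ms")
  if (any(ipi_song_ms >= ivi_vib_ms)) {
    abort("song interval range must lie elementwise below the vibration range.",
          class = "courtsig_config_error")
  }
  if (stationary_bout_rate < 0 || stationary_bout_mean_s <= 0) {
    abort("stationary bout parameters must be nonnegative rate, positive mean.",
          class = "courtsig_config_error")
  }
  structure(
    list(duration_s = duration_s, frame_rate_hz = frame_rate_hz, seed = seed,
         stationary_bout_rate = stationary_bout_rate,
         stationary_bout_mean_s = stationary_bout_mean_s,
         arena_radius_mm = arena_radius_mm, chase_gain = chase_gain,
         ipi_song_ms = ipi_song_ms, ivi_vib_ms = ivi_vib_ms,
         low_conf_frac = low_conf_frac),
    class = "synth_config"
  )
}

#' Canonical behavioral cue names
#'
#' The 19 kinematic cues used for choice modeling: eight per fly
#' (rotational speed/acceleration, velocity and its forward and lateral
#' components, acceleration and its forward and lateral components) plus
#' male-female distance, the male's angular position relative to the
#' female's body axis, and the male's heading relative to the female.
#'
#' @return Character vector of length 19.
#' @export
cue_names <- function() {
  per_fly <- c("rotational_speed", "rotational_acceleration",
               "velocity", "forward_velocity", "lateral_velocity",
               "acceleration", "forward_acceleration", "lateral_acceleration")
  c(paste0("male_", per_fly), paste0("female_", per_fly),
    "distance", "relative_angle", "relative_orientation")
}

choice_classes <- function() c("song", "vibration", "none")

#' Ground-truth choice model for label generation
#'
#' A known multinomial choice model over lagged cues, used to generate
#' per-frame signal labels whose generative filters are known exactly, so
#' that model fitting can be validated by filter recovery. Filters are
#' specified directly on the lag grid (one value per lag sample over a
#' trailing window), not in basis coefficients, so recovery tests are
#' basis-agnostic.
#'
#' @param cue_names character vector of cue identifiers.
#' @param filters named list with elements `song`, `vibration`, `none`;
#'   each a `lag x cue` matrix of filter weights (lag 1 = one sample back).
#'   All three matrices must share dimensions and column order matches
#'   `cue_names`.
#' @param intercepts named numeric vector of per-class intercepts.
#' @param rate_hz sampling rate of the lag grid in Hz.
#' @return A list of class `ground_truth_glm`.
#' @seealso [default_ground_truth()], [sample_signals()]
#' @export
ground_truth_glm <- function(cue_names, filters,
                             intercepts = c(song = 0, vibration = 0, none = 0),
                             rate_hz = 50) {
  classes <- choice_classes()
  if (!setequal(names(filters), classes)) {
    abort("`filters` must have elements song, vibration, none.",
          class = "courtsig_schema_error")
  }
  dims <- map(filters[classes], dim)
  if (length(unique(dims)) != 1) {
    abort("all class filter matrices must share dimensions.",
          class = "courtsig_schema_error")
  }
  if (dims[[1]][2] != length(cue_names)) {
    abort("filter columns must match `cue_names`.",
          class = "courtsig_schema_error")
  }
  structure(
    list(cue_names = cue_names, filters = filters[classes],
         intercepts = intercepts[classes], classes = classes,
         rate_hz = rate_hz, n_lags = dims[[1]][1]),
    class = "ground_truth_glm"
  )
}

#' Default ground-truth model: 3 informative cues among 19
#'
#' Builds a [ground_truth_glm()] over the 19 canonical cues in which only
#' three cues carry information (male velocity, female velocity, distance);
#' the other sixteen have all-zero filters. The informative filters lie in
#' the span of the default 4-function raised-cosine basis and are centred
#' across classes per cue (they sum to zero over classes), which makes the
#' model identifiable under the symmetric multinomial parameterization.
#' The female-velocity filter for the vibration class has a negative
#' integral: high female velocity suppresses vibration, mirroring the
#' central behavioral finding that vibrations require a stationary pair.
#'
#' @param rate_hz analysis rate in Hz (default 50).
#' @param window_s lag window in seconds (default 1).
#' @param scale overall filter amplitude.
#' @return A `ground_truth_glm`.
#' @export
default_ground_truth <- function(rate_hz = 50, window_s = 1, scale = 0.8) {
  basis <- cosine_basis(n_basis = 4, window_s = window_s, rate_hz = rate_hz)
  B <- basis$B
  nm <- cue_names()
  L <- nrow(B)
  zero <- matrix(0, L, length(nm), dimnames = list(NULL, nm))
  f <- list(song = zero, vibration = zero, none = zero)
  # informative cues, coefficients on the raised-cosine basis
  shape <- function(w) as.numeric(B %*% w) * scale
  mv <- shape(c(1.0, 0.4, -0.2, 0))     # male velocity: fast positive lobe
  fv <- shape(c(-0.3, -0.8, -0.5, 0))   # female velocity: negative (stationarity)
  ds <- shape(c(0, 0.5, 0.8, 0.4))      # distance: slow positive lobe
  # class-centred assignment: per cue the three class filters sum to zero
  f$song[, "male_velocity"] <- mv
  f$vibration[, "male_velocity"] <- -mv
  f$vibration[, "female_velocity"] <- fv
  f$none[, "female_velocity"] <- -fv
  f$song[, "distance"] <- ds
  f$none[, "distance"] <- -ds
  ground_truth_glm(nm, f, rate_hz = rate_hz)
}
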