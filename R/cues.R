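# kinematic cue extraction from two-fly pose tracks

#' Extract the 19 behavioral cues from pose tracks
#'
#' Computes, at the analysis rate, eight kinematic cues per fly plus three
#' relative cues. Heading is the thorax-to-head vector; velocity is the
#' central difference of the thorax position; forward/lateral components
#' are projections onto/orthogonal to the heading; rotational speed is the
#' angular velocity of the heading (deg/s) and rotational acceleration its
#' first difference. `acceleration` and its components are first
#' derivatives of the corresponding velocity cues. Relative cues are the
#' male-female thorax distance (mm), the male's angular position in the
#' female's body frame (`relative_angle`, 0 deg = directly in front of
#' her), and the male's heading relative to the direction to the female
#' centre (`relative_orientation`, 0 deg = facing her). When the track rate
#' exceeds `analysis_rate_hz`, coordinates are Gaussian-smoothed
#' (anti-aliasing) and decimated.
#'
#' @param tracks long tibble as from [generate_tracks()] or [read_tracks()]:
#'   columns `frame`, `fly_id`, `part`, `x_mm`, `y_mm`, `confidence`.
#' @param analysis_rate_hz target rate in Hz (default 50).
#' @param frame_rate_hz rate of `tracks`; defaults to its
#'   `frame_rate_hz` attribute.
#' @param signed_angles keep the sign of `relative_angle` and
#'   `relative_orientation` (default `FALSE`: absolute values, the
#'   convention used for modeling).
#' @return A tibble with `frame` (0-based, analysis clock), `time_s`, the
#'   19 cue columns (see [cue_names()]), head/thorax confidences, a signed
#'   copy of the relative angle, and logical `valid`/`courtship` columns
#'   (initialized `TRUE`/`NA`). Attribute `rate_hz` carries the analysis
#'   rate.
#' @export
extract_cues <- function(tracks, analysis_rate_hz = 50,
                         frame_rate_hz = attr(tracks, "frame_rate_hz"),
                         signed_angles = FALSE) {
  need <- c("frame", "fly_id", "part", "x_mm", "y_mm", "confidence")
  missing <- setdiff(need, names(tracks))
  if (length(missing)) {
    abort(paste0("tracks are missing columns: ", paste(missing, collapse = ", ")),
          class = "courtsig_schema_error")
  }
  if (is.null(frame_rate_hz)) {
    abort("`frame_rate_hz` not given and not stored on `tracks`.",
          class = "courtsig_config_error")
  }
  if (analysis_rate_hz > frame_rate_hz) {
    abort("analysis rate cannot exceed the track frame rate.",
          class = "courtsig_config_error")
  }
  w <- tracks |>
    filter(.data$part %in% c("head", "thorax")) |>
    tidyr::pivot_wider(id_cols = "frame",
                       names_from = c("fly_id", "part"),
                       values_from = c("x_mm", "y_mm", "confidence")) |>
    arrange(.data$frame)
  if (any(diff(w$frame) <= 0)) {
    abort("frame index must be strictly increasing.",
          class = "courtsig_schema_error")
  }

  k <- round(frame_rate_hz / analysis_rate_hz)
  rate <- frame_rate_hz / k
  coord_cols <- grep("^[xy]_mm_", names(w), value = TRUE)
  conf_cols <- grep("^confidence_", names(w), value = TRUE)
  if (k > 1) {
    for (cc in coord_cols) {
      w[[cc]] <- smooth_series(w[[cc]], sigma_s = 0.5 / analysis_rate_hz,
                               rate_hz = frame_rate_hz)
    }
    keep <- seq(1, nrow(w), by = k)
    # block-minimum confidence so a single bad raw frame invalidates the bin
    blk <- rep(seq_along(keep), each = k, length.out = nrow(w))
    conf <- w[conf_cols]
    w <- w[keep, ]
    for (cc in conf_cols) {
      w[[cc]] <- as.numeric(tapply(conf[[cc]], blk, min))
    }
  }
  n <- nrow(w)

  fly_kin <- function(prefix) {
    hx <- w[[paste0("x_mm_", prefix, "_head")]]
    hy <- w[[paste0("y_mm_", prefix, "_head")]]
    tx <- w[[paste0("x_mm_", prefix, "_thorax")]]
    ty <- w[[paste0("y_mm_", prefix, "_thorax")]]
    heading <- atan2(hy - ty, hx - tx)              # radians
    vx <- central_diff(tx, rate)
    vy <- central_diff(ty, rate)
    fwd <- vx * cos(heading) + vy * sin(heading)
    lat <- -vx * sin(heading) + vy * cos(heading)   # left positive
    speed <- sqrt(vx^2 + vy^2)
    # rotational speed from the unwrapped heading, deg/s
    dh <- central_diff(unwrap_rad(heading), rate) * 180 / pi
    rot_acc <- c(0, diff(dh)) * rate
    rot_acc[1] <- rot_acc[2]
    list(
      heading = heading, tx = tx, ty = ty,
      rotational_speed = abs(dh),
      rotational_acceleration = rot_acc,
      velocity = speed,
      forward_velocity = fwd,
      lateral_velocity = lat,
      acceleration = central_diff(speed, rate),
      forward_acceleration = central_diff(fwd, rate),
      lateral_acceleration = central_diff(lat, rate)
    )
  }
  m <- fly_kin("male")
  f <- fly_kin("female")

  dx <- m$tx - f$tx
  dy <- m$ty - f$ty
  distance <- sqrt(dx^2 + dy^2)
  # male position in the female body frame: 0 deg = in front of her
  rel_angle <- wrap_angle((atan2(dy, dx) - f$heading) * 180 / pi)
  # male heading vs the direction from male to female centre
  rel_orient <- wrap_angle((atan2(-dy, -dx) - m$heading) * 180 / pi)

  kin_cols <- setdiff(names(m), c("heading", "tx", "ty"))
  out <- tibble(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / rate)
  for (cc in kin_cols) out[[paste0("male_", cc)]] <- m[[cc]]
  for (cc in kin_cols) out[[paste0("female_", cc)]] <- f[[cc]]
  out$distance <- distance
  out$relative_angle <- if (signed_angles) rel_angle else abs(rel_angle)
  out$relative_orientation <- if (signed_angles) rel_orient else abs(rel_orient)
  out$relative_angle_signed <- rel_angle
  for (cc in conf_cols) {
    out[[sub("^confidence_", "conf_", cc)]] <- w[[cc]]
  }
  out$valid <- TRUE
  out$courtship <- NA
  attr(out, "rate_hz") <- rate
  out
}

unwrap_rad <- function(h) {
  d <- diff(h)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(h[1], d))
}

#' Courtship mask from distance and relative position
#'
#' A frame counts as courtship when the male is within `distance_mm` of the
#' female and within `angle_deg` of her rear body axis (i.e. behind her).
#' With the in-front-zero convention for `relative_angle`, "behind" means
#' `|wrap(relative_angle - 180)| <= angle_deg`.
#'
#' @param cues cue matrix from [extract_cues()].
#' @param distance_mm distance threshold in mm (8 for general analyses,
#'   6 for choice modeling).
#' @param angle_deg half-width of the rear sector in degrees (default 60).
#' @return Logical vector, one element per frame.
#' @seealso [courtship_index()]
#' @export
courtship_mask <- function(cues, distance_mm = 8, angle_deg = 60) {
  ra <- if ("relative_angle_signed" %in% names(cues)) {
    cues$relative_angle_signed
  } else {
    cues$relative_angle
  }
  cues$distance < distance_mm & abs(wrap_angle(abs(ra) - 180)) <= angle_deg
}

#' Courtship index
#'
#' Fraction of frames that are courtship, from the start of the recording
#' until copulation (or the end of the mask).
#'
#' @param mask logical courtship mask.
#' @param copulation_frame optional 0-based frame at which copulation
#'   starts; frames from there on are excluded from the denominator.
#' @return A single number in `[0, 1]`.
#' @export
courtship_index <- function(mask, copulation_frame = NULL) {
  if (!is.null(copulation_frame)) {
    mask <- mask[seq_len(min(length(mask), copulation_frame))]
  }
  mean(mask)
}

#' Validity mask: exclude tracking errors and post-copulation frames
#'
#' Marks frames invalid where the male-female thorax distance drops below
#' `min_distance_mm` (flies overlapping, tracking unreliable) or where the
#' head or thorax tracking confidence of either fly is below
#' `min_confidence`. All frames from the beginning of copulation on are
#' excluded as well.
#'
#' @param cues cue matrix from [extract_cues()] (carries the confidences).
#' @param min_distance_mm minimum thorax distance in mm (default 1).
#' @param min_confidence minimum head/thorax confidence (default 0.5).
#' @param copulation_frame optional 0-based frame of copulation onset on
#'   the analysis clock.
#' @return The cue matrix with its `valid` column updated.
#' @export
clean_kinematics <- function(cues, min_distance_mm = 1, min_confidence = 0.5,
                             copulation_frame = NULL) {
  conf_cols <- grep("^conf_(male|female)_(head|thorax)$", names(cues), value = TRUE)
  ok <- cues$distance >= min_distance_mm
  for (cc in conf_cols) ok <- ok & cues[[cc]] >= min_confidence
  if (!is.null(copulation_frame)) ok <- ok & cues$frame < copulation_frame
  cues$valid <- ok
  cues
}

#' Z-score the cue columns of a pair
#'
#' Centres and scales the 19 cue columns using means and SDs computed over
#' the selected frames (by default valid courtship frames, falling back to
#' valid frames when no courtship mask is set). The per-pair parameters are
#' stored in the `zscore` attribute so the transform is invertible and
#' pairs can be pooled after per-pair scaling.
#'
#' @param cues cue matrix.
#' @param frames optional logical vector selecting the frames used to
#'   compute the scaling parameters.
#' @return The cue matrix with scaled cue columns and a `zscore` attribute
#'   (tibble `cue`, `mean`, `sd`).
#' @export
zscore_cues <- function(cues, frames = NULL) {
  nm <- intersect(cue_names(), names(cues))
  if (is.null(frames)) {
    frames <- cues$valid
    if (!all(is.na(cues$courtship))) frames <- frames & cues$courtship %in% TRUE
  }
  params <- map(cues[frames, nm], function(x) {
    c(mean = mean(x), sd = stats::sd(x))
  })
  for (cc in nm) {
    s <- params[[cc]][["sd"]]
    if (!is.finite(s) || s == 0) s <- 1
    cues[[cc]] <- (cues[[cc]] - params[[cc]][["mean"]]) / s
  }
  attr(cues, "zscore") <- tibble(
    cue = nm,
    mean = map_dbl(params, 1),
    sd = map_dbl(params, 2)
  )
  cues
}

#' Pool per-pair z-scored cue matrices
#'
#' Concatenates cue matrices from several pairs (each already z-scored
#' per pair) into one matrix with a `pair` column, the pooled design used
#' for choice-model fitting.
#'
#' @param ... cue matrices, or a single list of them.
#' @return A single tibble with a `pair` identifier column.
#' @export
pool_pairs <- function(...) {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) && !is.data.frame(lst[[1]])) {
    lst <- lst[[1]]
  }
  rate <- attr(lst[[1]], "rate_hz")
  out <- map2(lst, seq_along(lst),
              function(df, i) mutate(df, pair = as.integer(i), .before = 1)) |>
    list_rbind()
  attr(out, "rate_hz") <- rate
  out
}
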