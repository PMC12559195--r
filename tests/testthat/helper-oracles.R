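# independent oracles used across the suite

cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# greedy agglomerative train grouping: every event starts as its own train;
# the closest same-type adjacent pair is merged while its gap is below the
# threshold. Algorithmically independent of the run-length implementation.
oracle_trains <- function(events, gap_pulse_ms = 80, gap_vib_ms = 400) {
  gaps <- c(pulse_song = gap_pulse_ms, vibration = gap_vib_ms)
  out <- list()
  for (ty in names(gaps)) {
    t <- sort(events$time_s[events$event_type == ty])
    if (length(t) == 0) next
    onset <- t
    offset <- t
    repeat {
      if (length(onset) < 2) break
      g <- (onset[-1] - offset[-length(offset)]) * 1000
      i <- which.min(g)
      if (g[i] >= gaps[[ty]]) break
      offset[i] <- offset[i + 1]
      onset <- onset[-(i + 1)]
      offset <- offset[-(i + 1)]
    }
    out[[ty]] <- tibble::tibble(
      onset_s = onset, offset_s = offset,
      seg_type = if (ty == "pulse_song") "pulse_train" else "vibration_train"
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          seg_type = character()))
  }
  dplyr::arrange(res, onset_s)
}

# exact paired Wilcoxon p-value by enumeration over all sign assignments
oracle_signed_rank_p <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% r)
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# frame-counting oracle for signal fractions
oracle_fraction <- function(segments, mask, rate_hz) {
  n <- length(mask)
  t <- (seq_len(n) - 1) / rate_hz
  per_type <- function(ty) {
    active <- rep(FALSE, n)
    rows <- which(courtsig:::canonical_signal(segments$seg_type) == ty)
    for (i in rows) {
      active <- active | (t >= segments$onset_s[i] - 1e-9 &
                            t <= segments$offset_s[i] + 1e-9)
    }
    active
  }
  a <- list(sine = per_type("sine"), pulse = per_type("pulse"),
            vibration = per_type("vibration"))
  c(sine = sum(a$sine & mask) / sum(mask),
    pulse = sum(a$pulse & mask) / sum(mask),
    vibration = sum(a$vibration & mask) / sum(mask),
    none = sum(!(a$sine | a$pulse | a$vibration) & mask) / sum(mask))
}

# random segment set on [0, dur] for fraction/overlap tests
random_segments <- function(n, dur_s, types = c("sine", "pulse_train", "vibration_train")) {
  on <- sort(runif(n, 0, dur_s))
  len <- runif(n, 0.05, 1)
  tibble::tibble(onset_s = on, offset_s = pmin(on + len, dur_s),
                 seg_type = sample(types, n, replace = TRUE))
}

# minimal two-fly track table from explicit thorax paths and headings (rad)
make_tracks <- function(mx, my, mh, fx, fy, fh, rate_hz = 50, conf = 1) {
  n <- length(mx)
  one <- function(cx, cy, h, fly) {
    parts <- courtsig:::body_part_offsets()
    purrr::pmap(parts, function(part, forward, lateral) {
      tibble::tibble(frame = seq_len(n) - 1L, fly_id = fly, part = part,
                     x_mm = cx + forward * cos(h) - lateral * sin(h),
                     y_mm = cy + forward * sin(h) + lateral * cos(h),
                     confidence = conf)
    }) |> purrr::list_rbind()
  }
  tr <- dplyr::bind_rows(one(mx, my, mh, "male"), one(fx, fy, fh, "female"))
  attr(tr, "frame_rate_hz") <- rate_hz
  tr
}
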