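# synthetic two-fly trajectory generator

# body-part offsets (mm) relative to the thorax in the fly's heading frame
body_part_offsets <- function() {
  tibble(
    part = c("head", "thorax", "abdomen", "wing_left", "wing_right"),
    forward = c(1.0, 0, -1.2, -1.0, -1.0),
    lateral = c(0, 0, 0, 0.5, -0.5)
  )
}

#' Generate synthetic two-fly pose tracks
#'
#' Simulates a male-female pair in a circular arena. The female alternates
#' Ornstein-Uhlenbeck-style walking with stationary bouts (exponentially
#' distributed durations, initiated at `stationary_bout_rate` while
#' walking). The male's position relaxes toward a point a few mm behind the
#' female at rate `chase_gain`, which makes male and female speeds
#' positively correlated, and his heading points at the female. Body parts
#' (head, thorax, abdomen, both wings) are placed rigidly in each fly's
#' heading frame. A fraction `low_conf_frac` of body-part samples get a
#' tracking confidence below 0.5 to exercise downstream exclusion rules.
#'
#' @param config a [synth_config()].
#' @return A tibble with columns `frame` (0-based), `fly_id`
#'   (`"male"`/`"female"`), `part`, `x_mm`, `y_mm`, `confidence`, and
#'   attributes `frame_rate_hz`, `arena_radius_mm`, `seed`.
#' @examples
#' tr <- generate_tracks(synth_config(duration_s = 10, seed = 1))
#' @export
generate_tracks <- function(config) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be a synth_config.", class = "courtsig_config_error")
  }
  withr::with_seed(config$seed, generate_tracks_impl(config))
}

generate_tracks_impl <- function(config) {
  rate <- config$frame_rate_hz
  dt <- 1 / rate
  n <- round(config$duration_s * rate)
  R <- config$arena_radius_mm

  # female: OU velocity + stop process
  tau_v <- 0.5          # velocity relaxation (s)
  sigma_v <- 12         # steady-state speed scale (mm/s)
  stopped <- stop_process(n, dt, config$stationary_bout_rate,
                          config$stationary_bout_mean_s)
  fx <- numeric(n); fy <- numeric(n)
  fvx <- numeric(n); fvy <- numeric(n)
  fx[1] <- R / 3; fy[1] <- 0
  fvx[1] <- sigma_v; fvy[1] <- 0
  ex <- rnorm(n); ey <- rnorm(n)
  kv <- sigma_v * sqrt(2 * dt / tau_v)
  for (t in 2:n) {
    vx <- fvx[t - 1] + dt * (-fvx[t - 1] / tau_v) + kv * ex[t]
    vy <- fvy[t - 1] + dt * (-fvy[t - 1] / tau_v) + kv * ey[t]
    if (stopped[t]) { vx <- 0; vy <- 0 }
    x <- fx[t - 1] + dt * vx
    y <- fy[t - 1] + dt * vy
    rr <- sqrt(x^2 + y^2)
    if (rr > R - 2) {      # soft wall: push back toward centre
      x <- x * (R - 2) / rr; y <- y * (R - 2) / rr
      vx <- vx - 2 * x / R * abs(vx); vy <- vy - 2 * y / R * abs(vy)
    }
    fx[t] <- x; fy[t] <- y; fvx[t] <- vx; fvy[t] <- vy
  }
  f_speed <- sqrt(fvx^2 + fvy^2)
  f_head <- heading_hold(fvx, fvy, f_speed, init = 0)

  # male: relaxation toward a point behind the female
  behind_mm <- 3
  g <- config$chase_gain
  mx <- numeric(n); my <- numeric(n)
  mx[1] <- fx[1] - behind_mm; my[1] <- fy[1]
  nmx <- rnorm(n); nmy <- rnorm(n)
  sig_m <- 1.0
  for (t in 2:n) {
    tx <- fx[t] - behind_mm * cos(f_head[t])
    ty <- fy[t] - behind_mm * sin(f_head[t])
    x <- mx[t - 1] + dt * g * (tx - mx[t - 1]) + sig_m * sqrt(dt) * nmx[t]
    y <- my[t - 1] + dt * g * (ty - my[t - 1]) + sig_m * sqrt(dt) * nmy[t]
    rr <- sqrt(x^2 + y^2)
    if (rr > R - 1) { x <- x * (R - 1) / rr; y <- y * (R - 1) / rr }
    mx[t] <- x; my[t] <- y
  }
  m_head <- atan2(fy - my, fx - mx)   # male faces the female

  parts <- body_part_offsets()
  place <- function(cx, cy, head, fly) {
    purrr::pmap(parts, function(part, forward, lateral) {
      tibble(frame = seq_len(n) - 1L, fly_id = fly, part = part,
             x_mm = cx + forward * cos(head) - lateral * sin(head),
             y_mm = cy + forward * sin(head) + lateral * cos(head))
    }) |> list_rbind()
  }
  out <- bind_rows(place(mx, my, m_head, "male"),
                   place(fx, fy, f_head, "female"))
  conf <- runif(nrow(out), 0.8, 1)
  drop <- runif(nrow(out)) < config$low_conf_frac
  conf[drop] <- runif(sum(drop), 0, 0.5)
  out$confidence <- conf
  out <- arrange(out, .data$frame, .data$fly_id, .data$part)
  attr(out, "frame_rate_hz") <- rate
  attr(out, "arena_radius_mm") <- R
  attr(out, "seed") <- config$seed
  out
}

# alternating walk/stop renewal process; returns logical stopped-per-frame
stop_process <- function(n, dt, rate, mean_s) {
  stopped <- logical(n)
  if (rate <= 0) return(stopped)
  t <- 0; total <- n * dt
  while (t < total) {
    walk <- rexp(1, rate)
    stop_d <- rexp(1, 1 / mean_s)
    i0 <- floor((t + walk) / dt) + 1
    i1 <- floor((t + walk + stop_d) / dt)
    if (i0 <= n) stopped[i0:min(i1, n)] <- TRUE
    t <- t + walk + stop_d
  }
  stopped
}

# heading from velocity; holds the last heading while stationary
heading_hold <- function(vx, vy, speed, init = 0, min_speed = 1e-6) {
  h <- atan2(vy, vx)
  h[speed < min_speed] <- NA
  if (is.na(h[1])) h[1] <- init
  # forward-fill
  idx <- cumsum(!is.na(h))
  h_filled <- h[!is.na(h)][pmax(idx, 1)]
  h_filled
}
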