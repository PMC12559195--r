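# rate-based model of the song/vibration circuit

circuit_nodes <- function() {
  c("pC2l", "P1a", "RNN", "pIP10", "DNvib", "inh_sv", "inh_vs")
}

#' Parameters of the rate-based signaling circuit
#'
#' Threshold-linear rate units for pC2l, P1a, a recurrent persistence unit
#' (RNN), the descending neurons pIP10 (song) and DNvib (vibration), and
#' two inhibitory interneurons mediating mutual inhibition between the
#' descending pathways (`inh_sv`: pIP10-driven, inhibits DNvib; `inh_vs`:
#' DNvib-driven, inhibits pIP10, and adapts so it acts as a high-pass
#' filter that speeds up the onset of song suppression). Each unit obeys
#' `tau dr/dt = -r + g f(sum W r + I - beta a)` with `f` threshold-linear
#' saturating at `r_max`; adaptation states `a` low-pass filter each
#' adapting unit's rate. The RNN unit self-excites above the threshold
#' `theta_rnn`, giving latch-like persistence that only strong (direct)
#' P1a activation can engage; slow RNN adaptation limits the persistence
#' to tens of seconds. P1a has a fast rise and a slow (5-10 s) intrinsic
#' decay. Ornstein-Uhlenbeck noise is added to the outputs of both
#' descending neurons (and propagates to the interneurons), enabling
#' stochastic switching; descending-neuron output maps linearly (clipped
#' to `[0, 1]`) onto song/vibration probability.
#'
#' @param tau_rise,tau_decay named per-node time constants in seconds
#'   (partial named vectors override defaults).
#' @param weights optional full connection matrix (target x source)
#'   overriding the default wiring.
#' @param theta_rnn activation threshold of the RNN unit.
#' @param gain named per-node excitability gains; satiation scales the
#'   gains of pC2l, P1a and RNN.
#' @param adapt_beta,adapt_tau named adaptation strengths and timescales
#'   (beta 0 disables adaptation for a node).
#' @param r_max named saturation rates.
#' @param sigma SD of the output noise on pIP10 and DNvib.
#' @param noise_tau_s correlation time of the output noise in seconds.
#' @param dt integration step in seconds (must be < min(tau)/10).
#' @param out_gain probability per unit descending-neuron rate.
#' @return A list of class `circuit_params`.
#' @export
circuit_params <- function(tau_rise = NULL, tau_decay = NULL, weights = NULL,
                           theta_rnn = 0.5, gain = NULL,
                           adapt_beta = NULL, adapt_tau = NULL, r_max = NULL,
                           sigma = 0.015, noise_tau_s = 0.05,
                           dt = 0.001, out_gain = 0.9) {
  nodes <- circuit_nodes()
  named_default <- function(x, defaults) {
    out <- defaults
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  tau_r <- named_default(tau_rise, c(pC2l = 0.2, P1a = 0.5, RNN = 1,
                                     pIP10 = 0.1, DNvib = 0.1,
                                     inh_sv = 0.1, inh_vs = 0.1))
  tau_d <- named_default(tau_decay, replace(tau_r, "P1a", 8))
  g <- named_default(gain, setNames(rep(1, 7), nodes))
  beta <- named_default(adapt_beta, c(pC2l = 0, P1a = 0, RNN = 0.3,
                                      pIP10 = 0.3, DNvib = 0.2,
                                      inh_sv = 0, inh_vs = 0.8))
  tau_a <- named_default(adapt_tau, c(pC2l = 1, P1a = 1, RNN = 40,
                                      pIP10 = 2, DNvib = 2,
                                      inh_sv = 1, inh_vs = 1))
  rmx <- named_default(r_max, c(pC2l = 2, P1a = 2, RNN = 1.5,
                                pIP10 = 2, DNvib = 2, inh_sv = 2, inh_vs = 2))
  if (is.null(weights)) {
    W <- matrix(0, 7, 7, dimnames = list(nodes, nodes))
    W["P1a", "pC2l"] <- 0.3      # weak: engages slow P1a decay, not the RNN
    W["RNN", "P1a"] <- 1.0
    W["RNN", "RNN"] <- 1.5       # self-excitation above theta_rnn
    W["pIP10", "pC2l"] <- 1.5
    W["pIP10", "RNN"] <- 0.5     # RNN drives song weakly...
    W["DNvib", "P1a"] <- 1.0
    W["DNvib", "RNN"] <- 1.5     # ...and vibration strongly
    W["pIP10", "inh_vs"] <- -2.0
    W["DNvib", "inh_sv"] <- -2.5
    W["inh_sv", "pIP10"] <- 1.0
    W["inh_vs", "DNvib"] <- 1.0
  } else {
    W <- weights
  }
  p <- structure(
    list(nodes = nodes, tau_rise = tau_r, tau_decay = tau_d, W = W,
         theta_rnn = theta_rnn, gain = g, adapt_beta = beta,
         adapt_tau = tau_a, r_max = rmx, sigma = sigma,
         noise_tau_s = noise_tau_s, dt = dt, out_gain = out_gain),
    class = "circuit_params"
  )
  validate_circuit_params(p)
  p
}

validate_circuit_params <- function(p) {
  if (any(p$tau_rise <= 0) || any(p$tau_decay <= 0)) {
    abort("all time constants must be positive.", class = "courtsig_config_error")
  }
  if (p$dt >= min(p$tau_rise, p$tau_decay) / 10) {
    abort("dt must be smaller than min(tau)/10.", class = "courtsig_config_error")
  }
  if (p$sigma < 0) abort("sigma must be >= 0.", class = "courtsig_config_error")
  inh_edges <- rbind(c("pIP10", "inh_vs"), c("DNvib", "inh_sv"))
  for (i in seq_len(nrow(inh_edges))) {
    if (p$W[inh_edges[i, 1], inh_edges[i, 2]] > 0) {
      abort("inhibitory weights must be <= 0.", class = "courtsig_config_error")
    }
  }
  exc <- p$W
  exc[inh_edges] <- 0
  if (any(exc < 0)) {
    abort("excitatory weights must be >= 0.", class = "courtsig_config_error")
  }
  invisible(p)
}

#' Optogenetic-style stimulation protocol
#'
#' @param target `"P1a"` or `"pC2l"`.
#' @param duration_s stimulus duration (default 5 s).
#' @param amplitude input amplitude during the stimulus.
#' @param n_trials number of independently initialized trials
#'   (default 100).
#' @param pre_s,post_s simulated time before/after stimulus onset; the
#'   defaults cover the before/during/offset/after analysis epochs.
#' @return A list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(target = c("P1a", "pC2l"), duration_s = 5,
                              amplitude = 1, n_trials = 100,
                              pre_s = 10, post_s = 35) {
  target <- match.arg(target)
  check_positive(duration_s, "duration_s")
  structure(
    list(target = target, duration_s = duration_s, amplitude = amplitude,
         n_trials = n_trials, pre_s = pre_s, post_s = post_s),
    class = "stimulus_protocol"
  )
}

#' Simulate the circuit model
#'
#' Integrates the rate equations with an exponential-Euler scheme (the
#' leak term is integrated exactly between steps, so a single isolated
#' unit reproduces its closed-form step response to machine precision).
#' All trials are integrated simultaneously with independent seeded noise.
#'
#' @param params a [circuit_params()].
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed for the noise.
#' @param n_trials number of trials; defaults to the protocol's.
#' @return An object of class `circuit_sim`: `time_s` (relative to
#'   stimulus onset), `p_song` and `p_vib` (`n_trials x time` matrices),
#'   `rates_mean` (`time x node` trial-averaged rates), plus params,
#'   protocol and seed.
#' @export
simulate_circuit <- function(params, protocol, seed = 1,
                             n_trials = protocol$n_trials) {
  validate_circuit_params(params)
  dt <- params$dt
  nodes <- params$nodes
  nn <- length(nodes)
  n_steps <- round((protocol$pre_s + protocol$post_s) / dt) + 1L
  time_s <- seq(-protocol$pre_s, protocol$post_s, length.out = n_steps)
  stim_on <- time_s >= 0 & time_s < protocol$duration_s
  I_ext <- matrix(0, n_steps, nn, dimnames = list(NULL, nodes))
  I_ext[stim_on, protocol$target] <- protocol$amplitude

  tau_r <- params$tau_rise[nodes]; tau_d <- params$tau_decay[nodes]
  kr <- 1 - exp(-dt / tau_r); kd <- 1 - exp(-dt / tau_d)
  ka <- 1 - exp(-dt / params$adapt_tau[nodes])
  beta <- params$adapt_beta[nodes]
  g <- params$gain[nodes]; rmx <- params$r_max[nodes]
  theta <- setNames(rep(0, nn), nodes); theta["RNN"] <- params$theta_rnn
  Wt <- t(params$W[nodes, nodes])
  kn <- exp(-dt / params$noise_tau_s)
  kn2 <- params$sigma * sqrt(1 - kn^2)

  r <- matrix(0, n_trials, nn, dimnames = list(NULL, nodes))
  a <- matrix(0, n_trials, nn)
  xi <- matrix(0, n_trials, 2)   # OU output noise for pIP10, DNvib
  p_song <- matrix(0, n_trials, n_steps)
  p_vib <- matrix(0, n_trials, n_steps)
  rates_sum <- matrix(0, n_steps, nn, dimnames = list(NULL, nodes))

  withr::with_seed(seed, {
    for (s in seq_len(n_steps)) {
      if (params$sigma > 0) {
        xi <- xi * kn + kn2 * matrix(rnorm(2 * n_trials), n_trials, 2)
      }
      out <- r
      out[, "pIP10"] <- pmax(r[, "pIP10"] + xi[, 1], 0)
      out[, "DNvib"] <- pmax(r[, "DNvib"] + xi[, 2], 0)
      p_song[, s] <- pmin(params$out_gain * out[, "pIP10"], 1)
      p_vib[, s] <- pmin(params$out_gain * out[, "DNvib"], 1)
      rates_sum[s, ] <- rates_sum[s, ] + colSums(r) / n_trials

      drive <- out %*% Wt
      drive <- sweep(drive, 2, I_ext[s, ], "+")
      drive <- drive - sweep(a, 2, beta, "*")
      drive <- sweep(drive, 2, theta, "-")
      target <- pmin(pmax(sweep(drive, 2, g, "*"), 0),
                     matrix(rmx, n_trials, nn, byrow = TRUE))
      k <- ifelse(target >= r,
                  matrix(kr, n_trials, nn, byrow = TRUE),
                  matrix(kd, n_trials, nn, byrow = TRUE))
      r <- r + (target - r) * k
      a <- a + sweep(r - a, 2, ka, "*")
      if (any(!is.finite(r)) || any(abs(r) > 100)) {
        abort("integration diverged; reduce dt.",
              class = "courtsig_integration_error")
      }
    }
  })
  structure(
    list(time_s = time_s, p_song = p_song, p_vib = p_vib,
         rates_mean = rates_sum, params = params, protocol = protocol,
         seed = seed, n_trials = n_trials),
    class = "circuit_sim"
  )
}

#' Trial-averaged simulation with epoch statistics
#'
#' Runs `simulate_circuit` with the protocol's trial count and summarizes
#' song/vibration probability per analysis epoch: per trial the mean
#' probability over the epoch window, then averaged across trials.
#'
#' @param params a [circuit_params()].
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed.
#' @param epochs epoch table from [trial_epochs()].
#' @return The `circuit_sim` with `trace` (trial-averaged tibble
#'   `time_s`, `p_song`, `p_vib`), `epochs` (per trial) and
#'   `epoch_summary` added.
#' @export
run_circuit_trials <- function(params, protocol, seed = 1,
                               epochs = trial_epochs()) {
  sim <- simulate_circuit(params, protocol, seed = seed)
  sim$trace <- tibble(time_s = sim$time_s,
                      p_song = colMeans(sim$p_song),
                      p_vib = colMeans(sim$p_vib))
  sim$epochs <- circuit_epochs(sim, epochs)
  sim$epoch_summary <- sim$epochs |>
    group_by(.data$epoch, .data$signal) |>
    summarise(probability = mean(.data$probability), .groups = "drop")
  sim
}

#' Per-trial epoch summary of a circuit simulation
#'
#' @param sim a `circuit_sim`.
#' @param epochs epoch table from [trial_epochs()].
#' @return A tibble `trial`, `epoch`, `signal`, `probability`.
#' @export
circuit_epochs <- function(sim, epochs = trial_epochs()) {
  out <- list()
  for (k in seq_len(nrow(epochs))) {
    sel <- sim$time_s >= epochs$start_s[k] & sim$time_s < epochs$end_s[k]
    for (sg in c("song", "vibration")) {
      m <- if (sg == "song") sim$p_song else sim$p_vib
      out[[paste(k, sg)]] <- tibble(
        trial = seq_len(nrow(m)), epoch = epochs$epoch[k], signal = sg,
        probability = rowMeans(m[, sel, drop = FALSE])
      )
    }
  }
  list_rbind(out)
}

#' Ablate the recurrent persistence stage
#'
#' Zeroes the RNN unit's outputs and its self-excitation; everything else
#' is unchanged. Idempotent.
#'
#' @param params a [circuit_params()].
#' @return Modified `circuit_params`.
#' @export
ablate_rnn <- function(params) {
  params$W[, "RNN"] <- 0
  params
}

#' Remove mutual inhibition between the descending pathways
#'
#' Zeroes both inhibitory interneuron pathways (drive onto and output from
#' `inh_sv` and `inh_vs`). Idempotent.
#'
#' @param params a [circuit_params()].
#' @return Modified `circuit_params`.
#' @export
remove_mutual_inhibition <- function(params) {
  params$W["pIP10", "inh_vs"] <- 0
  params$W["DNvib", "inh_sv"] <- 0
  params$W["inh_sv", "pIP10"] <- 0
  params$W["inh_vs", "DNvib"] <- 0
  params
}

#' Reduce circuit excitability (sexual satiation)
#'
#' Scales the gains of pC2l, P1a and the RNN by `scale`, modeling the
#' reduced excitability of satiated males.
#'
#' @param params a [circuit_params()].
#' @param scale gain multiplier in `(0, 1]`.
#' @return Modified `circuit_params`.
#' @export
apply_satiation <- function(params, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1) {
    abort("`scale` must be in (0, 1].", class = "courtsig_config_error")
  }
  params$gain[c("pC2l", "P1a", "RNN")] <- params$gain[c("pC2l", "P1a", "RNN")] * scale
  params
}

#' @method autoplot circuit_sim
#' @export
autoplot.circuit_sim <- function(object, ...) {
  tr <- if (!is.null(object$trace)) object$trace else {
    tibble(time_s = object$time_s,
           p_song = colMeans(object$p_song),
           p_vib = colMeans(object$p_vib))
  }
  df <- tidyr::pivot_longer(tr, c("p_song", "p_vib"),
                            names_to = "signal", values_to = "probability")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$probability,
                                   colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = 0, xmax = object$protocol$duration_s,
                      ymin = -Inf, ymax = Inf, alpha = 0.1) +
    ggplot2::labs(x = "time from stimulus onset (s)", y = "probability",
                  title = paste0(object$protocol$target,
                                 " activation, trial average"))
}

#' Effective decay timescale of post-offset vibration
#'
#' Fits a single exponential to the trial-averaged vibration probability
#' after its post-stimulus peak: baseline (pre-stimulus mean) is
#' subtracted, and a log-linear regression is run from half a second after
#' the peak for as long as the trace stays well above baseline. Quantifies
#' the slow intrinsic decay that drives vibrations at the offset of song
#' activation.
#'
#' @param sim a `circuit_sim` from [run_circuit_trials()].
#' @param min_ratio only use samples above `min_ratio` times baseline.
#' @return Effective timescale in seconds (`NA` if too few samples).
#' @export
offset_decay_tau <- function(sim, min_ratio = 4) {
  tr <- if (!is.null(sim$trace)) sim$trace else {
    tibble(time_s = sim$time_s, p_vib = colMeans(sim$p_vib))
  }
  base <- mean(tr$p_vib[tr$time_s < 0])
  off <- sim$protocol$duration_s
  post <- tr$time_s > off
  pk_t <- tr$time_s[post][which.max(tr$p_vib[post])]
  sel <- tr$time_s > pk_t + 0.5 & tr$p_vib > min_ratio * base
  if (sum(sel) < 10) return(NA_real_)
  fit <- stats::lm(log(tr$p_vib[sel] - base) ~ tr$time_s[sel])
  -1 / stats::coef(fit)[[2]]
}
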