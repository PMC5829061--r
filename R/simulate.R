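#' Canonical hemodynamic response model
#'
#' Double-gamma impulse response used to build class-conditional oxy- and
#' deoxyhemoglobin time courses: a positive lobe peaking `peak_delay`
#' seconds after stimulation, a late undershoot, and an HbR trace that is
#' the HbO trace scaled by `hbr_ratio` (negative, smaller in magnitude, so
#' HbO and HbR move in opposite directions with HbO dominating).
#'
#' @param peak_delay Peak latency of the positive lobe in seconds.
#' @param undershoot_delay Latency of the undershoot in seconds.
#' @param dispersion,undershoot_dispersion Gamma dispersions in seconds.
#' @param undershoot_ratio Undershoot amplitude relative to the peak.
#' @param hbr_ratio HbR amplitude relative to HbO (must be negative).
#' @return An object of class `hrf_model`.
#' @export
hemodynamic_response_model <- function(peak_delay = 6,
                                       undershoot_delay = 16,
                                       dispersion = 1,
                                       undershoot_dispersion = 1,
                                       undershoot_ratio = 1 / 6,
                                       hbr_ratio = -1 / 3) {
  if (hbr_ratio >= 0)
    stop("hbr_ratio must be negative: HbR moves opposite to HbO")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 dispersion = dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, hbr_ratio = hbr_ratio),
            class = "hrf_model")
}

# sampled impulse response, peak normalized to 1
hrf_kernel <- function(hrf, rate, duration = 32) {
  t <- seq(0, duration, by = 1 / rate)
  a1 <- hrf$peak_delay / hrf$dispersion
  a2 <- hrf$undershoot_delay / hrf$undershoot_dispersion
  h <- stats::dgamma(t, shape = a1, scale = hrf$dispersion) -
    hrf$undershoot_ratio *
    stats::dgamma(t, shape = a2, scale = hrf$undershoot_dispersion)
  h / max(h)
}

#' Synthetic-session configuration
#'
#' Defines the study conditions the generator emulates: three task classes
#' (mental arithmetic MA, motor imagery MI, idle state IS), 30 trials per
#' class in one randomized sequence, 10 s task periods separated by
#' 16-18 s uniform inter-trial breaks, 21 EEG channels (plus one vertical
#' EOG channel) at 200 Hz and 16 prefrontal NIRS channels at 13.3 Hz.
#'
#' EEG class effects are multiplicative band-amplitude factors applied to
#' region-specific rhythms during task windows (values below 1 model
#' event-related desynchronization); NIRS class effects are peak HbO
#' amplitudes in mM*cm of the convolved hemodynamic response.
#'
#' @param n_trials_per_class Trials per class (default 30).
#' @param task_duration Task period length in seconds.
#' @param iti_range Uniform inter-trial break range in seconds.
#' @param eeg_rate,nirs_rate Sampling rates in Hz.
#' @param lead_in,lead_out Quiet padding before the first and after the
#'   last trial, in seconds (must cover the epoch window).
#' @param eeg_effect Named list per class of band-amplitude multipliers
#'   with names among `frontal_theta`, `frontal_alpha`, `central_alpha`,
#'   `central_beta`.
#' @param eeg_background_sd 1/f background noise sd in uV.
#' @param eeg_rhythm_amplitude Named base rhythm amplitudes (sd, uV).
#' @param eeg_amp_wander_sd Log-sd of the slow (< 0.05 Hz) rhythm-amplitude
#'   wander, modeling spontaneous non-stationarity of band power.
#' @param effect_jitter_sd Log-sd of per-trial effect-size jitter, applied
#'   to the ERD/ERS modulation depth and to the hemodynamic response gain
#'   (single-trial responses vary strongly in practice).
#' @param blink_rate Blink events per second on the EOG channel.
#' @param blink_amplitude Blink peak amplitude in uV.
#' @param nirs_effect Named per-class peak HbO amplitudes in mM*cm.
#' @param nirs_noise Amplitudes of Mayer (~0.1 Hz), respiratory (~0.25 Hz)
#'   and cardiac (~1.1 Hz) oscillations, white noise sd, and 1/f baseline
#'   drift sd (the drift overlaps the 0.01-0.09 Hz analysis band and is the
#'   main in-band nuisance), all in mM*cm.
#' @param hrf A [hemodynamic_response_model()].
#' @param seed Integer seed; identical configs give bit-identical sessions.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_trials_per_class = 30L,
                              task_duration = 10,
                              iti_range = c(16, 18),
                              eeg_rate = 200,
                              nirs_rate = 13.3,
                              lead_in = 30,
                              lead_out = 30,
                              eeg_effect = list(
                                MA = c(frontal_theta = 0.62, frontal_alpha = 0.70),
                                MI = c(central_alpha = 0.48, central_beta = 0.65),
                                IS = c()),
                              eeg_background_sd = 10,
                              eeg_rhythm_amplitude = c(frontal_theta = 4,
                                                       frontal_alpha = 4,
                                                       central_alpha = 6,
                                                       central_beta = 3),
                              eeg_amp_wander_sd = 0.4,
                              effect_jitter_sd = 0.3,
                              blink_rate = 0.12,
                              blink_amplitude = 150,
                              nirs_effect = c(MA = 0.040, MI = 0.012, IS = 0),
                              nirs_noise = c(mayer = 0.004,
                                             respiratory = 0.003,
                                             cardiac = 0.003,
                                             white = 0.002,
                                             drift = 0.016),
                              hrf = hemodynamic_response_model(),
                              seed = 1L) {
  stopifnot(n_trials_per_class >= 1, task_duration > 0,
            length(iti_range) == 2, iti_range[1] <= iti_range[2],
            eeg_rate > 0, nirs_rate > 0,
            all(is.finite(unlist(eeg_effect))), all(unlist(eeg_effect) > 0),
            all(is.finite(nirs_effect)), all(is.finite(nirs_noise)))
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 task_duration = task_duration, iti_range = iti_range,
                 eeg_rate = eeg_rate, nirs_rate = nirs_rate,
                 lead_in = lead_in, lead_out = lead_out,
                 eeg_effect = eeg_effect,
                 eeg_background_sd = eeg_background_sd,
                 eeg_rhythm_amplitude = eeg_rhythm_amplitude,
                 eeg_amp_wander_sd = eeg_amp_wander_sd,
                 effect_jitter_sd = effect_jitter_sd,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 nirs_effect = nirs_effect, nirs_noise = nirs_noise,
                 hrf = hrf, seed = as.integer(seed)),
            class = "sim_config")
}

#' Named fixture presets for the synthetic generator
#'
#' * `"default"` — the standard study conditions.
#' * `"strong"` — deep ERD and large, low-noise hemodynamic responses; a
#'   well-separable subject.
#' * `"null"` — no class-dependent modulation at all (all EEG factors 1,
#'   all NIRS amplitudes 0); downstream accuracy must sit at chance.
#' * `"complementary"` — EEG carries mainly the motor-imagery contrast and
#'   NIRS mainly the mental-arithmetic contrast, so neither modality alone
#'   can resolve all three classes but their fusion can.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
simulation_preset <- function(name = c("default", "strong", "null",
                                       "complementary"),
                              seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    default = list(),
    strong = list(
      eeg_effect = list(
        MA = c(frontal_theta = 0.45, frontal_alpha = 0.55),
        MI = c(central_alpha = 0.30, central_beta = 0.50),
        IS = c()),
      eeg_amp_wander_sd = 0.2,
      effect_jitter_sd = 0.2,
      nirs_effect = c(MA = 0.080, MI = 0.025, IS = 0),
      nirs_noise = c(mayer = 0.003, respiratory = 0.002,
                     cardiac = 0.002, white = 0.001, drift = 0.003)),
    null = list(
      eeg_effect = list(MA = c(), MI = c(), IS = c()),
      nirs_effect = c(MA = 0, MI = 0, IS = 0)),
    complementary = list(
      eeg_effect = list(
        MA = c(frontal_theta = 0.92, frontal_alpha = 0.95),
        MI = c(central_alpha = 0.60, central_beta = 0.75),
        IS = c()),
      nirs_effect = c(MA = 0.050, MI = 0.004, IS = 0)))
  do.call(simulation_config, c(args, list(seed = seed), list(...)))
}

# run expr with a private, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Build a randomized trial schedule
#'
#' Draws one global random permutation of the `3 * n_trials_per_class`
#' class labels and places consecutive task onsets `task_duration` plus a
#' uniform inter-trial break apart. Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `events` (data frame of `onset_time` in seconds and
#'   `label`) and total session `duration` in seconds.
#' @export
build_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_trials_per_class
    labels <- sample(rep(c("MA", "MI", "IS"), each = n))
    total <- 3L * n
    gaps <- stats::runif(total, cfg$iti_range[1], cfg$iti_range[2])
    onsets <- cfg$lead_in +
      cumsum(c(0, (cfg$task_duration + gaps)[-total]))
    list(events = data.frame(onset_time = onsets, label = labels,
                             stringsAsFactors = FALSE),
         duration = onsets[total] + cfg$task_duration + gaps[total] +
           cfg$lead_out)
  })
}

# smooth task-gating envelope: 1 outside the task windows, per-onset
# `factors[i]` inside, with `ramp`-second raised-cosine edges
class_envelope <- function(t, onsets, factors, task_duration, ramp = 0.5) {
  env <- rep(1, length(t))
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    factor <- factors[k]
    if (factor == 1) next
    idx <- which(t >= on - ramp & t < on + task_duration + ramp)
    u <- t[idx]
    w <- rep(1, length(u))
    rising <- u < on + ramp
    falling <- u > on + task_duration - ramp
    w[rising] <- 0.5 * (1 - cos(pi * (u[rising] - on + ramp) / (2 * ramp)))
    w[falling] <- 0.5 *
      (1 + cos(pi * (u[falling] - (on + task_duration - ramp)) / (2 * ramp)))
    w[rising & falling] <- pmin(w[rising & falling], 1)
    env[idx] <- 1 + (factor - 1) * w
  }
  env
}

# slowly varying log-amplitude wander: band-limited (0.02-0.1 Hz, i.e.
# 10-50 s timescales, around the trial spacing) noise generated at 2 Hz and
# interpolated onto the target grid, unit sd
slow_wander <- function(n, rate, duration) {
  nr <- max(64L, ceiling(duration * 2))
  d <- butter_sos(0.02, 0.1, 2, order = 2L)
  s <- sos_filtfilt_mat(stats::rnorm(nr), d)
  s <- s / stats::sd(s)
  stats::approx(seq(0, by = 0.5, length.out = nr), s,
                xout = (seq_len(n) - 1) / rate, rule = 2)$y
}

# 1/f-shaped ("pink") noise columns via spectral shaping, unit sd;
# generated at an FFT-friendly length and truncated
pink_noise <- function(n, ncols) {
  nf <- stats::nextn(n, c(2, 3, 5))
  x <- matrix(stats::rnorm(nf * ncols), nf, ncols)
  f <- stats::mvfft(x)
  freq <- c(1, seq_len(nf - 1))
  freq <- pmin(freq, nf - (freq - 1))  # symmetric around Nyquist
  scale <- 1 / sqrt(freq)
  y <- Re(stats::mvfft(f * scale, inverse = TRUE))[seq_len(n), , drop = FALSE] / nf
  sweep(y, 2, apply(y, 2, stats::sd), "/")
}

# band-limited unit-sd noise columns (single forward pass is sufficient)
band_noise <- function(n, ncols, band, rate) {
  d <- butter_sos(band[1], band[2], rate, order = 4L)
  x <- sos_filter_mat(matrix(stats::rnorm(n * ncols), n, ncols), d$sos)
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

rhythm_bands <- list(frontal_theta = c(4, 8), frontal_alpha = c(8, 13),
                     central_alpha = c(8, 13), central_beta = c(13, 30))

#' Simulate the EEG stream of a session
#'
#' 21 EEG channels plus one vertical EOG channel. Each channel carries 1/f
#' background noise; region-specific rhythms (a resting alpha rhythm over
#' central channels, theta/alpha over frontal channels, beta over central
#' channels) are built from band-limited noise shared across the region
#' plus a per-channel component. During task windows the rhythm amplitude
#' is multiplied by the class effect factor with 0.5 s raised-cosine ramps
#' (factors below 1 model ERD). Stereotyped blink transients are placed on
#' the EOG channel and mixed into frontal channels with fixed gains.
#'
#' @param cfg A [simulation_config()].
#' @param schedule A [build_schedule()] result (defaults to the schedule
#'   implied by `cfg`).
#' @return A `bci_recording` in uV with one event per trial.
#' @export
simulate_eeg <- function(cfg, schedule = build_schedule(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    rate <- cfg$eeg_rate
    n <- ceiling(schedule$duration * rate)
    t <- (seq_len(n) - 1) / rate
    channels <- eeg_channel_table(eog = TRUE)
    is_eeg <- channels$modality == "EEG"
    data <- matrix(0, nrow(channels), n)

    # 1/f background on every channel
    data[is_eeg, ] <- t(pink_noise(n, sum(is_eeg))) * cfg$eeg_background_sd

    # region rhythms with class-conditional gating
    classes <- c("MA", "MI", "IS")
    for (key in names(cfg$eeg_rhythm_amplitude)) {
      region <- sub("_.*$", "", key)
      band <- rhythm_bands[[key]]
      members <- which(channels$region == region & is_eeg)
      if (!length(members)) next
      src <- band_noise(n, 1L + length(members), band, rate)
      gains <- stats::runif(length(members), 0.5, 1)
      env <- rep(1, n)
      for (cl in classes) {
        f <- cfg$eeg_effect[[cl]][key]
        if (is.null(f) || is.na(f)) f <- 1
        onsets <- schedule$events$onset_time[schedule$events$label == cl]
        if (f != 1 && length(onsets)) {
          # per-trial modulation-depth jitter (lognormal around the factor)
          jit <- exp(stats::rnorm(length(onsets), 0, cfg$effect_jitter_sd))
          f_tr <- pmin(2, pmax(0.05, 1 + (f - 1) * jit))
          env <- env * class_envelope(t, onsets, f_tr, cfg$task_duration)
        }
      }
      wander <- exp(cfg$eeg_amp_wander_sd *
                      slow_wander(n, rate, schedule$duration))
      amp <- cfg$eeg_rhythm_amplitude[[key]]
      for (j in seq_along(members)) {
        comp <- gains[j] * src[, 1] + 0.7 * src[, 1 + j]
        comp <- comp / sqrt(gains[j]^2 + 0.7^2)
        data[members[j], ] <- data[members[j], ] + amp * env * wander * comp
      }
    }

    # blinks: raised-cosine transients on the EOG channel, leaking into
    # frontal channels with fixed gains
    eog_row <- which(channels$modality == "EOG")
    n_blink <- stats::rpois(1, cfg$blink_rate * schedule$duration)
    eog <- numeric(n)
    if (n_blink > 0) {
      times <- sort(stats::runif(n_blink, 0, schedule$duration - 0.5))
      width <- 0.3
      for (bt in times) {
        idx <- which(t >= bt & t < bt + width)
        eog[idx] <- eog[idx] +
          cfg$blink_amplitude * 0.5 * (1 - cos(2 * pi * (t[idx] - bt) / width))
      }
    }
    frontal <- which(channels$region == "frontal" & is_eeg)
    leak <- stats::runif(length(frontal), 0.15, 0.35)
    for (j in seq_along(frontal))
      data[frontal[j], ] <- data[frontal[j], ] + leak[j] * eog
    data[eog_row, ] <- eog + 2 * stats::rnorm(n)

    events <- data.frame(
      onset_sample = round_half_to_zero(schedule$events$onset_time * rate),
      label = schedule$events$label, stringsAsFactors = FALSE)
    new_recording(data, rate, channels, events, unit = "uV")
  })
}

#' Simulate the NIRS stream of a session (optical densities)
#'
#' For each of the 16 prefrontal channels a latent (HbR, HbO) pair is built
#' by convolving each class's task boxcar with the hemodynamic response
#' model, scaled by the class effect amplitude and a fixed per-channel
#' spatial gain, plus physiological oscillations (Mayer ~0.1 Hz,
#' respiratory ~0.25 Hz, cardiac ~1.1 Hz) and white noise. The pair is then
#' mapped to three optical-density traces (780/805/830 nm) through the
#' Moore-Penrose pseudoinverse of the hemoglobin conversion matrix, so that
#' [mbll_convert()] recovers the latent hemodynamics exactly.
#'
#' @inheritParams simulate_eeg
#' @return A `bci_recording` in OD units (48 rows: 16 channels x 3
#'   wavelengths). The latent hemoglobin recording (32 rows, mM*cm) is
#'   attached as `attr(, "latent_hb")`.
#' @export
simulate_nirs <- function(cfg, schedule = build_schedule(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 2L, {
    rate <- cfg$nirs_rate
    n <- ceiling(schedule$duration * rate)
    t <- (seq_len(n) - 1) / rate
    nch <- nrow(nirs_pairs())
    kern <- hrf_kernel(cfg$hrf, rate)

    # class responses: boxcar convolved with the HRF, peak-normalized
    classes <- c("MA", "MI", "IS")
    resp <- matrix(0, n, length(classes))
    colnames(resp) <- classes
    peak <- max(stats::convolve(rep(1, round(cfg$task_duration * rate)),
                                rev(kern), type = "open"))
    for (cl in classes) {
      box <- rep(0, n)
      onsets <- schedule$events$onset_time[schedule$events$label == cl]
      # per-trial response-gain jitter
      jit <- exp(stats::rnorm(length(onsets), 0, cfg$effect_jitter_sd))
      for (k in seq_along(onsets)) {
        on <- onsets[k]
        box[t >= on & t < on + cfg$task_duration] <- jit[k]
      }
      conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n)]
      resp[, cl] <- conv / peak
    }

    gains <- stats::runif(nch, 0.5, 1)
    hb <- matrix(0, 2L * nch, n)  # rows interleaved CHi_HbR, CHi_HbO
    latent <- hb
    for (ch in seq_len(nch)) {
      hbo_sig <- gains[ch] *
        rowSums(sweep(resp, 2, cfg$nirs_effect[classes], "*"))
      hbr_sig <- cfg$hrf$hbr_ratio * hbo_sig
      latent[2 * ch - 1, ] <- hbr_sig
      latent[2 * ch, ] <- hbo_sig
      phases <- stats::runif(6, 0, 2 * pi)
      osc_o <- cfg$nirs_noise["mayer"] * sin(2 * pi * 0.1 * t + phases[1]) +
        cfg$nirs_noise["respiratory"] * sin(2 * pi * 0.25 * t + phases[2]) +
        cfg$nirs_noise["cardiac"] * sin(2 * pi * 1.1 * t + phases[3])
      osc_r <- -0.4 * (cfg$nirs_noise["mayer"] * sin(2 * pi * 0.1 * t + phases[4]) +
        cfg$nirs_noise["respiratory"] * sin(2 * pi * 0.25 * t + phases[5]) +
        cfg$nirs_noise["cardiac"] * sin(2 * pi * 1.1 * t + phases[6]))
      # slow vasomotor noise: band-limited to 0.01-0.1 Hz, i.e. inside the
      # analysis band (the main in-band nuisance for trial-wise decoding)
      drift_amp <- if ("drift" %in% names(cfg$nirs_noise))
        cfg$nirs_noise[["drift"]] else 0
      drift_o <- if (drift_amp > 0)
        drift_amp * band_noise(n, 1L, c(0.01, 0.1), rate)[, 1] else 0
      drift_r <- if (drift_amp > 0)
        0.4 * drift_amp * band_noise(n, 1L, c(0.01, 0.1), rate)[, 1] else 0
      hb[2 * ch - 1, ] <- hbr_sig + osc_r + drift_r +
        0.5 * cfg$nirs_noise["white"] * stats::rnorm(n)
      hb[2 * ch, ] <- hbo_sig + osc_o + drift_o +
        cfg$nirs_noise["white"] * stats::rnorm(n)
    }

    # map (HbR, HbO) to the three ODs via the pseudoinverse of the
    # conversion matrix: mbll_convert() then inverts this exactly
    C <- mbll_coefficients()
    pinv <- t(C) %*% solve(C %*% t(C))
    od <- matrix(0, 3L * nch, n)
    for (ch in seq_len(nch))
      od[(3 * ch - 2):(3 * ch), ] <- pinv %*% hb[(2 * ch - 1):(2 * ch), ]

    events <- data.frame(
      onset_sample = round_half_to_zero(schedule$events$onset_time * rate),
      label = schedule$events$label, stringsAsFactors = FALSE)
    rec <- new_recording(od, rate, nirs_channel_table(), events, unit = "OD")
    attr(rec, "latent_hb") <- new_recording(
      latent, rate, nirs_channel_table(chromophores = c("HbR", "HbO")),
      events, unit = "mM.cm")
    rec
  })
}

#' Simulate a complete synchronized session
#'
#' @param cfg A [simulation_config()] or preset.
#' @return A list with elements `eeg`, `nirs` (recordings sharing one
#'   schedule) and `schedule`.
#' @export
simulate_session <- function(cfg = simulation_config()) {
  schedule <- build_schedule(cfg)
  list(eeg = simulate_eeg(cfg, schedule),
       nirs = simulate_nirs(cfg, schedule),
       schedule = schedule)
}
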