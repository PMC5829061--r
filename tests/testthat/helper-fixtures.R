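# Small synthetic fixtures shared across tests. Everything is generated in
# code; sizes are kept small so unit tests stay fast, while acceptance-level
# checks build full-size sessions themselves.

# a short session: fewer trials and shorter breaks than the study timing
small_sim_config <- function(seed = 42, n = 6, ...) {
  simulation_config(n_trials_per_class = n, iti_range = c(8, 10),
                    lead_in = 10, lead_out = 28, seed = seed, ...)
}

# run the conditioning chain on a session and return aligned epoch sets
preprocess_session <- function(ses, epoch_window = c(-5, 25)) {
  eeg <- bandpass(ses$eeg, filter_spec(0.1, 50, 6))
  eeg <- remove_eog(eeg)
  nirs <- nirs_bandpass(mbll_convert(ses$nirs))
  list(eeg = epoch_recording(eeg, epoch_window),
       nirs = nirs_epoch_baseline(nirs, epoch_window))
}

# toy recording: deterministic sinusoids, optional events
toy_recording <- function(n_channels = 3, rate = 100, duration = 20,
                          events = NULL, unit = "uV") {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  data <- t(sapply(seq_len(n_channels), function(i)
    sin(2 * pi * i * t) + 0.1 * i))
  ch <- channel_table(paste0("ch", seq_len(n_channels)), "EEG", "central")
  if (is.null(events)) events <- empty_events()
  new_recording(data, rate, ch, events, unit)
}

# epochs with a planted spatial variance structure for two classes:
# class A carries extra variance along `direction`
planted_epochs <- function(n_trials = 20, n_channels = 3, n_time = 400,
                           rate = 100, direction = NULL, gain = 3,
                           seed = 7) {
  set.seed(seed)
  if (is.null(direction)) direction <- c(1, rep(0, n_channels - 1))
  direction <- direction / sqrt(sum(direction^2))
  make_class <- function(extra) {
    arr <- array(stats::rnorm(n_trials * n_channels * n_time),
                 c(n_trials, n_channels, n_time))
    if (extra) {
      for (i in seq_len(n_trials)) {
        src <- gain * stats::rnorm(n_time)
        arr[i, , ] <- arr[i, , ] + direction %o% src
      }
    }
    arr
  }
  ch <- channel_table(paste0("ch", seq_len(n_channels)), "EEG", "central")
  ep <- function(arr, label) {
    structure(list(data = arr, time = (seq_len(n_time) - 1) / rate,
                   labels = rep(label, n_trials), rate = rate,
                   channels = ch, unit = "uV"),
              class = "bci_epochs")
  }
  list(A = ep(make_class(TRUE), "MA"), B = ep(make_class(FALSE), "MI"),
       direction = direction)
}

# single-channel epochs of pure alpha-band noise whose amplitude is scaled
# by `task_factor` during the 0-10 s task window (ERSP ground truth)
make_alpha_epochs <- function(task_factor, n_trials = 24, rate = 200,
                              seed = 77) {
  set.seed(seed)
  n_time <- 30 * rate
  time <- seq(-5, by = 1 / rate, length.out = n_time)
  env <- ifelse(time >= 0 & time < 10, task_factor, 1)
  d <- hybridbci:::butter_sos(8, 13, rate, 4)
  ch <- channel_table("Cz", "EEG", "central")
  arr <- array(0, c(n_trials, 1, n_time))
  for (i in seq_len(n_trials)) {
    alpha <- hybridbci:::sos_filter_mat(matrix(rnorm(n_time), ncol = 1),
                                        d$sos)[, 1]
    arr[i, 1, ] <- env * alpha / sd(alpha)
  }
  structure(list(data = arr, time = time, labels = rep("MI", n_trials),
                 rate = rate, channels = ch, unit = "uV"),
            class = "bci_epochs")
}

# concatenate two trials x channels x time arrays along the trial axis
abind_trials <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# class-average trace-normalized covariance, written independently of the
# package internals (oracle helper)
oracle_class_cov <- function(epochs, window = c(0, 1e9)) {
  idx <- which(epochs$time >= window[1] & epochs$time < window[2])
  n_tr <- dim(epochs$data)[1]
  acc <- 0
  for (i in seq_len(n_tr)) {
    X <- t(epochs$data[i, , idx])
    X <- sweep(X, 2, colMeans(X))
    C <- crossprod(X) / (nrow(X) - 1)
    acc <- acc + C / sum(diag(C))
  }
  acc / n_tr
}
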