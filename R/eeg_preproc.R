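#' Downsample a recording with anti-alias filtering
#'
#' Applies a linear-phase windowed-sinc (Blackman) low-pass with cutoff at
#' 0.45 times the target rate before resampling onto the target grid, so
#' content above the new Nyquist frequency is attenuated by the window's
#' ~74 dB stopband. Supports arbitrary (also non-integer) rate ratios.
#' Event onsets are rescaled to the new rate and rounded to the nearest
#' sample with ties toward zero.
#'
#' @param rec A `bci_recording`.
#' @param target_rate New sampling rate in Hz, below `rec$rate`.
#' @return The downsampled recording.
#' @export
downsample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "bci_recording"))
  if (target_rate >= rec$rate)
    stop("target rate (", target_rate,
         " Hz) must be below the recording rate (", rec$rate, " Hz)")
  n <- ncol(rec$data)
  # FIR design: pass 0.45*target, stop 0.50*target -> transition 0.05*target
  trans <- 0.05 * target_rate
  L <- 2L * floor(2.75 * rec$rate / trans) + 1L
  L <- min(L, 2L * floor((n - 1) / 2) + 1L)
  m <- (L - 1) / 2
  fc <- 0.475 * target_rate
  k <- seq(-m, m)
  h <- 2 * fc / rec$rate * sinc(2 * fc / rec$rate * k)
  w <- 0.42 + 0.5 * cos(pi * k / m) + 0.08 * cos(2 * pi * k / m)
  h <- h * w
  h <- h / sum(h)

  # reflect-pad, centered convolution per channel (zero delay)
  x <- t(rec$data)
  pad <- m
  top <- x[seq(pad + 1, 2), , drop = FALSE]
  bot <- x[seq(n - 1, n - pad), , drop = FALSE]
  xf <- stats::filter(rbind(top, x, bot), h, method = "convolution", sides = 2)
  xf <- xf[seq(pad + 1, pad + n), , drop = FALSE]

  # sample the filtered signal on the new grid
  t_old <- (seq_len(n) - 1) / rec$rate
  n_new <- floor((n - 1) / rec$rate * target_rate) + 1
  t_new <- (seq_len(n_new) - 1) / target_rate
  y <- matrix(0, nrow(rec$data), n_new)
  for (i in seq_len(nrow(rec$data)))
    y[i, ] <- stats::approx(t_old, xf[, i], xout = t_new)$y

  events <- rec$events
  events$onset_sample <- round_half_to_zero(
    events$onset_sample * target_rate / rec$rate)
  new_recording(y, target_rate, rec$channels, events, rec$unit)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Remove ocular artifacts from EEG channels
#'
#' Pluggable artifact-removal stage. The default strategy regresses every
#' EEG channel on the EOG reference channel(s) by least squares and keeps
#' the residual; the EOG channels are dropped from the output. A custom
#' strategy can be supplied as `method = function(eeg, eog)` taking and
#' returning channels-by-samples matrices (e.g. an ICA-based remover).
#'
#' @param rec A `bci_recording` containing the named EOG channels.
#' @param eog_channels Character names of the EOG reference channels
#'   (default: all channels with modality `"EOG"`).
#' @param method Removal strategy; `NULL` uses the regression default.
#' @return A recording without the EOG channels.
#' @export
remove_eog <- function(rec, eog_channels = NULL, method = NULL) {
  stopifnot(inherits(rec, "bci_recording"))
  if (is.null(eog_channels))
    eog_channels <- rec$channels$name[rec$channels$modality == "EOG"]
  if (!length(eog_channels))
    stop("no EOG channel present; skip the ocular-removal stage instead")
  missing <- setdiff(eog_channels, rec$channels$name)
  if (length(missing))
    stop("EOG channel(s) not found: ", paste(missing, collapse = ", "))
  eog_idx <- match(eog_channels, rec$channels$name)
  keep <- setdiff(seq_len(nrow(rec$data)), eog_idx)
  eeg <- rec$data[keep, , drop = FALSE]
  eog <- rec$data[eog_idx, , drop = FALSE]
  if (is.null(method)) method <- regress_out
  cleaned <- method(eeg, eog)
  stopifnot(identical(dim(cleaned), dim(eeg)))
  new_recording(cleaned, rec$rate, rec$channels[keep, , drop = FALSE],
                rec$events, rec$unit)
}

# least-squares regression of each row of eeg on the rows of eog
regress_out <- function(eeg, eog) {
  E <- t(eog)
  E <- sweep(E, 2, colMeans(E))
  if (all(abs(E) < .Machine$double.eps)) return(eeg)
  X <- t(eeg)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  beta <- solve(crossprod(E), crossprod(E, Xc))
  t(sweep(Xc - E %*% beta, 2, mu, "+"))
}
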