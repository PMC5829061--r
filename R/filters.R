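#' Band-pass filter specification
#'
#' Describes a Butterworth band-pass design. The order is the order of the
#' underlying design; zero-phase application runs the filter forward and
#' backward, which cancels the group delay and squares the magnitude
#' response (a 6th-order design behaves as a 12th-order magnitude response).
#'
#' @param low_hz Lower band edge in Hz (must be >= 0 and < `high_hz`).
#' @param high_hz Upper band edge in Hz.
#' @param order Filter order of the one-way design (default 6).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 6L, zero_phase = TRUE) {
  stopifnot(is.numeric(low_hz), is.numeric(high_hz), length(low_hz) == 1,
            length(high_hz) == 1, is.finite(low_hz), is.finite(high_hz))
  if (low_hz < 0 || low_hz >= high_hz)
    stop("invalid band: require 0 <= low_hz < high_hz, got [",
         low_hz, ", ", high_hz, "]")
  if (order < 1) stop("filter order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Butterworth band-pass %g-%g Hz, order %d%s\n",
              x$low_hz, x$high_hz, x$order,
              if (x$zero_phase) " (zero-phase)" else ""))
  invisible(x)
}

# Butterworth band-pass designed in zero-pole-gain form and returned as
# second-order sections. Direct transfer-function designs are numerically
# unusable at edges far below the sampling rate (e.g. 0.01 Hz at 13.3 Hz),
# which the hemodynamic band requires; the zpk/SOS route stays stable.
butter_sos <- function(low_hz, high_hz, rate, order = 6L) {
  if (high_hz >= rate / 2)
    stop("band edge ", high_hz, " Hz is at or above the Nyquist frequency (",
         rate / 2, " Hz)")
  if (low_hz <= 0)
    stop("band-pass design requires low_hz > 0")
  n <- as.integer(order)
  fs2 <- 2 * rate
  # prewarped analog edges (rad/s)
  wl <- fs2 * tan(pi * low_hz / rate)
  wh <- fs2 * tan(pi * high_hz / rate)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # low-pass -> band-pass transform: each pole splits in two
  pb <- bw * p_lp / 2
  disc <- sqrt(pb^2 - w0^2 + 0i)
  p_bp <- c(pb + disc, pb - disc)
  # analog zeros: n at s = 0 (and n at infinity); gain bw^n
  # bilinear transform to the z-plane
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  # digital gain: k * prod(fs2 - zeros) / prod(fs2 - poles), zeros at 0
  k_z <- Re(bw^n * fs2^n / prod(fs2 - p_bp))
  # pair poles into conjugate second-order sections; each section takes one
  # zero at z = +1 and one at z = -1 (b = g * (1, 0, -1))
  tol <- 1e-8
  im <- Im(p_z)
  upper <- p_z[im > tol * Mod(p_z)]
  real_p <- Re(p_z[abs(im) <= tol * Mod(p_z)])
  sections <- list()
  # complex-conjugate pairs, poles closest to the unit circle last
  upper <- upper[order(Mod(upper))]
  for (p in upper)
    sections[[length(sections) + 1L]] <-
      c(1, -2 * Re(p), Mod(p)^2)
  if (length(real_p) >= 2) {
    real_p <- real_p[order(abs(real_p))]
    for (j in seq(1, length(real_p) - 1, by = 2)) {
      p1 <- real_p[j]; p2 <- real_p[j + 1]
      sections[[length(sections) + 1L]] <- c(1, -(p1 + p2), p1 * p2)
    }
  }
  nsec <- length(sections)
  stopifnot(nsec == n)
  sos <- matrix(0, nsec, 6)
  for (j in seq_len(nsec)) {
    gj <- abs(k_z)^(1 / nsec)
    if (j == 1) gj <- gj * sign(k_z)
    sos[j, ] <- c(gj * c(1, 0, -1), sections[[j]])
  }
  # transient length from the slowest pole, used to size reflective padding
  maxr <- max(Mod(p_z))
  maxr <- min(maxr, 1 - 1e-12)
  padlen <- ceiling(-9 / log(maxr))
  structure(list(sos = sos, rate = rate, padlen = padlen,
                 low_hz = low_hz, high_hz = high_hz, order = n),
            class = "butter_sos")
}

# one forward pass of a biquad cascade over the columns of x (in C)
sos_filter_mat <- function(x, sos) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  storage.mode(sos) <- "double"
  .Call(C_sosfilt, x, sos)
}

# zero-phase (forward-backward) SOS filtering with odd reflective padding;
# x: samples x traces matrix (or vector)
sos_filtfilt_mat <- function(x, design) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("signal too short to filter")
  padlen <- min(n - 1L, design$padlen)
  top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(padlen + 1, 2), , drop = FALSE]
  bot <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(n - 1, n - padlen), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- sos_filter_mat(xp, design$sos)
  y <- sos_filter_mat(y[nrow(y):1, , drop = FALSE], design$sos)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- y[seq(padlen + 1, padlen + n), , drop = FALSE]
  if (vec) drop(y) else y
}

# apply a filter_spec to a samples x traces matrix at the given rate
apply_filter_spec <- function(x, rate, spec) {
  design <- butter_sos(spec$low_hz, spec$high_hz, rate, spec$order)
  if (spec$zero_phase) sos_filtfilt_mat(x, design)
  else sos_filter_mat(as.matrix(x), design$sos)
}

#' Zero-phase band-pass filter a continuous recording
#'
#' Applies a Butterworth band-pass (designed as second-order sections) to
#' every channel. With `zero_phase = TRUE` in the spec the filter is run
#' forward and backward, so the output has no group delay and the DC
#' component is removed exactly (the numerator carries a zero at DC).
#'
#' @param rec A [new_recording()] object.
#' @param spec A [filter_spec()].
#' @return A filtered recording with the same metadata.
#' @export
bandpass <- function(rec, spec) {
  stopifnot(inherits(rec, "bci_recording"), inherits(spec, "filter_spec"))
  if (spec$high_hz >= rec$rate / 2)
    stop("band edge ", spec$high_hz,
         " Hz is at or above the Nyquist frequency (", rec$rate / 2, " Hz)")
  y <- t(apply_filter_spec(t(rec$data), rec$rate, spec))
  rec$data <- y
  rec
}
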