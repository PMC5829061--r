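#' Hemoglobin conversion coefficients (modified Beer-Lambert law)
#'
#' The 2x3 matrix mapping optical-density changes at 780, 805 and 830 nm
#' to concentration changes of reduced (HbR) and oxidized (HbO) hemoglobin
#' in mM*cm (unit optical pathlength):
#'
#' \deqn{(\Delta HbR, \Delta HbO)^T = C \, (\Delta OD_{780}, \Delta OD_{805},
#'   \Delta OD_{830})^T}
#'
#' @return A 2x3 numeric matrix with rows `HbR`, `HbO` and columns
#'   `780`, `805`, `830`.
#' @export
mbll_coefficients <- function() {
  matrix(c(1.8545, -0.2394, -1.0947,
           -1.4887, 0.5970, 1.4847),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("HbR", "HbO"), c("780", "805", "830")))
}

#' Convert optical densities to hemoglobin concentration changes
#'
#' Applies the modified Beer-Lambert conversion per NIRS channel and
#' sample: each channel must supply all three wavelengths (780, 805,
#' 830 nm). The map is linear and memoryless. Chromophore ordering in the
#' output is fixed as (HbR, HbO) per channel.
#'
#' @param od_rec A `bci_recording` in OD units whose channel table carries
#'   `source`, `detector`, and `wavelength` columns.
#' @param coefficients Conversion matrix (default [mbll_coefficients()]).
#' @return A `bci_recording` in mM*cm with two chromophore rows per NIRS
#'   channel; events are carried over.
#' @export
mbll_convert <- function(od_rec, coefficients = mbll_coefficients()) {
  stopifnot(inherits(od_rec, "bci_recording"))
  C <- as.matrix(coefficients)
  if (!identical(dim(C), c(2L, 3L)) || !all(is.finite(C)))
    stop("conversion matrix must be a finite 2x3 matrix")
  ch <- od_rec$channels
  if (!all(c("source", "detector", "wavelength") %in% names(ch)) ||
      any(is.na(ch$wavelength)))
    stop("optical-density recording must carry wavelength metadata")
  key <- paste(ch$source, ch$detector, sep = "-")
  groups <- unique(key)
  wl <- c(780, 805, 830)
  n <- ncol(od_rec$data)
  out <- matrix(0, 2L * length(groups), n)
  names_out <- character(2L * length(groups))
  src <- det <- integer(2L * length(groups))
  for (g in seq_along(groups)) {
    rows <- which(key == groups[g])
    sel <- match(wl, ch$wavelength[rows])
    if (anyNA(sel))
      stop("channel ", groups[g], " is missing wavelength(s): ",
           paste(wl[is.na(sel)], collapse = ", "))
    od <- od_rec$data[rows[sel], , drop = FALSE]
    out[(2 * g - 1):(2 * g), ] <- C %*% od
    base <- sub("_[0-9]+$", "", ch$name[rows[1]])
    names_out[(2 * g - 1):(2 * g)] <- paste0(base, "_", c("HbR", "HbO"))
    src[(2 * g - 1):(2 * g)] <- ch$source[rows[1]]
    det[(2 * g - 1):(2 * g)] <- ch$detector[rows[1]]
  }
  channels <- channel_table(names_out, "NIRS", "frontal",
                            source = src, detector = det,
                            chromophore = rep(c("HbR", "HbO"),
                                              length(groups)))
  new_recording(out, od_rec$rate, channels, od_rec$events, unit = "mM.cm")
}

#' Band-pass filter hemoglobin traces
#'
#' Zero-phase 6th-order Butterworth band-pass, by default 0.01-0.09 Hz, to
#' isolate the task-evoked hemodynamic response from physiological
#' oscillations (Mayer waves, respiration, cardiac pulsation). Applied to
#' the continuous recording before epoching so filter transients fall
#' outside the trials. Identical to [bandpass()]; provided as the named
#' NIRS stage.
#'
#' @param hb_rec A hemoglobin `bci_recording` (from [mbll_convert()]).
#' @param spec Filter specification (default 0.01-0.09 Hz, order 6,
#'   zero-phase).
#' @return The filtered recording.
#' @export
nirs_bandpass <- function(hb_rec, spec = filter_spec(0.01, 0.09, 6L)) {
  bandpass(hb_rec, spec)
}

#' Epoch hemoglobin traces with per-trial baseline correction
#'
#' Segments the recording into `[window[1], window[2])` epochs and
#' subtracts, per trial, channel, and chromophore, the temporal mean over
#' the baseline window (default -1..0 s). After correction the mean over
#' the baseline window is zero by construction.
#'
#' @param hb_rec A hemoglobin `bci_recording`.
#' @param window Epoch extent in seconds (default -5..25).
#' @param baseline Baseline window in seconds (default -1..0), must lie
#'   inside the epoch window.
#' @return A `bci_epochs` object.
#' @export
nirs_epoch_baseline <- function(hb_rec, window = c(-5, 25),
                                baseline = c(-1, 0)) {
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stop("baseline window [", baseline[1], ", ", baseline[2],
         ") must lie inside the epoch window")
  ep <- epoch_recording(hb_rec, window)
  idx <- window_index(ep$time, baseline)
  if (!length(idx)) stop("baseline window contains no samples")
  base <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(base)  # recycles over the time dimension
  ep
}
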