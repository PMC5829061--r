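#' Channel metadata table
#'
#' Builds a validated channel table. Each row describes one channel of a
#' continuous recording: a unique name, a modality (`"EEG"`, `"EOG"` or
#' `"NIRS"`), and a scalp region (`"frontal"`, `"central"` or `"other"`).
#' NIRS channels additionally carry the indices of the source-detector pair
#' and, for raw optical-density data, the wavelength in nm; hemoglobin
#' traces instead carry a chromophore (`"HbR"` or `"HbO"`).
#'
#' @param name Character vector of unique channel names.
#' @param modality One of `"EEG"`, `"EOG"`, `"NIRS"` (recycled).
#' @param region One of `"frontal"`, `"central"`, `"other"` (recycled).
#' @param source,detector Integer optode indices (NIRS only, else `NA`).
#' @param wavelength Wavelength in nm for optical-density channels.
#' @param chromophore `"HbR"` or `"HbO"` for hemoglobin channels.
#' @return A `data.frame` with one row per channel.
#' @export
channel_table <- function(name, modality, region,
                          source = NA_integer_, detector = NA_integer_,
                          wavelength = NA_real_, chromophore = NA_character_) {
  df <- data.frame(name = as.character(name),
                   modality = as.character(modality),
                   region = as.character(region),
                   source = as.integer(source),
                   detector = as.integer(detector),
                   wavelength = as.numeric(wavelength),
                   chromophore = as.character(chromophore),
                   stringsAsFactors = FALSE)
  validate_channels(df)
  df
}

validate_channels <- function(df) {
  if (anyDuplicated(df$name))
    stop("channel names must be unique; duplicated: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad_mod <- setdiff(unique(df$modality), c("EEG", "EOG", "NIRS"))
  if (length(bad_mod)) stop("unknown modality: ", paste(bad_mod, collapse = ", "))
  bad_reg <- setdiff(unique(df$region), c("frontal", "central", "other"))
  if (length(bad_reg)) stop("unknown region: ", paste(bad_reg, collapse = ", "))
  nirs <- df$modality == "NIRS"
  if (any(nirs & (is.na(df$source) | is.na(df$detector))))
    stop("NIRS channels must carry source and detector indices")
  if (any(!nirs & (!is.na(df$source) | !is.na(df$detector))))
    stop("EEG/EOG channels must not carry source/detector indices")
  invisible(df)
}

#' Default EEG montage: 21 electrodes over frontal and central areas
#'
#' Ten frontal electrodes (five forehead sites plus Fz, F1-F4) and eleven
#' central electrodes (FC3, FC4, Cz, C1-C6, CP3, CP4), with one vertical
#' EOG reference channel appended when `eog = TRUE`.
#'
#' @param eog Append a `"VEOG"` electro-oculogram channel (default `TRUE`).
#' @return A channel table.
#' @export
eeg_channel_table <- function(eog = TRUE) {
  frontal <- c("Fp1", "Fp2", "AFz", "AF3", "AF4", "Fz", "F1", "F2", "F3", "F4")
  central <- c("FC3", "FC4", "Cz", "C1", "C2", "C3", "C4", "C5", "C6",
               "CP3", "CP4")
  name <- c(frontal, central)
  region <- c(rep("frontal", length(frontal)), rep("central", length(central)))
  modality <- rep("EEG", length(name))
  if (eog) {
    name <- c(name, "VEOG")
    region <- c(region, "other")
    modality <- c(modality, "EOG")
  }
  channel_table(name, modality, region)
}

# 16 prefrontal source-detector pairs from a 6-source / 6-detector grid
nirs_pairs <- function() {
  rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 3), c(3, 3),
        c(4, 4), c(4, 5), c(5, 5), c(5, 6), c(6, 6),
        c(1, 4), c(2, 4), c(2, 5), c(3, 5), c(3, 6), c(6, 3))
}

#' Default NIRS montage: 16 prefrontal channels
#'
#' With `wavelengths` given, returns one optical-density channel per
#' channel-wavelength combination (wavelength-major within channel); with
#' `chromophores` given, one hemoglobin trace per channel and chromophore.
#'
#' @param wavelengths Numeric wavelengths in nm, or `NULL`.
#' @param chromophores Character chromophores, or `NULL`.
#' @return A channel table.
#' @export
nirs_channel_table <- function(wavelengths = c(780, 805, 830),
                               chromophores = NULL) {
  pairs <- nirs_pairs()
  nch <- nrow(pairs)
  if (!is.null(chromophores)) {
    k <- length(chromophores)
    channel_table(
      name = paste0("CH", rep(seq_len(nch), each = k), "_",
                    rep(chromophores, nch)),
      modality = "NIRS", region = "frontal",
      source = rep(pairs[, 1], each = k),
      detector = rep(pairs[, 2], each = k),
      chromophore = rep(chromophores, nch))
  } else {
    k <- length(wavelengths)
    channel_table(
      name = paste0("CH", rep(seq_len(nch), each = k), "_",
                    rep(wavelengths, nch)),
      modality = "NIRS", region = "frontal",
      source = rep(pairs[, 1], each = k),
      detector = rep(pairs[, 2], each = k),
      wavelength = rep(wavelengths, nch))
  }
}

#' Continuous multichannel recording
#'
#' The basic container for synchronized time-series: a channels-by-samples
#' matrix, a sampling rate, a channel table, and event markers giving trial
#' onsets as sample indices in this recording's own rate. Time convention:
#' sample `k` (0-based) covers `[k/rate, (k+1)/rate)` seconds.
#'
#' @param data Numeric matrix, channels x samples, all finite.
#' @param rate Sampling rate in Hz.
#' @param channels A [channel_table()] with `nrow(channels) == nrow(data)`.
#' @param events Data frame with integer `onset_sample` (0-based, strictly
#'   increasing) and character `label` columns; default no events.
#' @param unit Physical unit of `data` (`"uV"`, `"OD"`, or `"mM.cm"`).
#' @return An object of class `bci_recording`.
#' @export
new_recording <- function(data, rate, channels, events = empty_events(),
                          unit = "uV") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be a finite numeric matrix")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive scalar")
  validate_channels(channels)
  if (nrow(channels) != nrow(data))
    stop("channel table has ", nrow(channels), " rows but data has ",
         nrow(data), " rows")
  events <- validate_events(events, ncol(data))
  rownames(data) <- channels$name
  structure(list(data = data, rate = rate, channels = channels,
                 events = events, unit = unit),
            class = "bci_recording")
}

#' @export
#' @rdname new_recording
empty_events <- function() {
  data.frame(onset_sample = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(events, n_samples) {
  if (!is.data.frame(events) ||
      !all(c("onset_sample", "label") %in% names(events)))
    stop("events must be a data.frame with onset_sample and label columns")
  events$onset_sample <- as.integer(events$onset_sample)
  events$label <- as.character(events$label)
  if (nrow(events) > 1 && any(diff(events$onset_sample) <= 0))
    stop("event onset samples must be strictly increasing")
  if (nrow(events) && (min(events$onset_sample) < 0 ||
                       max(events$onset_sample) >= n_samples))
    stop("event onset outside recording bounds")
  events[c("onset_sample", "label")]
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %g Hz [%s], %d events\n",
              nrow(x$data), ncol(x$data), x$rate, x$unit, nrow(x$events)))
  tab <- table(x$channels$modality)
  cat("  channels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a recording container
#'
#' One session file per recording: a versioned serialized list holding the
#' data matrix, rate, unit, channel table, and event table. Round-trips are
#' bit-exact. `read_recording()` validates the container and reports any
#' missing field by name.
#'
#' @param rec A `bci_recording`.
#' @param path File path.
#' @return `read_recording()` returns the `bci_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bci_recording"))
  obj <- list(format = "hybridbci-recording", version = 1L,
              rate = rec$rate, unit = rec$unit, channels = rec$channels,
              events = rec$events, data = rec$data)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot parse recording container '",
                                           path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "hybridbci-recording"))
    stop("malformed recording container: missing field 'format'")
  for (f in c("rate", "unit", "channels", "events", "data"))
    if (is.null(obj[[f]]))
      stop("malformed recording container: missing field '", f, "'")
  new_recording(obj$data, obj$rate, obj$channels, obj$events, obj$unit)
}

#' Export event markers as tab-separated text
#'
#' Writes `onset_seconds` and `class_label` columns, one row per event.
#'
#' @param rec A `bci_recording`.
#' @param path Output path.
#' @export
write_events <- function(rec, path) {
  stopifnot(inherits(rec, "bci_recording"))
  df <- data.frame(onset_seconds = rec$events$onset_sample / rec$rate,
                   class_label = rec$events$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Segment a continuous recording into trial epochs
#'
#' Cuts a half-open window `[start_s, end_s)` around every event onset.
#' The number of samples is `floor((end - start) * rate)` (with a small
#' tolerance for non-integer rates such as 13.3 Hz), and the window start
#' offset is rounded to the nearest sample with ties toward zero.
#'
#' @param rec A `bci_recording` with at least one event.
#' @param window Numeric `c(start_s, end_s)` relative to event onset.
#' @return An object of class `bci_epochs`: a trials x channels x time
#'   array, a `time` axis in seconds relative to onset, per-trial `labels`,
#'   the rate, and the channel table.
#' @export
epoch_recording <- function(rec, window = c(-5, 25)) {
  stopifnot(inherits(rec, "bci_recording"), length(window) == 2)
  if (window[2] <= window[1])
    stop("empty epoch window [", window[1], ", ", window[2], ")")
  if (nrow(rec$events) == 0) stop("recording has no events to epoch")
  n_time <- floor((window[2] - window[1]) * rec$rate + 1e-6)
  off <- round_half_to_zero(window[1] * rec$rate)
  n_trial <- nrow(rec$events)
  nch <- nrow(rec$data)
  out <- array(NA_real_, c(n_trial, nch, n_time))
  for (i in seq_len(n_trial)) {
    i0 <- rec$events$onset_sample[i] + off
    i1 <- i0 + n_time - 1L
    if (i0 < 0 || i1 >= ncol(rec$data))
      stop("epoch window [", window[1], ", ", window[2],
           ") exceeds recording bounds for trial ", i)
    out[i, , ] <- rec$data[, seq(i0 + 1L, i1 + 1L), drop = FALSE]
  }
  structure(list(data = out,
                 time = (off + seq_len(n_time) - 1) / rec$rate,
                 labels = rec$events$label,
                 rate = rec$rate,
                 channels = rec$channels,
                 unit = rec$unit),
            class = "bci_epochs")
}

#' @export
print.bci_epochs <- function(x, ...) {
  cat(sprintf("<bci_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate))
  cat("  time: [", min(x$time), ",", max(x$time) + 1 / x$rate, ") s;",
      "labels:", paste(names(table(x$labels)), table(x$labels),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# nearest integer, ties toward zero
round_half_to_zero <- function(x) {
  as.integer(sign(x) * ceiling(abs(x) - 0.5))
}

# select samples of a time axis falling in half-open [w1, w2)
window_index <- function(time, window) {
  which(time >= window[1] - 1e-9 & time < window[2] - 1e-9)
}
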