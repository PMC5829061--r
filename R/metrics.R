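#' Information transfer rate in bits per minute
#'
#' Wolpaw-style ITR for an N-class selection task with accuracy `p` and
#' trial length `tau` seconds:
#' \deqn{ITR = \frac{60}{\tau}\left[\log_2 N + p \log_2 p +
#'   (1-p)\log_2\frac{1-p}{N-1}\right]}
#' `p log2 p` is taken as 0 at `p = 0` and the complementary term as 0 at
#' `p = 1`. At chance (`p = 1/N`) the ITR is exactly 0.
#'
#' @param p Classification accuracy in `[0, 1]` (vectorized).
#' @param n_classes Number of classes N (>= 2).
#' @param tau Trial length in seconds (> 0).
#' @return ITR in bits per minute.
#' @export
itr <- function(p, n_classes = 3, tau = 10) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("accuracy p must lie in [0, 1]")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (tau <= 0) stop("tau must be > 0")
  n <- n_classes
  t1 <- ifelse(p > 0, p * log2(p), 0)
  t2 <- ifelse(p < 1, (1 - p) * log2((1 - p) / (n - 1)), 0)
  60 / tau * (log2(n) + t1 + t2)
}

#' Percent improvement of a rate over a reference
#'
#' `100 * (a - b) / b`; rounding is left to the caller (the convention for
#' reporting is one decimal).
#'
#' @param a Achieved rate.
#' @param b Reference rate (> 0).
#' @return Percent improvement.
#' @export
percent_improvement <- function(a, b) {
  if (any(b <= 0)) stop("reference rate must be > 0")
  100 * (a - b) / b
}

#' Summarize cross-validated accuracies per modality
#'
#' Pools each repetition's confusion matrices over folds, takes
#' `trace / total` as that repetition's accuracy, and reports mean and
#' standard deviation across repetitions, in percent.
#'
#' @param cv A `bci_cv` from [crossvalidate()].
#' @return A data frame with columns `modality`, `mean_accuracy`,
#'   `sd_accuracy` (percent).
#' @export
accuracy_summary <- function(cv) {
  stopifnot(inherits(cv, "bci_cv"))
  rows <- lapply(names(cv$confusion), function(mod) {
    conf <- cv$confusion[[mod]]
    acc <- vapply(seq_len(dim(conf)[1]), function(r) {
      m <- apply(conf[r, , , , drop = FALSE], c(3, 4), sum)
      sum(diag(m)) / sum(m)
    }, 0)
    data.frame(modality = mod,
               mean_accuracy = 100 * mean(acc),
               sd_accuracy = 100 * stats::sd(acc))
  })
  do.call(rbind, rows)
}

#' Event-related spectral perturbation map
#'
#' Short-time Fourier power (1 s Hann window, 90% overlap by default) per
#' frequency and time, averaged over trials and over a channel group, then
#' expressed in dB relative to the mean baseline power per frequency
#' (baseline default -4..-3 s, before task onset).
#'
#' @param epochs A `bci_epochs`.
#' @param channels Channel names, or a region name (`"frontal"` /
#'   `"central"`) selecting all EEG channels of that region.
#' @param baseline Baseline window in seconds; must precede task onset and
#'   lie inside the epoch extent.
#' @param window_s STFT window length in seconds.
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @param freq_range Frequencies retained, in Hz.
#' @return An object of class `ersp_map` with `freq` (Hz), `time` (s,
#'   window centers), and the `power_db` matrix (frequencies x times).
#' @export
ersp <- function(epochs, channels = "central", baseline = c(-4, -3),
                 window_s = 1, overlap = 0.9, freq_range = c(1, 40)) {
  stopifnot(inherits(epochs, "bci_epochs"))
  if (baseline[2] > 0)
    stop("baseline window must precede task onset")
  if (baseline[1] < min(epochs$time))
    stop("baseline window outside epoch extent")
  if (length(channels) == 1 && channels %in% c("frontal", "central")) {
    sel <- which(epochs$channels$region == channels &
                   epochs$channels$modality == "EEG")
  } else {
    sel <- match(channels, epochs$channels$name)
    if (anyNA(sel)) stop("unknown channel(s): ",
                         paste(channels[is.na(sel)], collapse = ", "))
  }
  if (!length(sel)) stop("no channels selected")
  rate <- epochs$rate
  nwin <- round(window_s * rate)
  hop <- max(1L, round(nwin * (1 - overlap)))
  n_time <- dim(epochs$data)[3]
  starts <- seq(1L, n_time - nwin + 1L, by = hop)
  centers <- epochs$time[starts] + (nwin - 1) / (2 * rate)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))
  freq <- (seq_len(nwin %/% 2 + 1) - 1) * rate / nwin
  keep_f <- which(freq >= freq_range[1] & freq <= freq_range[2])
  pow <- matrix(0, length(keep_f), length(starts))
  n_tr <- dim(epochs$data)[1]
  for (i in seq_len(n_tr)) {
    for (ch in sel) {
      x <- epochs$data[i, ch, ]
      seg <- vapply(starts, function(s) x[s:(s + nwin - 1L)] * win,
                    numeric(nwin))
      sp <- stats::mvfft(seg)
      pow <- pow + (Mod(sp[keep_f, , drop = FALSE])^2)
    }
  }
  pow <- pow / (n_tr * length(sel))
  base_cols <- which(centers >= baseline[1] & centers < baseline[2])
  if (!length(base_cols)) stop("baseline window contains no STFT frames")
  base <- rowMeans(pow[, base_cols, drop = FALSE])
  db <- 10 * log10(sweep(pow, 1, base, "/"))
  structure(list(freq = freq[keep_f], time = centers, power_db = db,
                 baseline = baseline, channels = epochs$channels$name[sel]),
            class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf("<ersp_map> %d frequencies (%g-%g Hz) x %d frames (%.2f-%.2f s), baseline [%g, %g) s\n",
              length(x$freq), min(x$freq), max(x$freq), length(x$time),
              min(x$time), max(x$time), x$baseline[1], x$baseline[2]))
  invisible(x)
}
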