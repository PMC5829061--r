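#' Run the full decoding pipeline on a synthetic or provided session
#'
#' Orchestrates the complete chain: simulate (or accept) a synchronized
#' EEG+NIRS session; condition the EEG (downsample if above the working
#' rate, broadband band-pass, ocular-artifact regression, epoching);
#' condition the NIRS (Beer-Lambert conversion, narrow band-pass of the
#' continuous traces, epoching with baseline correction); run the repeated
#' stratified cross-validation of the one-versus-one hybrid decoder; and
#' summarize accuracies and the hybrid information transfer rate. The
#' result is stamped with a configuration hash; identical configurations
#' produce identical results.
#'
#' @param cfg A [pipeline_config()].
#' @param session Optional list with `eeg` and `nirs` recordings; by
#'   default a synthetic session is generated from `cfg$simulation`.
#' @param skip_eog Skip the ocular-removal stage (e.g. when no EOG channel
#'   was recorded).
#' @return An object of class `bci_result` with elements `summary`
#'   (per-modality accuracy), `itr_bits_per_min`, `cv`, `config`, and
#'   `config_hash`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), session = NULL,
                         skip_eog = FALSE) {
  stopifnot(inherits(cfg, "bci_config"))
  if (is.null(session)) session <- simulate_session(cfg$simulation)

  eeg <- session$eeg
  if (eeg$rate > cfg$eeg_rate) eeg <- downsample(eeg, cfg$eeg_rate)
  eeg <- bandpass(eeg, filter_spec(cfg$eeg_band[1], cfg$eeg_band[2],
                                   cfg$filter_order))
  if (!skip_eog && any(eeg$channels$modality == "EOG"))
    eeg <- remove_eog(eeg)
  eeg_epochs <- epoch_recording(eeg, cfg$epoch_window)

  nirs <- session$nirs
  if (identical(nirs$unit, "OD")) nirs <- mbll_convert(nirs)
  nirs <- nirs_bandpass(nirs, filter_spec(cfg$nirs_band[1], cfg$nirs_band[2],
                                          cfg$filter_order))
  nirs_epochs <- nirs_epoch_baseline(nirs, cfg$epoch_window,
                                     cfg$baseline_window)

  bank <- lapply(cfg$bands, function(b)
    filter_spec(b[1], b[2], cfg$filter_order))
  cv <- crossvalidate(eeg_epochs, nirs_epochs, k = cfg$folds,
                      repetitions = cfg$repetitions, seed = cfg$seed,
                      bands = bank, task_window = cfg$task_window,
                      nirs_windows = cfg$nirs_windows,
                      n_first = cfg$n_first, n_last = cfg$n_last,
                      inner_folds = cfg$inner_folds,
                      shrinkage_target = cfg$shrinkage_target)
  summ <- accuracy_summary(cv)
  itrs <- itr(summ$mean_accuracy / 100, n_classes = length(cv$classes),
              tau = cfg$itr_trial_length)
  names(itrs) <- summ$modality
  structure(list(summary = summ, itr_bits_per_min = itrs, cv = cv,
                 config = cfg, config_hash = config_hash(cfg)),
            class = "bci_result")
}

#' @export
print.bci_result <- function(x, ...) {
  cat("<bci_result> config", substr(x$config_hash, 1, 8), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-7s %5.1f +/- %4.1f %%   ITR %.2f bits/min\n",
                s$modality[i], s$mean_accuracy[i], s$sd_accuracy[i],
                x$itr_bits_per_min[i]))
  invisible(x)
}

#' Write pipeline results as JSON
#'
#' Serializes the accuracy summary, per-repetition/fold confusion
#' matrices, ITRs, and the configuration hash.
#'
#' @param result A `bci_result`.
#' @param path Output path.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "bci_result"))
  out <- list(
    config_hash = result$config_hash,
    classes = result$cv$classes,
    folds = result$cv$k,
    repetitions = result$cv$repetitions,
    summary = result$summary,
    itr_bits_per_min = as.list(result$itr_bits_per_min),
    confusion = lapply(result$cv$confusion, function(a) a))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
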