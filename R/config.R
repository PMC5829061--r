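#' Pipeline configuration
#'
#' All tunable parameters of the decoding chain, defaulting to the values
#' the method is defined with: EEG working rate 200 Hz with a 0.1-50 Hz
#' band-pass, NIRS band 0.01-0.09 Hz, filter bank theta 4-8 / alpha 8-13 /
#' beta 13-30 Hz (6th-order zero-phase Butterworth), epochs -5..25 s, task
#' window 0..10 s, NIRS temporal-mean windows 5-10 and 10-15 s with a
#' -1..0 s baseline, 3+3 CSP components, 10 x 10-fold cross-validation with
#' 5-fold inner stacking, and ITR trial length 10 s.
#'
#' @param eeg_rate EEG working sampling rate in Hz.
#' @param eeg_band EEG broadband filter edges in Hz.
#' @param nirs_band Hemoglobin band-pass edges in Hz.
#' @param filter_order Butterworth order for all band-pass designs.
#' @param bands Named list of filter-bank band edges in Hz.
#' @param epoch_window Epoch extent in seconds relative to task onset.
#' @param task_window CSP / feature window in seconds.
#' @param nirs_windows List of NIRS temporal-mean windows in seconds.
#' @param baseline_window NIRS baseline-correction window in seconds.
#' @param n_first,n_last CSP components kept from each end of the spectrum.
#' @param folds,repetitions Outer cross-validation geometry.
#' @param inner_folds Inner folds used to produce leakage-free decisions
#'   for the meta-classifier.
#' @param shrinkage_target `"scaled-identity"` shrinks the covariance toward
#'   `nu * I` with `nu` the average feature variance; `"identity"` uses the
#'   literal `I` target.
#' @param itr_trial_length Trial length tau in seconds for ITR reporting.
#' @param seed Integer seed fanned out to all stochastic stages.
#' @param simulation A [simulation_config()] for synthetic sessions.
#' @return An object of class `bci_config`.
#' @export
pipeline_config <- function(eeg_rate = 200,
                            eeg_band = c(0.1, 50),
                            nirs_band = c(0.01, 0.09),
                            filter_order = 6L,
                            bands = list(theta = c(4, 8),
                                         alpha = c(8, 13),
                                         beta = c(13, 30)),
                            epoch_window = c(-5, 25),
                            task_window = c(0, 10),
                            nirs_windows = list(c(5, 10), c(10, 15)),
                            baseline_window = c(-1, 0),
                            n_first = 3L, n_last = 3L,
                            folds = 10L, repetitions = 10L,
                            inner_folds = 5L,
                            shrinkage_target = "scaled-identity",
                            itr_trial_length = 10,
                            seed = 1L,
                            simulation = simulation_config(seed = seed)) {
  cfg <- list(eeg_rate = eeg_rate, eeg_band = eeg_band,
              nirs_band = nirs_band, filter_order = as.integer(filter_order),
              bands = bands, epoch_window = epoch_window,
              task_window = task_window, nirs_windows = nirs_windows,
              baseline_window = baseline_window,
              n_first = as.integer(n_first), n_last = as.integer(n_last),
              folds = as.integer(folds),
              repetitions = as.integer(repetitions),
              inner_folds = as.integer(inner_folds),
              shrinkage_target = match.arg(shrinkage_target,
                                           c("scaled-identity", "identity")),
              itr_trial_length = itr_trial_length,
              seed = as.integer(seed), simulation = simulation)
  validate_config(cfg)
  structure(cfg, class = "bci_config")
}

validate_config <- function(cfg) {
  check_band <- function(b, what) {
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("invalid ", what, ": low edge must be below high edge, got [",
           paste(b, collapse = ", "), "]")
  }
  check_band(cfg$eeg_band, "eeg_band")
  check_band(cfg$nirs_band, "nirs_band")
  for (nm in names(cfg$bands)) check_band(cfg$bands[[nm]], paste0("band '", nm, "'"))
  check_band(cfg$epoch_window, "epoch_window")
  check_band(cfg$task_window, "task_window")
  check_band(cfg$baseline_window, "baseline_window")
  for (w in cfg$nirs_windows) check_band(w, "nirs window")
  if (cfg$folds < 2) stop("folds must be >= 2")
  if (cfg$repetitions < 1) stop("repetitions must be >= 1")
  if (cfg$n_first + cfg$n_last < 1) stop("must keep at least one CSP component")
  if (cfg$itr_trial_length <= 0) stop("itr_trial_length must be > 0")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys override [pipeline_config()] arguments; an empty file yields the
#' all-defaults configuration. Unknown keys are rejected, and band edges
#' are validated (low must be below high).
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A `bci_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping")
  allowed <- setdiff(names(formals(pipeline_config)), "simulation")
  unknown <- setdiff(names(raw), c(allowed, "simulation"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sim <- raw$simulation
  raw$simulation <- NULL
  if (!is.null(sim)) {
    unknown_sim <- setdiff(names(sim), names(formals(simulation_config)))
    if (length(unknown_sim))
      stop("unknown simulation key(s): ", paste(unknown_sim, collapse = ", "))
  }
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  sim_cfg <- do.call(simulation_config,
                     c(sim, if (is.null(sim$seed)) list(seed = seed)))
  do.call(pipeline_config, c(raw, list(simulation = sim_cfg)))
}

# stable fingerprint of a configuration for provenance stamping
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  flat <- rapply(unclass(cfg), function(x) x, how = "replace")
  yaml::write_yaml(flat, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.bci_config <- function(x, ...) {
  cat("<bci_config>\n")
  cat(sprintf("  EEG %g Hz, band %g-%g Hz; NIRS band %g-%g Hz (order %d)\n",
              x$eeg_rate, x$eeg_band[1], x$eeg_band[2],
              x$nirs_band[1], x$nirs_band[2], x$filter_order))
  cat(sprintf("  filter bank: %s\n",
              paste(vapply(names(x$bands), function(n)
                sprintf("%s %g-%g", n, x$bands[[n]][1], x$bands[[n]][2]),
                ""), collapse = ", ")))
  cat(sprintf("  CV: %d x %d-fold (inner %d), CSP %d+%d, seed %d\n",
              x$repetitions, x$folds, x$inner_folds,
              x$n_first, x$n_last, x$seed))
  invisible(x)
}
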