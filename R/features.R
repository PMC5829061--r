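#' Default filter bank: theta, alpha, beta
#'
#' Three 6th-order zero-phase Butterworth band-passes: theta 4-8 Hz,
#' alpha 8-13 Hz, beta 13-30 Hz.
#'
#' @param order Butterworth order (default 6).
#' @return Named list of [filter_spec()] objects.
#' @export
default_filter_bank <- function(order = 6L) {
  list(theta = filter_spec(4, 8, order),
       alpha = filter_spec(8, 13, order),
       beta = filter_spec(13, 30, order))
}

# band-pass every trial of an epoch set (vectorized over trials x channels)
epochs_bandpass <- function(epochs, spec) {
  d <- dim(epochs$data)
  # time in rows, one column per trial-channel trace
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  y <- apply_filter_spec(x, epochs$rate, spec)
  epochs$data <- aperm(array(y, c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

# per-trial spatial covariance over a time window; channels x channels x trials
trial_covariances <- function(epochs, window) {
  idx <- window_index(epochs$time, window)
  if (!length(idx)) stop("empty task window after discretization")
  d <- dim(epochs$data)
  out <- array(0, c(d[2], d[2], d[1]))
  for (i in seq_len(d[1])) {
    X <- t(epochs$data[i, , idx])
    X <- sweep(X, 2, colMeans(X))
    out[, , i] <- crossprod(X) / (nrow(X) - 1)
  }
  out
}

# CSP on precomputed per-trial covariances (trace-normalized before
# averaging); returns filters ordered by descending class-A eigenvalue score
csp_fit_cov <- function(covs_a, covs_b, band = NA_character_,
                        problem = NA_character_, channel_names = NULL) {
  norm_mean <- function(cv) {
    m <- 0
    for (i in seq_len(dim(cv)[3])) m <- m + cv[, , i] / sum(diag(cv[, , i]))
    m / dim(cv)[3]
  }
  Ca <- norm_mean(covs_a)
  Cb <- norm_mean(covs_b)
  Cc <- Ca + Cb
  eps <- 1e-10 * mean(diag(Cc))
  Cc <- Cc + diag(eps, nrow(Cc))
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) < 1e-12 * max(ec$values))
    stop("composite covariance is rank-deficient; regularize the input ",
         "(e.g. drop linearly dependent channels)")
  W0 <- ec$vectors %*% diag(1 / sqrt(ec$values))
  S <- t(W0) %*% Ca %*% W0
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  W <- W0 %*% es$vectors
  # deterministic sign: largest-magnitude coefficient positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  if (!is.null(channel_names)) rownames(W) <- channel_names
  structure(list(W = W, scores = es$values, band = band, problem = problem),
            class = "csp_filters")
}

#' Fit common spatial patterns for one band and one binary problem
#'
#' Solves the two-class CSP problem on band-filtered epochs: per-trial
#' spatial covariances over the task window are trace-normalized and
#' averaged per class, and the generalized eigenproblem of the two class
#' covariances is solved by whitening their sum. The projection `W` jointly
#' diagonalizes both class covariances and whitens their sum
#' (`t(W) %*% (Ca + Cb) %*% W = I`). Component `j`'s eigenvalue score is
#' the class-A variance fraction `lambda_j` (class-B fraction
#' `1 - lambda_j`), sorted descending.
#'
#' @param epochs_a,epochs_b Band-filtered `bci_epochs` of the two classes
#'   (same channels, at least 2 trials each).
#' @param task_window Covariance window in seconds (default 0..10).
#' @return An object of class `csp_filters` with the projection matrix `W`
#'   (channels x components) and per-component `scores`.
#' @export
csp_fit <- function(epochs_a, epochs_b, task_window = c(0, 10)) {
  stopifnot(inherits(epochs_a, "bci_epochs"), inherits(epochs_b, "bci_epochs"))
  if (dim(epochs_a$data)[1] < 2 || dim(epochs_b$data)[1] < 2)
    stop("each class needs at least 2 trials")
  if (!identical(epochs_a$channels$name, epochs_b$channels$name))
    stop("both classes must share the same channel set")
  csp_fit_cov(trial_covariances(epochs_a, task_window),
              trial_covariances(epochs_b, task_window),
              channel_names = epochs_a$channels$name)
}

#' @export
print.csp_filters <- function(x, ...) {
  cat(sprintf("<csp_filters> %d channels -> %d components\n",
              nrow(x$W), ncol(x$W)))
  cat("  eigenvalue scores:", paste(sprintf("%.3f", x$scores), collapse = " "),
      "\n")
  invisible(x)
}

#' Keep the first and last CSP components by eigenvalue score
#'
#' The components most discriminative for each class sit at the two ends
#' of the eigenvalue spectrum; the standard choice keeps the first three
#' and last three.
#'
#' @param filters A `csp_filters` object.
#' @param n_first,n_last Components kept from each end (default 3 + 3).
#' @return A reduced `csp_filters`.
#' @export
csp_select <- function(filters, n_first = 3L, n_last = 3L) {
  stopifnot(inherits(filters, "csp_filters"))
  n <- ncol(filters$W)
  if (n_first + n_last < 1) stop("must keep at least one component")
  if (n_first + n_last > n)
    stop("cannot keep ", n_first, "+", n_last, " components from ", n)
  keep <- c(seq_len(n_first), seq(n - n_last + 1L, n))
  keep <- unique(keep)
  filters$W <- filters$W[, keep, drop = FALSE]
  filters$scores <- filters$scores[keep]
  filters
}

#' Filter-bank CSP log-variance features
#'
#' For each trial and band, projects the band-filtered epoch onto the kept
#' CSP components and takes the log of each component's variance over the
#' task window; features are concatenated across bands (default 6
#' components x 3 bands = 18 features per trial). The spatial filters must
#' have been fitted on a disjoint training set; this function only applies
#' them.
#'
#' @param epochs_by_band Named list of band-filtered `bci_epochs`, all
#'   holding the same trials.
#' @param filters_by_band Named list of (selected) `csp_filters`, aligned
#'   with `epochs_by_band`.
#' @param task_window Variance window in seconds.
#' @return A trials x features numeric matrix with per-trial labels in
#'   `attr(, "labels")`.
#' @export
fbcsp_features <- function(epochs_by_band, filters_by_band,
                           task_window = c(0, 10)) {
  stopifnot(length(epochs_by_band) == length(filters_by_band))
  bands <- names(epochs_by_band)
  feats <- NULL
  for (b in seq_along(epochs_by_band)) {
    ep <- epochs_by_band[[b]]
    W <- filters_by_band[[b]]$W
    idx <- window_index(ep$time, task_window)
    n_tr <- dim(ep$data)[1]
    fb <- matrix(0, n_tr, ncol(W))
    for (i in seq_len(n_tr)) {
      P <- t(W) %*% ep$data[i, , idx]
      v <- apply(P, 1, stats::var)
      if (any(v <= 0))
        stop("zero variance in a CSP component (degenerate signal), trial ", i)
      fb[i, ] <- log(v)
    }
    colnames(fb) <- paste0(if (!is.null(bands)) bands[b] else b,
                           "_csp", seq_len(ncol(W)))
    feats <- cbind(feats, fb)
  }
  attr(feats, "labels") <- epochs_by_band[[1]]$labels
  feats
}

# features from precomputed raw per-trial covariances (fast CV path);
# must agree with fbcsp_features to numerical precision
fbcsp_features_cov <- function(covs_by_band, filters_by_band) {
  feats <- NULL
  for (b in seq_along(covs_by_band)) {
    W <- filters_by_band[[b]]$W
    cv <- covs_by_band[[b]]
    n_tr <- dim(cv)[3]
    fb <- matrix(0, n_tr, ncol(W))
    for (i in seq_len(n_tr))
      fb[i, ] <- log(diag(t(W) %*% cv[, , i] %*% W))
    feats <- cbind(feats, fb)
  }
  feats
}

#' Temporal-mean NIRS features
#'
#' Per trial, the mean of each chromophore trace in each temporal window
#' (default 5-10 s and 10-15 s, chosen for the hemodynamic delay) for each
#' channel. With 16 channels, 2 chromophores and 2 windows this yields 64
#' features per trial, ordered channel-major, then chromophore (HbR, HbO),
#' then window.
#'
#' @param epochs A baseline-corrected hemoglobin `bci_epochs` (see
#'   [nirs_epoch_baseline()]); rows alternate HbR/HbO per channel.
#' @param windows List of half-open windows in seconds.
#' @return A trials x features matrix with labels in `attr(, "labels")`.
#' @export
nirs_mean_features <- function(epochs, windows = list(c(5, 10), c(10, 15))) {
  stopifnot(inherits(epochs, "bci_epochs"), length(windows) >= 1)
  d <- dim(epochs$data)
  idx_list <- lapply(windows, function(w) {
    idx <- window_index(epochs$time, w)
    if (!length(idx))
      stop("empty NIRS feature window [", w[1], ", ", w[2],
           ") after discretization")
    idx
  })
  n_win <- length(windows)
  feats <- matrix(0, d[1], d[2] * n_win)
  cn <- character(d[2] * n_win)
  for (ch in seq_len(d[2])) {
    for (w in seq_len(n_win)) {
      col <- (ch - 1L) * n_win + w
      feats[, col] <- rowMeans(epochs$data[, ch, idx_list[[w]], drop = FALSE],
                               dims = 1)
      cn[col] <- paste0(epochs$channels$name[ch], "_w", w)
    }
  }
  colnames(feats) <- cn
  attr(feats, "labels") <- epochs$labels
  feats
}
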