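# canonical class order: MA, MI, IS when those labels are present
canonical_classes <- function(labels) {
  u <- unique(as.character(labels))
  if (setequal(u, c("MA", "MI", "IS"))) c("MA", "MI", "IS") else sort(u)
}

#' Fit a shrinkage linear discriminant analysis classifier
#'
#' Binary LDA with the pooled empirical covariance `S` replaced by the
#' shrunken estimate `(1 - lambda) * S + lambda * T`. The shrinkage
#' intensity is estimated analytically from the training data
#' (Ledoit-Wolf / Schaefer-Strimmer, clipped to `[0, 1]`). The default
#' target is `T = nu * I` with `nu` the average feature variance, which
#' reduces to the literal identity target for standardized features; the
#' literal `T = I` is available via `target = "identity"`.
#'
#' @param x Trials x features numeric matrix.
#' @param y Binary labels aligned with the rows of `x`.
#' @param lambda Optional fixed shrinkage intensity in `[0, 1]`; `NULL`
#'   (default) estimates it analytically.
#' @param target `"scaled-identity"` (default) or `"identity"`.
#' @param positive Label treated as the positive class (decision values
#'   above zero); defaults to the first class in canonical order.
#' @return An object of class `slda_model` with weights `w`, bias `b`,
#'   intensity `lambda`, and class means.
#' @export
slda_fit <- function(x, y, lambda = NULL,
                     target = c("scaled-identity", "identity"),
                     positive = NULL) {
  target <- match.arg(target)
  x <- as.matrix(x)
  y <- as.character(y)
  if (!all(is.finite(x))) stop("features must be finite")
  classes <- canonical_classes(y)
  if (length(classes) != 2)
    stop("slda_fit needs exactly 2 classes, got ", length(classes))
  if (!is.null(positive)) {
    if (!positive %in% classes) stop("unknown positive class: ", positive)
    classes <- c(positive, setdiff(classes, positive))
  }
  n <- nrow(x); p <- ncol(x)
  mu_pos <- colMeans(x[y == classes[1], , drop = FALSE])
  mu_neg <- colMeans(x[y == classes[2], , drop = FALSE])
  xc <- x
  xc[y == classes[1], ] <- sweep(x[y == classes[1], , drop = FALSE], 2, mu_pos)
  xc[y == classes[2], ] <- sweep(x[y == classes[2], , drop = FALSE], 2, mu_neg)
  wbar <- crossprod(xc) / n
  S <- wbar * n / (n - 1)
  nu <- mean(diag(S))
  if (is.null(lambda)) {
    # Schaefer-Strimmer analytic intensity for the (scaled) identity target:
    # sum of estimated variances of the covariance entries over the squared
    # distance between S and the target
    w2 <- crossprod(xc^2)
    var_s <- n / (n - 1)^3 * (w2 - n * wbar^2)
    tgt <- if (target == "scaled-identity") diag(nu, p) else diag(1, p)
    denom <- sum((S - tgt)^2)
    lambda <- if (denom > 0) sum(var_s) / denom else 1
    lambda <- min(1, max(0, lambda))
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  }
  tgt_diag <- if (target == "scaled-identity") nu else 1
  sigma <- (1 - lambda) * S
  diag(sigma) <- diag(sigma) + lambda * tgt_diag
  w <- solve(sigma, mu_pos - mu_neg)
  b <- -sum(w * (mu_pos + mu_neg)) / 2
  structure(list(w = as.numeric(w), b = b, lambda = lambda, nu = nu,
                 target = target, classes = classes,
                 means = rbind(positive = mu_pos, negative = mu_neg)),
            class = "slda_model")
}

#' @export
print.slda_model <- function(x, ...) {
  cat(sprintf("<slda_model> %s vs %s, p = %d, lambda = %.4f (%s target)\n",
              x$classes[1], x$classes[2], length(x$w), x$lambda, x$target))
  invisible(x)
}

#' Continuous decision values of a fitted sLDA model
#'
#' `d(x) = w' x + b`; the sign gives the predicted class (positive class
#' above zero) and the magnitude serves as the meta-classification feature.
#'
#' @param model An `slda_model`.
#' @param x Trials x features matrix with the model's feature dimension.
#' @return Numeric vector of signed decision values.
#' @export
slda_decision <- function(model, x) {
  stopifnot(inherits(model, "slda_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$w))
    stop("feature dimension mismatch: model expects ", length(model$w),
         ", got ", ncol(x))
  as.numeric(x %*% model$w + model$b)
}

#' Fit the EEG+NIRS meta-classifier for one binary problem
#'
#' Stacks the two base classifiers' decision values into 2-dimensional
#' meta-features (each standardized by its training spread so the two
#' modalities enter on equal scale) and fits an sLDA on them. The supplied
#' decisions must have been produced without leakage, e.g. by inner
#' cross-validation within the training fold.
#'
#' @param eeg_decisions,nirs_decisions Aligned per-trial decision values.
#' @param y Binary labels.
#' @param ... Passed to [slda_fit()].
#' @return An object of class `meta_model`.
#' @export
meta_fit <- function(eeg_decisions, nirs_decisions, y, ...) {
  if (length(eeg_decisions) != length(nirs_decisions) ||
      length(eeg_decisions) != length(y))
    stop("decision vectors and labels must have equal lengths")
  scales <- c(eeg = stats::sd(eeg_decisions), nirs = stats::sd(nirs_decisions))
  scales[scales == 0 | !is.finite(scales)] <- 1
  m <- cbind(eeg = eeg_decisions / scales["eeg"],
             nirs = nirs_decisions / scales["nirs"])
  structure(list(model = slda_fit(m, y, ...), scales = scales),
            class = "meta_model")
}

#' @rdname meta_fit
#' @param meta A fitted `meta_model`.
#' @export
meta_decision <- function(meta, eeg_decisions, nirs_decisions) {
  stopifnot(inherits(meta, "meta_model"))
  m <- cbind(eeg_decisions / meta$scales["eeg"],
             nirs_decisions / meta$scales["nirs"])
  slda_decision(meta$model, m)
}

#' Majority voting over the one-versus-one binary problems
#'
#' A class winning at least two of the three binary votes is the final
#' estimate. The 1-1-1 cycle (each class backed by exactly one vote) is
#' broken deterministically by the largest absolute decision value backing
#' each vote; remaining ties fall back to canonical class order.
#'
#' @param votes Character vector of per-problem class votes (length 3 for
#'   the ternary problem).
#' @param confidences Absolute decision magnitudes aligned with `votes`.
#' @return The winning class label.
#' @export
majority_vote <- function(votes, confidences = rep(0, length(votes))) {
  votes <- as.character(votes)
  counts <- table(votes)
  top <- max(counts)
  leaders <- names(counts)[counts == top]
  if (length(leaders) == 1) return(leaders)
  conf <- vapply(leaders, function(cl) sum(abs(confidences[votes == cl])), 0)
  ord <- canonical_classes(votes)
  leaders <- leaders[order(-conf, match(leaders, ord))]
  leaders[1]
}

# stratified fold assignment: per class, seeded shuffle then round-robin
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("fold count k = ", k, " exceeds trial count of class ", cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated evaluation of the hybrid decoder
#'
#' Repeated stratified k-fold cross-validation of the full one-versus-one
#' chain. Within each training fold and for each binary problem: CSP
#' filters are fitted per band and reduced to the first/last components;
#' an EEG sLDA is fitted on the filter-bank log-variance features and a
#' NIRS sLDA on the temporal-mean features; inner cross-validation within
#' the training fold produces leakage-free base decisions on which the
#' meta sLDA is fitted. Test-fold trials pass through the frozen chain.
#' Unimodal (EEG-only / NIRS-only) results vote on the base decisions
#' without the meta stage. No statistic of any test trial influences any
#' fitted parameter. Deterministic given `seed`.
#'
#' @param eeg_epochs Broadband EEG `bci_epochs` (band filtering is applied
#'   internally per filter-bank band).
#' @param nirs_epochs Baseline-corrected hemoglobin `bci_epochs`, aligned
#'   trial-by-trial with `eeg_epochs`.
#' @param k Outer folds (default 10).
#' @param repetitions Outer repetitions (default 10).
#' @param seed Integer seed.
#' @param bands Filter bank (default [default_filter_bank()]).
#' @param task_window CSP/variance window in seconds.
#' @param nirs_windows NIRS temporal-mean windows.
#' @param n_first,n_last CSP components kept.
#' @param inner_folds Inner folds for meta training (default 5).
#' @param shrinkage_target Passed to [slda_fit()].
#' @return An object of class `bci_cv` holding, per modality, a
#'   repetitions x folds x class x class confusion array.
#' @export
crossvalidate <- function(eeg_epochs, nirs_epochs, k = 10L,
                          repetitions = 10L, seed = 1L,
                          bands = default_filter_bank(),
                          task_window = c(0, 10),
                          nirs_windows = list(c(5, 10), c(10, 15)),
                          n_first = 3L, n_last = 3L, inner_folds = 5L,
                          shrinkage_target = "scaled-identity") {
  stopifnot(inherits(eeg_epochs, "bci_epochs"),
            inherits(nirs_epochs, "bci_epochs"))
  labels <- as.character(eeg_epochs$labels)
  if (!identical(labels, as.character(nirs_epochs$labels)))
    stop("EEG and NIRS trials are not aligned (label mismatch)")
  classes <- canonical_classes(labels)
  n_trial <- length(labels)
  pairs <- utils::combn(classes, 2, simplify = FALSE)

  # fold-independent precomputation (unsupervised, per-trial)
  covs_by_band <- lapply(bands, function(spec) {
    trial_covariances(epochs_bandpass(eeg_epochs, spec), task_window)
  })
  nirs_feats <- nirs_mean_features(nirs_epochs, nirs_windows)

  modalities <- c("eeg", "nirs", "hybrid")
  confusion <- lapply(modalities, function(m)
    array(0L, c(repetitions, k, length(classes), length(classes)),
          dimnames = list(NULL, NULL, classes, classes)))
  names(confusion) <- modalities

  for (r in seq_len(repetitions)) {
    fold <- with_seed(seed + r, stratified_folds(labels, k))
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      dec <- list(eeg = matrix(0, length(test), length(pairs)),
                  nirs = matrix(0, length(test), length(pairs)),
                  hybrid = matrix(0, length(test), length(pairs)))
      vote <- lapply(dec, function(d) matrix("", length(test), length(pairs)))
      for (pidx in seq_along(pairs)) {
        pair <- pairs[[pidx]]
        tr <- train[labels[train] %in% pair]
        y_tr <- labels[tr]

        # EEG: CSP per band on training trials only, then log-variance
        filt <- lapply(covs_by_band, function(cv)
          csp_select(csp_fit_cov(cv[, , tr[y_tr == pair[1]], drop = FALSE],
                                 cv[, , tr[y_tr == pair[2]], drop = FALSE]),
                     n_first, n_last))
        covs_tr <- lapply(covs_by_band, function(cv) cv[, , tr, drop = FALSE])
        covs_te <- lapply(covs_by_band, function(cv) cv[, , test, drop = FALSE])
        x_eeg_tr <- fbcsp_features_cov(covs_tr, filt)
        x_eeg_te <- fbcsp_features_cov(covs_te, filt)
        x_nirs_tr <- nirs_feats[tr, , drop = FALSE]
        x_nirs_te <- nirs_feats[test, , drop = FALSE]

        base_eeg <- slda_fit(x_eeg_tr, y_tr, target = shrinkage_target,
                             positive = pair[1])
        base_nirs <- slda_fit(x_nirs_tr, y_tr, target = shrinkage_target,
                              positive = pair[1])

        # inner CV: leakage-free base decisions for the meta stage
        # (fold count capped by the smallest class so tiny sets still run)
        inner_k <- min(inner_folds, min(table(y_tr)))
        inner <- with_seed(seed + 1000L * r + 17L * f + pidx,
                           stratified_folds(y_tr, inner_k))
        d_eeg_cv <- d_nirs_cv <- numeric(length(tr))
        for (g in seq_len(inner_k)) {
          itr <- inner != g
          m_e <- slda_fit(x_eeg_tr[itr, , drop = FALSE], y_tr[itr],
                          target = shrinkage_target, positive = pair[1])
          m_n <- slda_fit(x_nirs_tr[itr, , drop = FALSE], y_tr[itr],
                          target = shrinkage_target, positive = pair[1])
          d_eeg_cv[!itr] <- slda_decision(m_e, x_eeg_tr[!itr, , drop = FALSE])
          d_nirs_cv[!itr] <- slda_decision(m_n, x_nirs_tr[!itr, , drop = FALSE])
        }
        meta <- meta_fit(d_eeg_cv, d_nirs_cv, y_tr,
                         target = shrinkage_target, positive = pair[1])

        d_e <- slda_decision(base_eeg, x_eeg_te)
        d_n <- slda_decision(base_nirs, x_nirs_te)
        d_h <- meta_decision(meta, d_e, d_n)
        for (mod in modalities) {
          d <- switch(mod, eeg = d_e, nirs = d_n, hybrid = d_h)
          dec[[mod]][, pidx] <- abs(d)
          vote[[mod]][, pidx] <- ifelse(d > 0, pair[1], pair[2])
        }
      }
      for (mod in modalities) {
        pred <- vapply(seq_along(test), function(i)
          majority_vote(vote[[mod]][i, ], dec[[mod]][i, ]), "")
        for (i in seq_along(test))
          confusion[[mod]][r, f, labels[test[i]], pred[i]] <-
            confusion[[mod]][r, f, labels[test[i]], pred[i]] + 1L
      }
    }
  }
  structure(list(confusion = confusion, classes = classes, k = k,
                 repetitions = repetitions, seed = seed,
                 n_trials = n_trial),
            class = "bci_cv")
}

#' @export
print.bci_cv <- function(x, ...) {
  cat(sprintf("<bci_cv> %d x %d-fold, %d trials, classes: %s\n",
              x$repetitions, x$k, x$n_trials,
              paste(x$classes, collapse = ", ")))
  print(accuracy_summary(x))
  invisible(x)
}
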