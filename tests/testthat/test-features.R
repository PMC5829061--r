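test_that("CSP recovers a planted discriminative direction", {
  toy <- planted_epochs(n_trials = 40, n_channels = 4, seed = 7,
                        direction = c(1, -2, 0.5, 1))
  f <- csp_fit(toy$A, toy$B, task_window = c(0, 100))
  w_pat <- solve(t(f$W))[, 1]  # spatial pattern of the top component
  cosine <- abs(sum(w_pat * toy$direction)) /
    sqrt(sum(w_pat^2) * sum(toy$direction^2))
  expect_gt(cosine, 0.99)
  expect_true(all(diff(f$scores) <= 1e-12))  # sorted descending
  expect_gt(f$scores[1], 0.6)                # class A dominates component 1
})

test_that("CSP maximizes the variance ratio (brute-force grid oracle)", {
  toy <- planted_epochs(n_trials = 30, n_channels = 3, seed = 15,
                        direction = c(2, 1, -1), gain = 2)
  Ca <- oracle_class_cov(toy$A)
  Cb <- oracle_class_cov(toy$B)
  # dense grid over the half-sphere of unit spatial filters
  th <- seq(0, pi, length.out = 181)
  ph <- seq(0, 2 * pi, length.out = 361)[-361]
  grid <- rbind(sin(rep(th, each = length(ph))) * cos(ph),
                sin(rep(th, each = length(ph))) * sin(ph),
                cos(rep(th, each = length(ph))))
  ratio <- colSums((Ca %*% grid) * grid) /
    colSums(((Ca + Cb) %*% grid) * grid)
  w_best <- grid[, which.max(ratio)]
  f <- csp_fit(toy$A, toy$B, task_window = c(0, 100))
  w_top <- f$W[, 1]
  cosine <- abs(sum(w_best * w_top)) / sqrt(sum(w_best^2) * sum(w_top^2))
  expect_gt(cosine, 0.99)
  # the filter attains (not exceeds, up to grid resolution) the oracle max
  r_top <- sum(w_top * (Ca %*% w_top)) / sum(w_top * ((Ca + Cb) %*% w_top))
  expect_gt(r_top, max(ratio) - 1e-4)
  expect_equal(r_top, f$scores[1], tolerance = 1e-8)
})

test_that("CSP jointly diagonalizes the class covariances", {
  toy <- planted_epochs(n_trials = 25, n_channels = 5, seed = 8,
                        direction = c(1, 1, 0, -1, 2))
  f <- csp_fit(toy$A, toy$B, task_window = c(0, 100))
  Ca <- oracle_class_cov(toy$A)
  Cb <- oracle_class_cov(toy$B)
  Pa <- t(f$W) %*% Ca %*% f$W
  Pb <- t(f$W) %*% Cb %*% f$W
  expect_lt(max(abs(Pa - diag(diag(Pa)))), 1e-8)
  expect_lt(max(abs(Pb - diag(diag(Pb)))), 1e-8)
  # whitening of the composite: W' (Ca + Cb) W = I
  expect_lt(max(abs(Pa + Pb - diag(ncol(f$W)))), 1e-8)
  # scores are the class-A diagonal: lambda(A) + lambda(B) = 1
  expect_equal(diag(Pa), f$scores, tolerance = 1e-10)
  expect_equal(diag(Pa) + diag(Pb), rep(1, ncol(f$W)), tolerance = 1e-8)
})

test_that("identical classes give 0.5 scores; swapping reverses the spectrum", {
  toy <- planted_epochs(n_trials = 20, n_channels = 4, seed = 12)
  same <- csp_fit(toy$A, toy$A, task_window = c(0, 100))
  expect_lt(max(abs(same$scores - 0.5)), 1e-6)
  ab <- csp_fit(toy$A, toy$B, task_window = c(0, 100))
  ba <- csp_fit(toy$B, toy$A, task_window = c(0, 100))
  expect_equal(sort(ab$scores), sort(1 - ba$scores), tolerance = 1e-8)
})

test_that("component selection keeps both ends of the spectrum", {
  toy <- planted_epochs(n_trials = 20, n_channels = 6, seed = 10)
  f <- csp_fit(toy$A, toy$B, task_window = c(0, 100))
  sel <- csp_select(f, 2, 2)
  expect_equal(ncol(sel$W), 4L)
  expect_equal(sel$scores, f$scores[c(1, 2, 5, 6)])
  expect_equal(ncol(csp_select(f, 3, 3)$W), 6L)  # all kept on 6 channels
  expect_error(csp_select(f, 4, 3), "cannot keep")
  expect_error(csp_select(f, 0, 0), "at least one")
})

test_that("filter-bank features have the contracted dimension and log identity", {
  toy <- planted_epochs(n_trials = 30, n_channels = 6, seed = 3)
  both <- toy$A
  both$data <- abind_trials(toy$A$data, toy$B$data)
  both$labels <- c(toy$A$labels, toy$B$labels)
  bank <- list(theta = both, alpha = both, beta = both)  # already filtered
  f <- csp_select(csp_fit(toy$A, toy$B, task_window = c(0, 100)), 3, 3)
  filters <- list(theta = f, alpha = f, beta = f)
  X <- fbcsp_features(bank, filters, task_window = c(0, 100))
  expect_equal(dim(X), c(60L, 18L))
  expect_true(all(is.finite(X)))
  # doubling a trial's amplitude shifts each log-variance by log(4)
  bank2 <- bank
  bank2$theta$data[1, , ] <- 2 * bank2$theta$data[1, , ]
  X2 <- fbcsp_features(bank2, filters, task_window = c(0, 100))
  expect_equal(unname(X2[1, 1:6] - X[1, 1:6]), rep(log(4), 6),
               tolerance = 1e-10)
  expect_identical(X, fbcsp_features(bank, filters, task_window = c(0, 100)))
})

test_that("channel permutation permutes filters but leaves features unchanged", {
  toy <- planted_epochs(n_trials = 20, n_channels = 4, seed = 19,
                        direction = c(1, 0, -1, 2))
  perm <- c(3, 1, 4, 2)
  permuted_A <- toy$A; permuted_B <- toy$B
  permuted_A$data <- toy$A$data[, perm, ]
  permuted_B$data <- toy$B$data[, perm, ]
  permuted_A$channels <- toy$A$channels[perm, ]
  permuted_B$channels <- toy$B$channels[perm, ]
  f1 <- csp_fit(toy$A, toy$B, task_window = c(0, 100))
  f2 <- csp_fit(permuted_A, permuted_B, task_window = c(0, 100))
  expect_equal(unname(f2$W), unname(f1$W[perm, ]), tolerance = 1e-8)
  X1 <- fbcsp_features(list(b = toy$A), list(b = csp_select(f1, 2, 2)),
                       task_window = c(0, 100))
  X2 <- fbcsp_features(list(b = permuted_A), list(b = csp_select(f2, 2, 2)),
                       task_window = c(0, 100))
  expect_equal(X1, X2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("NIRS temporal means have dimension 64 and match closed forms", {
  rate <- 13.3
  ch <- nirs_channel_table(chromophores = c("HbR", "HbO"))
  n_time <- floor(30 * rate + 1e-6)
  time <- seq(-5, by = 1 / rate, length.out = n_time)
  # constant traces: every feature equals the constant
  arr <- array(2.5, c(60, nrow(ch), n_time))
  ep <- structure(list(data = arr, time = time, labels = rep("MA", 60),
                       rate = rate, channels = ch, unit = "mM.cm"),
                  class = "bci_epochs")
  X <- nirs_mean_features(ep)
  expect_equal(dim(X), c(60L, 64L))
  expect_true(all(abs(X - 2.5) < 1e-12))
  # linear ramp x(t) = t: mean over window [a, b) is the mean of the
  # sample times in the window (exact closed form on the grid)
  arr2 <- array(rep(time, each = 60 * nrow(ch)), c(60, nrow(ch), n_time))
  ep$data <- arr2
  X2 <- nirs_mean_features(ep)
  idx1 <- which(time >= 5 - 1e-9 & time < 10 - 1e-9)
  idx2 <- which(time >= 10 - 1e-9 & time < 15 - 1e-9)
  expect_equal(unname(X2[1, 1]), mean(time[idx1]), tolerance = 1e-12)
  expect_equal(unname(X2[1, 2]), mean(time[idx2]), tolerance = 1e-12)
  expect_error(nirs_mean_features(ep, windows = list(c(40, 50))),
               "empty NIRS feature window")
})

test_that("cov-based fast path agrees with the direct feature path", {
  toy <- planted_epochs(n_trials = 15, n_channels = 4, seed = 30)
  f <- list(b = csp_select(csp_fit(toy$A, toy$B, task_window = c(0, 100)),
                           2, 2))
  X_direct <- fbcsp_features(list(b = toy$A), f, task_window = c(0, 100))
  covs <- hybridbci:::trial_covariances(toy$A, c(0, 100))
  X_cov <- hybridbci:::fbcsp_features_cov(list(b = covs), f)
  expect_equal(unname(X_direct), unname(X_cov), tolerance = 1e-12,
               ignore_attr = TRUE)
})
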