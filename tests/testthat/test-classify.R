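test_that("sLDA separates well-separated Gaussian clouds", {
  set.seed(101)
  p <- 10; n <- 200
  mu <- c(rep(2, 8), rep(0, p - 8))  # Mahalanobis distance 5.7: near-perfect
  xtr <- rbind(sweep(matrix(rnorm(n * p), n), 2, mu, "+"),
               matrix(rnorm(n * p), n))
  ytr <- rep(c("MA", "MI"), each = n)
  xte <- rbind(sweep(matrix(rnorm(n * p), n), 2, mu, "+"),
               matrix(rnorm(n * p), n))
  yte <- rep(c("MA", "MI"), each = n)
  m <- slda_fit(xtr, ytr)
  pred <- ifelse(slda_decision(m, xte) > 0, m$classes[1], m$classes[2])
  expect_gte(mean(pred == yte), 0.99)
  expect_true(m$lambda >= 0 && m$lambda <= 1)
  expect_error(slda_fit(xtr, rep("MA", 2 * n)), "2 classes")
})

test_that("lambda = 1 reduces to the nearest-class-mean direction", {
  set.seed(5)
  x <- matrix(rnorm(60 * 6), 60)
  x[1:30, ] <- x[1:30, ] + 1
  y <- rep(c("MA", "MI"), each = 30)
  m <- slda_fit(x, y, lambda = 1)
  diff_mu <- colMeans(x[1:30, ]) - colMeans(x[31:60, ])
  cosine <- sum(m$w * diff_mu) / sqrt(sum(m$w^2) * sum(diff_mu^2))
  expect_equal(cosine, 1, tolerance = 1e-10)
})

test_that("duplicated feature columns do not break the shrunken fit", {
  set.seed(6)
  x <- matrix(rnorm(40 * 4), 40)
  x <- cbind(x, x)  # rank-deficient empirical covariance
  y <- rep(c("MA", "IS"), each = 20)
  m <- slda_fit(x, y)
  expect_true(all(is.finite(m$w)))
  expect_gt(m$lambda, 0)
  expect_true(all(is.finite(slda_decision(m, x))))
})

test_that("decision values behave at the boundary and under affine shifts", {
  set.seed(7)
  x <- matrix(rnorm(80 * 5), 80)
  x[1:40, ] <- x[1:40, ] + 2
  y <- rep(c("MA", "MI"), each = 40)
  m <- slda_fit(x, y)
  mid <- (m$means["positive", ] + m$means["negative", ]) / 2
  expect_equal(slda_decision(m, matrix(mid, 1)), 0, tolerance = 1e-10)
  d_means <- slda_decision(m, m$means)
  expect_gt(d_means[1], 0)
  expect_lt(d_means[2], 0)
  # affine shift of train and test features leaves decisions unchanged
  shift <- rnorm(5)
  m2 <- slda_fit(sweep(x, 2, shift, "+"), y)
  xte <- matrix(rnorm(20 * 5), 20)
  d1 <- slda_decision(m, xte)
  d2 <- slda_decision(m2, sweep(xte, 2, shift, "+"))
  expect_equal(d1, d2, tolerance = 1e-8)
  expect_error(slda_decision(m, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("stacking complementary base classifiers beats either alone", {
  # two modalities, each ~75% accurate with independent errors
  set.seed(8)
  n <- 600
  y <- rep(c("MA", "MI"), each = n / 2)
  s <- ifelse(y == "MA", 1, -1)
  sd_75 <- 1 / qnorm(0.75)
  d_eeg <- s + rnorm(n, 0, sd_75)
  d_nirs <- s + rnorm(n, 0, sd_75)
  tr <- sample(n, n / 2)
  meta <- meta_fit(d_eeg[tr], d_nirs[tr], y[tr])
  te <- setdiff(seq_len(n), tr)
  pred_meta <- ifelse(meta_decision(meta, d_eeg[te], d_nirs[te]) > 0,
                      "MA", "MI")
  acc_meta <- mean(pred_meta == y[te])
  acc_eeg <- mean(ifelse(d_eeg[te] > 0, "MA", "MI") == y[te])
  acc_nirs <- mean(ifelse(d_nirs[te] > 0, "MA", "MI") == y[te])
  expect_gt(acc_meta, acc_eeg)
  expect_gt(acc_meta, acc_nirs)
})

test_that("stacking never loses much to a dominant modality", {
  set.seed(9)
  n <- 400
  y <- rep(c("MA", "MI"), each = n / 2)
  s <- ifelse(y == "MA", 1, -1)
  d_eeg <- s * (1 + abs(rnorm(n, 0, 0.1)))   # perfectly separating
  d_noise <- rnorm(n)                         # pure noise
  tr <- sample(n, n / 2)
  te <- setdiff(seq_len(n), tr)
  meta <- meta_fit(d_eeg[tr], d_noise[tr], y[tr])
  pred <- ifelse(meta_decision(meta, d_eeg[te], d_noise[te]) > 0, "MA", "MI")
  acc_eeg <- mean(ifelse(d_eeg[te] > 0, "MA", "MI") == y[te])
  expect_gte(mean(pred == y[te]), acc_eeg - 0.02)
  # identical modalities reproduce the base decisions' accuracy
  meta2 <- meta_fit(d_eeg[tr], d_eeg[tr], y[tr])
  pred2 <- ifelse(meta_decision(meta2, d_eeg[te], d_eeg[te]) > 0, "MA", "MI")
  expect_equal(mean(pred2 == y[te]), acc_eeg)
  expect_error(meta_fit(1:3, 1:4, c("a", "b", "a")), "equal lengths")
})

test_that("majority voting follows the stated rule incl. the 1-1-1 tie", {
  expect_equal(majority_vote(c("MA", "MA", "MI"), c(0.2, 0.3, 5)), "MA")
  expect_equal(majority_vote(c("MI", "MI", "MI"), c(1, 1, 1)), "MI")
  expect_equal(majority_vote(c("MA", "IS", "MI"), c(0.9, 0.1, 0.2)), "MA")
  expect_equal(majority_vote(c("MA", "IS", "MI"), c(0.1, 0.8, 0.2)), "IS")
  # exactly equal confidences fall back to canonical order deterministically
  expect_equal(majority_vote(c("IS", "MI", "MA"), c(0.5, 0.5, 0.5)), "MA")
})

test_that("cross-validation bookkeeping: confusion sums, determinism, errors", {
  ses <- simulate_session(small_sim_config(seed = 31, n = 6))
  pre <- preprocess_session(ses)
  cv <- crossvalidate(pre$eeg, pre$nirs, k = 3, repetitions = 2, seed = 4)
  for (mod in names(cv$confusion)) {
    conf <- cv$confusion[[mod]]
    # every fold's confusion entries sum to the number of test trials
    for (r in 1:2)
      for (f in 1:3)
        expect_equal(sum(conf[r, f, , ]), 6)
    # row sums equal per-class test counts (stratified folds: 2 each)
    pooled <- apply(conf[1, , , , drop = FALSE], c(3, 4), sum)
    expect_equal(unname(rowSums(pooled)), rep(6, 3))
  }
  cv2 <- crossvalidate(pre$eeg, pre$nirs, k = 3, repetitions = 2, seed = 4)
  expect_identical(cv$confusion, cv2$confusion)
  expect_error(crossvalidate(pre$eeg, pre$nirs, k = 7, repetitions = 1),
               "exceeds trial count")
  bad <- pre$nirs
  bad$labels <- rev(bad$labels)
  expect_error(crossvalidate(pre$eeg, bad, k = 3), "not aligned")
})
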