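test_that("downsampling preserves in-band sinusoids (analytic oracle)", {
  rate <- 2048
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  ch <- channel_table("c1", "EEG", "central")
  rec <- new_recording(matrix(sin(2 * pi * 10 * t), 1), rate, ch)
  out <- downsample(rec, 200)
  expect_equal(out$rate, 200)
  t_new <- (seq_len(ncol(out$data)) - 1) / 200
  i <- which(t_new > 1 & t_new < 9)
  # amplitude within 1% of the analytic sinusoid
  expect_lt(max(abs(out$data[1, i] - sin(2 * pi * 10 * t_new[i]))), 0.01)
})

test_that("downsampling attenuates content above the new Nyquist", {
  rate <- 2048
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  ch <- channel_table("c1", "EEG", "central")
  mk <- function(f) new_recording(matrix(sin(2 * pi * f * t), 1), rate, ch)
  # 90 Hz is below the new Nyquist (100 Hz): preserved
  out90 <- downsample(mk(90), 200)
  i <- 200:1800
  expect_gt(mean(out90$data[1, i]^2) / 0.5, 0.9)
  # 150 Hz is above: residual power < 0.1% of input power
  out150 <- downsample(mk(150), 200)
  expect_lt(mean(out150$data[1, i]^2) / 0.5, 1e-3)
})

test_that("event onsets are rescaled to the new rate", {
  rate <- 2048
  ev <- data.frame(onset_sample = 2048L, label = "MA")
  rec <- toy_recording(2, rate = rate, duration = 5, events = ev)
  out <- downsample(rec, 200)
  expect_identical(out$events$onset_sample, 200L)
  expect_error(downsample(rec, 4096), "must be below")
})

test_that("regression EOG removal recovers a planted mixture", {
  set.seed(3)
  n <- 5000
  clean <- matrix(rnorm(3 * n), 3)
  eog <- matrix(cumsum(rnorm(n)), 1)  # smooth artifact reference
  g <- c(0.8, -0.5, 0.3)
  mixed <- clean + g %o% drop(eog)
  ch <- channel_table(c("a", "b", "c", "VEOG"),
                      c("EEG", "EEG", "EEG", "EOG"),
                      c("frontal", "frontal", "central", "other"))
  rec <- new_recording(rbind(mixed, eog), 100, ch)
  out <- remove_eog(rec, "VEOG")
  expect_equal(nrow(out$data), 3L)
  for (i in 1:3)
    expect_lt(abs(cor(out$data[i, ], drop(eog))), 0.05)
})

test_that("zero EOG leaves EEG channels untouched and missing EOG errors", {
  ch <- channel_table(c("a", "b", "VEOG"), c("EEG", "EEG", "EOG"),
                      c("central", "central", "other"))
  x <- matrix(rnorm(2 * 100), 2)
  rec <- new_recording(rbind(x, 0), 100, ch)
  out <- remove_eog(rec)
  expect_equal(out$data, rec$data[1:2, ], ignore_attr = TRUE)
  rec2 <- toy_recording(2)
  expect_error(remove_eog(rec2), "skip")
})

test_that("EOG removal reduces frontal low-frequency power on simulated blinks", {
  cfg <- small_sim_config(seed = 13, n = 4)
  eeg <- simulate_eeg(cfg)
  cleaned <- remove_eog(eeg)
  frontal <- which(eeg$channels$region == "frontal" &
                     eeg$channels$modality == "EEG")
  lp <- function(rec, rows) {
    y <- bandpass(rec, filter_spec(0.2, 4, 4))
    mean(y$data[rows, ]^2)
  }
  expect_lt(lp(cleaned, seq_along(frontal)), lp(eeg, frontal))
})

test_that("epoching has exact geometry and validates its window", {
  ev <- data.frame(onset_sample = c(1000L, 3000L), label = c("MA", "MI"))
  rec <- toy_recording(3, rate = 200, duration = 40, events = ev)
  ep <- epoch_recording(rec, c(-5, 25))
  expect_equal(dim(ep$data), c(2L, 3L, 6000L))
  expect_equal(ep$labels, c("MA", "MI"))
  expect_equal(ep$time[1], -5)
  expect_equal(diff(ep$time)[1], 1 / 200)
  # trial 1 onset at sample 1000 (t = 5 s): window starts at sample 0
  expect_identical(ep$data[1, , 1], unname(rec$data[, 1]))
  expect_error(epoch_recording(rec, c(0, 0)), "empty epoch window")
  ev2 <- data.frame(onset_sample = 100L, label = "IS")
  rec2 <- toy_recording(1, rate = 200, duration = 40, events = ev2)
  expect_error(epoch_recording(rec2, c(-5, 25)), "trial 1")
})

test_that("epoching adjacent windows tiles the recording losslessly", {
  ev <- data.frame(onset_sample = c(400L, 800L, 1200L),
                   label = c("MA", "MI", "IS"))
  rec <- toy_recording(2, rate = 100, duration = 20, events = ev)
  ep <- epoch_recording(rec, c(0, 4))
  tiled <- cbind(ep$data[1, , ], ep$data[2, , ], ep$data[3, , ])
  expect_identical(tiled, unname(rec$data[, 401:1600]))
})
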