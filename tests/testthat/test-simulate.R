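test_that("schedule has the study trial structure and is seed-deterministic", {
  cfg <- simulation_config(seed = 5)
  sch <- build_schedule(cfg)
  expect_equal(nrow(sch$events), 90L)
  expect_equal(as.vector(table(sch$events$label)), rep(30L, 3))
  gaps <- diff(sch$events$onset_time)
  expect_true(all(gaps >= cfg$task_duration + cfg$iti_range[1] - 1e-9))
  expect_true(all(gaps <= cfg$task_duration + cfg$iti_range[2] + 1e-9))
  expect_identical(sch, build_schedule(simulation_config(seed = 5)))
  # different seed, different order
  sch2 <- build_schedule(simulation_config(seed = 6))
  expect_false(identical(sch$events$label, sch2$events$label))
  expect_equal(nrow(build_schedule(simulation_config(n_trials_per_class = 1,
                                                     seed = 1))$events), 3L)
})

test_that("simulated recordings are bit-identical for identical configs", {
  cfg <- small_sim_config(seed = 11, n = 2)
  a <- simulate_session(cfg)
  b <- simulate_session(small_sim_config(seed = 11, n = 2))
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$nirs$data, b$nirs$data)
  expect_identical(a$eeg$events, b$eeg$events)
})

test_that("EEG stream has the expected layout and rate", {
  cfg <- small_sim_config(n = 2)
  eeg <- simulate_eeg(cfg)
  expect_equal(nrow(eeg$data), 22L)  # 21 EEG + 1 EOG
  expect_equal(eeg$rate, cfg$eeg_rate)
  expect_equal(sum(eeg$channels$modality == "EOG"), 1L)
  expect_equal(nrow(eeg$events), 6L)
})

test_that("motor-imagery trials show central alpha suppression vs idle", {
  # ERD factor well below 1 must depress central alpha-band variance in MI
  # task windows relative to IS windows, measured over >= 30 trials
  cfg <- simulation_config(n_trials_per_class = 30, iti_range = c(4, 5),
                           lead_in = 8, lead_out = 8, seed = 21,
                           eeg_effect = list(MA = c(),
                                             MI = c(central_alpha = 0.5),
                                             IS = c()),
                           eeg_amp_wander_sd = 0.1, effect_jitter_sd = 0.1)
  eeg <- simulate_eeg(cfg)
  alpha <- bandpass(eeg, filter_spec(8, 13, 4))
  ep <- epoch_recording(alpha, c(0, 10))
  central <- which(ep$channels$region == "central" &
                     ep$channels$modality == "EEG")
  pwr <- function(lab) {
    idx <- which(ep$labels == lab)
    mean(apply(ep$data[idx, central, , drop = FALSE], 1:2, var))
  }
  expect_lt(pwr("MI"), pwr("IS"))
})

test_that("unit effect factors give equal band power across classes", {
  cfg <- simulation_config(n_trials_per_class = 20, iti_range = c(4, 5),
                           lead_in = 8, lead_out = 8, seed = 22,
                           eeg_effect = list(MA = c(), MI = c(), IS = c()),
                           eeg_amp_wander_sd = 0, effect_jitter_sd = 0)
  eeg <- simulate_eeg(cfg)
  alpha <- bandpass(eeg, filter_spec(8, 13, 4))
  ep <- epoch_recording(alpha, c(0, 10))
  central <- which(ep$channels$region == "central" &
                     ep$channels$modality == "EEG")
  pwr <- sapply(c("MA", "MI", "IS"), function(lab) {
    idx <- which(ep$labels == lab)
    mean(apply(ep$data[idx, central, , drop = FALSE], 1:2, var))
  })
  expect_lt(max(pwr) / min(pwr), 1.15)  # equal within sampling error
})

test_that("NIRS stream is 16 channels x 3 wavelengths at 13.3 Hz and the
           optical densities invert exactly to the latent hemodynamics", {
  cfg <- small_sim_config(n = 2,
                          nirs_noise = c(mayer = 0, respiratory = 0,
                                         cardiac = 0, white = 0, drift = 0))
  nirs <- simulate_nirs(cfg)
  expect_equal(nrow(nirs$data), 48L)
  expect_equal(nirs$rate, 13.3)
  hb <- mbll_convert(nirs)
  latent <- attr(nirs, "latent_hb")
  expect_lt(max(abs(hb$data - latent$data)), 1e-9)
})

test_that("zero effects and zero noise give identically zero OD traces", {
  cfg <- small_sim_config(n = 2,
                          nirs_effect = c(MA = 0, MI = 0, IS = 0),
                          nirs_noise = c(mayer = 0, respiratory = 0,
                                         cardiac = 0, white = 0, drift = 0))
  nirs <- simulate_nirs(cfg)
  expect_equal(max(abs(nirs$data)), 0)
})

test_that("hemodynamic model has opposite-signed chromophores with HbO larger", {
  hrf <- hemodynamic_response_model()
  expect_lt(hrf$hbr_ratio, 0)
  expect_lt(abs(hrf$hbr_ratio), 1)
  cfg <- small_sim_config(n = 2,
                          nirs_noise = c(mayer = 0, respiratory = 0,
                                         cardiac = 0, white = 0, drift = 0))
  latent <- attr(simulate_nirs(cfg), "latent_hb")
  hbo <- latent$data[latent$channels$chromophore == "HbO", ]
  hbr <- latent$data[latent$channels$chromophore == "HbR", ]
  expect_gt(max(hbo), 0)
  expect_equal(max(abs(hbr)) / max(abs(hbo)), 1 / 3, tolerance = 1e-9)
  expect_lt(max(hbr * hbo), 1e-12)  # pointwise opposite signs
  expect_error(hemodynamic_response_model(hbr_ratio = 0.5), "negative")
})
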