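test_that("all-zero gains give all-zero signals with the right trial count", {
  cfg <- quiet_config(seed = 3)
  ses <- generate_session(cfg)
  expect_true(all(ses$recording$data == 0))
  expect_equal(length(ses$stims$onsets), 10)
  expect_equal(ses$recording$channels, c("EEG", "L6", "VPm", "PoM"))
})

test_that("generation is bit-identical under a repeated seed", {
  cfg <- tiny_config(seed = 11)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$stims$onsets, b$stims$onsets)
})

test_that("full shared mix makes L6 and VPm gamma signals proportional", {
  cfg <- quiet_config(seed = 5, background_gains = gains_only("gamma"),
                      shared_gamma_mix = 1)
  ses <- generate_session(cfg)
  l6 <- ses$recording$data["L6", ]
  vpm <- ses$recording$data["VPm", ]
  expect_gt(sd(l6), 0)
  expect_lt(max(abs(l6 - vpm)), 1e-10 * sd(l6))   # identical up to gain 1
})

test_that("a gamma-only session concentrates spectral power in 30-80 Hz", {
  cfg <- quiet_config(seed = 9, background_gains = gains_only("gamma"))
  ses <- generate_session(cfg)
  x <- ses$recording$data["PoM", ]
  p <- Mod(stats::fft(x))^2
  f <- fft_freqs_for_test(length(x), ses$recording$sampling_rate)
  expect_gt(sum(p[abs(f) >= 30 & abs(f) <= 80]) / sum(p), 0.90)
})

test_that("induced bursts are random-phase: they vanish in the trial average", {
  cfg <- session_config(seed = 13, inter_stimulus_interval = 2,
                        background_gains = silent_gains, pink_gain = 0,
                        evoked_amplitude = 0, broadband_noise_gain = 0,
                        induced_gain_beta = 0, induced_gain_gamma = 1)
  ses <- generate_session(cfg)   # 40 trials, gamma bursts only
  late <- extract_epochs(ses$recording, ses$stims, "PoM", late_window())
  avg_power <- mean(colMeans(late$trials)^2)
  single_power <- mean(late$trials[1, ]^2)
  expect_lt(avg_power, 0.10 * single_power)
})

test_that("the evoked kernel is phase-locked and avoids the late window", {
  cfg <- quiet_config(seed = 2, evoked_amplitude = 5)
  ses <- generate_session(cfg)
  early <- extract_epochs(ses$recording, ses$stims, "L6", c(0, 0.2))
  # identical every trial: trial average power == single-trial power
  expect_equal(mean(colMeans(early$trials)^2), mean(early$trials[1, ]^2),
               tolerance = 1e-12)
  expect_gt(mean(early$trials[1, ]^2), 0)
  # nothing leaks past 200 ms
  late <- extract_epochs(ses$recording, ses$stims, "L6", late_window())
  expect_true(all(late$trials == 0))
})

test_that("condition pairs share trial structure and differ by RNG stream", {
  sal <- tiny_config(seed = 21)
  pair <- generate_condition_pair(sal, sal)   # identical configs
  expect_identical(pair$saline$stims$onsets, pair$ketamine$stims$onsets)
  expect_false(identical(pair$saline$recording$data,
                         pair$ketamine$recording$data))
  mismatched <- tiny_config(seed = 21)
  mismatched$n_rats <- 3L
  expect_error(generate_condition_pair(sal, mismatched), "trial structure")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(session_config(shared_gamma_mix = 1.2), "\\[0, 1\\]")
  expect_error(session_config(evoked_amplitude = -1), ">= 0")
  expect_error(session_config(inter_stimulus_interval = 0.5), "analysis span")
})

test_that("recordings round-trip through the binary+JSON format", {
  ses <- generate_session(tiny_config(seed = 4))
  dir <- withr::local_tempdir()
  write_recording(ses$recording, dir)
  back <- read_recording(dir)
  expect_identical(back$data, ses$recording$data)
  expect_equal(back$sampling_rate, ses$recording$sampling_rate)
  expect_equal(back$condition_label, ses$recording$condition_label)
  tsv <- file.path(dir, "onsets.tsv")
  write_stim_train(ses$stims, tsv)
  expect_equal(read_stim_train(tsv)$onsets, ses$stims$onsets)
})

test_that("session configs round-trip through JSON and YAML files", {
  dir <- withr::local_tempdir()
  jpath <- file.path(dir, "cfg.json")
  jsonlite::write_json(
    list(seed = 9, n_rats = 2, n_trials_per_rat = 5,
         inter_stimulus_interval = 2, shared_gamma_mix = 0.5,
         background_gains = list(delta = 4, theta = 1, sigma = 1.5,
                                 beta = 1, gamma = 1)),
    jpath, auto_unbox = TRUE)
  cfg <- read_session_config(jpath)
  expect_equal(cfg$shared_gamma_mix, 0.5)
  expect_identical(generate_session(cfg)$recording$data,
                   generate_session(tiny_config(seed = 9,
                                                shared_gamma_mix = 0.5))$recording$data)

  ypath <- file.path(dir, "cfg.yaml")
  writeLines(c("seed: 9", "n_rats: 2", "n_trials_per_rat: 5",
               "inter_stimulus_interval: 2"), ypath)
  expect_equal(read_session_config(ypath)$seed, 9L)
  writeLines("bogus_field: 1", file.path(dir, "bad.yaml"))
  expect_error(read_session_config(file.path(dir, "bad.yaml")), "unknown config")
})
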