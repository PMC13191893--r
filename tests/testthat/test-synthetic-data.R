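test_that("USV generator handles the empty case and is seed-deterministic", {
  rec <- gen_usv_recording(list(), noise_sd = 0, seed = 1)
  expect_true(all(rec$waveform == 0))
  expect_equal(nrow(rec$truth), 0)

  specs <- list(call_spec("flat", 0.02, 0.03, 70e3, 70e3),
                call_spec("chevron", 0.08, 0.04, 60e3, 62e3))
  r1 <- gen_usv_recording(specs, noise_sd = 0.01, seed = 42)
  r2 <- gen_usv_recording(specs, noise_sd = 0.01, seed = 42)
  expect_identical(r1$waveform, r2$waveform)
  expect_identical(r1$truth, r2$truth)
  r3 <- gen_usv_recording(specs, noise_sd = 0.01, seed = 43)
  expect_false(identical(r1$waveform, r3$waveform))
})

test_that("generated flat call concentrates spectral power at its frequency", {
  rec <- gen_usv_recording(list(call_spec("flat", 0.02, 0.05, 70e3, 70e3)),
                           noise_sd = 0, seed = 1)
  sg <- compute_spectrogram(rec$waveform, rec$fs)
  # frames fully inside the call (clear of onset/offset ramps)
  inside <- sg$times > 0.025 & sg$times < 0.065
  peak_bins <- apply(sg$power[inside, ], 1, which.max)
  bin_width <- rec$fs / 512
  expect_true(all(abs(sg$freqs[peak_bins] - 70e3) <= bin_width))
})

test_that("USV generator rejects overlapping calls and sub-Nyquist rates", {
  specs <- list(call_spec("flat", 0.02, 0.05, 70e3, 70e3),
                call_spec("flat", 0.04, 0.05, 60e3, 60e3))
  expect_error(gen_usv_recording(specs, seed = 1), "overlap")
  expect_error(
    gen_usv_recording(list(call_spec("flat", 0.02, 0.05, 110e3, 110e3)),
                      fs = 200e3, seed = 1),
    "Nyquist")
  expect_error(call_spec("flat", 0.02, 0.05, 5e3, 70e3), "10-120")
  expect_error(call_spec("flat", 0.02, -0.05, 70e3, 70e3), "duration")
})

test_that("every generated call appears exactly once in the truth table", {
  rec <- make_recording(20, seed = 5)
  expect_equal(nrow(rec$truth), 20)
  expect_equal(anyDuplicated(rec$truth$onset_s), 0)
  expect_true(all(diff(rec$truth$onset_s) > 0))
  expect_true(all(rec$truth$offset_s > rec$truth$onset_s))
})

test_that("FRA trial generator matches its generative model", {
  grid <- default_tone_grid()
  expect_equal(length(grid$freqs_hz), 8)
  expect_equal(grid$levels_db, seq(20, 80, 10))

  # noiseless tuned cell: response at (BF, max level) equals gain
  sp <- ensemble_spec(1, is_tuned = TRUE, bf_hz = 16000, threshold_db = 40,
                      gain = 1.7, noise_sd = 0)
  g <- gen_fra_trials(sp, seed = 1)
  expect_equal(nrow(g$trials), 8 * 7 * 15)
  at_peak <- g$trials$frequency_hz == 16000 & g$trials$level_db == 80
  expect_equal(unique(g$trials$evoked[at_peak]), 1.7)

  # untuned cell: law of large numbers pulls the mean to 0
  grid500 <- default_tone_grid(); grid500$n_repeats <- 500L
  sp0 <- ensemble_spec(1, is_tuned = FALSE, grid = grid500)
  g0 <- gen_fra_trials(sp0, seed = 2)
  expect_lt(abs(mean(g0$trials$evoked)), 0.01)

  # determinism and truth bookkeeping
  g2 <- gen_fra_trials(sp, seed = 1)
  expect_identical(g$trials, g2$trials)
  expect_equal(g$truth$bf_hz, 16000)
  expect_error(gen_fra_trials(ensemble_spec(
    1, grid = list(freqs_hz = c(4e3, 8e3), levels_db = c(60, 70),
                   n_repeats = 1L))), "n_repeats")
})

test_that("behavior generator hits its psychometric probabilities", {
  # degenerate observer: infinite sensitivity, no lapse/guess
  sp <- psycho_spec(nontarget_hz = 4000, sessions = 1,
                    trials_per_condition = 200,
                    sensitivity = function(u) Inf,
                    lapse_rate = 0, guess_rate = 0)
  perf <- session_performance(score_trials(gen_behavior_sessions(sp, seed = 1)))
  expect_equal(perf$hit_rate, 1)
  expect_equal(perf$fa_rate, 0)

  # null observer: hit rate ~ false-alarm rate within a binomial band
  sp0 <- psycho_spec(nontarget_hz = 4000, sessions = 1,
                     trials_per_condition = 1000,
                     sensitivity = function(u) 0)
  tr <- gen_behavior_sessions(sp0, seed = 2)
  perf0 <- session_performance(score_trials(tr))
  p_expect <- 0.05 + (1 - 0.05 - 0.02) * 0.5
  ci_half <- stats::qnorm(0.995) * sqrt(p_expect * (1 - p_expect) / 1000)
  expect_lt(abs(perf0$hit_rate - p_expect), ci_half)
  expect_lt(abs(perf0$fa_rate - p_expect), ci_half)
  expect_lt(abs(perf0$hit_rate - perf0$fa_rate), 2 * ci_half)

  # determinism; zero-trial rejection
  expect_identical(gen_behavior_sessions(sp0, seed = 2), tr)
  expect_error(psycho_spec(trials_per_condition = 0), ">= 1")
  expect_error(psycho_spec(target_hz = 12000, nontarget_hz = c(4000, 12000)),
               "distinct")
})

test_that("ABR generator follows its growth law and noise model", {
  sp <- abr_spec(true_threshold_db = 40, slope_uv_per_db = 0.05, noise_sd = 0)
  s <- gen_abr_series(sp, seed = 1)
  below <- s$levels_db < 40
  expect_true(all(s$average[, below] == 0))
  # generative wave-I amplitude at threshold + 20 dB equals 20 * slope
  expect_equal(s$true_wave1_uv[match(60, s$levels_db)], 20 * 0.05)
  # same seed, same waveforms
  expect_identical(gen_abr_series(sp, seed = 1), s)
})
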