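test_that("spectrogram conventions: pure tone, silence, white-noise flatness", {
  fs <- 250e3
  tone <- sin(2 * pi * 70e3 * seq(0, 0.02, by = 1 / fs))
  sg <- compute_spectrogram(tone, fs)
  peak_bins <- apply(sg$power, 1, which.max)
  expect_true(all(abs(sg$freqs[peak_bins] - 70e3) <= fs / 512))

  sg0 <- compute_spectrogram(numeric(5000), fs)
  expect_true(all(sg0$power == 0))

  # white noise: equal energy in equal-width bands (flat-spectrum oracle)
  wn <- withr::with_seed(11, stats::rnorm(300e3))
  sgn <- compute_spectrogram(wn, fs)
  expect_gte(nrow(sgn$power), 1000)
  edges <- seq(20e3, 120e3, by = 25e3)
  band_energy <- vapply(seq_len(length(edges) - 1), function(b) {
    cols <- sgn$freqs >= edges[b] & sgn$freqs < edges[b + 1]
    mean(sgn$power[, cols])
  }, numeric(1))
  expect_lt(diff(range(band_energy)) / mean(band_energy), 0.05)

  # Parseval consistency: integrated PSD of a unit-variance noise ~ 1
  total <- mean(rowSums(sgn$power)) * (sgn$freqs[2] - sgn$freqs[1])
  expect_lt(abs(total - 1), 0.05)

  expect_error(compute_spectrogram(numeric(0), fs), "empty")
  expect_error(compute_spectrogram(tone, -1), "positive")
  expect_error(compute_spectrogram(tone[1:100], fs, window_samples = 512),
               "exceeds")
})

test_that("detection finds silence empty and recovers one call's boundaries", {
  rec0 <- gen_usv_recording(list(), noise_sd = 0.01, seed = 3,
                            duration_s = 1)
  sg0 <- compute_spectrogram(rec0$waveform, rec0$fs)
  expect_equal(nrow(detect_calls(sg0)), 0)

  rec <- gen_usv_recording(list(call_spec("flat", 0.1, 0.05, 70e3, 70e3)),
                           noise_sd = snr_noise_sd(0.25, 20), seed = 4,
                           duration_s = 0.5)
  sg <- compute_spectrogram(rec$waveform, rec$fs)
  det <- detect_calls(sg)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$start_s - 0.1), 0.005)
  expect_lt(abs(det$end_s - 0.15), 0.005)

  expect_error(detect_calls(sg, k_mad = -1), "positive")
  expect_error(detect_calls(sg, band = c(30e3, 200e3)), "band")
})

test_that("detection is perfect on 20 calls at 20 dB SNR and monotone in threshold", {
  rec <- make_recording(20, seed = 7, snr_db = 20)
  sg <- compute_spectrogram(rec$waveform, rec$fs)
  det <- detect_calls(sg)
  ev <- evaluate_detection(det, rec$truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  n_calls <- vapply(c(2, 5, 10, 20, 50),
                    function(k) nrow(detect_calls(sg, k_mad = k)), numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("feature extraction recovers flat, chirp and chevron structure", {
  fs <- 250e3
  bin <- fs / 512
  specs <- list(call_spec("flat", 0.05, 0.05, 70e3, 70e3),
                call_spec("flat", 0.25, 0.05, 60e3, 80e3),       # linear chirp
                call_spec("chevron", 0.45, 0.05, 75e3, 75e3,
                          extra = list(f_peak_hz = 90e3)))
  rec <- gen_usv_recording(specs, noise_sd = 0, seed = 8)
  sg <- compute_spectrogram(rec$waveform, rec$fs)
  det <- detect_calls(sg)
  expect_equal(nrow(det), 3)
  feat <- extract_call_features(sg, det)

  # duration error within one hop on noiseless calls
  expect_true(all(abs(feat$duration_s - 0.05) <= 512 / 4 / fs + 1e-9))

  # averaging-window bias: 3 frames x hop over a 20 kHz / 50 ms chirp
  chirp_bias <- 3 * (512 / 4 / fs) * (20e3 / 0.05)
  expect_lt(abs(feat$f_start_hz[1] - 70e3), bin)
  expect_lt(abs(feat$f_end_hz[1] - 70e3), bin)
  expect_lt(abs(feat$f_start_hz[2] - 60e3), bin + chirp_bias)
  expect_lt(abs(feat$f_end_hz[2] - 80e3), bin + chirp_bias)

  # chevron: edges below the mid-call peak
  expect_lt(feat$f_start_hz[3], feat$peak_freq_hz[3])
  expect_lt(feat$f_end_hz[3], feat$peak_freq_hz[3])
  expect_gt(feat$peak_freq_hz[3], 85e3)
})

test_that("inter-syllable intervals follow the 0.5 s inter-burst convention", {
  one <- data.frame(start_s = 1, end_s = 1.05)
  expect_equal(nrow(compute_isi(one)), 0)

  calls <- data.frame(start_s = c(0, 0.2, 0.9), end_s = c(0.1, 0.3, 1.0))
  isi <- compute_isi(calls)
  expect_equal(nrow(isi), 2)
  expect_equal(isi$gap_s, c(0.1, 0.6))
  expect_equal(isi$is_inter_burst, c(FALSE, TRUE))
  s <- isi_summary(isi)
  expect_equal(s$n, 1)            # only the 0.1 s gap is analyzed
  expect_equal(s$mean_s, 0.1)
  expect_equal(s$n_inter_burst, 1)

  # boundary: a gap of exactly 0.5 s is retained (strict inequality)
  exact <- compute_isi(data.frame(start_s = c(0, 0.6), end_s = c(0.1, 0.7)))
  expect_false(exact$is_inter_burst)

  unsorted <- data.frame(start_s = c(0.2, 0), end_s = c(0.3, 0.1))
  expect_error(compute_isi(unsorted), "sorted")
})

test_that("ISI record count is calls minus one on a detected recording", {
  rec <- make_recording(15, seed = 9)
  sg <- compute_spectrogram(rec$waveform, rec$fs)
  det <- detect_calls(sg)
  expect_equal(nrow(compute_isi(det)), nrow(det) - 1)
})

test_that("repertoire chi-square matches hand computation and printed totals", {
  # identical distributions: chi-square 0, p 1
  r0 <- repertoire_counts(rep(c("flat", "chevron"), times = c(10, 10)),
                          rep(c("a", "b"), 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # perfectly separated 2x2: sum over cells of (O - E)^2 / E = 20
  r1 <- repertoire_counts(rep(c("x", "y"), each = 10),
                          rep(c("a", "b"), each = 10))
  expect_equal(r1$statistic, 20)
  expect_equal(r1$df, 1)

  # published male-repertoire counts sum to 4304 calls
  counts <- c(frequency_step = 1786, composite = 693, chevron = 560,
              two_syllable = 1265)
  types <- rep(names(counts), times = counts)
  r2 <- repertoire_counts(types, rep("male", length(types)))
  expect_equal(sum(r2$table), 4304)

  expect_error(repertoire_counts(c("a", "a"), c("g1", "g1", "g2")), "length")
})
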