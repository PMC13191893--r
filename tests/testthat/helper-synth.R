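# shared fixture builders (everything is generated in code at test time)

# noise SD giving a target SNR (dB) for a sine of peak amplitude `amp`
snr_noise_sd <- function(amp, snr_db) (amp / sqrt(2)) / 10^(snr_db / 20)

# a seeded multi-call recording with randomized types and frequencies
make_recording <- function(n_calls, seed, snr_db = 20, amp = 0.25,
                           gap_range = c(0.15, 0.35),
                           dur_range = c(0.03, 0.08)) {
  withr::with_seed(seed, {
    types <- sample(c("flat", "chevron", "frequency_step", "composite",
                      "two_syllable"), n_calls, replace = TRUE)
    onsets <- cumsum(stats::runif(n_calls, gap_range[1], gap_range[2]))
    specs <- lapply(seq_len(n_calls), function(i) {
      call_spec(types[i], onsets[i], stats::runif(1, dur_range[1], dur_range[2]),
                f_start_hz = stats::runif(1, 55e3, 75e3),
                f_end_hz = stats::runif(1, 60e3, 85e3), amplitude = amp)
    })
  })
  gen_usv_recording(specs, noise_sd = snr_noise_sd(amp, snr_db),
                    seed = seed + 1)
}

# hand-built FRA grid (frequency x level), for direct metric checks
make_grid <- function(mean_response, driven_mask, freqs, levels) {
  structure(list(freqs = freqs, levels = levels,
                 mean_response = mean_response,
                 n_trials = matrix(15L, nrow(mean_response), ncol(mean_response)),
                 driven_mask = driven_mask, constant_flag = FALSE),
            class = "fra_grid")
}

# tuned-ensemble feature matrix in a regime where decoding is off ceiling;
# best frequencies drawn log-uniform past both grid ends so every tone pair
# has comparable cell coverage
lean_ensemble_features <- function(width_oct, seed, n_cells = 12,
                                   noise_sd = 0.8) {
  bf <- withr::with_seed(seed * 7L,
                         2^(stats::runif(n_cells, log2(2800), log2(64000))))
  sp <- ensemble_spec(n_cells, p_tuned = 1, is_tuned = TRUE, bf_hz = bf,
                      tuning_width_oct = width_oct, threshold_db = 40,
                      noise_sd = noise_sd)
  g <- gen_fra_trials(sp, seed = seed)
  trial_feature_matrix(g$trials, level_db = 70)
}
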