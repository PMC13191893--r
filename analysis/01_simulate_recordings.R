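#!/usr/bin/env Rscript
# Simulate a neonatal isolation-call recording session with known ground
# truth: 100 syllables of the five repertoire types in background noise at
# 20 dB SNR, written as 250 kHz PCM16 WAV plus a truth table.

suppressPackageStartupMessages(library(audiphen))
dir.create("results", showWarnings = FALSE)

seed <- 101
amp <- 0.25
withr::with_seed(seed, {
  types <- sample(c("flat", "chevron", "frequency_step", "composite",
                    "two_syllable"), 100, replace = TRUE)
  onsets <- cumsum(runif(100, 0.15, 0.35))
  # drop in two long pauses so the recording contains inter-burst gaps
  onsets[34:100] <- onsets[34:100] + 0.8
  onsets[67:100] <- onsets[67:100] + 1.1
  specs <- lapply(seq_along(onsets), function(i) {
    call_spec(types[i], onsets[i], runif(1, 0.03, 0.08),
              f_start_hz = runif(1, 55e3, 75e3),
              f_end_hz = runif(1, 60e3, 85e3), amplitude = amp)
  })
})
noise_sd <- (amp / sqrt(2)) / 10^(20 / 20)   # 20 dB SNR
rec <- gen_usv_recording(specs, noise_sd = noise_sd, seed = seed + 1)

write_wav(rec$waveform, rec$fs, "results/usv_recording.wav")
write.csv(rec$truth, "results/usv_truth.csv", row.names = FALSE)

message(sprintf("wrote %.1f s recording (%d calls, %d Hz) and truth table",
                length(rec$waveform) / rec$fs, nrow(rec$truth), rec$fs))
message("call types: ",
        paste(names(table(rec$truth$call_type)),
              table(rec$truth$call_type), collapse = ", "))
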