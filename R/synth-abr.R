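#' Specify a synthetic ABR level series
#'
#' Emulates averaged auditory-brainstem-response waveforms to tone pips over
#' an ascending level series (default 20--95 dB SPL in 5 dB steps). At and
#' above the true threshold, the waveform is a stereotyped five-wave template
#' (difference-of-Gaussians peaks at fixed latencies) scaled by a linear
#' wave-I growth law; below threshold it is noise only. The wave-I
#' peak-to-trough amplitude at level L (>= threshold) is
#' `slope_uv_per_db * max(L - threshold, 2.5)` microvolts: growth is linear
#' in level re threshold, with a floor of half a 5 dB step so the response at
#' threshold itself is just detectable.
#'
#' @param frequency_hz stimulus frequency (8, 16 or 32 kHz typical).
#' @param true_threshold_db generative threshold, dB SPL.
#' @param slope_uv_per_db wave-I growth slope above threshold (default
#'   0.05 uV/dB).
#' @param noise_sd residual noise SD of each half-average, uV (default 0.05).
#' @param levels_db stimulus levels (default `seq(20, 95, by = 5)`).
#' @param fs_hz waveform sampling rate (default 50 kHz).
#' @param dur_ms epoch length (default 10 ms).
#' @param latencies_ms wave I--V peak latencies (defaults 1.5, 2.5, 3.5,
#'   4.7, 5.8 ms).
#' @param rel_amp relative amplitudes of waves II--V re wave I (defaults
#'   0.7, 0.8, 0.5, 0.3).
#' @return an `abr_spec` list.
#' @export
abr_spec <- function(frequency_hz = 16000, true_threshold_db = 40,
                     slope_uv_per_db = 0.05, noise_sd = 0.05,
                     levels_db = seq(20, 95, by = 5), fs_hz = 50e3,
                     dur_ms = 10, latencies_ms = c(1.5, 2.5, 3.5, 4.7, 5.8),
                     rel_amp = c(0.7, 0.8, 0.5, 0.3)) {
  stopifnot(noise_sd >= 0, !is.unsorted(levels_db))
  structure(list(frequency_hz = frequency_hz,
                 true_threshold_db = true_threshold_db,
                 slope_uv_per_db = slope_uv_per_db, noise_sd = noise_sd,
                 levels_db = levels_db, fs_hz = fs_hz, dur_ms = dur_ms,
                 latencies_ms = latencies_ms, rel_amp = rel_amp),
            class = "abr_spec")
}

# five-wave template normalized so the wave-I peak-to-trough equals 1
abr_template <- function(spec) {
  t_ms <- seq(0, spec$dur_ms, by = 1000 / spec$fs_hz)
  wave <- function(lat, amp) {
    amp * (exp(-((t_ms - lat) / 0.18)^2) -
           0.9 * exp(-((t_ms - lat - 0.45) / 0.28)^2))
  }
  amps <- c(1, spec$rel_amp)
  tmpl <- Reduce(`+`, Map(wave, spec$latencies_ms, amps))
  # normalize by the wave-I peak-to-trough of the summed template
  w1 <- t_ms >= spec$latencies_ms[1] - 0.3 & t_ms <= spec$latencies_ms[1] + 0.8
  p2t <- max(tmpl[w1]) - min(tmpl[w1])
  list(t_ms = t_ms, template = tmpl / p2t)
}

#' Simulate an ABR level series with split-half averages
#'
#' @param spec an [abr_spec()].
#' @param seed integer seed.
#' @return an `abr_series` list: `frequency_hz`, `levels_db`, `t_ms`,
#'   `half1`, `half2`, `average` (matrices, time x level, uV),
#'   `true_threshold_db`, `true_wave1_uv` (generative wave-I amplitude per
#'   level).
#' @export
gen_abr_series <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "abr_spec"))
  tm <- abr_template(spec)
  nl <- length(spec$levels_db)
  amp <- ifelse(spec$levels_db >= spec$true_threshold_db,
                spec$slope_uv_per_db *
                  pmax(spec$levels_db - spec$true_threshold_db, 2.5),
                0)
  n <- length(tm$t_ms)
  withr::with_seed(seed, {
    noise1 <- matrix(if (spec$noise_sd > 0) stats::rnorm(n * nl, 0, spec$noise_sd)
                     else 0, n, nl)
    noise2 <- matrix(if (spec$noise_sd > 0) stats::rnorm(n * nl, 0, spec$noise_sd)
                     else 0, n, nl)
  })
  signal <- outer(tm$template, amp)
  half1 <- signal + noise1
  half2 <- signal + noise2
  structure(list(frequency_hz = spec$frequency_hz,
                 levels_db = spec$levels_db, t_ms = tm$t_ms,
                 half1 = half1, half2 = half2,
                 average = (half1 + half2) / 2,
                 true_threshold_db = spec$true_threshold_db,
                 true_wave1_uv = amp), class = "abr_series")
}
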