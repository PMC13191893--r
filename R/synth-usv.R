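#' Specify one synthetic USV syllable
#'
#' Builds the parameter record for a single frequency-modulated call of one of
#' the five syllable classes scored in neonatal mouse repertoires:
#' \describe{
#'   \item{flat}{constant-frequency tone (a shallow linear chirp if
#'     `f_start_hz != f_end_hz`).}
#'   \item{chevron}{rise-then-fall trajectory: linear chirp up to a peak at
#'     the syllable midpoint, then back down.}
#'   \item{frequency_step}{abrupt switch between two stable frequency bands
#'     within one syllable.}
#'   \item{composite}{two harmonically independent components emitted
#'     simultaneously.}
#'   \item{two_syllable}{a main syllable followed, after a short gap, by a
#'     brief punctuated second component.}
#' }
#'
#' @param call_type one of `"flat"`, `"chevron"`, `"frequency_step"`,
#'   `"composite"`, `"two_syllable"`.
#' @param onset_s syllable onset, seconds.
#' @param duration_s main-syllable duration, seconds (> 0).
#' @param f_start_hz,f_end_hz start/end frequency, Hz; must lie in
#'   10--120 kHz.
#' @param amplitude linear peak amplitude (full scale = 1); keep at or below
#'   0.5 to avoid PCM clipping headroom issues.
#' @param extra named list of per-type parameters, all optional:
#'   `f_peak_hz` (chevron peak; default `max(f_start, f_end) + 8000`),
#'   `step_frac` (frequency-step switch point as fraction of duration,
#'   default 0.5), `f2_hz` (composite second component, default
#'   `1.5 * f_start`; or two-syllable second-syllable frequency, default
#'   `f_end`), `a2` (composite second-component relative amplitude, default
#'   0.6), `gap_s` (two-syllable gap, default 0.008), `dur2_s` (two-syllable
#'   second-component duration, default 0.010).
#' @return a `usv_call_spec` list.
#' @export
call_spec <- function(call_type, onset_s, duration_s, f_start_hz, f_end_hz,
                      amplitude = 0.25, extra = list()) {
  call_type <- match.arg(call_type, c("flat", "chevron", "frequency_step",
                                      "composite", "two_syllable"))
  if (!(duration_s > 0)) stop("duration_s must be > 0")
  if (onset_s < 0) stop("onset_s must be >= 0")
  for (f in c(f_start_hz, f_end_hz)) {
    if (f < 10e3 || f > 120e3)
      stop("call frequencies must lie within 10-120 kHz, got ", f, " Hz")
  }
  defaults <- list(
    f_peak_hz = max(f_start_hz, f_end_hz) + 8000,
    step_frac = 0.5,
    f2_hz     = if (call_type == "two_syllable") f_end_hz else 1.5 * f_start_hz,
    a2        = 0.6,
    gap_s     = 0.008,
    dur2_s    = 0.010
  )
  extra <- utils::modifyList(defaults, extra)
  structure(list(call_type = call_type, onset_s = onset_s,
                 duration_s = duration_s, f_start_hz = f_start_hz,
                 f_end_hz = f_end_hz, amplitude = amplitude, extra = extra),
            class = "usv_call_spec")
}

# total time footprint of a spec, including the second syllable of
# two_syllable calls
call_extent_s <- function(spec) {
  dur <- spec$duration_s
  if (spec$call_type == "two_syllable")
    dur <- dur + spec$extra$gap_s + spec$extra$dur2_s
  c(spec$onset_s, spec$onset_s + dur)
}

# max instantaneous frequency a spec can reach (Nyquist check)
call_max_freq <- function(spec) {
  fmax <- max(spec$f_start_hz, spec$f_end_hz)
  switch(spec$call_type,
         chevron   = max(fmax, spec$extra$f_peak_hz),
         composite = max(fmax, spec$extra$f2_hz),
         two_syllable = max(fmax, spec$extra$f2_hz),
         fmax)
}

# single-component chirp: instantaneous frequency vector -> samples
chirp_samples <- function(freq_hz, fs, amplitude, ramp_s = 0.001) {
  phase <- 2 * pi * cumsum(freq_hz) / fs
  s <- amplitude * sin(phase)
  n <- length(s)
  nr <- min(max(round(ramp_s * fs), 1L), floor(n / 2))
  ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  s[seq_len(nr)] <- s[seq_len(nr)] * ramp
  s[(n - nr + 1L):n] <- s[(n - nr + 1L):n] * rev(ramp)
  s
}

# render one call spec to samples (list: offset index, samples)
render_call <- function(spec, fs) {
  n <- round(spec$duration_s * fs)
  tfrac <- (seq_len(n) - 0.5) / n
  ex <- spec$extra
  samples <- switch(
    spec$call_type,
    flat = chirp_samples(spec$f_start_hz + tfrac * (spec$f_end_hz - spec$f_start_hz),
                         fs, spec$amplitude),
    chevron = {
      up <- tfrac < 0.5
      f <- numeric(n)
      f[up]  <- spec$f_start_hz + (tfrac[up] / 0.5) * (ex$f_peak_hz - spec$f_start_hz)
      f[!up] <- ex$f_peak_hz + ((tfrac[!up] - 0.5) / 0.5) * (spec$f_end_hz - ex$f_peak_hz)
      chirp_samples(f, fs, spec$amplitude)
    },
    frequency_step = {
      f <- ifelse(tfrac < ex$step_frac, spec$f_start_hz, spec$f_end_hz)
      chirp_samples(f, fs, spec$amplitude)
    },
    composite = {
      main <- chirp_samples(spec$f_start_hz + tfrac * (spec$f_end_hz - spec$f_start_hz),
                            fs, spec$amplitude)
      second <- chirp_samples(rep(ex$f2_hz, n), fs, spec$amplitude * ex$a2)
      main + second
    },
    two_syllable = {
      main <- chirp_samples(spec$f_start_hz + tfrac * (spec$f_end_hz - spec$f_start_hz),
                            fs, spec$amplitude)
      gap <- numeric(round(ex$gap_s * fs))
      n2 <- round(ex$dur2_s * fs)
      second <- chirp_samples(rep(ex$f2_hz, n2), fs, spec$amplitude)
      c(main, gap, second)
    })
  samples
}

#' Synthesize an ultrasonic recording with known call ground truth
#'
#' Renders each call spec as a frequency-modulated tone into additive white
#' Gaussian noise, emulating a high-bandwidth microphone recording of an
#' isolated pup. Every generated call is listed exactly once in the returned
#' truth table. The generator is a pure function of `(specs, seed)`: the same
#' seed yields bit-identical output.
#'
#' @param specs list of [call_spec()] records; onsets must not overlap
#'   (two-syllable calls occupy their full extent including the gap and
#'   second component).
#' @param fs sampling rate, Hz (default 250 kHz); must be at least twice the
#'   highest instantaneous frequency of any call.
#' @param noise_sd standard deviation of the additive background noise
#'   (linear full-scale units).
#' @param seed integer seed.
#' @param duration_s total recording length; defaults to the last call offset
#'   plus 50 ms.
#' @return list with `waveform` (numeric vector), `fs`, and `truth`
#'   (data.frame: onset_s, offset_s, f_start_hz, f_end_hz, call_type,
#'   amplitude).
#' @examples
#' rec <- gen_usv_recording(list(
#'   call_spec("flat", 0.05, 0.05, 70e3, 70e3)), noise_sd = 0, seed = 1)
#' nrow(rec$truth)
#' @export
gen_usv_recording <- function(specs, fs = 250e3, noise_sd = 0.005, seed = 1,
                              duration_s = NULL) {
  stopifnot(is.list(specs), fs > 0, noise_sd >= 0)
  if (length(specs) > 0) {
    if (!all(vapply(specs, inherits, logical(1), "usv_call_spec")))
      stop("all specs must be usv_call_spec objects")
    extents <- t(vapply(specs, call_extent_s, numeric(2)))
    ord <- order(extents[, 1])
    extents <- extents[ord, , drop = FALSE]
    specs <- specs[ord]
    if (nrow(extents) > 1 &&
        any(extents[-1, 1] < extents[-nrow(extents), 2]))
      stop("call specs overlap in time; onsets must be non-overlapping")
    fmax <- max(vapply(specs, call_max_freq, numeric(1)))
    if (fs < 2 * fmax)
      stop("fs = ", fs, " Hz is below the Nyquist rate for a ", fmax,
           " Hz component")
  }
  if (is.null(duration_s)) {
    duration_s <- if (length(specs)) max(extents[, 2]) + 0.05 else 0.1
  }
  n <- round(duration_s * fs)
  truth <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      f_start_hz = numeric(0), f_end_hz = numeric(0),
                      call_type = character(0), amplitude = numeric(0),
                      stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    waveform <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    for (spec in specs) {
      s <- render_call(spec, fs)
      i0 <- round(spec$onset_s * fs) + 1L
      idx <- i0:min(i0 + length(s) - 1L, n)
      waveform[idx] <- waveform[idx] + s[seq_along(idx)]
      truth <- rbind(truth, data.frame(
        onset_s = spec$onset_s,
        offset_s = spec$onset_s + (length(s) / fs),
        f_start_hz = spec$f_start_hz, f_end_hz = spec$f_end_hz,
        call_type = spec$call_type, amplitude = spec$amplitude,
        stringsAsFactors = FALSE))
    }
  })
  list(waveform = waveform, fs = fs, truth = truth)
}
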