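#' Short-time power spectrogram
#'
#' Computes a one-sided short-time power spectral density over half-open
#' frames `[k*hop, k*hop + window)`, each timestamped at its center. Power is
#' scaled so that summing `power * df` over frequency recovers the in-frame
#' signal power up to the windowing loss (Parseval-consistent for the Hann
#' taper used by default).
#'
#' @param waveform numeric vector, non-empty.
#' @param fs sampling rate, Hz (> 0).
#' @param window_samples analysis window length in samples (default 512,
#'   about 2 ms at 250 kHz).
#' @param hop hop size in samples (default `window_samples / 4`, i.e. 75%
#'   overlap).
#' @param window taper: `"hann"` or `"rect"`.
#' @return a `usv_spectrogram` list: `times` (frame centers, s), `freqs`
#'   (bin centers, Hz), `power` (frames x frequency, linear power density),
#'   and `params`.
#' @export
compute_spectrogram <- function(waveform, fs, window_samples = 512,
                                hop = window_samples %/% 4,
                                window = c("hann", "rect")) {
  window <- match.arg(window)
  if (length(waveform) == 0) stop("waveform is empty")
  if (fs <= 0) stop("fs must be positive")
  if (window_samples > length(waveform))
    stop("window (", window_samples, " samples) exceeds waveform length")
  if (hop < 1) stop("hop must be >= 1")

  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, window_samples - 1) / window_samples)
  } else rep(1, window_samples)

  starts <- seq(1L, length(waveform) - window_samples + 1L, by = hop)
  frames <- matrix(waveform[outer(seq_len(window_samples) - 1L, starts, "+")],
                   nrow = window_samples)
  frames <- frames * w
  spec <- stats::mvfft(frames)
  nbin <- window_samples %/% 2 + 1L
  pow <- Mod(spec[seq_len(nbin), , drop = FALSE])^2
  # one-sided PSD scaling; double interior bins
  scale <- 1 / (fs * sum(w^2))
  pow <- pow * scale
  if (nbin > 2) pow[2:(nbin - 1L), ] <- 2 * pow[2:(nbin - 1L), ]
  structure(list(
    times = (starts - 1 + (window_samples - 1) / 2) / fs,
    freqs = (seq_len(nbin) - 1) * fs / window_samples,
    power = t(pow),
    params = list(window_samples = window_samples, hop = hop,
                  window = window, fs = fs)
  ), class = "usv_spectrogram")
}
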