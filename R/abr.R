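#' ABR threshold by split-half repeatability
#'
#' Operationalizes "lowest level with a repeatable waveform": repeatability
#' at a level is the Pearson correlation between the two split-half averages
#' over the response window (default 1--6 ms). The threshold is the lowest
#' level L whose repeatability reaches `r_min` at L and at every level above
#' L (monotonic enforcement); if no level qualifies, the conventional 100 dB
#' ceiling is returned. Zero-variance halves (flat waveforms) count as not
#' repeatable.
#'
#' @param series an `abr_series` from [gen_abr_series()], or any list with
#'   `levels_db`, `t_ms`, `half1`, `half2` (time x level matrices covering
#'   every level).
#' @param r_min repeatability criterion (default 0.5).
#' @param window_ms response window, ms (default `c(1, 6)`).
#' @param ceiling_db value returned when nothing is repeatable (default 100).
#' @return list with `threshold_db` and `repeatability` (per-level r).
#' @export
abr_threshold <- function(series, r_min = 0.5, window_ms = c(1, 6),
                          ceiling_db = 100) {
  need <- c("levels_db", "t_ms", "half1", "half2")
  if (!all(need %in% names(series))) stop("series is missing split-half data")
  if (ncol(series$half1) != length(series$levels_db) ||
      ncol(series$half2) != length(series$levels_db))
    stop("waveform matrices must have one column per level; levels missing")
  idx <- series$t_ms >= window_ms[1] & series$t_ms <= window_ms[2]
  r <- vapply(seq_along(series$levels_db), function(j) {
    a <- series$half1[idx, j]; b <- series$half2[idx, j]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  ok <- r >= r_min
  # repeatable at L and every level above L
  ok_above <- rev(cumprod(rev(ok))) > 0
  threshold <- if (any(ok_above)) series$levels_db[which(ok_above)[1]]
               else ceiling_db
  list(threshold_db = threshold, repeatability = r)
}

#' Wave-I peak-to-trough amplitude
#'
#' Takes the wave-I peak as the waveform maximum within the latency window
#' (default 1.0--2.5 ms) and subtracts the following trough, the minimum
#' over the `trough_within_ms` interval after the peak. Returns 0 with a
#' flag when the window holds no peak (flat waveform, or no sample rises
#' above both window endpoints).
#'
#' @param waveform numeric vector, uV.
#' @param t_ms time base, ms, same length.
#' @param window_ms wave-I search window (default `c(1, 2.5)`).
#' @param trough_within_ms how far after the peak the trough is searched
#'   (default 1 ms).
#' @param smooth_ms optional moving-average width in ms applied before
#'   peak-picking (default 0 = none); use ~0.15 ms on noisy averages so the
#'   peak is not a noise ripple.
#' @return list with `amplitude_uv`, `peak_ms`, `trough_ms`, `flagged`.
#' @export
wave1_amplitude <- function(waveform, t_ms, window_ms = c(1, 2.5),
                            trough_within_ms = 1, smooth_ms = 0) {
  stopifnot(length(waveform) == length(t_ms))
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / (t_ms[2] - t_ms[1])))
    if (w %% 2 == 0) w <- w + 1L
    waveform <- stats::filter(waveform, rep(1 / w, w), sides = 2)
    waveform[is.na(waveform)] <- 0
    waveform <- as.numeric(waveform)
  }
  if (min(t_ms) > window_ms[1] || max(t_ms) < window_ms[2])
    stop("waveform does not cover the wave-I latency window")
  in_win <- which(t_ms >= window_ms[1] & t_ms <= window_ms[2])
  n <- length(waveform)
  w <- waveform[in_win]
  # flat window, or maximum that never rises above the window edges: no peak
  if (max(w) - min(w) == 0 ||
      (max(w) <= w[1] && max(w) <= w[length(w)]))
    return(list(amplitude_uv = 0, peak_ms = NA_real_, trough_ms = NA_real_,
                flagged = TRUE))
  peak_i <- in_win[which.max(w)]
  after <- which(t_ms > t_ms[peak_i] &
                 t_ms <= t_ms[peak_i] + trough_within_ms)
  if (length(after) == 0) after <- min(peak_i + 1L, n)
  trough_i <- after[which.min(waveform[after])]
  list(amplitude_uv = waveform[peak_i] - waveform[trough_i],
       peak_ms = t_ms[peak_i], trough_ms = t_ms[trough_i], flagged = FALSE)
}

#' Threshold and wave-I growth for a set of ABR series
#'
#' @param series_list list of `abr_series` objects (e.g. one per stimulus
#'   frequency).
#' @param smooth_ms smoothing passed to [wave1_amplitude()] (default 0.15,
#'   suited to noisy averages).
#' @param ... passed to [abr_threshold()].
#' @return data.frame: `frequency_hz`, `threshold_db`, plus one row per
#'   level with `level_db` and measured `wave1_uv` in the attached
#'   `"wave1"` attribute.
#' @export
analyze_abr <- function(series_list, smooth_ms = 0.15, ...) {
  out <- data.frame(frequency_hz = numeric(0), threshold_db = numeric(0))
  w1 <- list()
  for (s in series_list) {
    th <- abr_threshold(s, ...)
    out <- rbind(out, data.frame(frequency_hz = s$frequency_hz,
                                 threshold_db = th$threshold_db))
    amp <- vapply(seq_along(s$levels_db), function(j) {
      wave1_amplitude(s$average[, j], s$t_ms, smooth_ms = smooth_ms)$amplitude_uv
    }, numeric(1))
    w1[[length(w1) + 1L]] <- data.frame(frequency_hz = s$frequency_hz,
                                        level_db = s$levels_db,
                                        wave1_uv = amp)
  }
  attr(out, "wave1") <- do.call(rbind, w1)
  out
}
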