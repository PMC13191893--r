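#' Detect USV syllables by band-energy thresholding
#'
#' Flags spectrogram frames whose in-band energy exceeds a robust threshold
#' (median + `k_mad` * MAD of the recording's frame energies), merges active
#' runs separated by short gaps, and discards runs shorter than a minimum
#' duration. The spectrogram is scanned in short segments (default 0.5 s)
#' with one-window overlap so no boundary frame is lost; the threshold is
#' computed once over the whole recording, so segmentation does not change
#' the result. Reported boundaries are frame-center times trimmed by half the
#' analysis window (minus half a hop), compensating the smearing of the
#' short-time transform, and are sorted and non-overlapping.
#'
#' @param sg a `usv_spectrogram` from [compute_spectrogram()].
#' @param band numeric length-2, detection band in Hz (default 30--120 kHz,
#'   the mouse USV band).
#' @param k_mad MAD multiplier for the energy threshold (> 0, default 5).
#' @param merge_gap_s merge active runs separated by gaps at most this long
#'   (default 10 ms).
#' @param min_dur_s discard calls shorter than this (default 5 ms).
#' @param segment_s segment length for chunked scanning (default 0.5 s).
#' @return data.frame with `start_s`, `end_s`, `duration_s`, one row per
#'   detected call.
#' @export
detect_calls <- function(sg, band = c(30e3, 120e3), k_mad = 5,
                         merge_gap_s = 0.01, min_dur_s = 0.005,
                         segment_s = 0.5) {
  stopifnot(inherits(sg, "usv_spectrogram"))
  if (k_mad <= 0 || merge_gap_s < 0 || min_dur_s <= 0)
    stop("threshold parameters must be positive")
  if (band[1] >= band[2] || band[1] < min(sg$freqs) || band[2] > max(sg$freqs))
    stop("detection band must lie within the spectrogram frequency range")

  cols <- which(sg$freqs >= band[1] & sg$freqs <= band[2])
  df <- sg$freqs[2] - sg$freqs[1]
  energy <- rowSums(sg$power[, cols, drop = FALSE]) * df

  thr <- stats::median(energy) + k_mad * stats::mad(energy)
  hop_s <- sg$params$hop / sg$params$fs
  win_s <- sg$params$window_samples / sg$params$fs

  # chunked scan with one-window overlap; global threshold makes the union
  # identical to a single pass while keeping per-segment memory flat
  active <- logical(length(energy))
  seg_frames <- max(1L, round(segment_s / hop_s))
  ovl <- max(1L, ceiling(win_s / hop_s))
  s0 <- 1L
  while (s0 <= length(energy)) {
    s1 <- min(s0 + seg_frames - 1L, length(energy))
    lo <- max(1L, s0 - ovl)
    hi <- min(length(energy), s1 + ovl)
    active[lo:hi] <- active[lo:hi] | (energy[lo:hi] > thr)
    s0 <- s1 + 1L
  }

  runs <- active_runs(active)
  if (nrow(runs) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  # merge runs separated by short gaps
  merge_frames <- round(merge_gap_s / hop_s)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$first[i] - merged$last[nrow(merged)] - 1L <= merge_frames) {
        merged$last[nrow(merged)] <- runs$last[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  trim <- (win_s - hop_s) / 2
  start <- sg$times[merged$first] + trim
  end <- sg$times[merged$last] - trim
  short <- end - start < pmax(min_dur_s, hop_s)
  start <- start[!short]; end <- end[!short]
  data.frame(start_s = start, end_s = end, duration_s = end - start)
}

# first/last frame index of each TRUE run
active_runs <- function(active) {
  r <- rle(active)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.frame(first = first[r$values], last = last[r$values])
}

#' Extract per-call spectral and temporal features
#'
#' For each detected call, tracks the peak frequency (argmax of in-band power
#' per frame) and derives the standard syllable features: start frequency
#' (mean of the peak track over the first `edge_frames` frames), end
#' frequency (mean over the last `edge_frames` frames), and duration. Calls
#' shorter than the averaging window use all available frames and are
#' flagged.
#'
#' @param sg a `usv_spectrogram`.
#' @param boundaries data.frame with `start_s`, `end_s` (from
#'   [detect_calls()] or a truth table).
#' @param band analysis band in Hz for the peak track.
#' @param edge_frames frames averaged at each call edge (default 3).
#' @return data.frame: `start_s`, `end_s`, `duration_s`, `f_start_hz`,
#'   `f_end_hz`, `peak_freq_hz` (track maximum), `short_flag`. The per-frame
#'   peak tracks are attached as the `"peak_tracks"` attribute.
#' @export
extract_call_features <- function(sg, boundaries, band = c(30e3, 120e3),
                                  edge_frames = 3) {
  stopifnot(inherits(sg, "usv_spectrogram"))
  if (nrow(boundaries) > 0 &&
      (min(boundaries$start_s) < min(sg$times) - 1 ||
       max(boundaries$end_s) > max(sg$times) + 1))
    stop("call boundaries outside the spectrogram time range")
  cols <- which(sg$freqs >= band[1] & sg$freqs <= band[2])
  out <- boundaries[, c("start_s", "end_s")]
  out$duration_s <- out$end_s - out$start_s
  out$f_start_hz <- out$f_end_hz <- out$peak_freq_hz <- NA_real_
  out$short_flag <- FALSE
  tracks <- vector("list", nrow(boundaries))
  for (i in seq_len(nrow(boundaries))) {
    idx <- which(sg$times >= boundaries$start_s[i] &
                 sg$times <= boundaries$end_s[i])
    if (length(idx) == 0)
      idx <- which.min(abs(sg$times - (boundaries$start_s[i] +
                                       boundaries$end_s[i]) / 2))
    pk <- cols[max.col(sg$power[idx, cols, drop = FALSE], ties.method = "first")]
    track <- sg$freqs[pk]
    tracks[[i]] <- track
    ne <- min(edge_frames, length(track))
    out$short_flag[i] <- length(track) < edge_frames
    out$f_start_hz[i] <- mean(track[seq_len(ne)])
    out$f_end_hz[i] <- mean(track[(length(track) - ne + 1L):length(track)])
    out$peak_freq_hz[i] <- max(track)
  }
  attr(out, "peak_tracks") <- tracks
  out
}

#' Inter-syllable intervals with inter-burst flagging
#'
#' Computes the silent gap between each call's end and the next call's start.
#' Gaps longer than `burst_gap_s` (default 0.5 s) are flagged as inter-burst
#' intervals; by the scoring convention these are excluded from ISI
#' summaries. A gap of exactly `burst_gap_s` is retained (strict inequality).
#'
#' @param calls data.frame with `start_s`, `end_s`, sorted by `start_s`,
#'   non-overlapping.
#' @param burst_gap_s inter-burst boundary in seconds (default 0.5).
#' @return data.frame with `gap_s` and `is_inter_burst` (n - 1 rows for n
#'   calls).
#' @export
compute_isi <- function(calls, burst_gap_s = 0.5) {
  n <- nrow(calls)
  if (n > 1 && is.unsorted(calls$start_s, strictly = FALSE))
    stop("calls must be sorted by start time")
  if (n <= 1)
    return(data.frame(gap_s = numeric(0), is_inter_burst = logical(0)))
  gap <- calls$start_s[-1] - calls$end_s[-n]
  if (any(gap < 0)) stop("calls overlap; input must be non-overlapping")
  data.frame(gap_s = gap, is_inter_burst = gap > burst_gap_s)
}

#' Summarize inter-syllable intervals (inter-burst gaps excluded)
#'
#' @param isi data.frame from [compute_isi()].
#' @return list with `n`, `mean_s`, `median_s` over the retained gaps and
#'   `n_inter_burst` excluded.
#' @export
isi_summary <- function(isi) {
  keep <- isi$gap_s[!isi$is_inter_burst]
  list(n = length(keep),
       mean_s = if (length(keep)) mean(keep) else NA_real_,
       median_s = if (length(keep)) stats::median(keep) else NA_real_,
       n_inter_burst = sum(isi$is_inter_burst))
}

#' Call-repertoire contingency table and chi-square comparison
#'
#' Cross-tabulates call-type labels against group labels and tests whether
#' the repertoire composition differs between groups with a chi-square test
#' of independence (no continuity correction). Rejects when any expected
#' cell count is zero.
#'
#' @param types character/factor vector of call-type labels.
#' @param groups character/factor vector of group labels, same length.
#' @return list with `table` (type x group counts), `statistic`, `df`,
#'   `p_value`.
#' @export
repertoire_counts <- function(types, groups) {
  if (length(types) != length(groups))
    stop("types and groups must have the same length")
  tab <- table(type = types, group = groups)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("chi-square undefined: expected count of 0 in cell(s) ",
         paste(which(expected == 0), collapse = ", "))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Score detected calls against a ground-truth table
#'
#' Greedy one-to-one matching by call midpoint: a detection matches a truth
#' call when its midpoint falls inside the (tolerance-padded) truth extent
#' and vice versa. Reports precision, recall and F1.
#'
#' @param detected data.frame with `start_s`, `end_s`.
#' @param truth data.frame with `onset_s`, `offset_s`.
#' @param tol_s boundary tolerance in seconds (default 10 ms).
#' @return list with `precision`, `recall`, `f1`, `n_matched`, and `matches`
#'   (detected index, truth index).
#' @export
evaluate_detection <- function(detected, truth, tol_s = 0.01) {
  used <- logical(nrow(truth))
  matches <- data.frame(detected = integer(0), truth = integer(0))
  mid_d <- (detected$start_s + detected$end_s) / 2
  for (i in seq_len(nrow(detected))) {
    j <- which(!used & truth$onset_s - tol_s <= mid_d[i] &
               mid_d[i] <= truth$offset_s + tol_s)
    if (length(j)) {
      j <- j[which.min(abs((truth$onset_s[j] + truth$offset_s[j]) / 2 - mid_d[i]))]
      used[j] <- TRUE
      matches <- rbind(matches, data.frame(detected = i, truth = j))
    }
  }
  tp <- nrow(matches)
  precision <- if (nrow(detected)) tp / nrow(detected) else NA_real_
  recall <- if (nrow(truth)) tp / nrow(truth) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, n_matched = tp,
       matches = matches)
}
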