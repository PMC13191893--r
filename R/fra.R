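#' Tone-evoked response scalar from a fluorescence trace
#'
#' Mean activity in the window after tone onset minus mean activity in the
#' window before it (default 120 ms each side). Windows are half-open
#' (`[onset - w, onset)` and `[onset, onset + w)`) and frames are assigned by
#' their center times; at a 30 Hz frame rate each window holds 3--4 frames.
#'
#' @param trace numeric fluorescence samples (e.g. dF/F).
#' @param times frame-center times, seconds, same length as `trace`.
#' @param onset_s tone onset, seconds.
#' @param window_s pre/post window length, seconds (default 0.12).
#' @return evoked scalar (post mean minus pre mean).
#' @export
evoked_response <- function(trace, times, onset_s, window_s = 0.12) {
  stopifnot(length(trace) == length(times))
  pre <- times >= onset_s - window_s & times < onset_s
  post <- times >= onset_s & times < onset_s + window_s
  if (sum(pre) < 2 || sum(post) < 2)
    stop("fewer than 2 frames in the pre or post window; trace must cover ",
         "[onset - ", window_s, ", onset + ", window_s, "] s")
  mean(trace[post]) - mean(trace[pre])
}

# 3x3 median filter with replicate edge padding
median_filter_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- stats::median(pad[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

# 4-connected component of `mask` containing (seed_i, seed_j)
connected_component <- function(mask, seed_i, seed_j) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[seed_i, seed_j]) return(comp)
  stack <- list(c(seed_i, seed_j))
  comp[seed_i, seed_j] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      i <- p[1] + d[1]; j <- p[2] + d[2]
      if (i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask) &&
          mask[i, j] && !comp[i, j]) {
        comp[i, j] <- TRUE
        stack[[length(stack) + 1L]] <- c(i, j)
      }
    }
  }
  comp
}

#' Build a frequency-response area for one cell
#'
#' Averages evoked responses over repeats per frequency-level combination and
#' determines the tone-driven portion of the FRA: the mean grid is smoothed
#' with a 3x3 median filter and thresholded at `baseline + max(boundary_frac
#' * (peak - baseline), mad_floor * MAD)`, where the baseline is the median
#' of the smoothed grid and the MAD is its median absolute deviation; the
#' 4-connected component containing the smoothed peak is kept. The
#' fraction-of-peak term sets the boundary for responsive cells, while the
#' MAD floor stops the boundary collapsing onto sampling noise in
#' unresponsive grids (where 20% of the noise peak is indistinguishable from
#' baseline fluctuation). If smoothing removes all contrast the raw grid
#' carries (an isolated single-combination responder), the boundary is
#' determined on the raw grid instead. An all-constant cell yields an empty
#' mask and a flag.
#'
#' @param trials data.frame for one cell: `frequency_hz`, `level_db`,
#'   `evoked` (a `cell_id` column is allowed; it must contain one cell).
#' @param boundary_frac boundary threshold as a fraction of the
#'   peak-above-baseline range (default 0.2).
#' @param mad_floor robust floor on the boundary threshold, in MADs of the
#'   smoothed grid (default 2.5).
#' @param min_coverage minimum fraction of grid combinations that must have
#'   data (default 0.9).
#' @return an `fra_grid` list: `freqs`, `levels`, `mean_response`
#'   (frequency x level), `n_trials` (same shape), `driven_mask`,
#'   `constant_flag`.
#' @export
build_fra <- function(trials, boundary_frac = 0.2, mad_floor = 2.5,
                      min_coverage = 0.9) {
  if ("cell_id" %in% names(trials) && length(unique(trials$cell_id)) > 1)
    stop("build_fra expects trials from a single cell")
  freqs <- sort(unique(trials$frequency_hz))
  levels <- sort(unique(trials$level_db))
  fi <- match(trials$frequency_hz, freqs)
  li <- match(trials$level_db, levels)
  sums <- matrix(0, length(freqs), length(levels))
  n <- matrix(0L, length(freqs), length(levels))
  for (r in seq_len(nrow(trials))) {
    sums[fi[r], li[r]] <- sums[fi[r], li[r]] + trials$evoked[r]
    n[fi[r], li[r]] <- n[fi[r], li[r]] + 1L
  }
  if (mean(n > 0) < min_coverage)
    stop("grid coverage ", round(mean(n > 0), 2), " below required ",
         min_coverage)
  mean_response <- sums / ifelse(n > 0, n, NA_integer_)

  filled <- mean_response
  filled[is.na(filled)] <- stats::median(mean_response, na.rm = TRUE)
  sm <- median_filter_3x3(filled)
  # median smoothing flattens isolated single-combo responders; fall back to
  # the raw grid when it has removed all contrast that the raw grid carries
  if (max(sm) - stats::median(sm) <= 0 && max(filled) > min(filled))
    sm <- filled
  baseline <- stats::median(sm)
  peak <- max(sm)
  constant_flag <- peak - baseline <= 0 ||
    isTRUE(all.equal(max(filled), min(filled)))
  if (constant_flag) {
    driven <- matrix(FALSE, length(freqs), length(levels))
  } else {
    thr <- baseline + max(boundary_frac * (peak - baseline),
                          mad_floor * stats::mad(sm))
    above <- sm >= thr
    pk <- which(sm == peak, arr.ind = TRUE)[1, ]
    driven <- connected_component(above, pk[1], pk[2])
    driven[is.na(mean_response)] <- FALSE
  }
  structure(list(freqs = freqs, levels = levels,
                 mean_response = mean_response, n_trials = n,
                 driven_mask = driven, constant_flag = constant_flag),
            class = "fra_grid")
}

#' Resampled d-prime tuning-quality statistic of an FRA
#'
#' Quantifies how separable the tone-driven portion of the FRA is from the
#' tone-unrelated portion. On each of `n_iter` iterations, `n_sub`
#' combinations are drawn with replacement from the driven portion and
#' `n_sub` from the undriven portion, and the two subsample means are
#' recorded. If the driven portion holds fewer than `pad_to` combinations it
#' is padded with random undriven combinations up to `pad_to` candidates
#' before sampling (a conservative dilution of the driven pool). d-prime is
#' the difference between the means of the two iteration-mean distributions
#' divided by the arithmetic average of their SDs. If both SDs are zero with
#' unequal means the statistic is reported at the cap (`cap`); equal means
#' give 0.
#'
#' @param grid an `fra_grid` from [build_fra()].
#' @param seed integer seed for the resampling.
#' @param n_iter iterations (default 1000).
#' @param n_sub combinations per subsample (default 30).
#' @param pad_to driven-pool padding target (default 50).
#' @param cap value reported for the zero-variance unequal-means degenerate
#'   case (default 10).
#' @return d-prime scalar; `NA` (with a message attribute) when the driven
#'   portion is empty.
#' @export
fra_dprime <- function(grid, seed = 1, n_iter = 1000, n_sub = 30,
                       pad_to = 50, cap = 10) {
  stopifnot(inherits(grid, "fra_grid"))
  driven_vals <- grid$mean_response[grid$driven_mask]
  undriven_vals <- grid$mean_response[!grid$driven_mask & !is.na(grid$mean_response)]
  driven_vals <- driven_vals[!is.na(driven_vals)]
  if (length(driven_vals) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "empty driven portion"
    return(out)
  }
  if (length(undriven_vals) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "empty undriven portion"
    return(out)
  }
  withr::with_seed(seed, {
    n_pad <- max(0L, pad_to - length(driven_vals))
    driven_means <- numeric(n_iter)
    undriven_means <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      pool <- if (n_pad > 0) {
        c(driven_vals, sample(undriven_vals, n_pad, replace = TRUE))
      } else driven_vals
      driven_means[it] <- mean(sample(pool, n_sub, replace = TRUE))
      undriven_means[it] <- mean(sample(undriven_vals, n_sub, replace = TRUE))
    }
  })
  num <- mean(driven_means) - mean(undriven_means)
  den <- (stats::sd(driven_means) + stats::sd(undriven_means)) / 2
  if (den == 0) {
    if (num == 0) 0 else sign(num) * cap
  } else {
    num / den
  }
}

#' Best frequency, response threshold, and bandwidth of an FRA
#'
#' BF is the frequency maximizing the driven-portion response summed across
#' levels; the minimum response threshold is the lowest level containing at
#' least one driven combination; bandwidth is the octave span
#' `log2(f_hi / f_lo)` of the driven combinations in the level row one
#' `bw_step_db` above threshold (0 octaves if a single frequency is driven
#' there; `NA` if that row has no driven combination or lies above the grid).
#'
#' @param grid an `fra_grid`.
#' @param bw_step_db level step above threshold at which bandwidth is read
#'   (default 10 dB).
#' @return list with `best_frequency_hz`, `threshold_db`,
#'   `bandwidth_octaves`; all `NA` when the driven mask is empty.
#' @export
fra_metrics <- function(grid, bw_step_db = 10) {
  stopifnot(inherits(grid, "fra_grid"))
  if (!any(grid$driven_mask))
    return(list(best_frequency_hz = NA_real_, threshold_db = NA_real_,
                bandwidth_octaves = NA_real_))
  resp <- grid$mean_response
  resp[!grid$driven_mask] <- 0
  resp[is.na(resp)] <- 0
  bf <- grid$freqs[which.max(rowSums(resp))]
  threshold <- min(grid$levels[colSums(grid$driven_mask) > 0])
  bw_level <- threshold + bw_step_db
  j <- match(bw_level, grid$levels)
  bandwidth <- if (is.na(j) || !any(grid$driven_mask[, j])) {
    NA_real_
  } else {
    f_driven <- grid$freqs[grid$driven_mask[, j]]
    log2(max(f_driven) / min(f_driven))
  }
  list(best_frequency_hz = bf, threshold_db = threshold,
       bandwidth_octaves = bandwidth)
}

#' Analyze every cell of a trial table
#'
#' Runs [build_fra()], [fra_dprime()] and [fra_metrics()] per cell and
#' returns the per-cell metrics table used by the downstream selection and
#' statistics steps. Each cell's resampling seed is derived from `seed` and
#' its cell id.
#'
#' @param trials data.frame with `cell_id`, `frequency_hz`, `level_db`,
#'   `evoked`.
#' @param seed base seed for the d-prime resampling.
#' @param ... passed to [build_fra()].
#' @return data.frame: `cell_id`, `dprime`, `bf_hz`, `threshold_db`,
#'   `bandwidth_oct`, `mask_area`, `retained` (d-prime > 1.5).
#' @export
analyze_fra_cells <- function(trials, seed = 1, ...) {
  cells <- sort(unique(trials$cell_id))
  out <- data.frame(cell_id = cells, dprime = NA_real_, bf_hz = NA_real_,
                    threshold_db = NA_real_, bandwidth_oct = NA_real_,
                    mask_area = NA_integer_, retained = FALSE)
  for (i in seq_along(cells)) {
    g <- build_fra(trials[trials$cell_id == cells[i], ], ...)
    dp <- fra_dprime(g, seed = seed + i)
    m <- fra_metrics(g)
    out$dprime[i] <- as.numeric(dp)
    out$bf_hz[i] <- m$best_frequency_hz
    out$threshold_db[i] <- m$threshold_db
    out$bandwidth_oct[i] <- m$bandwidth_octaves
    out$mask_area[i] <- sum(g$driven_mask)
  }
  out$retained <- !is.na(out$dprime) & out$dprime > 1.5
  out
}

#' Select cells with well-defined FRAs
#'
#' Keeps cells whose resampled d-prime strictly exceeds the cutoff (default
#' 1.5); a cell at exactly the cutoff is excluded.
#'
#' @param metrics data.frame with a `dprime` column (e.g. from
#'   [analyze_fra_cells()]).
#' @param cutoff d-prime cutoff (default 1.5).
#' @return the retained subset, with the retained fraction attached as the
#'   `"retained_fraction"` attribute.
#' @export
filter_cells <- function(metrics, cutoff = 1.5) {
  keep <- !is.na(metrics$dprime) & metrics$dprime > cutoff
  out <- metrics[keep, , drop = FALSE]
  attr(out, "retained_fraction") <- mean(keep)
  out
}
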