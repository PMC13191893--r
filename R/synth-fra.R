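#' Default tone grid for imaging experiments
#'
#' 4--45 kHz in half-octave steps (8 frequencies) crossed with 20--80 dB SPL
#' in 10 dB steps (7 levels), each combination repeated 15 times: the
#' standard passive pure-tone protocol emulated by [gen_fra_trials()].
#'
#' @return list with `freqs_hz`, `levels_db`, `n_repeats`.
#' @export
default_tone_grid <- function() {
  k <- 0:7
  freqs <- 4000 * 2^(k / 2)
  freqs <- freqs[freqs <= 45.3e3]
  list(freqs_hz = freqs, levels_db = seq(20, 80, by = 10), n_repeats = 15L)
}

#' Specify a synthetic imaged ensemble
#'
#' Each cell is either frequency-tuned (Gaussian tuning in octaves around its
#' best frequency, multiplied by a saturating level ramp) or untuned (noise
#' only). Defaults emulate layer 2/3 auditory-cortex cells under the default
#' tone grid.
#'
#' @param n_cells number of cells.
#' @param p_tuned probability a cell is tuned (default 0.5).
#' @param bf_hz optional vector of best frequencies; defaults to random grid
#'   frequencies.
#' @param tuning_width_oct Gaussian tuning SD in octaves (default 0.5;
#'   recycled).
#' @param threshold_db cell response threshold in dB SPL (default random in
#'   {30, 40, 50}; recycled).
#' @param gain peak evoked response (dF/F units, default 1; recycled).
#' @param noise_sd trial noise SD (default 0.3; recycled).
#' @param grid tone grid, see [default_tone_grid()].
#' @param is_tuned optional logical vector overriding the tuned/untuned draw.
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_cells, p_tuned = 0.5, bf_hz = NULL,
                          tuning_width_oct = 0.5, threshold_db = NULL,
                          gain = 1, noise_sd = 0.3,
                          grid = default_tone_grid(), is_tuned = NULL) {
  stopifnot(n_cells >= 1, noise_sd >= 0)
  structure(list(n_cells = as.integer(n_cells), p_tuned = p_tuned,
                 bf_hz = bf_hz, tuning_width_oct = tuning_width_oct,
                 threshold_db = threshold_db, gain = gain,
                 noise_sd = noise_sd, grid = grid, is_tuned = is_tuned),
            class = "ensemble_spec")
}

# saturating level ramp: 0 at threshold - 10 dB, 1 at threshold + 20 dB
level_ramp <- function(level_db, threshold_db) {
  pmin(pmax((level_db - (threshold_db - 10)) / 30, 0), 1)
}

# unit-peak Gaussian tuning curve in octave distance
octave_tuning <- function(freq_hz, bf_hz, width_oct) {
  exp(-0.5 * (log2(freq_hz / bf_hz) / width_oct)^2)
}

#' Simulate tone-evoked trials for an imaged ensemble
#'
#' For a tuned cell, the evoked scalar on a trial at frequency f and level L
#' is `gain * G(log2(f / BF); width) * S(L - threshold) + N(0, noise_sd)`,
#' with G a unit-peak Gaussian in octaves and S a saturating ramp that is 0
#' at threshold - 10 dB and 1 from threshold + 20 dB. Untuned cells are noise
#' only. The truth table carries every generative parameter per cell.
#'
#' @param spec an [ensemble_spec()].
#' @param seed integer seed.
#' @return list with `trials` (data.frame: cell_id, frequency_hz, level_db,
#'   repeat_index, evoked) and `truth` (one row per cell: cell_id, is_tuned,
#'   bf_hz, tuning_width_oct, threshold_db, gain, noise_sd).
#' @export
gen_fra_trials <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "ensemble_spec"))
  grid <- spec$grid
  if (grid$n_repeats < 2) stop("n_repeats must be >= 2")
  combos <- expand.grid(frequency_hz = grid$freqs_hz,
                        level_db = grid$levels_db)
  n_cells <- spec$n_cells
  withr::with_seed(seed, {
    is_tuned <- if (!is.null(spec$is_tuned)) {
      rep_len(spec$is_tuned, n_cells)
    } else stats::runif(n_cells) < spec$p_tuned
    bf <- if (!is.null(spec$bf_hz)) rep_len(spec$bf_hz, n_cells) else
      sample(grid$freqs_hz, n_cells, replace = TRUE)
    thr <- if (!is.null(spec$threshold_db)) rep_len(spec$threshold_db, n_cells) else
      sample(c(30, 40, 50), n_cells, replace = TRUE)
    width <- rep_len(spec$tuning_width_oct, n_cells)
    gain <- rep_len(spec$gain, n_cells)
    noise_sd <- rep_len(spec$noise_sd, n_cells)

    trials <- vector("list", n_cells)
    for (c_i in seq_len(n_cells)) {
      mu <- if (is_tuned[c_i]) {
        gain[c_i] * octave_tuning(combos$frequency_hz, bf[c_i], width[c_i]) *
          level_ramp(combos$level_db, thr[c_i])
      } else rep(0, nrow(combos))
      d <- combos[rep(seq_len(nrow(combos)), each = grid$n_repeats), ]
      d$repeat_index <- rep(seq_len(grid$n_repeats), times = nrow(combos))
      d$evoked <- rep(mu, each = grid$n_repeats) +
        if (noise_sd[c_i] > 0) stats::rnorm(nrow(d), 0, noise_sd[c_i]) else 0
      d$cell_id <- c_i
      trials[[c_i]] <- d
    }
  })
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  trials <- trials[, c("cell_id", "frequency_hz", "level_db",
                       "repeat_index", "evoked")]
  truth <- data.frame(cell_id = seq_len(n_cells), is_tuned = is_tuned,
                      bf_hz = bf, tuning_width_oct = width,
                      threshold_db = thr, gain = gain, noise_sd = noise_sd)
  list(trials = trials, truth = truth)
}
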