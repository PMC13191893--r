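#' Specify a synthetic go/no-go frequency-discrimination experiment
#'
#' The task: lick to the target tone (go) for reward, withhold to non-target
#' tones (no-go). Each non-target condition has a true sensitivity d
#' determined by its octave distance u from the target through a saturating
#' curve `d(u) = asymptote * (1 - exp(-slope * u))`. Trial outcomes follow
#' equal-variance signal detection with the criterion midway between the two
#' distributions, mixed with lapse and guess rates:
#' `P(lick | go) = guess + (1 - guess - lapse) * pnorm(d/2)` and
#' `P(lick | no-go) = guess + (1 - guess - lapse) * pnorm(-d/2)`.
#'
#' @param target_hz go frequency (default 12 kHz).
#' @param nontarget_hz no-go frequencies (default 4, 6, 8.48, 10.09, 11.04,
#'   11.35 kHz).
#' @param sessions number of sessions (default 9, a typical testing block).
#' @param trials_per_condition go and no-go trials per condition per session
#'   (default 25).
#' @param sens_asymptote,sens_slope sensitivity-curve parameters (defaults
#'   4.5 and 2.2 per octave: near-ceiling d' for the easiest condition,
#'   moderate for the hardest).
#' @param sensitivity optional function `u -> d` overriding the default
#'   curve (e.g. `function(u) 0` for a null observer).
#' @param lapse_rate,guess_rate lapse and guess probabilities (defaults
#'   0.02 and 0.05).
#' @param lick_meanlog,lick_sdlog lognormal lick-latency parameters,
#'   seconds post-onset (defaults log(0.4) and 0.35, truncated into the
#'   response window).
#' @return a `psycho_spec` list.
#' @export
psycho_spec <- function(target_hz = 12000,
                        nontarget_hz = c(4000, 6000, 8480, 10090, 11040, 11350),
                        sessions = 9, trials_per_condition = 25,
                        sens_asymptote = 4.5, sens_slope = 2.2,
                        sensitivity = NULL,
                        lapse_rate = 0.02, guess_rate = 0.05,
                        lick_meanlog = log(0.4), lick_sdlog = 0.35) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 1, guess_rate >= 0, guess_rate <= 1,
            lapse_rate + guess_rate <= 1)
  if (target_hz %in% nontarget_hz)
    stop("target frequency must be distinct from all non-targets")
  if (sessions < 1 || trials_per_condition < 1)
    stop("sessions and trials_per_condition must be >= 1")
  if (is.null(sensitivity))
    sensitivity <- function(u) sens_asymptote * (1 - exp(-sens_slope * u))
  structure(list(target_hz = target_hz, nontarget_hz = nontarget_hz,
                 sessions = as.integer(sessions),
                 trials_per_condition = as.integer(trials_per_condition),
                 sensitivity = sensitivity, lapse_rate = lapse_rate,
                 guess_rate = guess_rate, lick_meanlog = lick_meanlog,
                 lick_sdlog = lick_sdlog), class = "psycho_spec")
}

#' Simulate go/no-go sessions with known psychometric ground truth
#'
#' Generates per-trial tone identity, role, onset, and lick times. On each
#' trial the animal "responds" with the probability given by the spec's
#' psychometric model; a response places one lick at onset plus a lognormal
#' latency truncated into the scoring window. Go trials are interleaved with
#' every non-target condition in equal numbers so the shared hit rate is
#' estimated from all go trials. Seed-reproducible.
#'
#' @param spec a [psycho_spec()].
#' @param seed integer seed.
#' @param window response window used to place lick latencies, seconds
#'   (default `c(0.15, 1.2)`).
#' @return data.frame: `session_id`, `trial_index`, `condition_hz` (the
#'   non-target defining the condition), `frequency_hz`, `role`
#'   (`"go"`/`"no-go"`), `tone_onset_s`, `lick_times_s` (semicolon-separated
#'   string, possibly empty), plus attribute `"truth"` with the per-condition
#'   generative d and response probabilities.
#' @export
gen_behavior_sessions <- function(spec, seed = 1, window = c(0.15, 1.2)) {
  stopifnot(inherits(spec, "psycho_spec"))
  u <- octave_distance(spec$nontarget_hz, spec$target_hz)
  d_true <- vapply(u, spec$sensitivity, numeric(1))
  scale <- 1 - spec$guess_rate - spec$lapse_rate
  p_go <- spec$guess_rate + scale * stats::pnorm(d_true / 2)
  p_nogo <- spec$guess_rate + scale * stats::pnorm(-d_true / 2)
  truth <- data.frame(condition_hz = spec$nontarget_hz, octave_dist = u,
                      d_true = d_true, p_lick_go = p_go, p_lick_nogo = p_nogo)

  iti <- 4  # seconds between tone onsets
  rows <- withr::with_seed(seed, {
    out <- vector("list", spec$sessions)
    for (s in seq_len(spec$sessions)) {
      cond <- rep(spec$nontarget_hz, each = 2 * spec$trials_per_condition)
      role <- rep(rep(c("go", "no-go"), each = spec$trials_per_condition),
                  times = length(spec$nontarget_hz))
      ord <- sample(length(cond))
      cond <- cond[ord]; role <- role[ord]
      freq <- ifelse(role == "go", spec$target_hz, cond)
      ci <- match(cond, spec$nontarget_hz)
      p <- ifelse(role == "go", p_go[ci], p_nogo[ci])
      respond <- stats::runif(length(p)) < p
      onset <- iti * seq_along(p)
      lat <- stats::rlnorm(length(p), spec$lick_meanlog, spec$lick_sdlog)
      lat <- pmin(pmax(lat, window[1]), window[2] - 1e-3)
      licks <- ifelse(respond, sprintf("%.6f", onset + lat), "")
      out[[s]] <- data.frame(session_id = s, trial_index = seq_along(p),
                             condition_hz = cond, frequency_hz = freq,
                             role = role, tone_onset_s = onset,
                             lick_times_s = licks,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  attr(rows, "truth") <- truth
  rows
}
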