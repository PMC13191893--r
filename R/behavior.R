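#' Score go/no-go trials into hits, misses, false alarms, correct rejections
#'
#' A go trial with at least one lick in the response window
#' `[onset + w1, onset + w2)` (default 0.15--1.2 s, closed at the left and
#' open at the right) is a hit, otherwise a miss; a no-go trial with a lick
#' in the window is a false alarm, otherwise a correct rejection. Licks
#' before the session start are ignored with a warning.
#'
#' @param events data.frame with `role` (`"go"`/`"no-go"`), `tone_onset_s`,
#'   and `lick_times_s` (semicolon-separated string or list-column of
#'   numeric vectors); onsets must be sorted within a session.
#' @param window response window relative to tone onset, seconds.
#' @return `events` with an added `outcome` column (`hit`, `miss`,
#'   `false_alarm`, `correct_rejection`).
#' @export
score_trials <- function(events, window = c(0.15, 1.2)) {
  licks <- parse_licks(events$lick_times_s)
  neg <- vapply(licks, function(l) any(l < 0), logical(1))
  if (any(neg)) {
    warning("ignoring ", sum(neg), " trial(s) with licks before session start")
    licks <- lapply(licks, function(l) l[l >= 0])
  }
  responded <- mapply(function(l, onset) {
    any(l >= onset + window[1] & l < onset + window[2])
  }, licks, events$tone_onset_s)
  events$outcome <- ifelse(events$role == "go",
                           ifelse(responded, "hit", "miss"),
                           ifelse(responded, "false_alarm", "correct_rejection"))
  events
}

parse_licks <- function(x) {
  if (is.list(x)) return(lapply(x, function(l) as.numeric(l)))
  lapply(strsplit(ifelse(is.na(x), "", x), ";"), function(s) {
    s <- trimws(s)
    as.numeric(s[nzchar(s)])
  })
}

#' Behavioral d-prime from hit and false-alarm counts
#'
#' Signal-detection sensitivity `d' = z(HR) - z(FAR)` with the standard
#' finite-sample correction: rates are clipped to
#' `[1/(2N), 1 - 1/(2N)]` where N is the trial count of the respective
#' condition, so perfect rates stay finite.
#'
#' @param n_hit,n_go hits and go-trial count.
#' @param n_fa,n_nogo false alarms and no-go-trial count.
#' @return d-prime scalar; `NA` if either condition has zero trials.
#' @examples
#' behavioral_dprime(45, 50, 5, 50)  # ~2.563
#' @export
behavioral_dprime <- function(n_hit, n_go, n_fa, n_nogo) {
  if (n_go < 1 || n_nogo < 1) return(NA_real_)
  hr <- clip_rate(n_hit / n_go, n_go)
  far <- clip_rate(n_fa / n_nogo, n_nogo)
  stats::qnorm(hr) - stats::qnorm(far)
}

clip_rate <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))

#' Per-session, per-condition go/no-go performance
#'
#' Aggregates scored trials into hit and false-alarm counts and d-prime per
#' non-target condition. The hit rate is shared within a session (all go
#' trials), while false-alarm rates are per non-target condition; clipping
#' uses each condition's own trial count.
#'
#' @param scored data.frame from [score_trials()] with `session_id`,
#'   `condition_hz`, `role`, `outcome`.
#' @return data.frame: `session_id`, `condition_hz`, `n_go`, `n_hit`,
#'   `n_nogo`, `n_fa`, `hit_rate`, `fa_rate`, `dprime`.
#' @export
session_performance <- function(scored) {
  out <- list()
  for (s in sort(unique(scored$session_id))) {
    d <- scored[scored$session_id == s, ]
    go <- d[d$role == "go", ]
    n_go <- nrow(go); n_hit <- sum(go$outcome == "hit")
    for (f in sort(unique(d$condition_hz))) {
      ng <- d[d$role == "no-go" & d$condition_hz == f, ]
      n_nogo <- nrow(ng); n_fa <- sum(ng$outcome == "false_alarm")
      out[[length(out) + 1L]] <- data.frame(
        session_id = s, condition_hz = f, n_go = n_go, n_hit = n_hit,
        n_nogo = n_nogo, n_fa = n_fa,
        hit_rate = if (n_go) n_hit / n_go else NA_real_,
        fa_rate = if (n_nogo) n_fa / n_nogo else NA_real_,
        dprime = behavioral_dprime(n_hit, n_go, n_fa, n_nogo))
    }
  }
  do.call(rbind, out)
}

#' Easy/hard condition contrast and hard-to-easy ratio
#'
#' Contrasts the easiest discrimination (default the 4 kHz non-target, 1.58
#' octaves from the 12 kHz target) with the hardest (default 11.35 kHz, 0.08
#' octaves). The hard-to-easy ratio `d'_hard / d'_easy` is computed per
#' session and is undefined when `d'_easy <= eps`.
#'
#' @param perf data.frame from [session_performance()].
#' @param easy_hz,hard_hz condition frequencies (defaults 4000 and 11350).
#' @param eps minimum easy d-prime for the ratio (default 0.1).
#' @return data.frame: `session_id`, `dprime_easy`, `dprime_hard`,
#'   `hard_easy_ratio` (`NA` when undefined or a condition is missing).
#' @export
condition_contrasts <- function(perf, easy_hz = 4000, hard_hz = 11350,
                                eps = 0.1) {
  sessions <- sort(unique(perf$session_id))
  out <- data.frame(session_id = sessions, dprime_easy = NA_real_,
                    dprime_hard = NA_real_, hard_easy_ratio = NA_real_)
  for (i in seq_along(sessions)) {
    d <- perf[perf$session_id == sessions[i], ]
    de <- d$dprime[d$condition_hz == easy_hz]
    dh <- d$dprime[d$condition_hz == hard_hz]
    if (length(de) == 1) out$dprime_easy[i] <- de
    if (length(dh) == 1) out$dprime_hard[i] <- dh
    if (length(de) == 1 && length(dh) == 1 && !is.na(de) && de > eps)
      out$hard_easy_ratio[i] <- dh / de
  }
  out
}
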