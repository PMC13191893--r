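#' Octave distance between two frequencies
#'
#' @param f1,f2 frequencies in Hz (> 0); vectorized.
#' @return `|log2(f1 / f2)|` in octaves.
#' @examples
#' octave_distance(4000, 12000)   # 1.58 octaves
#' octave_distance(11350, 12000)  # 0.08 octaves
#' @export
octave_distance <- function(f1, f2) {
  if (any(f1 <= 0) || any(f2 <= 0)) stop("frequencies must be positive")
  abs(log2(f1 / f2))
}

#' Trial-by-cell feature matrix at one sound level
#'
#' Pivots a trial table into the decoding feature matrix: one row per trial
#' at the requested level, one column per cell, values the evoked response
#' scalars (sound-evoked activity in the FRA window, already normalized by
#' the pre-stimulus activity upstream). All cells recorded in the session are
#' included. Missing entries are imputed with 0 and flagged via the
#' `"n_imputed"` attribute.
#'
#' @param trials data.frame: `cell_id`, `frequency_hz`, `level_db`,
#'   `repeat_index`, `evoked`.
#' @param level_db sound level to decode at (default 70 dB SPL, well above
#'   threshold).
#' @return list with `X` (trials x cells matrix) and `y` (tone frequency per
#'   trial, Hz).
#' @export
trial_feature_matrix <- function(trials, level_db = 70) {
  d <- trials[trials$level_db == level_db, ]
  if (nrow(d) == 0) stop("no trials at level ", level_db, " dB SPL")
  cells <- sort(unique(trials$cell_id))
  key <- interaction(d$frequency_hz, d$repeat_index, drop = TRUE)
  trial_ids <- levels(key)
  X <- matrix(NA_real_, length(trial_ids), length(cells),
              dimnames = list(trial_ids, paste0("cell_", cells)))
  X[cbind(match(key, trial_ids), match(d$cell_id, cells))] <- d$evoked
  y <- d$frequency_hz[match(trial_ids, key)]
  n_imputed <- sum(is.na(X))
  X[is.na(X)] <- 0
  out <- list(X = X, y = y)
  attr(out, "n_imputed") <- n_imputed
  out
}

# stratified k-fold assignment; returns fold index per observation
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Pairwise linear decoding of tone frequency from ensemble activity
#'
#' Trains a linear-kernel support-vector machine to discriminate two tone
#' frequencies from the trial feature matrix, using stratified k-fold
#' cross-validation (default k = 5) repeated `reps` times with re-randomized
#' fold assignments (repetition r uses `seed + r`). Features are z-scored
#' per column on the training folds only; the regularization constant is
#' fixed at 1. Accuracy is 1 minus the mean misclassification rate over
#' held-out trials, averaged over repetitions. Deterministic given `seed`.
#'
#' @param X trials x cells numeric matrix.
#' @param y class label per row (tone frequency, Hz, or any two-level label).
#' @param pair length-2 vector naming the two classes to decode (default the
#'   two unique values of `y`).
#' @param k folds (default 5); both classes must have at least k trials.
#' @param reps cross-validation repetitions (default 100).
#' @param seed integer seed.
#' @param cost SVM regularization constant (default 1).
#' @return list with `f1`, `f2`, `octave_separation` (when the labels are
#'   frequencies), `mean_accuracy`, `n_repetitions`, `accuracy_per_rep`.
#' @export
pairwise_decode <- function(X, y, pair = NULL, k = 5, reps = 100, seed = 1,
                            cost = 1) {
  if (is.null(pair)) {
    pair <- unique(y)
    if (length(pair) != 2) stop("y must contain exactly 2 classes, or give `pair`")
  }
  keep <- y %in% pair
  X <- X[keep, , drop = FALSE]
  y <- factor(y[keep], levels = pair)
  counts <- table(y)
  if (any(counts < k))
    stop("each class needs at least k = ", k, " trials; got ",
         paste(counts, collapse = ", "))
  acc <- numeric(reps)
  for (r in seq_len(reps)) {
    acc[r] <- withr::with_seed(seed + r, {
      fold <- stratified_folds(y, k)
      err <- 0L
      for (f in seq_len(k)) {
        tr <- fold != f
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
        sdv[sdv == 0 | is.na(sdv)] <- 1
        Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
        Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
        fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost,
                          scale = FALSE)
        pred <- stats::predict(fit, Xte)
        err <- err + sum(pred != y[!tr])
      }
      1 - err / length(y)
    })
  }
  octs <- suppressWarnings(as.numeric(as.character(pair)))
  structure(list(
    f1 = pair[1], f2 = pair[2],
    octave_separation = if (!any(is.na(octs))) octave_distance(octs[1], octs[2])
                        else NA_real_,
    mean_accuracy = mean(acc), n_repetitions = reps,
    accuracy_per_rep = acc), class = "pair_decoding_result")
}

#' Decode all frequency pairs of a session
#'
#' Runs [pairwise_decode()] on every unordered pair of tone frequencies in
#' the feature matrix and tabulates accuracy against octave separation.
#'
#' @inheritParams pairwise_decode
#' @return data.frame: `f1_hz`, `f2_hz`, `octave_separation`,
#'   `mean_accuracy`, `n_repetitions`.
#' @export
decode_all_pairs <- function(X, y, k = 5, reps = 100, seed = 1, cost = 1) {
  freqs <- sort(unique(y))
  pairs <- utils::combn(freqs, 2)
  out <- data.frame(f1_hz = pairs[1, ], f2_hz = pairs[2, ],
                    octave_separation = NA_real_, mean_accuracy = NA_real_,
                    n_repetitions = reps)
  for (i in seq_len(ncol(pairs))) {
    res <- pairwise_decode(X, y, pair = pairs[, i], k = k, reps = reps,
                           seed = seed + 1000L * i, cost = cost)
    out$octave_separation[i] <- res$octave_separation
    out$mean_accuracy[i] <- res$mean_accuracy
  }
  out
}

#' Summarize decoding accuracy by octave separation
#'
#' Bins pair-decoding results by octave separation and reports the per-bin
#' mean and SEM of accuracy. The default two-bin split puts pairs at 1.5
#' octaves or less in the "small" bin and pairs above 1.5 octaves in the
#' "big" bin (inclusive left boundary). Arbitrary bin edges produce the
#' finer per-separation curve. Empty bins are reported with `NA` summaries,
#' not dropped.
#'
#' @param results data.frame with `octave_separation` and `mean_accuracy`
#'   (e.g. from [decode_all_pairs()]).
#' @param edges bin edges in octaves; default `c(0, 1.5, Inf)` giving the
#'   small/big split. A separation equal to an interior edge falls in the
#'   lower bin.
#' @param labels optional bin labels; defaults to `"small"`/`"big"` for the
#'   two-bin split, else interval notation.
#' @return data.frame: `bin`, `n`, `mean_accuracy`, `sem_accuracy`.
#' @export
accuracy_by_separation <- function(results, edges = c(0, 1.5, Inf),
                                   labels = NULL) {
  if (nrow(results) == 0) stop("results is empty")
  if (is.null(labels)) {
    labels <- if (length(edges) == 3 && edges[2] == 1.5) c("small", "big")
              else NULL
  }
  bin <- cut(results$octave_separation, breaks = edges, right = TRUE,
             include.lowest = TRUE, labels = labels)
  out <- data.frame(bin = levels(bin), n = 0L, mean_accuracy = NA_real_,
                    sem_accuracy = NA_real_)
  for (i in seq_along(levels(bin))) {
    a <- results$mean_accuracy[!is.na(bin) & bin == levels(bin)[i]]
    out$n[i] <- length(a)
    if (length(a)) {
      out$mean_accuracy[i] <- mean(a)
      out$sem_accuracy[i] <- if (length(a) > 1) stats::sd(a) / sqrt(length(a))
                             else NA_real_
    }
  }
  out
}
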