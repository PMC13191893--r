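test_that("evoked response is the post-minus-pre window mean", {
  times <- seq(-0.2, 0.32, by = 1 / 30)  # 30 Hz frame centers
  flat <- rep(2.5, length(times))
  expect_equal(evoked_response(flat, times, onset_s = 0), 0)

  # pre frames (1,1,1), post frames (2,2,2)
  tt <- c(-0.11, -0.07, -0.03, 0.01, 0.05, 0.09)
  expect_equal(evoked_response(c(1, 1, 1, 2, 2, 2), tt, onset_s = 0), 1)

  # injected step of amplitude a, no noise
  a <- 0.37
  step <- ifelse(times >= 0, a, 0)
  expect_equal(evoked_response(step, times, onset_s = 0), a)

  expect_error(evoked_response(c(1, 2), c(-0.01, 0.01), onset_s = 0),
               "fewer than 2 frames")
})

test_that("driven mask is exact on a designed noiseless cell and conservative otherwise", {
  grid <- default_tone_grid()
  # wide tuning + high threshold: every generative-positive combo clears the
  # 20% boundary, so the mask must equal the positive set exactly
  sp <- ensemble_spec(1, is_tuned = TRUE, bf_hz = grid$freqs_hz[4],
                      tuning_width_oct = 1.5, threshold_db = 70, noise_sd = 0)
  fg <- build_fra(gen_fra_trials(sp, seed = 1)$trials)
  positive <- outer(grid$freqs_hz, grid$levels_db, function(f, l) l > 60)
  expect_identical(unname(fg$driven_mask), positive)

  # narrow cell: mask is a subset of the generative-positive combos
  sp2 <- ensemble_spec(1, is_tuned = TRUE, bf_hz = 16000,
                       tuning_width_oct = 0.4, threshold_db = 40, noise_sd = 0)
  f2 <- build_fra(gen_fra_trials(sp2, seed = 1)$trials)
  positive2 <- outer(grid$freqs_hz, grid$levels_db, function(f, l) l > 30)
  expect_true(all(!f2$driven_mask | positive2))
  expect_true(any(f2$driven_mask))

  # single-combo responder: the mask is exactly that combo
  single <- expand.grid(frequency_hz = grid$freqs_hz,
                        level_db = grid$levels_db, repeat_index = 1:3)
  single$evoked <- ifelse(single$frequency_hz == 16000 &
                          single$level_db == 70, 1, 0)
  fs <- build_fra(single)
  expect_equal(sum(fs$driven_mask), 1)
  expect_true(fs$driven_mask[match(16000, fs$freqs), match(70, fs$levels)])

  # all-constant cell: empty mask, flagged
  const <- expand.grid(frequency_hz = grid$freqs_hz, level_db = grid$levels_db,
                       repeat_index = 1:3)
  const$evoked <- 1
  fc <- build_fra(const)
  expect_true(fc$constant_flag)
  expect_false(any(fc$driven_mask))
})

test_that("pure-noise masks stay small across seeds", {
  area <- vapply(1:100, function(s) {
    g <- gen_fra_trials(ensemble_spec(1, is_tuned = FALSE), seed = 3000 + s)
    sum(build_fra(g$trials)$driven_mask)
  }, numeric(1))
  expect_gte(mean(area <= 0.1 * 56), 0.95)
})

test_that("grid bookkeeping: driven + undriven = complete default grid", {
  g <- gen_fra_trials(ensemble_spec(3, p_tuned = 1, is_tuned = TRUE), seed = 6)
  for (cid in 1:3) {
    fg <- build_fra(g$trials[g$trials$cell_id == cid, ])
    expect_equal(sum(fg$driven_mask) + sum(!fg$driven_mask), 56)
    expect_equal(dim(fg$mean_response), c(8, 7))
  }
})

test_that("resampled d-prime handles degenerate and scaled inputs", {
  grid <- default_tone_grid()
  m <- matrix(1, 8, 7)  # driven and undriven share one constant
  mask <- matrix(FALSE, 8, 7); mask[3:5, 4:6] <- TRUE
  fg <- make_grid(m, mask, grid$freqs_hz, grid$levels_db)
  expect_equal(fra_dprime(fg, seed = 1), 0)

  # driven 1 / undriven 0 exactly: zero variance, unequal means -> cap
  m2 <- matrix(0, 8, 7); m2[mask] <- 1
  # padding mixes undriven values into the driven pool, so suppress it to
  # exercise the pure degenerate branch
  fg2 <- make_grid(m2, mask, grid$freqs_hz, grid$levels_db)
  expect_equal(fra_dprime(fg2, seed = 1, pad_to = 0), 10)

  # affine invariance: shared gain and offset leave d-prime unchanged
  g <- gen_fra_trials(ensemble_spec(1, is_tuned = TRUE, bf_hz = 11313.7,
                                    threshold_db = 40), seed = 9)
  fg3 <- build_fra(g$trials)
  d0 <- fra_dprime(fg3, seed = 21)
  fg4 <- fg3
  fg4$mean_response <- 3.7 * fg3$mean_response + 1.2
  expect_equal(fra_dprime(fg4, seed = 21), d0, tolerance = 1e-12)

  # empty driven portion -> NA with reason
  fg5 <- make_grid(m, matrix(FALSE, 8, 7), grid$freqs_hz, grid$levels_db)
  expect_true(is.na(fra_dprime(fg5, seed = 1)))
})

test_that("d-prime grows with the generative gain-to-noise ratio", {
  gains <- c(0.25, 0.5, 1, 2)
  mean_dp <- vapply(gains, function(gn) {
    dp <- vapply(1:40, function(s) {
      g <- gen_fra_trials(ensemble_spec(1, is_tuned = TRUE, bf_hz = 16000,
                                        threshold_db = 40, gain = gn),
                          seed = 400 + s)
      as.numeric(fra_dprime(build_fra(g$trials), seed = 500 + s))
    }, numeric(1))
    mean(dp, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_dp) > 0))
})

test_that("FRA metrics recover BF, threshold, and bandwidth", {
  grid <- default_tone_grid()
  # noiseless cells with generative BF on the grid: exact recovery
  sp <- ensemble_spec(8, is_tuned = TRUE, bf_hz = grid$freqs_hz,
                      threshold_db = 40, noise_sd = 0)
  g <- gen_fra_trials(sp, seed = 1)
  for (cid in 1:8) {
    m <- fra_metrics(build_fra(g$trials[g$trials$cell_id == cid, ]))
    expect_equal(m$best_frequency_hz, grid$freqs_hz[cid])
    expect_equal(m$threshold_db, 40)
  }

  # hand-built masks: bandwidth at threshold + 10 dB
  resp <- matrix(0, 8, 7); mask <- matrix(FALSE, 8, 7)
  resp[4, 3:5] <- 1; mask[4, 3:5] <- TRUE   # single frequency driven
  m1 <- fra_metrics(make_grid(resp, mask, grid$freqs_hz, grid$levels_db))
  expect_equal(m1$threshold_db, 40)
  expect_equal(m1$bandwidth_octaves, 0)

  # driven row spanning 8-32 kHz at threshold + 10: log2(32/8) = 2 octaves
  resp2 <- matrix(0, 8, 7); mask2 <- matrix(FALSE, 8, 7)
  i8 <- match(8000, grid$freqs_hz); i32 <- match(32000, grid$freqs_hz)
  mask2[i8:i32, 4:6] <- TRUE; resp2[i8:i32, 4:6] <- 1
  mask2[i8 + 1, 3] <- TRUE; resp2[i8 + 1, 3] <- 1  # threshold row at 40 dB
  m2 <- fra_metrics(make_grid(resp2, mask2, grid$freqs_hz, grid$levels_db))
  expect_equal(m2$threshold_db, 40)
  expect_equal(m2$bandwidth_octaves, 2)

  # empty mask: undefined metrics
  m3 <- fra_metrics(make_grid(resp, matrix(FALSE, 8, 7), grid$freqs_hz,
                              grid$levels_db))
  expect_true(all(is.na(unlist(m3))))
})

test_that("the d-prime > 1.5 filter separates tuned from untuned cells", {
  g <- gen_fra_trials(ensemble_spec(60, p_tuned = 0.5), seed = 31)
  met <- analyze_fra_cells(g$trials, seed = 77)
  kept <- filter_cells(met)
  # strict inequality at the cutoff
  met_edge <- data.frame(cell_id = 1:2, dprime = c(1.5, 1.500001))
  expect_equal(filter_cells(met_edge)$cell_id, 2L)

  tuned <- g$truth$is_tuned
  sens <- mean(met$retained[tuned])
  spc <- mean(!met$retained[!tuned])
  expect_gte((sens + spc) / 2, 0.9)
  expect_equal(sort(kept$cell_id), sort(met$cell_id[met$retained]))

  # all-noise population: under 10% retained
  g0 <- gen_fra_trials(ensemble_spec(40, is_tuned = FALSE), seed = 32)
  met0 <- analyze_fra_cells(g0$trials, seed = 78)
  expect_lt(mean(met0$retained), 0.1)
})
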