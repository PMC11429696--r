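make_tally <- function(n_left, n_right, dwell_left = n_left * 100,
                       dwell_right = n_right * 100, first = NA) {
  tibble::tibble(
    session_id = "S1", monkey_id = "M1", office = "gubernatorial",
    trial_index = seq_along(n_left) - 1,
    race_id = paste0("R", seq_along(n_left)),
    left_candidate_id = paste0("R", seq_along(n_left), "_a"),
    right_candidate_id = paste0("R", seq_along(n_left), "_b"),
    n_fix_left = n_left, n_fix_right = n_right,
    dwell_left_ms = dwell_left, dwell_right_ms = dwell_right,
    first_side = first, n_ignored = 0
  )
}

test_that("gaze bias index is a signed normalized ratio", {
  expect_equal(gaze_bias_index(6, 4), 0.2)
  for (k in c(1, 3, 17)) expect_equal(gaze_bias_index(k, k), 0)
  expect_true(is.na(gaze_bias_index(0, 0)))
  expect_equal(gaze_bias_index(c(6, 2, 0), c(4, 2, 0)),
               c(0.2, 0, NA_real_))
})

test_that("votes go to the less-looked-at candidate under every rule", {
  tal <- make_tally(n_left = c(5, 4, 0), n_right = c(3, 4, 0),
                    first = c("left", "right", NA))
  fc <- cast_votes(tal, "fixation_count")
  expect_equal(fc$predicted_winner_id, c("R1_b", NA, NA))

  dw <- cast_votes(make_tally(2, 3, dwell_left = 900, dwell_right = 300),
                   "dwell_time")
  expect_equal(dw$predicted_winner_id, "R1_b")

  ff <- cast_votes(tal, "first_fixation")
  expect_equal(ff$predicted_winner_id, c("R1_b", "R2_a", NA))

  # exactly one of {left, right, tie} per trial under every rule
  study <- simulate_study(small_config())
  el <- validate_elections(study$candidates)
  tl <- tally_trials(study$fixations, study$layouts)
  for (r in vote_rules) {
    v <- cast_votes(tl, r)
    ok <- is.na(v$predicted_winner_id) |
      v$predicted_winner_id == v$left_candidate_id |
      v$predicted_winner_id == v$right_candidate_id
    expect_true(all(ok))
  }
})

test_that("rule outcomes are side-symmetric given the same tallies", {
  tal <- make_tally(n_left = c(5, 2, 3), n_right = c(3, 2, 7),
                    dwell_left = c(500, 100, 300),
                    dwell_right = c(300, 100, 800),
                    first = c("left", "right", "left"))
  swapped <- tal
  swapped$left_candidate_id <- tal$right_candidate_id
  swapped$right_candidate_id <- tal$left_candidate_id
  swapped$n_fix_left <- tal$n_fix_right
  swapped$n_fix_right <- tal$n_fix_left
  swapped$dwell_left_ms <- tal$dwell_right_ms
  swapped$dwell_right_ms <- tal$dwell_left_ms
  swapped$first_side <- c(left = "right", right = "left")[tal$first_side]
  for (r in vote_rules) {
    expect_equal(cast_votes(tal, r)$predicted_winner_id,
                 cast_votes(swapped, r)$predicted_winner_id)
  }
})

test_that("session accuracy gives ties half credit and matches a manual recount", {
  el <- make_elections(paste0("R", 1:10))  # winner is always the _a candidate
  tal <- make_tally(n_left = c(rep(3, 7), rep(5, 3)),
                    n_right = c(rep(5, 7), rep(3, 3)))
  tal$left_candidate_id <- paste0("R", 1:10, "_a")
  tal$right_candidate_id <- paste0("R", 1:10, "_b")
  acc <- session_accuracy(cast_votes(tal, "fixation_count"), el$candidates)
  expect_equal(acc$accuracy, 0.7)

  tal$n_fix_right[10] <- 5  # turn one wrong prediction into a tie
  acc2 <- session_accuracy(cast_votes(tal, "fixation_count"), el$candidates)
  expect_equal(acc2$accuracy, 0.75)
  expect_equal(acc2$n_ties, 1)

  # all ties -> exactly chance
  tal$n_fix_left <- tal$n_fix_right <- rep(2, 10)
  acc3 <- session_accuracy(cast_votes(tal, "fixation_count"), el$candidates)
  expect_equal(acc3$accuracy, 0.5)

  # manual recount on an enumerated toy session
  counts_l <- c(1, 4, 2, 2, 6)
  counts_r <- c(3, 1, 2, 5, 2)
  tal4 <- make_tally(counts_l, counts_r)
  tal4$left_candidate_id <- paste0("R", 1:5, "_a")
  tal4$right_candidate_id <- paste0("R", 1:5, "_b")
  el4 <- make_elections(paste0("R", 1:5))
  manual <- mean(ifelse(counts_l == counts_r, 0.5,
                        as.numeric(counts_l < counts_r)))
  acc4 <- session_accuracy(cast_votes(tal4, "fixation_count"), el4$candidates)
  expect_equal(acc4$accuracy, manual)

  expect_error(session_accuracy(tal4[0, ], el4$candidates),
               class = "gazepoll_validation_error")
})

test_that("accuracy summary matches a hand-computed one-sample t test", {
  x <- c(0.52, 0.55, 0.58, 0.51, 0.56, 0.55)
  s <- accuracy_summary(x)
  # independent oracle: explicit formulas
  m <- sum(x) / 6
  sdev <- sqrt(sum((x - m)^2) / 5)
  t_oracle <- (m - 0.5) / (sdev / sqrt(6))
  p_oracle <- 2 * pt(-abs(t_oracle), 5)
  expect_equal(s$mean, m)
  expect_equal(s$sem, sdev / sqrt(6))
  expect_equal(s$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(s$p_value, p_oracle, tolerance = 1e-12)

  z <- accuracy_summary(rep(0.5, 4))
  expect_equal(z$mean, 0.5)
  expect_equal(z$sem, 0)
  expect_true(is.na(z$p_value))

  expect_error(accuracy_summary(0.7), class = "gazepoll_validation_error")
})

test_that("paired test matches exact enumeration and handles degenerate input", {
  expect_equal(paired_gaze_test(1:5, 1:5)$p_value, 1)
  expect_true(paired_gaze_test(1:5, 1:5)$all_zero)

  a <- c(3.2, 4.1, 5.5, 2.2, 6.1, 7.3, 1.9, 4.8)
  b <- a - c(0.5, 0.7, 0.2, 0.9, 0.4, 1.1, 0.3, 0.6)  # strictly positive diffs
  p <- paired_gaze_test(a, b)$p_value
  expect_equal(p, exact_signed_rank_p(a - b))
  expect_equal(p, 2 / 2^8)  # most extreme assignment

  expect_equal(paired_gaze_test(a, b)$p_value,
               paired_gaze_test(b, a)$p_value)

  set.seed(7)
  for (n in 2:8) {
    d <- round(rnorm(n), 6)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(paired_gaze_test(d, rep(0, length(d)))$p_value,
                 exact_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("unpaired test matches exact enumeration and is rank-based", {
  expect_equal(unpaired_gaze_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 1)

  x <- 1:4
  y <- 11:14
  expect_equal(unpaired_gaze_test(x, y)$p_value, exact_rank_sum_p(x, y))
  expect_equal(unpaired_gaze_test(x, y)$p_value, 2 / choose(8, 4))

  set.seed(11)
  for (rep in 1:10) {
    g1 <- rnorm(sample(2:8, 1))
    g2 <- rnorm(sample(2:8, 1))
    expect_equal(unpaired_gaze_test(g1, g2)$p_value,
                 exact_rank_sum_p(g1, g2), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(unpaired_gaze_test(exp(g1), exp(g2))$p_value,
                 unpaired_gaze_test(g1, g2)$p_value)
  }

  expect_error(unpaired_gaze_test(numeric(0), 1:3),
               class = "gazepoll_validation_error")
})

test_that("candidate fixation profile averages over presentations and conserves counts", {
  tal <- make_tally(n_left = c(3, 4, 5, 4, 3, 5), n_right = c(1, 2, 1, 2, 1, 2))
  tal$left_candidate_id <- "X"   # same candidate shown six times on the left
  tal$right_candidate_id <- paste0("Y", 1:6)
  prof <- candidate_fixation_profile(tal)
  expect_equal(prof$mean_fixations[prof$candidate_id == "X"], 4.0)
  expect_equal(prof$n_presentations[prof$candidate_id == "X"], 6)
  # candidates shown twice have denominator 2
  tal2 <- make_tally(n_left = c(3, 5), n_right = c(1, 1))
  tal2$left_candidate_id <- "Z"
  prof2 <- candidate_fixation_profile(tal2)
  expect_equal(prof2$mean_fixations[prof2$candidate_id == "Z"], 4)
  # conservation within a trial
  study <- simulate_study(small_config())
  tl <- tally_trials(study$fixations, study$layouts)
  per_trial_events <- dplyr::count(study$fixations, session_id, trial_index)
  joined <- dplyr::left_join(tl, per_trial_events,
                             by = c("session_id", "trial_index"))
  expect_true(all(joined$n_fix_left + joined$n_fix_right +
                    joined$n_ignored == joined$n))
})
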