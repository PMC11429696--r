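# Gaze-bias scoring: bias indices, rule-based election "votes", prediction
# accuracy, and the paired/unpaired rank tests used throughout the analyses.
#
# The voting direction follows the empirical loser-directed gaze bias:
# monkeys look MORE at the eventual loser, so every rule predicts the
# LESS-looked-at candidate as the winner.

#' Vote rules
#'
#' The three analytical approaches for converting a trial's gaze tally into a
#' predicted winner: fewest fixations, least dwell time, or not-first-fixated.
#' @export
vote_rules <- c("fixation_count", "dwell_time", "first_fixation")

#' Signed gaze-bias index
#'
#' `(n_target - n_other) / (n_target + n_other)`, a normalized preferential
#' looking index in `[-1, 1]`. Undefined (NA) when both counts are zero.
#' Works on fixation counts or dwell times alike.
#'
#' @param n_target,n_other Non-negative counts (or dwell ms) for the target
#'   and the other side; vectorized.
#' @return Numeric vector of bias indices, `NA` where both inputs are zero.
#' @export
gaze_bias_index <- function(n_target, n_other) {
  tot <- n_target + n_other
  ifelse(tot == 0, NA_real_, (n_target - n_other) / tot)
}

#' Cast election votes from gaze tallies
#'
#' Applies a vote rule to every trial tally: under `fixation_count` the
#' predicted winner is the side with fewer fixations; under `dwell_time` the
#' side with less summed dwell; under `first_fixation` the side that was not
#' fixated first. Equal counts/dwell, or no in-box fixation at all, give a
#' tie (`NA` prediction). Trials with zero in-box fixations are ties under
#' every rule.
#'
#' @param tallies A trial tally tibble from [tally_trials()].
#' @param rule One of `r paste0('"', vote_rules, '"', collapse = ", ")`.
#' @return The tally tibble with `rule` and `predicted_winner_id` columns
#'   (`NA` = tie).
#' @export
cast_votes <- function(tallies, rule = vote_rules) {
  rule <- match.arg(rule)
  pick <- function(left_stat, right_stat) {
    dplyr::case_when(
      left_stat == 0 & right_stat == 0 ~ NA_character_,
      left_stat < right_stat ~ tallies$left_candidate_id,
      right_stat < left_stat ~ tallies$right_candidate_id,
      TRUE ~ NA_character_
    )
  }
  predicted <- switch(
    rule,
    fixation_count = pick(tallies$n_fix_left, tallies$n_fix_right),
    dwell_time = pick(tallies$dwell_left_ms, tallies$dwell_right_ms),
    first_fixation = dplyr::case_when(
      is.na(tallies$first_side) ~ NA_character_,
      tallies$first_side == "left" ~ tallies$right_candidate_id,
      TRUE ~ tallies$left_candidate_id
    )
  )
  dplyr::mutate(tallies, rule = rule, predicted_winner_id = predicted)
}

#' Score predictions against recorded winners
#'
#' @param predictions Output of [cast_votes()].
#' @param candidates Candidate tibble with `candidate_id` and `winner`.
#' @return The predictions with a `correct` column: 1 correct, 0 wrong,
#'   `NA` for ties.
#' @export
score_predictions <- function(predictions, candidates) {
  winners <- candidates[candidates$winner == 1, c("race_id", "candidate_id")]
  names(winners)[2] <- "winner_id"
  missing <- setdiff(unique(predictions$race_id), winners$race_id)
  if (length(missing) > 0) {
    gp_validation_error(sprintf(
      "predictions: race '%s' has no recorded winner", missing[1]
    ))
  }
  df <- dplyr::left_join(predictions, winners, by = "race_id")
  df$correct <- ifelse(is.na(df$predicted_winner_id), NA_real_,
                       as.numeric(df$predicted_winner_id == df$winner_id))
  df
}

#' Per-session prediction accuracy
#'
#' Accuracy is `(correct + 0.5 * ties) / predictions`: ties earn half credit
#' so every race stays in the denominator and chance is exactly 0.5.
#'
#' @param predictions Output of [cast_votes()].
#' @param candidates Candidate tibble with recorded winners.
#' @return A tibble with one row per session: `session_id`, `n_trials`,
#'   `n_ties`, `accuracy`.
#' @export
session_accuracy <- function(predictions, candidates) {
  if (nrow(predictions) == 0) {
    gp_validation_error("session_accuracy: empty prediction list")
  }
  df <- score_predictions(predictions, candidates)
  dplyr::summarise(
    dplyr::group_by(df, .data$session_id),
    n_trials = dplyr::n(),
    n_ties = sum(is.na(.data$correct)),
    accuracy = (sum(.data$correct, na.rm = TRUE) +
                  0.5 * sum(is.na(.data$correct))) / dplyr::n(),
    .groups = "drop"
  )
}

#' Summarize per-session accuracies against chance
#'
#' Mean, standard error of the mean, and a two-sided one-sample t test of the
#' session accuracies against chance (0.5). With zero variance across
#' sessions the t statistic is undefined and `p_value` is returned as `NA`
#' rather than fabricated.
#'
#' @param per_session Numeric vector of per-session accuracy proportions
#'   (length >= 2).
#' @param chance Null value, default 0.5.
#' @return A list: `mean`, `sem`, `t_statistic`, `p_value`, `df`,
#'   `n_sessions`.
#' @export
accuracy_summary <- function(per_session, chance = 0.5) {
  n <- length(per_session)
  if (n < 2) {
    gp_validation_error("accuracy_summary: need at least 2 sessions")
  }
  m <- mean(per_session)
  s <- sd(per_session)
  sem <- s / sqrt(n)
  if (s == 0) {
    return(list(mean = m, sem = 0, t_statistic = NA_real_,
                p_value = NA_real_, df = n - 1, n_sessions = n))
  }
  t_stat <- (m - chance) / sem
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  list(mean = m, sem = sem, t_statistic = t_stat, p_value = p,
       df = n - 1, n_sessions = n)
}

# Shared policy for the rank tests: exact null distribution for small
# samples (n <= 12 per group) without ties, normal approximation with
# continuity and tie correction otherwise.
gp_use_exact <- function(n, has_ties) n <= 12 && !has_ties

#' Paired gaze test (Wilcoxon signed rank)
#'
#' Two-sided Wilcoxon signed-rank test for paired per-race values (e.g.
#' fixations on the loser vs on the winner of each race). Zero differences
#' are dropped per the standard convention; if all differences are zero the
#' test returns p = 1 with a flag. The exact null distribution is used for
#' up to 12 non-zero untied differences, the tie-corrected normal
#' approximation otherwise.
#'
#' @param values_a,values_b Equal-length numeric vectors paired by race.
#' @return A list: `p_value`, `statistic`, `n_pairs` (non-zero differences),
#'   `method`, and `all_zero` flag.
#' @export
paired_gaze_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    gp_validation_error("paired_gaze_test: inputs must have equal length")
  }
  d <- values_a - values_b
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(p_value = 1, statistic = NA_real_, n_pairs = 0,
                method = "all differences zero", all_zero = TRUE))
  }
  exact <- gp_use_exact(length(d), anyDuplicated(abs(d)) > 0)
  ht <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE)
  )
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       n_pairs = length(d),
       method = if (exact) "exact signed rank" else "normal approximation",
       all_zero = FALSE)
}

#' Unpaired gaze test (Wilcoxon rank sum)
#'
#' Two-sided Wilcoxon rank-sum test between two independent groups (e.g.
#' female vs male candidates). Exact null distribution when both groups have
#' at most 12 untied observations, tie-corrected normal approximation
#' otherwise.
#'
#' @param values_g1,values_g2 Non-empty numeric vectors.
#' @return A list: `p_value`, `statistic`, `n1`, `n2`, `method`.
#' @export
unpaired_gaze_test <- function(values_g1, values_g2) {
  if (length(values_g1) == 0 || length(values_g2) == 0) {
    gp_validation_error("unpaired_gaze_test: both groups must be non-empty")
  }
  has_ties <- anyDuplicated(c(values_g1, values_g2)) > 0
  exact <- gp_use_exact(max(length(values_g1), length(values_g2)), has_ties)
  ht <- suppressWarnings(
    wilcox.test(values_g1, values_g2, exact = exact, correct = TRUE)
  )
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       n1 = length(values_g1), n2 = length(values_g2),
       method = if (exact) "exact rank sum" else "normal approximation")
}

#' Per-candidate fixation profile
#'
#' For each candidate, the mean in-box fixation count per presentation, over
#' every trial in which the candidate appeared (on either side). Downstream,
#' this joins to vote share for the fixations-vs-vote-share correlation.
#'
#' @param tallies A trial tally tibble from [tally_trials()].
#' @param measure `"count"` (fixation counts) or `"dwell"` (dwell ms).
#' @return A tibble: `candidate_id`, `n_presentations`, `mean_fixations`.
#' @export
candidate_fixation_profile <- function(tallies, measure = c("count", "dwell")) {
  measure <- match.arg(measure)
  left <- tibble::tibble(
    candidate_id = tallies$left_candidate_id,
    value = if (measure == "count") tallies$n_fix_left else tallies$dwell_left_ms
  )
  right <- tibble::tibble(
    candidate_id = tallies$right_candidate_id,
    value = if (measure == "count") tallies$n_fix_right else tallies$dwell_right_ms
  )
  both <- dplyr::bind_rows(left, right)
  dplyr::summarise(
    dplyr::group_by(both, .data$candidate_id),
    n_presentations = dplyr::n(),
    mean_fixations = mean(.data$value),
    .groups = "drop"
  )
}

#' Per-race loser-vs-winner gaze values
#'
#' Reduces trial tallies to one row per race with the mean per-presentation
#' gaze measure directed at the eventual loser and at the winner — the paired
#' inputs for the loser-bias signed-rank test.
#'
#' @param tallies A trial tally tibble.
#' @param candidates Candidate tibble with `winner` flags.
#' @param measure `"count"` or `"dwell"`.
#' @return A tibble: `race_id`, `loser_value`, `winner_value`, `n_trials`.
#' @export
outcome_gaze_values <- function(tallies, candidates,
                                measure = c("count", "dwell")) {
  measure <- match.arg(measure)
  winners <- candidates[candidates$winner == 1, c("race_id", "candidate_id")]
  names(winners)[2] <- "winner_id"
  df <- dplyr::left_join(tallies, winners, by = "race_id")
  lv <- if (measure == "count") df$n_fix_left else df$dwell_left_ms
  rv <- if (measure == "count") df$n_fix_right else df$dwell_right_ms
  winner_left <- df$left_candidate_id == df$winner_id
  df$winner_value <- ifelse(winner_left, lv, rv)
  df$loser_value <- ifelse(winner_left, rv, lv)
  dplyr::summarise(
    dplyr::group_by(df, .data$race_id),
    loser_value = mean(.data$loser_value),
    winner_value = mean(.data$winner_value),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}
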