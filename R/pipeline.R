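# Pipeline orchestration: simulate a study to disk, analyze a data
# directory into a figure-ready report, and render the report. Each command
# writes a manifest recording its inputs, resolved configuration, seed, and
# output digests.

gp_manifest <- function(command, config = NULL, seed = NULL,
                        inputs = character(), outputs = character(),
                        extra = list(), started = NULL) {
  digest <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  c(list(
    command = command,
    tool_version = as.character(utils::packageVersion("gazepoll")),
    seed = seed,
    config = config,
    input_digests = digest(inputs),
    output_files = as.list(unname(outputs)),
    output_digests = digest(outputs),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
}

gp_write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' Simulate a study and write it to disk
#'
#' Writes the four data files (`fixations.csv`, `elections.csv`,
#' `landmarks.csv`, `layout.csv`), the optional `competence.csv` ratings, the
#' generating-truth sidecar `truth.json`, and a `manifest.json`. Output is
#' deterministic given the configuration seed.
#'
#' @param config A `gp_sim_config` from [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite existing outputs; without it, existing data files
#'   cause a refusal.
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config, out_dir, force = FALSE) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  cfg <- validate_sim_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, c("fixations.csv", "elections.csv",
                                "landmarks.csv", "layout.csv",
                                "competence.csv", "truth.json",
                                "manifest.json"))
  names(files) <- c("fixations", "elections", "landmarks", "layout",
                    "competence", "truth", "manifest")
  existing <- files[file.exists(files)]
  if (length(existing) > 0 && !force) {
    gp_config_error(sprintf(
      "run_simulate: output exists (%s); use force = TRUE to overwrite",
      basename(existing[1])
    ))
  }
  study <- simulate_study(cfg)
  write_fixation_table(study$fixations, files["fixations"])
  write_election_table(study$candidates, files["elections"])
  write_landmark_table(study$landmarks, files["landmarks"])
  write_layout_table(study$layouts, files["layout"])
  readr::write_csv(study$competence, files["competence"])
  gp_write_json(study$truth, files["truth"])
  manifest <- gp_manifest(
    "simulate",
    config = cfg[setdiff(names(cfg), "feature_loadings")],
    seed = cfg$seed,
    outputs = files[names(files) != "manifest"],
    extra = list(
      feature_loadings = study$config$feature_loadings,
      n_sessions = study$truth$n_sessions,
      n_session_blocks = study$truth$n_session_blocks,
      n_races = study$truth$n_races,
      n_candidates = study$truth$n_candidates
    ),
    started = started
  )
  gp_write_json(manifest, files["manifest"])
  invisible(manifest)
}

gp_subset_races <- function(races, candidates, subset) {
  keep <- races$race_id
  note <- character()
  for (key in names(subset)) {
    val <- subset[[key]]
    ids <- switch(
      key,
      office = races$race_id[races$office == val],
      gender_composition = {
        comp <- dplyr::summarise(
          dplyr::group_by(candidates, .data$race_id),
          n_f = sum(.data$gender == "F"), .groups = "drop"
        )
        want <- switch(val, male_male = 0L, mixed = 1L, female_female = 2L,
                       gp_config_error(sprintf(
                         "unknown gender_composition subset '%s'", val)))
        comp$race_id[comp$n_f == want]
      },
      incumbency = {
        inc <- dplyr::summarise(
          dplyr::group_by(candidates, .data$race_id),
          has = any(.data$incumbent == 1), .groups = "drop"
        )
        switch(val,
               with_incumbent = inc$race_id[inc$has],
               open = inc$race_id[!inc$has],
               gp_config_error(sprintf("unknown incumbency subset '%s'", val)))
      },
      party = candidates$race_id[candidates$winner == 1 &
                                   candidates$party == val],
      lean = races$race_id[
        classify_state_lean(races$ref_presidential_margin_pct) == val],
      gp_config_error(sprintf("unknown subset key '%s'", key))
    )
    keep <- intersect(keep, ids)
    note <- c(note, sprintf("%s=%s", key, val))
  }
  list(race_ids = keep, note = note)
}

#' Run the full analysis over a data directory
#'
#' Executes the stage graph: read and validate all tables, tally gaze per
#' trial, cast votes under every rule, compute morphometrics with rater
#' aggregation, and run the correlation, partial-correlation, joint-model,
#' age, and state-lean analyses. Writes `analysis_report.json`,
#' `predictions.csv`, `accuracy.json`, `metrics.csv`, `strata.csv`, and a
#' manifest. Validation failures abort with the violation report attached.
#'
#' @param data_dir Directory containing the data files written by
#'   [run_simulate()] (or real data in the same schemas); `competence.csv`
#'   is optional — competence analyses are skipped with a notice when absent.
#' @param out_dir Output directory.
#' @param rule Vote rule used for the prediction file and state-lean strata;
#'   accuracy is always reported for all three rules.
#' @param subset Optional named character vector restricting every analysis,
#'   e.g. `c(gender_composition = "male_male")`, keys `office`,
#'   `gender_composition` (`male_male`/`mixed`/`female_female`),
#'   `incumbency` (`with_incumbent`/`open`), `party` (winner's party), and
#'   `lean` (`blue`/`swing`/`red`).
#' @param force Overwrite existing outputs.
#' @return Invisibly, the analysis report list.
#' @export
run_analyze <- function(data_dir, out_dir, rule = "fixation_count",
                        subset = NULL, force = FALSE) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  rule <- match.arg(rule, vote_rules)
  inputs <- file.path(data_dir, c("fixations.csv", "elections.csv",
                                  "landmarks.csv", "layout.csv"))
  fixations <- read_fixation_table(inputs[1])
  elections <- read_election_table(inputs[2])
  landmarks <- read_landmark_table(inputs[3])
  layouts <- read_layout_table(inputs[4])
  competence_path <- file.path(data_dir, "competence.csv")
  competence <- NULL
  if (file.exists(competence_path)) {
    competence <- readr::read_csv(competence_path, show_col_types = FALSE,
                                  progress = FALSE)
  } else {
    message("competence.csv not found; skipping competence analyses")
  }

  violations <- validate_dataset(fixations, elections)
  if (nrow(violations) > 0) {
    print(violations)
    gp_validation_error(sprintf(
      "run_analyze: dataset failed validation with %d violation(s); first: %s",
      nrow(violations), violations$type[1]
    ))
  }

  subset_note <- character()
  if (!is.null(subset)) {
    sel <- gp_subset_races(elections$races, elections$candidates, subset)
    subset_note <- sel$note
    elections$races <- elections$races[
      elections$races$race_id %in% sel$race_ids, ]
    elections$candidates <- elections$candidates[
      elections$candidates$race_id %in% sel$race_ids, ]
    fixations <- fixations[fixations$race_id %in% sel$race_ids, ]
    landmarks <- landmarks[
      landmarks$candidate_id %in% elections$candidates$candidate_id, ]
    if (!is.null(competence)) {
      competence <- competence[
        competence$candidate_id %in% elections$candidates$candidate_id, ]
    }
    if (nrow(elections$races) == 0) {
      gp_config_error("run_analyze: subset filters matched no races")
    }
  }

  report <- build_analysis_report(fixations, layouts, elections, landmarks,
                                  competence, rule = rule,
                                  subset_note = subset_note)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, c("analysis_report.json", "predictions.csv",
                                "accuracy.json", "metrics.csv", "strata.csv",
                                "manifest.json"))
  names(files) <- c("report", "predictions", "accuracy", "metrics", "strata",
                    "manifest")
  existing <- files[file.exists(files)]
  if (length(existing) > 0 && !force) {
    gp_config_error(sprintf(
      "run_analyze: output exists (%s); use force = TRUE to overwrite",
      basename(existing[1])
    ))
  }

  gp_write_json(report, files["report"])

  tallies <- tally_trials(fixations, layouts)
  preds <- score_predictions(cast_votes(tallies, rule),
                             elections$candidates)
  readr::write_csv(
    tibble::tibble(
      session_id = preds$session_id, race_id = preds$race_id,
      rule = preds$rule,
      predicted_winner_id = ifelse(is.na(preds$predicted_winner_id), "",
                                   preds$predicted_winner_id),
      correct = preds$correct
    ),
    files["predictions"]
  )
  gp_write_json(report$accuracy, files["accuracy"])

  agg <- aggregate_raters(compute_metrics(landmarks))
  metrics_out <- agg$metrics
  metrics_out$concordance <- agg$concordance
  readr::write_csv(metrics_out, files["metrics"])

  strata <- report$state_lean$accuracy_by_lean$summary
  strata_tbl <- tibble::tibble(
    group = strata$group, n = strata$n, mean = strata$mean, sem = strata$sem,
    contrast = "anova+tukey",
    p = report$state_lean$accuracy_by_lean$p_value
  )
  readr::write_csv(strata_tbl, files["strata"])

  manifest <- gp_manifest(
    "analyze", seed = NULL,
    config = list(rule = rule, subset = as.list(subset)),
    inputs = c(inputs, if (!is.null(competence)) competence_path),
    outputs = files[names(files) != "manifest"],
    extra = list(
      n_races = nrow(elections$races),
      n_candidates = nrow(elections$candidates),
      n_sessions = length(unique(fixations$session_id)),
      subset = subset_note
    ),
    started = started
  )
  gp_write_json(manifest, files["manifest"])
  invisible(report)
}

#' Assemble the full analysis report
#'
#' The in-memory stage graph behind [run_analyze()]: every reported number is
#' produced by a named package operation, and each section carries the n it
#' was computed from.
#'
#' @param fixations,layouts,elections,landmarks Validated input tables.
#' @param competence Optional competence tibble (`candidate_id`,
#'   `competence`); `NULL` skips the competence sections.
#' @param rule Vote rule for the per-race and state-lean sections.
#' @param subset_note Character vector describing applied subset filters.
#' @return A nested list, JSON-serializable.
#' @export
build_analysis_report <- function(fixations, layouts, elections, landmarks,
                                  competence = NULL, rule = "fixation_count",
                                  subset_note = character()) {
  candidates <- elections$candidates
  races <- elections$races
  tallies <- tally_trials(fixations, layouts)

  comp_tbl <- dplyr::summarise(
    dplyr::group_by(candidates, .data$race_id),
    n_f = sum(.data$gender == "F"), .groups = "drop"
  )
  dataset <- list(
    operation = "dataset_composition",
    n_races = nrow(races),
    n_candidates = nrow(candidates),
    n_sessions = length(unique(fixations$session_id)),
    n_trials = nrow(tallies),
    n_mixed_gender = sum(comp_tbl$n_f == 1),
    n_male_male = sum(comp_tbl$n_f == 0),
    n_female_female = sum(comp_tbl$n_f == 2),
    pct_mixed_gender = 100 * mean(comp_tbl$n_f == 1),
    pct_male_male = 100 * mean(comp_tbl$n_f == 0),
    candidates_by_office = as.list(table(candidates$office)),
    subset = subset_note
  )

  accuracy <- lapply(vote_rules, function(r) {
    acc <- session_accuracy(cast_votes(tallies, r), candidates)
    summ <- if (nrow(acc) >= 2) {
      accuracy_summary(acc$accuracy)
    } else {
      # a single session: no across-session dispersion to test against
      list(mean = mean(acc$accuracy), sem = NA_real_,
           t_statistic = NA_real_, p_value = NA_real_,
           n_sessions = nrow(acc))
    }
    list(operation = "session_accuracy + accuracy_summary", rule = r,
         tie_policy = "half credit, ties kept in denominator",
         per_session = as.list(setNames(acc$accuracy, acc$session_id)),
         mean = summ$mean, sem = summ$sem, t_statistic = summ$t_statistic,
         p_value = summ$p_value, n_sessions = summ$n_sessions)
  })
  names(accuracy) <- vote_rules

  ogv <- outcome_gaze_values(tallies, candidates, measure = "count")
  bias_test <- paired_gaze_test(ogv$loser_value, ogv$winner_value)
  gaze_bias_outcome <- list(
    operation = "outcome_gaze_values + paired_gaze_test",
    measure = "mean fixations per presentation",
    mean_loser = mean(ogv$loser_value), mean_winner = mean(ogv$winner_value),
    sem_loser = sd(ogv$loser_value) / sqrt(nrow(ogv)),
    sem_winner = sd(ogv$winner_value) / sqrt(nrow(ogv)),
    mean_bias_index = mean(
      gaze_bias_index(ogv$loser_value, ogv$winner_value), na.rm = TRUE),
    p_value = bias_test$p_value, n_races = nrow(ogv),
    test = bias_test$method
  )

  profile <- candidate_fixation_profile(tallies)
  prof <- dplyr::inner_join(profile, candidates, by = "candidate_id")
  both_genders <- sum(prof$gender == "F") >= 2 && sum(prof$gender == "M") >= 2
  gaze_bias_gender <- NULL
  if (both_genders) {
    gender_test <- unpaired_gaze_test(
      prof$mean_fixations[prof$gender == "F"],
      prof$mean_fixations[prof$gender == "M"]
    )
    gaze_bias_gender <- list(
      operation = "candidate_fixation_profile + unpaired_gaze_test",
      mean_female = mean(prof$mean_fixations[prof$gender == "F"]),
      mean_male = mean(prof$mean_fixations[prof$gender == "M"]),
      n_female = sum(prof$gender == "F"), n_male = sum(prof$gender == "M"),
      p_value = gender_test$p_value, test = gender_test$method
    )
  }

  fix_vs_share <- correlate(prof$mean_fixations, prof$vote_share_norm)
  inc_races <- unique(candidates$race_id[candidates$incumbent == 1])
  prof_inc <- prof[prof$race_id %in% inc_races, ]
  fix_vs_share_inc <- if (nrow(prof_inc) >= 3 &&
                            sd(prof_inc$mean_fixations) > 0) {
    correlate(prof_inc$mean_fixations, prof_inc$vote_share_norm)
  } else NULL

  agg <- aggregate_raters(compute_metrics(landmarks))
  met <- dplyr::inner_join(agg$metrics, candidates, by = "candidate_id")

  morpho_gender <- if (both_genders) {
    group_contrast(agg$metrics, candidates, "gender")
  } else NULL
  morpho_outcome <- suppressWarnings(
    group_contrast(agg$metrics, candidates, "outcome")
  )

  jaw_overall <- correlate(met$jaw_prominence, met$vote_share_norm)
  jaw_by_office <- lapply(split(met, met$office), function(d) {
    if (nrow(d) >= 3 && sd(d$jaw_prominence) > 0) {
      correlate(d$jaw_prominence, d$vote_share_norm)
    } else NULL
  })

  gprof <- dplyr::inner_join(profile, met, by = "candidate_id")
  gaze_vs_facial <- lapply(c(jaw_prominence = "jaw_prominence",
                             fwhr = "fwhr", lfp = "lfp"), function(f) {
    correlate(gprof$mean_fixations, gprof[[f]])
  })

  competence_section <- NULL
  if (!is.null(competence)) {
    cm <- dplyr::inner_join(met, competence, by = "candidate_id")
    competence_section <- list(
      operation = "correlate + partial_correlate + fit_joint_model",
      jaw_vs_competence = correlate(cm$jaw_prominence, cm$competence),
      partial_competence_vs_share_given_jaw = partial_correlate(
        cm$competence, cm$vote_share_norm, cm$jaw_prominence),
      partial_jaw_vs_share_given_competence = partial_correlate(
        cm$jaw_prominence, cm$vote_share_norm, cm$competence),
      joint_model = fit_joint_model(cm$vote_share_norm, cm$jaw_prominence,
                                    cm$competence)
    )
  }

  met$age <- candidate_age(met$birth_year, met$year)
  prof_age <- dplyr::inner_join(profile, met[, c("candidate_id", "age")],
                                by = "candidate_id")
  age_section <- list(
    operation = "candidate_age + correlate",
    age_vs_vote_share = correlate(met$age, met$vote_share_norm),
    age_vs_gaze = correlate(prof_age$age, prof_age$mean_fixations)
  )

  lean <- classify_state_lean(races$ref_presidential_margin_pct)
  lean_by_race <- setNames(lean, races$race_id)
  preds <- score_predictions(cast_votes(tallies, rule), candidates)
  preds$score <- ifelse(is.na(preds$correct), 0.5, preds$correct)
  race_score <- dplyr::summarise(
    dplyr::group_by(preds, .data$race_id),
    score = mean(.data$score), .groups = "drop"
  )
  race_score$lean <- lean_by_race[race_score$race_id]
  acc_by_lean <- stratified_summary(race_score$score, race_score$lean)
  ogv$lean <- lean_by_race[ogv$race_id]
  bias_by_lean <- stratified_summary(
    ogv$loser_value - ogv$winner_value, ogv$lean
  )
  state_lean <- list(
    operation = "classify_state_lean + stratified_summary",
    rule = rule,
    n_by_lean = as.list(table(lean)),
    accuracy_by_lean = acc_by_lean,
    loser_bias_by_lean = bias_by_lean
  )

  list(
    dataset = dataset,
    accuracy = accuracy,
    gaze_bias_outcome = gaze_bias_outcome,
    gaze_bias_gender = gaze_bias_gender,
    fixations_vs_vote_share = fix_vs_share,
    fixations_vs_vote_share_incumbent_races = fix_vs_share_inc,
    morphometrics = list(
      operation = "compute_metrics + aggregate_raters + group_contrast",
      n_raters = length(unique(landmarks$rater_id)),
      concordance = agg$concordance,
      by_gender = if (!is.null(morpho_gender)) morpho_gender$table,
      by_outcome = morpho_outcome$table,
      winner_jaw_pct_diff = morpho_outcome$jaw_pct_diff
    ),
    jaw_vs_vote_share = c(list(overall = jaw_overall), jaw_by_office),
    gaze_vs_facial = gaze_vs_facial,
    competence = competence_section,
    age = age_section,
    state_lean = state_lean
  )
}

#' Render an analysis report
#'
#' @param analysis_dir Directory containing `analysis_report.json`.
#' @param format `"json"` (returns the parsed report) or `"markdown"`
#'   (writes and returns `report.md` with the headline numbers).
#' @return The parsed report (json) or the path to the rendered file
#'   (markdown).
#' @export
run_report <- function(analysis_dir, format = c("json", "markdown")) {
  format <- match.arg(format)
  path <- file.path(analysis_dir, "analysis_report.json")
  if (!file.exists(path)) {
    gp_config_error(sprintf("run_report: %s not found", path))
  }
  report <- jsonlite::read_json(path)
  if (format == "json") return(report)
  fmt_p <- function(p) {
    if (is.null(p)) "NA" else formatC(as.numeric(p), format = "g", digits = 3)
  }
  acc <- report$accuracy$fixation_count
  lines <- c(
    "# Gaze-bias election analysis",
    "",
    sprintf("- races: %s, candidates: %s, sessions: %s",
            report$dataset$n_races, report$dataset$n_candidates,
            report$dataset$n_sessions),
    sprintf("- accuracy (fixation count rule): %.1f%% +/- %.1f%% (p = %s, n = %s sessions)",
            100 * acc$mean, 100 * acc$sem, fmt_p(acc$p_value),
            acc$n_sessions),
    sprintf("- loser-directed gaze bias: %.2f vs %.2f fixations (p = %s)",
            report$gaze_bias_outcome$mean_loser,
            report$gaze_bias_outcome$mean_winner,
            fmt_p(report$gaze_bias_outcome$p_value)),
    sprintf("- jaw prominence vs vote share: r = %.3f (p = %s, n = %s)",
            as.numeric(report$jaw_vs_vote_share$overall$estimate),
            fmt_p(report$jaw_vs_vote_share$overall$p_value),
            report$jaw_vs_vote_share$overall$n)
  )
  if (!is.null(report$competence)) {
    lines <- c(lines, sprintf(
      "- joint model (jaw + competence): R^2 = %.3f (n = %s)",
      as.numeric(report$competence$joint_model$r_squared),
      report$competence$joint_model$n
    ))
  }
  out <- file.path(analysis_dir, "report.md")
  writeLines(lines, out)
  out
}
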