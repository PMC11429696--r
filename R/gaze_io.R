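# Reading, validation, and structuring of fixation-level gaze data, election
# metadata, stimulus layouts, and facial landmark tables.
#
# All interchange files are comma-separated UTF-8 text with one header row.
# Pixel coordinates are 0-based with the origin at the top-left corner of the
# screen; stimulus boxes are half-open on their max edges, so a fixation at
# exactly x_max falls outside the box. Times are integer milliseconds from
# stimulus onset.

gp_fixation_cols <- c(
  "session_id", "monkey_id", "office", "trial_index", "race_id",
  "left_candidate_id", "right_candidate_id", "onset_ms", "offset_ms",
  "x_px", "y_px"
)

gp_election_cols <- c(
  "race_id", "office", "year", "state", "candidate_id", "name", "gender",
  "birth_year", "party", "incumbent", "vote_share_pct", "winner",
  "ref_presidential_margin_pct", "smile", "bald", "facial_hair", "glasses"
)

gp_landmark_points <- c(
  "pupil_left", "pupil_right", "zygion_left", "zygion_right",
  "gonion_left", "gonion_right", "face_top", "lower_face_top", "chin_bottom"
)

gp_landmark_cols <- c(
  "candidate_id", "rater_id",
  paste0(rep(gp_landmark_points, each = 2), c("_x", "_y"))
)

gp_layout_cols <- c(
  "session_id", "screen_w", "screen_h",
  "left_x_min", "left_y_min", "left_x_max", "left_y_max",
  "right_x_min", "right_y_min", "right_x_max", "right_y_max"
)

gp_check_columns <- function(df, expected, what) {
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing) > 0) {
    gp_schema_error(sprintf(
      "%s: missing column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  if (length(extra) > 0) {
    gp_schema_error(sprintf(
      "%s: unexpected column(s): %s", what, paste(extra, collapse = ", ")
    ))
  }
  invisible(df)
}

gp_check_numeric <- function(df, cols, what) {
  for (col in cols) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad) > 0) {
        gp_parse_error(sprintf(
          "%s: column '%s' is not numeric at data row %d (value '%s')",
          what, col, bad[1], v[bad[1]]
        ))
      }
      df[[col]] <- parsed
    }
    if (any(!is.finite(df[[col]]))) {
      bad <- which(!is.finite(df[[col]]))[1]
      gp_parse_error(sprintf(
        "%s: column '%s' has a missing or non-finite value at data row %d",
        what, col, bad
      ))
    }
  }
  df
}

gp_read_csv <- function(path, what) {
  if (!file.exists(path)) {
    gp_config_error(sprintf("%s: file not found: %s", what, path))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read a fixation-event table
#'
#' Reads fixation-level gaze events for two-image candidate presentations.
#' Each row is one fixation tagged with its session, trial, race, and the
#' candidate shown on each side. Fixations are validated (positive duration,
#' finite coordinates), sorted by onset within trial, truncated at the
#' stimulus offset, and dropped entirely when they start after it.
#'
#' @param path Path to a `fixations.csv` file with columns
#'   `session_id, monkey_id, office, trial_index, race_id, left_candidate_id,
#'   right_candidate_id, onset_ms, offset_ms, x_px, y_px`.
#' @param stimulus_duration_ms Presentation window in milliseconds; fixations
#'   straddling this offset are truncated, later ones dropped. Default 2500.
#' @return A tibble of validated fixation events, one row per fixation,
#'   ordered by session, trial, and onset.
#' @export
read_fixation_table <- function(path, stimulus_duration_ms = 2500) {
  df <- gp_read_csv(path, "fixations")
  gp_check_columns(df, gp_fixation_cols, "fixations")
  df <- gp_check_numeric(
    df, c("trial_index", "onset_ms", "offset_ms", "x_px", "y_px"), "fixations"
  )
  validate_fixations(df, stimulus_duration_ms)
}

#' Validate and normalize an in-memory fixation table
#'
#' Applies the same invariants as [read_fixation_table()]: positive duration,
#' truncation at the stimulus offset, onset ordering within trial (ties kept
#' in input order with a warning), and consistent trial metadata.
#'
#' @param df A data frame with the fixation schema columns.
#' @param stimulus_duration_ms Presentation window in milliseconds.
#' @return A tibble of validated fixation events.
#' @export
validate_fixations <- function(df, stimulus_duration_ms = 2500) {
  df <- tibble::as_tibble(df)
  bad <- which(df$offset_ms <= df$onset_ms)
  if (length(bad) > 0) {
    gp_validation_error(sprintf(
      "fixations: offset_ms <= onset_ms at data row %d (onset %s, offset %s)",
      bad[1], df$onset_ms[bad[1]], df$offset_ms[bad[1]]
    ))
  }
  if (any(df$trial_index < 0)) {
    gp_validation_error("fixations: trial_index must be >= 0")
  }
  same <- df$left_candidate_id == df$right_candidate_id
  if (any(same)) {
    gp_validation_error(sprintf(
      "fixations: left and right candidate identical at data row %d",
      which(same)[1]
    ))
  }
  # Presentation-window policy: truncate straddling fixations, drop fixations
  # entirely after stimulus offset.
  df <- df[df$onset_ms < stimulus_duration_ms, , drop = FALSE]
  df$offset_ms <- pmin(df$offset_ms, stimulus_duration_ms)

  df <- dplyr::arrange(df, .data$session_id, .data$trial_index, .data$onset_ms)
  dup_onsets <- dplyr::summarise(
    dplyr::group_by(df, .data$session_id, .data$trial_index),
    dup = anyDuplicated(.data$onset_ms) > 0, .groups = "drop"
  )
  if (any(dup_onsets$dup)) {
    warning("fixations: tied onset times within a trial; file order kept",
            call. = FALSE)
  }
  df
}

#' Read an election metadata table
#'
#' Reads the roster of races and candidates: gender, birth year, party,
#' incumbency, vote share, winner flag, office, state, and the reference
#' presidential margin used to classify state lean. Enforces exactly two
#' candidates per race, exactly one winner, and that the winner's vote share
#' strictly exceeds the loser's. Vote shares are two-party normalized at
#' ingestion (each candidate's share divided by the pair sum, times 100) into
#' a `vote_share_norm` column; the raw column is kept.
#'
#' @param path Path to an `elections.csv` file.
#' @return A list with `races` (one row per race) and `candidates`
#'   (one row per candidate) tibbles.
#' @export
read_election_table <- function(path) {
  df <- gp_read_csv(path, "elections")
  gp_check_columns(df, gp_election_cols, "elections")
  df <- gp_check_numeric(
    df,
    c("year", "birth_year", "incumbent", "vote_share_pct", "winner",
      "ref_presidential_margin_pct", "smile", "bald", "facial_hair",
      "glasses"),
    "elections"
  )
  validate_elections(df)
}

#' Validate an in-memory election table
#'
#' @param df A data frame with the election schema columns.
#' @return A list with `races` and `candidates` tibbles, as in
#'   [read_election_table()].
#' @export
validate_elections <- function(df) {
  df <- tibble::as_tibble(df)
  if (any(df$vote_share_pct < 0 | df$vote_share_pct > 100)) {
    gp_validation_error("elections: vote_share_pct outside [0, 100]")
  }
  if (!all(df$gender %in% c("F", "M"))) {
    gp_validation_error("elections: gender must be 'F' or 'M'")
  }
  if (!all(df$winner %in% c(0, 1))) {
    gp_validation_error("elections: winner must be 0 or 1")
  }
  per_race <- dplyr::summarise(
    dplyr::group_by(df, .data$race_id),
    n_candidates = dplyr::n(),
    n_winners = sum(.data$winner),
    .groups = "drop"
  )
  bad_n <- per_race$race_id[per_race$n_candidates != 2]
  if (length(bad_n) > 0) {
    gp_validation_error(sprintf(
      "elections: race '%s' has %d candidate rows (expected 2)",
      bad_n[1], per_race$n_candidates[per_race$race_id == bad_n[1]]
    ))
  }
  bad_w <- per_race$race_id[per_race$n_winners != 1]
  if (length(bad_w) > 0) {
    gp_validation_error(sprintf(
      "elections: race '%s' has %d winners (expected exactly 1)",
      bad_w[1], per_race$n_winners[per_race$race_id == bad_w[1]]
    ))
  }
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$race_id),
    vote_share_norm = 100 * .data$vote_share_pct / sum(.data$vote_share_pct)
  )
  df <- dplyr::ungroup(df)
  mismatch <- dplyr::summarise(
    dplyr::group_by(df, .data$race_id),
    ok = .data$vote_share_norm[.data$winner == 1] >
      .data$vote_share_norm[.data$winner == 0],
    .groups = "drop"
  )
  if (!all(mismatch$ok)) {
    gp_validation_error(sprintf(
      "elections: winner's vote share not greater than loser's in race '%s'",
      mismatch$race_id[!mismatch$ok][1]
    ))
  }
  races <- dplyr::distinct(
    df, .data$race_id, .data$office, .data$year, .data$state,
    .data$ref_presidential_margin_pct
  )
  if (anyDuplicated(races$race_id) > 0) {
    gp_validation_error(
      "elections: inconsistent race-level fields across a race's candidates"
    )
  }
  list(races = races, candidates = df)
}

#' Read a facial landmark table
#'
#' One row per candidate per rater, with x/y pixel coordinates of the nine
#' named landmarks: left/right pupils, left/right zygions (cheekbone
#' extrema), left/right gonions (jaw extrema), and the midline face top,
#' lower-face top, and chin bottom.
#'
#' @param path Path to a `landmarks.csv` file.
#' @return A tibble of landmark rows; bilateral ordering (left x < right x)
#'   and vertical ordering of midline points are enforced.
#' @export
read_landmark_table <- function(path) {
  df <- gp_read_csv(path, "landmarks")
  gp_check_columns(df, gp_landmark_cols, "landmarks")
  df <- gp_check_numeric(df, setdiff(gp_landmark_cols,
                                     c("candidate_id", "rater_id")),
                         "landmarks")
  validate_landmarks(df)
}

#' Validate an in-memory landmark table
#'
#' @param df A data frame with the landmark schema columns.
#' @return The validated tibble.
#' @export
validate_landmarks <- function(df) {
  df <- tibble::as_tibble(df)
  for (pair in c("pupil", "zygion", "gonion")) {
    lx <- df[[paste0(pair, "_left_x")]]
    rx <- df[[paste0(pair, "_right_x")]]
    if (any(lx >= rx)) {
      gp_validation_error(sprintf(
        "landmarks: %s_left_x must be < %s_right_x (data row %d)",
        pair, pair, which(lx >= rx)[1]
      ))
    }
  }
  top <- df$face_top_y
  mid <- df$lower_face_top_y
  bot <- df$chin_bottom_y
  if (any(!(top < mid & mid < bot))) {
    gp_validation_error(
      "landmarks: midline points must satisfy face_top above lower_face_top above chin_bottom"
    )
  }
  df
}

#' Read a stimulus layout table
#'
#' One row per session giving screen size and the left/right candidate-image
#' rectangles (0-based pixels, half-open on max edges).
#'
#' @param path Path to a `layout.csv` file.
#' @return A tibble of validated layouts.
#' @export
read_layout_table <- function(path) {
  df <- gp_read_csv(path, "layout")
  gp_check_columns(df, gp_layout_cols, "layout")
  df <- gp_check_numeric(df, setdiff(gp_layout_cols, "session_id"), "layout")
  for (i in seq_len(nrow(df))) {
    stimulus_layout(
      screen_w = df$screen_w[i], screen_h = df$screen_h[i],
      left_box = c(df$left_x_min[i], df$left_y_min[i],
                   df$left_x_max[i], df$left_y_max[i]),
      right_box = c(df$right_x_min[i], df$right_y_min[i],
                    df$right_x_max[i], df$right_y_max[i])
    )
  }
  tibble::as_tibble(df)
}

#' Construct and validate a stimulus layout
#'
#' @param screen_w,screen_h Screen size in pixels.
#' @param left_box,right_box Numeric length-4 vectors
#'   `(x_min, y_min, x_max, y_max)`, 0-based, half-open on the max edges.
#' @return A `gp_layout` list. Boxes must lie within the screen, must not
#'   overlap, and the left box must end at or before the right box starts.
#' @export
stimulus_layout <- function(screen_w, screen_h, left_box, right_box) {
  for (b in list(left = left_box, right = right_box)) {
    if (length(b) != 4 || b[1] >= b[3] || b[2] >= b[4]) {
      gp_validation_error("layout: box must satisfy x_min < x_max and y_min < y_max")
    }
    if (b[1] < 0 || b[2] < 0 || b[3] > screen_w || b[4] > screen_h) {
      gp_validation_error("layout: box extends beyond the screen")
    }
  }
  if (left_box[3] > right_box[1]) {
    gp_validation_error("layout: left box must end at or before the right box starts")
  }
  structure(
    list(screen_w = screen_w, screen_h = screen_h,
         left_box = as.numeric(left_box), right_box = as.numeric(right_box)),
    class = "gp_layout"
  )
}

gp_layout_from_row <- function(row) {
  stimulus_layout(
    screen_w = row$screen_w, screen_h = row$screen_h,
    left_box = c(row$left_x_min, row$left_y_min,
                 row$left_x_max, row$left_y_max),
    right_box = c(row$right_x_min, row$right_y_min,
                  row$right_x_max, row$right_y_max)
  )
}

gp_in_box <- function(x, y, box) {
  x >= box[1] & x < box[3] & y >= box[2] & y < box[4]
}

#' Assign the fixations of one trial to candidate regions
#'
#' A fixation counts for a side iff it falls inside that side's box under the
#' half-open convention (`x_min <= x < x_max`, `y_min <= y < y_max`).
#' Fixations outside both boxes are ignored. `first_fixated` marks the side
#' of the earliest in-box fixation.
#'
#' @param fixations A data frame of fixation events for a single trial
#'   (columns `onset_ms`, `offset_ms`, `x_px`, `y_px`).
#' @param layout A `gp_layout` from [stimulus_layout()].
#' @return A list with per-side fixation counts `n_fix`, summed dwell times
#'   `dwell_ms`, logical `first_fixated`, and the count of ignored events.
#' @export
assign_fixations <- function(fixations, layout) {
  stopifnot(inherits(layout, "gp_layout"))
  fx <- fixations[order(fixations$onset_ms), , drop = FALSE]
  in_left <- gp_in_box(fx$x_px, fx$y_px, layout$left_box)
  in_right <- gp_in_box(fx$x_px, fx$y_px, layout$right_box)
  dur <- fx$offset_ms - fx$onset_ms
  side <- rep(NA_character_, nrow(fx))
  side[in_left] <- "left"
  side[in_right] <- "right"
  first_side <- if (any(!is.na(side))) side[!is.na(side)][1] else NA_character_
  list(
    n_fix = c(left = sum(in_left), right = sum(in_right)),
    dwell_ms = c(left = sum(dur[in_left]), right = sum(dur[in_right])),
    first_fixated = c(left = identical(first_side, "left"),
                      right = identical(first_side, "right")),
    n_ignored = sum(is.na(side))
  )
}

#' Tally gaze for every trial in a fixation table
#'
#' Vectorized region assignment over a whole dataset: joins each fixation to
#' its session's layout and reduces to one row per trial with per-side
#' fixation counts, dwell times, and the first-fixated side.
#'
#' @param fixations A validated fixation tibble ([read_fixation_table()]).
#' @param layouts A layout tibble ([read_layout_table()]); matched to
#'   fixations by `session_id`.
#' @return A tibble with one row per trial: trial identifiers, candidate ids,
#'   `n_fix_left`, `n_fix_right`, `dwell_left_ms`, `dwell_right_ms`,
#'   `first_side` (`"left"`, `"right"`, or `NA`), and `n_ignored`. Trials
#'   present in the input always appear, even with zero in-box fixations.
#' @export
tally_trials <- function(fixations, layouts) {
  missing_layout <- setdiff(unique(fixations$session_id), layouts$session_id)
  if (length(missing_layout) > 0) {
    gp_validation_error(sprintf(
      "layout: no layout row for session '%s'", missing_layout[1]
    ))
  }
  df <- dplyr::left_join(fixations, layouts, by = "session_id")
  df$in_left <- df$x_px >= df$left_x_min & df$x_px < df$left_x_max &
    df$y_px >= df$left_y_min & df$y_px < df$left_y_max
  df$in_right <- df$x_px >= df$right_x_min & df$x_px < df$right_x_max &
    df$y_px >= df$right_y_min & df$y_px < df$right_y_max
  df$dur <- df$offset_ms - df$onset_ms
  df$side <- dplyr::case_when(df$in_left ~ "left", df$in_right ~ "right",
                              TRUE ~ NA_character_)
  df <- dplyr::arrange(df, .data$session_id, .data$trial_index, .data$onset_ms)
  dplyr::summarise(
    dplyr::group_by(df, .data$session_id, .data$monkey_id, .data$office,
                    .data$trial_index, .data$race_id,
                    .data$left_candidate_id, .data$right_candidate_id),
    n_fix_left = sum(.data$in_left),
    n_fix_right = sum(.data$in_right),
    dwell_left_ms = sum(.data$dur[.data$in_left]),
    dwell_right_ms = sum(.data$dur[.data$in_right]),
    first_side = if (any(!is.na(.data$side))) {
      .data$side[!is.na(.data$side)][1]
    } else NA_character_,
    n_ignored = sum(is.na(.data$side)),
    .groups = "drop"
  )
}

#' Cross-validate a gaze dataset against election metadata
#'
#' Reports structural violations rather than stopping: duplicate races within
#' a session, trials referencing unknown races or candidates, and trial
#' candidate pairs that do not match the race's candidates.
#'
#' @param fixations A validated fixation tibble.
#' @param elections The list returned by [read_election_table()].
#' @return A tibble of violations (`type`, `session_id`, `race_id`,
#'   `detail`); zero rows iff the dataset is clean.
#' @export
validate_dataset <- function(fixations, elections) {
  candidates <- elections$candidates
  races <- elections$races
  trials <- dplyr::distinct(
    fixations, .data$session_id, .data$trial_index, .data$race_id,
    .data$left_candidate_id, .data$right_candidate_id
  )
  out <- list()

  dup <- dplyr::summarise(
    dplyr::group_by(trials, .data$session_id, .data$race_id),
    n = dplyr::n(), .groups = "drop"
  )
  dup <- dup[dup$n > 1, , drop = FALSE]
  if (nrow(dup) > 0) {
    out[[length(out) + 1]] <- tibble::tibble(
      type = "duplicate race in session",
      session_id = dup$session_id, race_id = dup$race_id,
      detail = sprintf("race shown %d times", dup$n)
    )
  }

  unk_race <- trials[!trials$race_id %in% races$race_id, , drop = FALSE]
  if (nrow(unk_race) > 0) {
    out[[length(out) + 1]] <- tibble::tibble(
      type = "unknown race", session_id = unk_race$session_id,
      race_id = unk_race$race_id, detail = "race_id not in election table"
    )
  }

  known_cand <- candidates$candidate_id
  unk_cand <- trials[!(trials$left_candidate_id %in% known_cand) |
                       !(trials$right_candidate_id %in% known_cand), ,
                     drop = FALSE]
  if (nrow(unk_cand) > 0) {
    out[[length(out) + 1]] <- tibble::tibble(
      type = "unknown candidate", session_id = unk_cand$session_id,
      race_id = unk_cand$race_id,
      detail = "candidate_id not in election table"
    )
  }

  ok_trials <- trials[trials$race_id %in% races$race_id &
                        trials$left_candidate_id %in% known_cand &
                        trials$right_candidate_id %in% known_cand, ,
                      drop = FALSE]
  if (nrow(ok_trials) > 0) {
    race_pairs <- dplyr::summarise(
      dplyr::group_by(candidates, .data$race_id),
      pair = paste(sort(.data$candidate_id), collapse = "|"),
      .groups = "drop"
    )
    ok_trials$pair <- vapply(
      seq_len(nrow(ok_trials)),
      function(i) paste(sort(c(ok_trials$left_candidate_id[i],
                               ok_trials$right_candidate_id[i])),
                        collapse = "|"),
      character(1)
    )
    joined <- dplyr::left_join(ok_trials, race_pairs, by = "race_id",
                               suffix = c("_trial", "_race"))
    bad <- joined[joined$pair_trial != joined$pair_race, , drop = FALSE]
    if (nrow(bad) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        type = "candidate pair mismatch", session_id = bad$session_id,
        race_id = bad$race_id,
        detail = "trial candidates do not match the race's candidates"
      )
    }
  }

  if (length(out) == 0) {
    tibble::tibble(type = character(), session_id = character(),
                   race_id = character(), detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Write gaze-pipeline tables to CSV
#'
#' Thin wrappers around [readr::write_csv()] so that simulated or validated
#' tables round-trip through the documented file schemas.
#'
#' @param df The table to write.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_fixation_table <- function(df, path) {
  readr::write_csv(df[gp_fixation_cols], path)
  invisible(df)
}

#' @rdname write_fixation_table
#' @export
write_election_table <- function(df, path) {
  readr::write_csv(df[gp_election_cols], path)
  invisible(df)
}

#' @rdname write_fixation_table
#' @export
write_landmark_table <- function(df, path) {
  readr::write_csv(df[gp_landmark_cols], path)
  invisible(df)
}

#' @rdname write_fixation_table
#' @export
write_layout_table <- function(df, path) {
  readr::write_csv(df[gp_layout_cols], path)
  invisible(df)
}
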