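# Landmark-based facial masculinity metrics: normalized widths and heights,
# jaw prominence, facial width-to-height ratio (FWHR), and lower face
# prominence (LFP), with multi-rater aggregation and group contrasts.
#
# Landmark semantics (fixed here so data producers can match): zygion = the
# widest point of the cheekbone, gonion = the widest point of the jaw,
# face_top = mid-brow midline point, lower_face_top = upper-lip midline
# point, chin_bottom = chin midline point. All distances are Euclidean
# point-to-point (robust to slight head tilt), and every width/height is
# normalized by the inter-pupillary distance (IPD), which makes the metrics
# invariant to image scale.

gp_metric_features <- c(
  "jaw_width_norm", "cheekbone_width_norm", "face_height_norm",
  "lower_face_height_norm", "jaw_prominence", "fwhr", "lfp"
)

gp_dist <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

#' Compute facial metrics from landmark coordinates
#'
#' From the nine named pixel landmarks computes inter-pupillary distance
#' (IPD), the four IPD-normalized measurements (jaw width, cheekbone width,
#' face height, lower face height), and three ratios:
#' * jaw prominence = jaw width / cheekbone width,
#' * FWHR = cheekbone width / face height,
#' * LFP = lower face height / face height.
#'
#' Widths are Euclidean distances between bilateral landmark pairs; face
#' height runs from `face_top` to `chin_bottom` and lower face height from
#' `lower_face_top` to `chin_bottom`. All ratios are invariant under
#' translation, uniform scaling, and mirroring of the landmark set.
#'
#' @param landmarks A data frame in the landmark schema
#'   ([read_landmark_table()]); any number of rows.
#' @return A tibble with `candidate_id`, `rater_id` (when present), `ipd_px`,
#'   and the seven metric columns.
#' @export
compute_metrics <- function(landmarks) {
  lm <- validate_landmarks(landmarks)
  ipd <- gp_dist(lm$pupil_left_x, lm$pupil_left_y,
                 lm$pupil_right_x, lm$pupil_right_y)
  jaw <- gp_dist(lm$gonion_left_x, lm$gonion_left_y,
                 lm$gonion_right_x, lm$gonion_right_y)
  cheek <- gp_dist(lm$zygion_left_x, lm$zygion_left_y,
                   lm$zygion_right_x, lm$zygion_right_y)
  face_h <- gp_dist(lm$face_top_x, lm$face_top_y,
                    lm$chin_bottom_x, lm$chin_bottom_y)
  lower_h <- gp_dist(lm$lower_face_top_x, lm$lower_face_top_y,
                     lm$chin_bottom_x, lm$chin_bottom_y)
  if (any(ipd <= 0)) gp_degenerate_error("metrics: inter-pupillary distance <= 0")
  if (any(cheek <= 0)) gp_degenerate_error("metrics: cheekbone width <= 0")
  if (any(face_h <= 0)) gp_degenerate_error("metrics: face height <= 0")
  out <- tibble::tibble(
    ipd_px = ipd,
    jaw_width_norm = jaw / ipd,
    cheekbone_width_norm = cheek / ipd,
    face_height_norm = face_h / ipd,
    lower_face_height_norm = lower_h / ipd,
    jaw_prominence = jaw / cheek,
    fwhr = cheek / face_h,
    lfp = lower_h / face_h
  )
  id_cols <- intersect(c("candidate_id", "rater_id"), names(lm))
  if (length(id_cols) > 0) {
    out <- dplyr::bind_cols(lm[id_cols], out)
  }
  out
}

#' Aggregate facial metrics across raters
#'
#' Per-candidate arithmetic mean of each metric across raters (rater
#' averaging happens at the metric level, not the landmark level), plus a
#' concordance measure: for every feature and every rater pair, the Pearson
#' correlation across candidates, averaged over rater pairs and then over
#' features. Concordance is `NA` with fewer than 2 raters or fewer than 3
#' candidates. All raters must have measured the same candidate set.
#'
#' @param rater_metrics A metrics tibble ([compute_metrics()]) with
#'   `candidate_id` and `rater_id` columns.
#' @return A list: `metrics` (one row per candidate, per-feature means plus
#'   `n_raters`), `concordance` (scalar), and `concordance_by_feature`.
#' @export
aggregate_raters <- function(rater_metrics) {
  raters <- unique(rater_metrics$rater_id)
  sets <- lapply(raters, function(r) {
    sort(rater_metrics$candidate_id[rater_metrics$rater_id == r])
  })
  if (length(raters) > 1) {
    for (i in seq_along(sets)[-1]) {
      if (!identical(sets[[i]], sets[[1]])) {
        gp_validation_error(sprintf(
          "aggregate_raters: rater '%s' measured a different candidate set than rater '%s'",
          raters[i], raters[1]
        ))
      }
    }
  }
  agg <- dplyr::summarise(
    dplyr::group_by(rater_metrics, .data$candidate_id),
    dplyr::across(dplyr::all_of(c("ipd_px", gp_metric_features)), mean),
    n_raters = dplyr::n(),
    .groups = "drop"
  )
  n_candidates <- length(sets[[1]])
  if (length(raters) < 2 || n_candidates < 3) {
    return(list(metrics = agg, concordance = NA_real_,
                concordance_by_feature = setNames(
                  rep(NA_real_, length(gp_metric_features)),
                  gp_metric_features)))
  }
  wide <- lapply(raters, function(r) {
    df <- rater_metrics[rater_metrics$rater_id == r, , drop = FALSE]
    df[order(df$candidate_id), , drop = FALSE]
  })
  pairs <- utils::combn(length(raters), 2, simplify = FALSE)
  by_feature <- vapply(gp_metric_features, function(f) {
    mean(vapply(pairs, function(p) {
      cor(wide[[p[1]]][[f]], wide[[p[2]]][[f]])
    }, numeric(1)))
  }, numeric(1))
  list(metrics = agg, concordance = mean(by_feature),
       concordance_by_feature = by_feature)
}

#' Contrast facial metrics by gender or election outcome
#'
#' Per feature: group means with standard errors, and a two-sided test —
#' unpaired rank sum for gender, signed rank pairing winner and loser within
#' each race for outcome. For jaw prominence under the outcome grouping the
#' result also carries the mean within-race percent difference
#' `100 * (J_winner - J_loser) / J_loser`.
#'
#' @param metrics Aggregated per-candidate metrics ([aggregate_raters()]).
#' @param candidates Candidate tibble with `candidate_id`, `race_id`,
#'   `gender`, `winner`.
#' @param grouping `"gender"` or `"outcome"`.
#' @return A list: `table` (feature, per-group mean/sem/n, `p_value`) and,
#'   for the outcome grouping, `jaw_pct_diff`.
#' @export
group_contrast <- function(metrics, candidates,
                           grouping = c("gender", "outcome")) {
  grouping <- match.arg(grouping)
  df <- dplyr::inner_join(
    metrics,
    candidates[, c("candidate_id", "race_id", "gender", "winner")],
    by = "candidate_id"
  )
  if (grouping == "gender") {
    rows <- lapply(gp_metric_features, function(f) {
      f_vals <- df[[f]][df$gender == "F"]
      m_vals <- df[[f]][df$gender == "M"]
      if (length(f_vals) < 2 || length(m_vals) < 2) {
        gp_validation_error("group_contrast: need >= 2 observations per group")
      }
      ht <- unpaired_gaze_test(f_vals, m_vals)
      tibble::tibble(
        feature = f,
        mean_f = mean(f_vals), sem_f = sd(f_vals) / sqrt(length(f_vals)),
        n_f = length(f_vals),
        mean_m = mean(m_vals), sem_m = sd(m_vals) / sqrt(length(m_vals)),
        n_m = length(m_vals),
        p_value = ht$p_value
      )
    })
    return(list(table = dplyr::bind_rows(rows)))
  }
  # outcome: pair winner and loser within race
  complete <- dplyr::summarise(
    dplyr::group_by(df, .data$race_id),
    ok = dplyr::n() == 2 && sum(.data$winner) == 1, .groups = "drop"
  )
  dropped <- complete$race_id[!complete$ok]
  if (length(dropped) > 0) {
    warning(sprintf(
      "group_contrast: %d race(s) missing one candidate's metrics; excluded",
      length(dropped)
    ), call. = FALSE)
    df <- df[!df$race_id %in% dropped, , drop = FALSE]
  }
  w <- df[df$winner == 1, , drop = FALSE]
  l <- df[df$winner == 0, , drop = FALSE]
  w <- w[order(w$race_id), , drop = FALSE]
  l <- l[order(l$race_id), , drop = FALSE]
  if (nrow(w) < 2) {
    gp_validation_error("group_contrast: need >= 2 complete races")
  }
  rows <- lapply(gp_metric_features, function(f) {
    ht <- paired_gaze_test(w[[f]], l[[f]])
    tibble::tibble(
      feature = f,
      mean_winner = mean(w[[f]]), sem_winner = sd(w[[f]]) / sqrt(nrow(w)),
      mean_loser = mean(l[[f]]), sem_loser = sd(l[[f]]) / sqrt(nrow(l)),
      n_races = nrow(w),
      p_value = ht$p_value
    )
  })
  jaw_pct_diff <- mean(
    100 * (w$jaw_prominence - l$jaw_prominence) / l$jaw_prominence
  )
  list(table = dplyr::bind_rows(rows), jaw_pct_diff = jaw_pct_diff)
}
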