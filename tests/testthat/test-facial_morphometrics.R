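test_that("metrics match the hand-computed landmark worked example", {
  m <- compute_metrics(worked_landmarks())
  # hand-verified distances: ipd 60, cheekbone 120, jaw 90,
  # face height 150, lower face height 60
  expect_equal(m$ipd_px, 60)
  expect_equal(m$cheekbone_width_norm, 2.0)
  expect_equal(m$jaw_width_norm, 1.5)
  expect_equal(m$face_height_norm, 2.5)
  expect_equal(m$lower_face_height_norm, 1.0)
  expect_equal(m$jaw_prominence, 0.75)
  expect_equal(m$fwhr, 0.8)
  expect_equal(m$lfp, 0.4)
})

test_that("a 100 px jaw against a 125 px cheekbone gives jaw prominence 0.8", {
  lm <- worked_landmarks()
  lm$gonion_left_x <- 20
  lm$gonion_right_x <- 120    # jaw width 100
  lm$zygion_left_x <- 7.5
  lm$zygion_right_x <- 132.5  # cheekbone width 125
  expect_equal(compute_metrics(lm)$jaw_prominence, 0.8)
})

test_that("ratios are invariant to scaling, translation, and mirroring", {
  lm <- worked_landmarks()
  coords <- setdiff(names(lm), c("candidate_id", "rater_id"))
  m0 <- compute_metrics(lm)

  scaled <- lm
  scaled[coords] <- lapply(lm[coords], function(v) v * 2)
  m2 <- compute_metrics(scaled)
  for (f in c("jaw_prominence", "fwhr", "lfp", "jaw_width_norm",
              "cheekbone_width_norm", "face_height_norm",
              "lower_face_height_norm")) {
    expect_equal(m2[[f]], m0[[f]], tolerance = 1e-12)
  }
  expect_equal(m2$ipd_px, 120)

  shifted <- lm
  xcols <- coords[grepl("_x$", coords)]
  ycols <- coords[grepl("_y$", coords)]
  shifted[xcols] <- lapply(lm[xcols], `+`, 37)
  shifted[ycols] <- lapply(lm[ycols], `+`, -12)
  m3 <- compute_metrics(shifted)
  expect_equal(m3$jaw_prominence, m0$jaw_prominence, tolerance = 1e-12)
  expect_equal(m3$fwhr, m0$fwhr, tolerance = 1e-12)

  # horizontal mirror: x -> 140 - x, swapping left/right labels
  mir <- lm
  for (pair in c("pupil", "zygion", "gonion")) {
    mir[[paste0(pair, "_left_x")]] <- 140 - lm[[paste0(pair, "_right_x")]]
    mir[[paste0(pair, "_right_x")]] <- 140 - lm[[paste0(pair, "_left_x")]]
  }
  for (pt in c("face_top", "lower_face_top", "chin_bottom")) {
    mir[[paste0(pt, "_x")]] <- 140 - lm[[paste0(pt, "_x")]]
  }
  m4 <- compute_metrics(mir)
  expect_equal(m4$jaw_prominence, m0$jaw_prominence, tolerance = 1e-12)
  expect_equal(m4$lfp, m0$lfp, tolerance = 1e-12)
})

test_that("degenerate landmark sets are rejected", {
  lm <- worked_landmarks()
  lm$pupil_right_x <- lm$pupil_left_x
  expect_error(compute_metrics(lm), class = "gazepoll_validation_error")

  lm2 <- worked_landmarks()
  lm2$lower_face_top_y <- 10  # above face_top
  expect_error(compute_metrics(lm2), class = "gazepoll_validation_error")
})

test_that("rater aggregation averages metrics and scores concordance", {
  set.seed(3)
  base <- tibble::tibble(
    jaw_width_norm = runif(10, 1.5, 1.9),
    cheekbone_width_norm = runif(10, 2.0, 2.2),
    face_height_norm = runif(10, 1.8, 2.0),
    lower_face_height_norm = runif(10, 0.6, 0.8)
  )
  lmk <- landmarks_from_metrics(base)
  lmk$candidate_id <- sprintf("C%02d", 1:10)
  two <- dplyr::bind_rows(
    dplyr::mutate(lmk, rater_id = "r1"),
    dplyr::mutate(lmk, rater_id = "r2")
  )
  agg <- aggregate_raters(compute_metrics(two))
  expect_equal(agg$concordance, 1.0)
  one <- compute_metrics(dplyr::mutate(lmk, rater_id = "r1"))
  expect_equal(agg$metrics$jaw_prominence,
               one$jaw_prominence[match(agg$metrics$candidate_id,
                                        one$candidate_id)])

  # single rater: concordance undefined
  single <- aggregate_raters(one)
  expect_true(is.na(single$concordance))

  # two raters over 5 candidates: concordance equals the mean of
  # hand-computed per-feature Pearson correlations
  set.seed(4)
  m1 <- compute_metrics(dplyr::mutate(lmk[1:5, ], rater_id = "r1"))
  noisy <- base[1:5, ] + matrix(rnorm(20, 0, 0.02), 5)
  lmk2 <- landmarks_from_metrics(noisy)
  lmk2$candidate_id <- sprintf("C%02d", 1:5)
  m2 <- compute_metrics(dplyr::mutate(lmk2, rater_id = "r2"))
  agg2 <- aggregate_raters(dplyr::bind_rows(m1, m2))
  feats <- c("jaw_width_norm", "cheekbone_width_norm", "face_height_norm",
             "lower_face_height_norm", "jaw_prominence", "fwhr", "lfp")
  oracle <- mean(vapply(feats, function(f) hand_pearson(m1[[f]], m2[[f]]),
                        numeric(1)))
  expect_equal(agg2$concordance, oracle, tolerance = 1e-12)

  # mismatched candidate sets across raters
  expect_error(aggregate_raters(dplyr::bind_rows(m1, m2[1:4, ])),
               class = "gazepoll_validation_error")
})

test_that("aggregation commutes with affine rescaling; concordance is invariant", {
  ro <- simulate_election_roster(small_config())
  met <- compute_metrics(ro$landmarks)
  agg <- aggregate_raters(met)
  met2 <- met
  met2$jaw_prominence <- 3 * met$jaw_prominence + 1
  agg2 <- aggregate_raters(met2)
  expect_equal(agg2$metrics$jaw_prominence,
               3 * agg$metrics$jaw_prominence + 1, tolerance = 1e-12)
  expect_equal(agg2$concordance_by_feature[["jaw_prominence"]],
               agg$concordance_by_feature[["jaw_prominence"]],
               tolerance = 1e-9)
})

test_that("group contrasts report the jaw advantage and exact small-sample p-values", {
  # one race, winner jaw 0.816 vs loser 0.80 -> +2.0% (arithmetic check via
  # a two-race table so the paired test has n >= 2)
  base <- tibble::tibble(
    jaw_width_norm = c(0.816 * 2, 0.80 * 2, 0.9 * 2, 0.9 * 2),
    cheekbone_width_norm = 2,
    face_height_norm = 2,
    lower_face_height_norm = 0.8
  )
  lmk <- landmarks_from_metrics(base)
  lmk$candidate_id <- c("W1", "L1", "W2", "L2")
  lmk$rater_id <- "r1"
  met <- compute_metrics(lmk)
  cand <- tibble::tibble(
    candidate_id = c("W1", "L1", "W2", "L2"),
    race_id = c("R1", "R1", "R2", "R2"),
    gender = "M",
    winner = c(1, 0, 1, 0)
  )
  gc <- group_contrast(met, cand, "outcome")
  expect_equal(gc$jaw_pct_diff, mean(c(100 * (0.816 - 0.80) / 0.80, 0)))
  # restricted to the first race the difference is exactly +2%
  met_r1 <- dplyr::bind_rows(met[1:2, ], met[1:2, ])
  met_r1$candidate_id <- c("W1", "L1", "W3", "L3")
  cand_r1 <- tibble::tibble(
    candidate_id = c("W1", "L1", "W3", "L3"),
    race_id = c("R1", "R1", "R3", "R3"),
    gender = "M", winner = c(1, 0, 1, 0)
  )
  gc1 <- group_contrast(met_r1, cand_r1, "outcome")
  expect_equal(gc1$jaw_pct_diff, 100 * (0.816 - 0.80) / 0.80)

  # identical winner and loser distributions -> signed-rank p = 1
  met_eq <- met
  met_eq[met_eq$candidate_id %in% c("L1", "L2"), -1] <-
    met_eq[met_eq$candidate_id %in% c("W1", "W2"), -1]
  gc_eq <- group_contrast(met_eq, cand, "outcome")
  expect_true(all(gc_eq$table$p_value == 1))

  # fully separated male vs female, 4 per group: exact enumeration p
  set.seed(9)
  vals <- c(runif(4, 1.8, 1.9), runif(4, 1.5, 1.6))  # M wider jaws
  base8 <- tibble::tibble(
    jaw_width_norm = vals, cheekbone_width_norm = 2.1,
    face_height_norm = 1.9, lower_face_height_norm = 0.75
  )
  lmk8 <- landmarks_from_metrics(base8)
  lmk8$candidate_id <- sprintf("C%d", 1:8)
  lmk8$rater_id <- "r1"
  met8 <- compute_metrics(lmk8)
  cand8 <- tibble::tibble(
    candidate_id = sprintf("C%d", 1:8),
    race_id = sprintf("R%d", rep(1:4, 2)),
    gender = rep(c("M", "F"), each = 4),
    winner = rep(c(1, 0), each = 4)
  )
  gcg <- group_contrast(met8, cand8, "gender")
  jaw_row <- gcg$table[gcg$table$feature == "jaw_width_norm", ]
  expect_equal(jaw_row$p_value,
               exact_rank_sum_p(vals[5:8], vals[1:4]))
  expect_equal(jaw_row$p_value, 2 / choose(8, 4))
})

test_that("dimorphic rosters separate the sexes on all five masculinity cues", {
  ro <- simulate_election_roster(sim_config(seed = 21))
  agg <- aggregate_raters(compute_metrics(ro$landmarks))
  gc <- group_contrast(agg$metrics, ro$candidates, "gender")
  cues <- c("jaw_prominence", "cheekbone_width_norm", "jaw_width_norm",
            "fwhr", "lfp")
  p <- gc$table$p_value[gc$table$feature %in% cues]
  expect_true(all(p < 0.05))
  # direction: males have wider jaws but narrower cheekbones
  tab <- gc$table
  expect_gt(tab$mean_m[tab$feature == "jaw_width_norm"],
            tab$mean_f[tab$feature == "jaw_width_norm"])
  expect_lt(tab$mean_m[tab$feature == "cheekbone_width_norm"],
            tab$mean_f[tab$feature == "cheekbone_width_norm"])
})

test_that("landmark synthesis inverts metric computation to 1e-9", {
  set.seed(12)
  mets <- tibble::tibble(
    jaw_width_norm = runif(50, 1.4, 2.0),
    cheekbone_width_norm = runif(50, 1.9, 2.3),
    face_height_norm = runif(50, 1.6, 2.2),
    lower_face_height_norm = runif(50, 0.5, 1.0)
  )
  lmk <- landmarks_from_metrics(mets, ipd_px = 60)
  lmk$candidate_id <- sprintf("C%02d", 1:50)
  lmk$rater_id <- "r"
  out <- compute_metrics(lmk)
  for (f in names(mets)) {
    expect_equal(out[[f]], mets[[f]], tolerance = 1e-9)
  }
  expect_equal(out$jaw_prominence,
               mets$jaw_width_norm / mets$cheekbone_width_norm,
               tolerance = 1e-9)

  # doubling ipd doubles pixel distances, ratios unchanged
  lmk2 <- landmarks_from_metrics(mets[1, ], ipd_px = 120)
  out2 <- compute_metrics(dplyr::mutate(lmk2, candidate_id = "a",
                                        rater_id = "r"))
  expect_equal(out2$ipd_px, 120)
  expect_equal(out2$jaw_prominence, out$jaw_prominence[1], tolerance = 1e-9)

  # the worked-example ratios reproduce the documented landmark geometry
  wm <- tibble::tibble(jaw_width_norm = 1.6, cheekbone_width_norm = 2.0,
                       face_height_norm = 2.5, lower_face_height_norm = 1.0)
  wl <- landmarks_from_metrics(wm, ipd_px = 60)
  wo <- compute_metrics(dplyr::mutate(wl, candidate_id = "a", rater_id = "r"))
  expect_equal(wo$jaw_prominence, 0.8)
  expect_equal(wo$fwhr, 0.8)
  expect_equal(wo$lfp, 0.4)

  expect_error(landmarks_from_metrics(
    tibble::tibble(jaw_width_norm = -1, cheekbone_width_norm = 2,
                   face_height_norm = 2, lower_face_height_norm = 0.5)),
    class = "gazepoll_degenerate_error")
})
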