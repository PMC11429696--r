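# Synthetic study generator: candidate rosters with dimorphic facial
# metrics, competence ratings, a linear vote-share model, per-rater landmark
# tables, and stochastic fixation-level gaze sessions, plus an exact analytic
# accuracy oracle for calibration.
#
# The generator emulates the study conditions: 124 gubernatorial and 149
# senatorial races (273 candidate pairs, 546 candidates) with a fixed gender
# composition of 66 mixed-gender, 201 male-male, and 6 female-female pairs;
# 3 monkeys, each viewing the full stimulus set on 2 separate days; one 2.5 s
# two-image presentation per race per session.

gp_office_years <- list(
  gubernatorial = 1995:2006,
  senatorial = 2000:2008,
  presidential = seq(2000, 2020, by = 4)
)

#' Build a simulation configuration
#'
#' Returns the full generative parameterization of the synthetic study. The
#' defaults are the emulated study conditions; any field can be overridden by
#' name. Key groups:
#'
#' * Design: `n_gubernatorial` (124), `n_senatorial` (149),
#'   `n_presidential` (0), `n_monkeys` (3), `sessions_per_monkey` (2 days;
#'   each day every office set is shown once in shuffled order).
#' * Gender: `gender_composition` `"fixed"` reproduces the stimulus-set
#'   composition (66/273 mixed, 201/273 male-male, 6/273 female-female,
#'   scaled to the requested race count); `"bernoulli"` draws each
#'   candidate's gender independently with `p_female`.
#' * Faces: latent masculinity ~ Normal(`masc_mean_m` or `masc_mean_f`,
#'   `masc_sd`); each raw measurement (IPD units) is
#'   `intercept + slope * masculinity + Normal(0, noise_sd)` per the
#'   `feature_loadings` table. Raters re-measure with additive
#'   Normal(0, `rater_noise_sd`) error.
#' * Votes: competence = `competence_slope_on_jaw * jaw_prominence` + noise;
#'   a race's first-candidate share is
#'   `50 + 0.5 * (beta_jaw dJ + beta_competence dC + beta_incumbent dI +
#'   beta_age dAge) + Normal(0, vote_noise_sd)`, clipped to (0, 100), with
#'   the pair summing to 100.
#' * Gaze: in-box fixation count per trial ~ Poisson(`mean_fixations`); each
#'   fixation lands left with probability
#'   `plogis(side_bias + alloc_direct_loser * (loseL - loseR) +
#'   alloc_jaw * (jawR - jawL) + alloc_female * (femL - femR) +
#'   alloc_age * (ageL - ageR)/10)`; durations ~ Gamma(`dwell_shape`) scaled
#'   to `dwell_mean_ms`, laid out sequentially with `fixation_gap_ms` gaps
#'   and compressed to fit the `stimulus_duration_ms` window when the drawn
#'   sequence overruns (the count is never truncated).
#'
#' @param seed Integer seed; every substream derives from it.
#' @param ... Named overrides of any default field.
#' @return A validated `gp_sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    n_gubernatorial = 124L,
    n_senatorial = 149L,
    n_presidential = 0L,
    gender_composition = "fixed",
    p_female = 80 / 546,
    p_incumbent = c(gubernatorial = 74 / 124, senatorial = 120 / 149,
                    presidential = 0.5),
    masc_mean_m = 0.5,
    masc_mean_f = -0.5,
    masc_sd = 1,
    feature_loadings = tibble::tibble(
      feature = c("jaw_width", "cheekbone_width", "face_height",
                  "lower_face_height"),
      intercept = c(1.70, 2.10, 1.90, 0.75),
      slope = c(0.08, -0.05, -0.10, 0.03),
      noise_sd = c(0.03, 0.03, 0.03, 0.03)
    ),
    n_raters = 2L,
    rater_noise_sd = 0.035,
    ipd_px = 60,
    competence_slope_on_jaw = 2.4,
    competence_noise_sd = 1,
    beta_jaw = 68,
    beta_competence = 5.4,
    beta_incumbent = 3,
    beta_age = 0.2,
    vote_noise_sd = 7.2,
    age_mean = 52,
    age_sd = 9,
    age_min = 30,
    age_max = 80,
    margin_sd = 13,
    mean_fixations = 6,
    alloc_direct_loser = 0,
    alloc_jaw = 2,
    alloc_female = 0.3,
    alloc_age = 0.05,
    side_bias = 0,
    dwell_shape = 2,
    dwell_mean_ms = 250,
    jitter_sd_px = 40,
    screen_w = 2560,
    screen_h = 1440,
    image_w = 600,
    image_h = 600,
    stimulus_duration_ms = 2500,
    fixation_gap_ms = 30,
    n_monkeys = 3L,
    sessions_per_monkey = 2L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    gp_config_error(sprintf("sim_config: unknown field(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A configuration list with the [sim_config()] fields.
#' @return The validated `gp_sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) gp_config_error(paste0("sim_config: ", msg))
  chk(!is.null(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed) &&
        cfg$seed == as.integer(cfg$seed), "field 'seed' must be an integer")
  chk(cfg$gender_composition %in% c("fixed", "bernoulli"),
      "field 'gender_composition' must be 'fixed' or 'bernoulli'")
  chk(cfg$p_female >= 0 && cfg$p_female <= 1,
      "field 'p_female' must be in [0, 1]")
  chk(all(cfg$p_incumbent >= 0 & cfg$p_incumbent <= 1),
      "field 'p_incumbent' must be in [0, 1]")
  for (f in c("masc_sd", "rater_noise_sd", "competence_noise_sd",
              "vote_noise_sd", "age_sd", "margin_sd", "jitter_sd_px")) {
    chk(cfg[[f]] >= 0, sprintf("field '%s' must be >= 0", f))
  }
  chk(cfg$mean_fixations > 0, "field 'mean_fixations' must be > 0")
  chk(cfg$dwell_shape > 0 && cfg$dwell_mean_ms > 0,
      "fields 'dwell_shape'/'dwell_mean_ms' must be > 0")
  chk(all(cfg$feature_loadings$noise_sd >= 0),
      "feature loading noise SDs must be >= 0")
  for (f in c("n_gubernatorial", "n_senatorial", "n_presidential",
              "n_monkeys", "sessions_per_monkey", "n_raters")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] == as.integer(cfg[[f]]),
        sprintf("field '%s' must be a non-negative integer", f))
  }
  chk(cfg$n_gubernatorial + cfg$n_senatorial + cfg$n_presidential > 0,
      "at least one race is required")
  chk(cfg$n_raters >= 1, "field 'n_raters' must be >= 1")
  structure(cfg, class = "gp_sim_config")
}

# Stimulus geometry shared by the generator and the layout table: images
# centered vertically, horizontally at 1/4 and 3/4 of the screen.
gp_config_layout <- function(cfg) {
  cy <- (cfg$screen_h - cfg$image_h) / 2
  lx <- cfg$screen_w / 4 - cfg$image_w / 2
  rx <- 3 * cfg$screen_w / 4 - cfg$image_w / 2
  stimulus_layout(
    screen_w = cfg$screen_w, screen_h = cfg$screen_h,
    left_box = c(lx, cy, lx + cfg$image_w, cy + cfg$image_h),
    right_box = c(rx, cy, rx + cfg$image_w, cy + cfg$image_h)
  )
}

# Fixed-composition race types scaled from the emulated stimulus set
# (66 mixed, 201 male-male, 6 female-female out of 273).
gp_fixed_composition <- function(n_races) {
  n_mixed <- round(n_races * 66 / 273)
  n_ff <- round(n_races * 6 / 273)
  n_mm <- n_races - n_mixed - n_ff
  c(FM = n_mixed, MM = n_mm, FF = n_ff)
}

#' Simulate an election roster
#'
#' Generates races, candidates, true facial metrics, competence ratings,
#' vote shares, and per-rater landmark tables under the configured generative
#' model (see [sim_config()]). Winners are decided by the larger (two-party)
#' vote share.
#'
#' @param config A `gp_sim_config`.
#' @return A list: `races`, `candidates` (full election schema plus
#'   `competence` and true-metric join keys), `metrics_true` (per-candidate
#'   latent masculinity and noiseless metrics), `landmarks` (per rater),
#'   `competence`, and `truth` (generating parameters and bookkeeping).
#' @export
simulate_election_roster <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(gp_derive_seed(cfg$seed, 1))

  offices <- rep(c("gubernatorial", "senatorial", "presidential"),
                 times = c(cfg$n_gubernatorial, cfg$n_senatorial,
                           cfg$n_presidential))
  n_races <- length(offices)
  races <- tibble::tibble(
    race_id = sprintf("R%04d", seq_len(n_races)),
    office = offices,
    year = vapply(offices, function(o) {
      yrs <- gp_office_years[[o]]
      yrs[sample.int(length(yrs), 1)]
    }, numeric(1)),
    state = sample(datasets::state.abb, n_races, replace = TRUE),
    ref_presidential_margin_pct = rnorm(n_races, 0, cfg$margin_sd)
  )

  # Gender composition of the candidate pairs
  if (cfg$gender_composition == "fixed") {
    comp <- gp_fixed_composition(n_races)
    race_type <- sample(rep(names(comp), times = comp))
    g1 <- ifelse(race_type == "FF", "F",
                 ifelse(race_type == "MM", "M",
                        sample(c("F", "M"), n_races, replace = TRUE)))
    g2 <- ifelse(race_type == "FM", ifelse(g1 == "F", "M", "F"), g1)
  } else {
    g1 <- ifelse(runif(n_races) < cfg$p_female, "F", "M")
    g2 <- ifelse(runif(n_races) < cfg$p_female, "F", "M")
  }

  n_cand <- 2L * n_races
  cand <- tibble::tibble(
    candidate_id = sprintf("C%05d", seq_len(n_cand)),
    race_id = rep(races$race_id, each = 2),
    slot = rep(1:2, times = n_races),
    gender = as.vector(rbind(g1, g2))
  )
  cand <- dplyr::left_join(cand, races, by = "race_id")
  cand$name <- paste("Candidate", cand$candidate_id)

  # Party: one Democrat and one Republican per race (a small share of
  # second-listed candidates run as 'other').
  first_d <- runif(n_races) < 0.5
  p1 <- ifelse(first_d, "D", "R")
  p2 <- ifelse(first_d, "R", "D")
  p2[runif(n_races) < 0.03] <- "other"
  cand$party <- as.vector(rbind(p1, p2))

  # Age and incumbency
  age <- round(pmin(pmax(rnorm(n_cand, cfg$age_mean, cfg$age_sd),
                         cfg$age_min), cfg$age_max))
  cand$birth_year <- cand$year - age
  cand$age <- age
  has_inc <- runif(n_races) < cfg$p_incumbent[offices]
  which_inc <- sample(1:2, n_races, replace = TRUE)
  cand$incumbent <- as.integer(
    has_inc[match(cand$race_id, races$race_id)] &
      cand$slot == which_inc[match(cand$race_id, races$race_id)]
  )

  # Latent masculinity and raw facial measurements (IPD units)
  masc_mean <- ifelse(cand$gender == "M", cfg$masc_mean_m, cfg$masc_mean_f)
  masculinity <- rnorm(n_cand, masc_mean, cfg$masc_sd)
  fl <- cfg$feature_loadings
  raw <- lapply(seq_len(nrow(fl)), function(i) {
    pmax(fl$intercept[i] + fl$slope[i] * masculinity +
           rnorm(n_cand, 0, fl$noise_sd[i]), 0.05)
  })
  names(raw) <- fl$feature
  raw$lower_face_height <- pmin(raw$lower_face_height, 0.95 * raw$face_height)
  metrics_true <- tibble::tibble(
    candidate_id = cand$candidate_id,
    masculinity = masculinity,
    jaw_width_norm = raw$jaw_width,
    cheekbone_width_norm = raw$cheekbone_width,
    face_height_norm = raw$face_height,
    lower_face_height_norm = raw$lower_face_height,
    jaw_prominence = raw$jaw_width / raw$cheekbone_width,
    fwhr = raw$cheekbone_width / raw$face_height,
    lfp = raw$lower_face_height / raw$face_height
  )

  competence <- cfg$competence_slope_on_jaw * metrics_true$jaw_prominence +
    rnorm(n_cand, 0, cfg$competence_noise_sd)
  cand$competence <- competence

  # Vote shares: linear in the within-race differences, noise on the pair,
  # clipped to (0, 100), summing to 100.
  i1 <- seq(1, n_cand, by = 2)
  i2 <- i1 + 1
  d <- cfg$beta_jaw * (metrics_true$jaw_prominence[i1] -
                         metrics_true$jaw_prominence[i2]) +
    cfg$beta_competence * (competence[i1] - competence[i2]) +
    cfg$beta_incumbent * (cand$incumbent[i1] - cand$incumbent[i2]) +
    cfg$beta_age * (age[i1] - age[i2])
  share1 <- 50 + d / 2 + rnorm(n_races, 0, cfg$vote_noise_sd)
  n_clipped <- sum(share1 <= 0.5 | share1 >= 99.5)
  share1 <- pmin(pmax(share1, 0.5), 99.5)
  share1[share1 == 50] <- 50 + 1e-9
  shares <- as.vector(rbind(share1, 100 - share1))
  cand$vote_share_pct <- shares
  cand$winner <- as.integer(shares > 100 - shares)

  # Cosmetic photo codes (most official portraits are smiling)
  smile <- sample(0:2, n_cand, replace = TRUE, prob = c(0.077, 0.3, 0.623))
  cand$smile <- smile
  cand$bald <- as.integer(cand$gender == "M" & runif(n_cand) < 0.12)
  cand$facial_hair <- as.integer(cand$gender == "M" & runif(n_cand) < 0.06)
  cand$glasses <- as.integer(runif(n_cand) < 0.10)

  # Per-rater landmark tables: raters re-measure the raw widths/heights with
  # additive error, then landmarks are laid out on the fixed template.
  landmark_list <- lapply(seq_len(cfg$n_raters), function(r) {
    noisy <- tibble::tibble(
      jaw_width_norm = pmax(raw$jaw_width +
                              rnorm(n_cand, 0, cfg$rater_noise_sd), 0.05),
      cheekbone_width_norm = pmax(raw$cheekbone_width +
                                    rnorm(n_cand, 0, cfg$rater_noise_sd), 0.05),
      face_height_norm = pmax(raw$face_height +
                                rnorm(n_cand, 0, cfg$rater_noise_sd), 0.1),
      lower_face_height_norm = pmax(raw$lower_face_height +
                                      rnorm(n_cand, 0, cfg$rater_noise_sd), 0.05)
    )
    noisy$lower_face_height_norm <- pmin(noisy$lower_face_height_norm,
                                         0.95 * noisy$face_height_norm)
    lmk <- landmarks_from_metrics(noisy, ipd_px = cfg$ipd_px)
    lmk$candidate_id <- cand$candidate_id
    lmk$rater_id <- sprintf("rater%02d", r)
    lmk[, gp_landmark_cols]
  })
  landmarks <- dplyr::bind_rows(landmark_list)

  truth <- list(
    seed = cfg$seed,
    n_races = n_races,
    n_candidates = n_cand,
    n_clipped_vote_shares = n_clipped,
    beta_jaw = cfg$beta_jaw,
    beta_competence = cfg$beta_competence,
    beta_incumbent = cfg$beta_incumbent,
    beta_age = cfg$beta_age,
    vote_noise_sd = cfg$vote_noise_sd,
    competence_slope_on_jaw = cfg$competence_slope_on_jaw,
    alloc_direct_loser = cfg$alloc_direct_loser,
    alloc_jaw = cfg$alloc_jaw,
    alloc_female = cfg$alloc_female,
    alloc_age = cfg$alloc_age
  )

  list(races = races, candidates = cand, metrics_true = metrics_true,
       landmarks = landmarks,
       competence = tibble::tibble(candidate_id = cand$candidate_id,
                                   competence = competence),
       truth = truth)
}

#' Lay out face landmarks reproducing given metrics
#'
#' Inverse of [compute_metrics()] for fixture construction: builds a
#' symmetric, untilted landmark set centered on a template whose computed
#' metrics reproduce the input widths and heights (and hence all ratios)
#' up to floating-point error.
#'
#' @param metrics A data frame (or one-row list) with `jaw_width_norm`,
#'   `cheekbone_width_norm`, `face_height_norm`, `lower_face_height_norm`
#'   in IPD units; all positive, lower face height strictly below face
#'   height.
#' @param ipd_px Inter-pupillary distance in pixels (sets the scale).
#' @param center Pixel coordinates of the pupil midpoint.
#' @return A tibble of landmark coordinates (one row per input row).
#' @export
landmarks_from_metrics <- function(metrics, ipd_px = 60, center = c(300, 300)) {
  m <- tibble::as_tibble(metrics)
  need <- c("jaw_width_norm", "cheekbone_width_norm", "face_height_norm",
            "lower_face_height_norm")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    gp_config_error(sprintf("landmarks_from_metrics: missing metric(s): %s",
                            paste(miss, collapse = ", ")))
  }
  vals <- as.matrix(m[need])
  if (any(vals <= 0) || any(!is.finite(vals)) || any(ipd_px <= 0)) {
    gp_degenerate_error("landmarks_from_metrics: metrics must be positive and finite")
  }
  if (any(m$lower_face_height_norm >= m$face_height_norm)) {
    gp_degenerate_error(
      "landmarks_from_metrics: lower face height must be smaller than face height"
    )
  }
  cx <- center[1]
  cy <- center[2]
  face_top_y <- cy - 0.5 * ipd_px
  chin_y <- face_top_y + m$face_height_norm * ipd_px
  tibble::tibble(
    pupil_left_x = cx - ipd_px / 2, pupil_left_y = cy,
    pupil_right_x = cx + ipd_px / 2, pupil_right_y = cy,
    zygion_left_x = cx - m$cheekbone_width_norm * ipd_px / 2,
    zygion_left_y = cy + 0.25 * ipd_px,
    zygion_right_x = cx + m$cheekbone_width_norm * ipd_px / 2,
    zygion_right_y = cy + 0.25 * ipd_px,
    gonion_left_x = cx - m$jaw_width_norm * ipd_px / 2,
    gonion_left_y = cy + 0.9 * ipd_px,
    gonion_right_x = cx + m$jaw_width_norm * ipd_px / 2,
    gonion_right_y = cy + 0.9 * ipd_px,
    face_top_x = cx, face_top_y = face_top_y,
    lower_face_top_x = cx,
    lower_face_top_y = chin_y - m$lower_face_height_norm * ipd_px,
    chin_bottom_x = cx, chin_bottom_y = chin_y
  )
}

# Per-trial left-allocation probability given trial attributes.
gp_alloc_p_left <- function(cfg, lose_l, lose_r, jaw_l, jaw_r,
                            fem_l, fem_r, age_l, age_r) {
  plogis(cfg$side_bias +
           cfg$alloc_direct_loser * (lose_l - lose_r) +
           cfg$alloc_jaw * (jaw_r - jaw_l) +
           cfg$alloc_female * (fem_l - fem_r) +
           cfg$alloc_age * (age_l - age_r) / 10)
}

#' Simulate fixation-level gaze sessions
#'
#' For each monkey, day, and office set: every race shown exactly once, in
#' shuffled order and with random side assignment. Per trial the in-box
#' fixation count is Poisson; each fixation is allocated to a side by the
#' logistic rule in [sim_config()]; durations are Gamma with the configured
#' mean, laid out sequentially with fixed inter-fixation gaps and compressed
#' to fit the presentation window when the drawn sequence overruns (so the
#' drawn fixation count is always realized). Fixation positions are box
#' centers plus Gaussian jitter clamped inside the box.
#'
#' @param roster A roster from [simulate_election_roster()].
#' @param config The `gp_sim_config` used to generate it.
#' @return A list: `fixations` (file-schema tibble), `layouts` (one row per
#'   session), and `trials` (per-trial truth: sides and allocation
#'   probabilities).
#' @export
simulate_gaze_sessions <- function(roster, config) {
  cfg <- validate_sim_config(config)
  set.seed(gp_derive_seed(cfg$seed, 2))
  layout <- gp_config_layout(cfg)

  cand <- dplyr::left_join(
    roster$candidates[, c("candidate_id", "race_id", "gender", "winner",
                          "age")],
    roster$metrics_true[, c("candidate_id", "jaw_prominence")],
    by = "candidate_id"
  )
  races <- roster$races

  blocks <- expand.grid(
    monkey = seq_len(cfg$n_monkeys),
    day = seq_len(cfg$sessions_per_monkey),
    office = unique(races$office),
    stringsAsFactors = FALSE
  )

  trial_list <- lapply(seq_len(nrow(blocks)), function(b) {
    office_races <- races$race_id[races$office == blocks$office[b]]
    shuffled <- sample(office_races)
    pair <- cand[match(shuffled, cand$race_id), ]           # slot-1 candidates
    pair2 <- cand[match(shuffled, cand$race_id) + 1L, ]     # slot-2 candidates
    first_left <- runif(length(shuffled)) < 0.5
    tibble::tibble(
      session_id = sprintf("M%d_d%d_%s", blocks$monkey[b], blocks$day[b],
                           substr(blocks$office[b], 1, 3)),
      monkey_id = sprintf("M%d", blocks$monkey[b]),
      office = blocks$office[b],
      trial_index = seq_along(shuffled) - 1L,
      race_id = shuffled,
      left_candidate_id = ifelse(first_left, pair$candidate_id,
                                 pair2$candidate_id),
      right_candidate_id = ifelse(first_left, pair2$candidate_id,
                                  pair$candidate_id),
      lose_l = ifelse(first_left, 1 - pair$winner, 1 - pair2$winner),
      jaw_l = ifelse(first_left, pair$jaw_prominence, pair2$jaw_prominence),
      jaw_r = ifelse(first_left, pair2$jaw_prominence, pair$jaw_prominence),
      fem_l = ifelse(first_left, pair$gender == "F", pair2$gender == "F"),
      fem_r = ifelse(first_left, pair2$gender == "F", pair$gender == "F"),
      age_l = ifelse(first_left, pair$age, pair2$age),
      age_r = ifelse(first_left, pair2$age, pair$age)
    )
  })
  trials <- dplyr::bind_rows(trial_list)
  trials$p_left <- gp_alloc_p_left(
    cfg, trials$lose_l, 1 - trials$lose_l, trials$jaw_l, trials$jaw_r,
    as.numeric(trials$fem_l), as.numeric(trials$fem_r),
    trials$age_l, trials$age_r
  )

  gap <- cfg$fixation_gap_ms
  dur_window <- cfg$stimulus_duration_ms
  n_cap <- floor((dur_window + gap) / (gap + 1))
  n_fix <- pmin(rpois(nrow(trials), cfg$mean_fixations), n_cap)
  trials$n_fix <- n_fix

  pos <- n_fix > 0
  trial_row <- rep(which(pos), times = n_fix[pos])
  total <- length(trial_row)
  if (total == 0) {
    gp_config_error("simulate_gaze_sessions: no fixations generated")
  }
  side_left <- rbinom(total, 1, trials$p_left[trial_row]) == 1
  dur <- rgamma(total, shape = cfg$dwell_shape,
                scale = cfg$dwell_mean_ms / cfg$dwell_shape)

  # Compress overlong sequences into the presentation window, reserving one
  # millisecond per fixation so integer rounding can never overrun it.
  n_per <- n_fix[pos]
  avail <- dur_window - gap * (n_per - 1) - n_per
  sum_dur <- as.vector(rowsum(dur, trial_row))
  scale <- pmin(1, avail / sum_dur)
  dur_i <- pmax(1, floor(dur * rep(scale, times = n_per)))

  step <- dur_i + gap
  cum0 <- cumsum(c(0, head(step, -1)))
  first_idx <- !duplicated(trial_row)
  onset <- cum0 - rep(cum0[first_idx], times = n_per)
  offset <- onset + dur_i

  lb <- layout$left_box
  rb <- layout$right_box
  cx <- ifelse(side_left, (lb[1] + lb[3]) / 2, (rb[1] + rb[3]) / 2)
  cy <- ifelse(side_left, (lb[2] + lb[4]) / 2, (rb[2] + rb[4]) / 2)
  x <- round(cx + rnorm(total, 0, cfg$jitter_sd_px))
  y <- round(cy + rnorm(total, 0, cfg$jitter_sd_px))
  x <- pmin(pmax(x, ifelse(side_left, lb[1], rb[1])),
            ifelse(side_left, lb[3], rb[3]) - 1)
  y <- pmin(pmax(y, ifelse(side_left, lb[2], rb[2])),
            ifelse(side_left, lb[4], rb[4]) - 1)

  fixations <- tibble::tibble(
    session_id = trials$session_id[trial_row],
    monkey_id = trials$monkey_id[trial_row],
    office = trials$office[trial_row],
    trial_index = trials$trial_index[trial_row],
    race_id = trials$race_id[trial_row],
    left_candidate_id = trials$left_candidate_id[trial_row],
    right_candidate_id = trials$right_candidate_id[trial_row],
    onset_ms = onset,
    offset_ms = offset,
    x_px = x,
    y_px = y
  )

  # Trials whose Poisson draw is zero still happened: emit one off-box
  # fixation in the gap between the images so the trial stays representable
  # in the event format and scores as a tie under every rule.
  zero <- which(n_fix == 0)
  if (length(zero) > 0) {
    gx <- (lb[3] + rb[1]) / 2
    zx <- pmin(pmax(round(gx + rnorm(length(zero), 0, cfg$jitter_sd_px)),
                    lb[3] + 1), rb[1] - 2)
    zy <- round(cfg$screen_h / 2 + rnorm(length(zero), 0, cfg$jitter_sd_px))
    zdur <- pmax(1, round(rgamma(length(zero), shape = cfg$dwell_shape,
                                 scale = cfg$dwell_mean_ms / cfg$dwell_shape)))
    zdur <- pmin(zdur, dur_window)
    fixations <- dplyr::bind_rows(fixations, tibble::tibble(
      session_id = trials$session_id[zero],
      monkey_id = trials$monkey_id[zero],
      office = trials$office[zero],
      trial_index = trials$trial_index[zero],
      race_id = trials$race_id[zero],
      left_candidate_id = trials$left_candidate_id[zero],
      right_candidate_id = trials$right_candidate_id[zero],
      onset_ms = 0,
      offset_ms = zdur,
      x_px = zx,
      y_px = zy
    ))
    fixations <- dplyr::arrange(fixations, .data$session_id,
                                .data$trial_index, .data$onset_ms)
  }

  session_ids <- unique(trials$session_id)
  layouts <- tibble::tibble(
    session_id = session_ids,
    screen_w = layout$screen_w, screen_h = layout$screen_h,
    left_x_min = lb[1], left_y_min = lb[2],
    left_x_max = lb[3], left_y_max = lb[4],
    right_x_min = rb[1], right_y_min = rb[2],
    right_x_max = rb[3], right_y_max = rb[4]
  )

  list(fixations = fixations, layouts = layouts, trials = trials)
}

#' Simulate a complete study
#'
#' Roster plus gaze sessions under one configuration; the result conforms to
#' the file schemas and passes [validate_dataset()] with an empty report.
#'
#' @param config A `gp_sim_config`.
#' @return A list: `config`, all roster components, `fixations`, `layouts`,
#'   `trials`, and `truth` (with session bookkeeping added).
#' @export
simulate_study <- function(config) {
  cfg <- validate_sim_config(config)
  roster <- simulate_election_roster(cfg)
  gaze <- simulate_gaze_sessions(roster, cfg)
  truth <- roster$truth
  truth$n_sessions <- cfg$n_monkeys * cfg$sessions_per_monkey
  truth$n_session_blocks <- length(unique(gaze$fixations$session_id))
  c(list(config = cfg), roster[setdiff(names(roster), "truth")],
    gaze, list(truth = truth))
}

#' Exact expected accuracy of the fixation-count rule for one pair
#'
#' Analytic oracle: the expectation of (correct + 0.5 * tie) for a single
#' race under the generative gaze model, summing the Poisson fixation-count
#' distribution (truncated at cumulative mass 1 - 1e-12) against the
#' binomial side-allocation law, averaged over the two possible side
#' assignments of the pair.
#'
#' @param config A `gp_sim_config`.
#' @param pairs Optional tibble of pair attributes with columns
#'   `jaw_winner`, `jaw_loser`, `female_winner`, `female_loser`,
#'   `age_winner`, `age_loser`; `NULL` means a featureless pair (all
#'   attribute differences zero), leaving only the direct loser coefficient
#'   and side bias.
#' @return Numeric vector of expected accuracies, one per pair.
#' @export
analytic_pair_accuracy <- function(config, pairs = NULL) {
  cfg <- validate_sim_config(config)
  if (is.null(pairs)) {
    pairs <- tibble::tibble(jaw_winner = 0, jaw_loser = 0, female_winner = 0,
                            female_loser = 0, age_winner = 0, age_loser = 0)
  }
  eta0 <- cfg$alloc_direct_loser +
    cfg$alloc_jaw * (pairs$jaw_winner - pairs$jaw_loser) +
    cfg$alloc_female * (pairs$female_loser - pairs$female_winner) +
    cfg$alloc_age * (pairs$age_loser - pairs$age_winner) / 10
  p_mat <- cbind(plogis(cfg$side_bias + eta0), plogis(-cfg$side_bias + eta0))

  lambda <- cfg$mean_fixations
  n_max <- qpois(1 - 1e-12, lambda)
  acc <- matrix(0, nrow = nrow(p_mat), ncol = 2)
  for (n in 0:n_max) {
    w <- stats::dpois(n, lambda)
    if (n == 0) {
      acc <- acc + w * 0.5
      next
    }
    # correct iff the loser receives K > n/2 fixations; tie iff K = n/2
    p_correct <- 1 - pbinom(floor(n / 2), n, p_mat)
    p_tie <- if (n %% 2 == 0) stats::dbinom(n / 2, n, p_mat) else 0
    acc <- acc + w * (p_correct + 0.5 * p_tie)
  }
  # residual Poisson mass (< 1e-12) is scored as chance
  acc <- acc + (1 - ppois(n_max, lambda)) * 0.5
  rowMeans(acc)
}

#' Pair attributes of a roster, winner vs loser
#'
#' @param roster A roster from [simulate_election_roster()].
#' @return A tibble (one row per race) with the winner/loser jaw prominence,
#'   gender indicator, and age columns used by [analytic_pair_accuracy()].
#' @export
roster_pair_attributes <- function(roster) {
  df <- dplyr::left_join(
    roster$candidates[, c("candidate_id", "race_id", "gender", "winner",
                          "age")],
    roster$metrics_true[, c("candidate_id", "jaw_prominence")],
    by = "candidate_id"
  )
  w <- df[df$winner == 1, ]
  l <- df[df$winner == 0, ]
  w <- w[order(w$race_id), ]
  l <- l[order(l$race_id), ]
  tibble::tibble(
    race_id = w$race_id,
    jaw_winner = w$jaw_prominence, jaw_loser = l$jaw_prominence,
    female_winner = as.numeric(w$gender == "F"),
    female_loser = as.numeric(l$gender == "F"),
    age_winner = w$age, age_loser = l$age
  )
}

#' Calibrate the direct loser-allocation coefficient to a target accuracy
#'
#' Solves (by monotone root finding on the analytic oracle) for the
#' `alloc_direct_loser` value whose expected per-race fixation-count accuracy,
#' averaged over `pairs`, equals `target_accuracy`.
#'
#' @param config A `gp_sim_config`.
#' @param target_accuracy Expected per-race accuracy in (0, 1).
#' @param pairs Optional pair-attribute tibble (see
#'   [analytic_pair_accuracy()]).
#' @return The configuration with `alloc_direct_loser` set to the solution.
#' @export
calibrate_loser_allocation <- function(config, target_accuracy, pairs = NULL) {
  cfg <- validate_sim_config(config)
  if (target_accuracy <= 0 || target_accuracy >= 1) {
    gp_config_error("calibrate_loser_allocation: target must be in (0, 1)")
  }
  f <- function(theta) {
    cfg$alloc_direct_loser <- theta
    mean(analytic_pair_accuracy(cfg, pairs)) - target_accuracy
  }
  root <- uniroot(f, interval = c(-10, 10), tol = 1e-9)
  cfg$alloc_direct_loser <- root$root
  cfg
}

#' Expected jaw-prominence/vote-share correlation under a configuration
#'
#' Closed-form (delta-method) population Pearson correlation between a
#' candidate's jaw prominence and vote share implied by the generative
#' parameters: the jaw-prominence ratio is linearized around the population
#' mean measurements, vote-share variance is assembled from the beta-weighted
#' difference terms, and clipping is ignored (it is rare at the default noise
#' scales).
#'
#' @param config A `gp_sim_config`.
#' @return The expected correlation (scalar).
#' @export
expected_jaw_vote_r <- function(config) {
  cfg <- validate_sim_config(config)
  mom <- gp_jaw_moments(cfg)
  k <- cfg$beta_jaw + cfg$competence_slope_on_jaw * cfg$beta_competence

  n_off <- c(gubernatorial = cfg$n_gubernatorial,
             senatorial = cfg$n_senatorial,
             presidential = cfg$n_presidential)
  q_inc <- sum(cfg$p_incumbent[names(n_off)] * n_off) / sum(n_off)

  cov_js <- 0.5 * k * mom$var_j
  var_share <- 0.25 * (k^2 * 2 * mom$var_j +
                         cfg$beta_competence^2 * 2 * cfg$competence_noise_sd^2 +
                         cfg$beta_incumbent^2 * q_inc +
                         cfg$beta_age^2 * 2 * cfg$age_sd^2) +
    cfg$vote_noise_sd^2
  cov_js / sqrt(mom$var_j * var_share)
}

# Delta-method moments of jaw prominence under the configured loadings and
# gender mix.
gp_jaw_moments <- function(cfg) {
  if (cfg$gender_composition == "fixed") {
    comp <- gp_fixed_composition(
      cfg$n_gubernatorial + cfg$n_senatorial + cfg$n_presidential
    )
    p_f <- (comp["FM"] + 2 * comp["FF"]) / (2 * sum(comp))
  } else {
    p_f <- cfg$p_female
  }
  p_f <- unname(p_f)
  mu_m <- p_f * cfg$masc_mean_f + (1 - p_f) * cfg$masc_mean_m
  var_m <- cfg$masc_sd^2 +
    p_f * (1 - p_f) * (cfg$masc_mean_m - cfg$masc_mean_f)^2
  fl <- cfg$feature_loadings
  jw <- fl[fl$feature == "jaw_width", ]
  cw <- fl[fl$feature == "cheekbone_width", ]
  mu_jw <- jw$intercept + jw$slope * mu_m
  mu_cw <- cw$intercept + cw$slope * mu_m
  g_m <- jw$slope / mu_cw - mu_jw * cw$slope / mu_cw^2
  var_j <- g_m^2 * var_m + (jw$noise_sd / mu_cw)^2 +
    (mu_jw * cw$noise_sd / mu_cw^2)^2
  list(mu_j = mu_jw / mu_cw, var_j = var_j, p_f = p_f)
}

#' Calibrate the jaw vote coefficient to a target correlation
#'
#' Solves for `beta_jaw` such that [expected_jaw_vote_r()] equals `target_r`,
#' holding every other generative parameter fixed.
#'
#' @param config A `gp_sim_config`.
#' @param target_r Target population jaw-prominence/vote-share correlation.
#' @return The configuration with `beta_jaw` set to the solution.
#' @export
calibrate_jaw_effect <- function(config, target_r = 0.27) {
  cfg <- validate_sim_config(config)
  f <- function(b) {
    cfg$beta_jaw <- b
    expected_jaw_vote_r(cfg) - target_r
  }
  root <- uniroot(f, interval = c(0, 2000), tol = 1e-9)
  cfg$beta_jaw <- root$root
  cfg
}
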