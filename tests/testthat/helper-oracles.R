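# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles never call the package functions they check.

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# Exact two-sided rank-sum p by enumerating all group assignments.
exact_rank_sum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- utils::combn(length(r), nx)
  ws <- apply(cmb, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# Pearson r computed from explicit sums (no cor()).
hand_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# A 600x600-boxes-on-2560x1440 layout matching the generator's geometry.
test_layout <- function() {
  stimulus_layout(
    screen_w = 2560, screen_h = 1440,
    left_box = c(440, 420, 1040, 1020),
    right_box = c(1520, 420, 2120, 1020)
  )
}

test_layout_row <- function(session_id = "S1") {
  tibble::tibble(
    session_id = session_id,
    screen_w = 2560, screen_h = 1440,
    left_x_min = 440, left_y_min = 420, left_x_max = 1040, left_y_max = 1020,
    right_x_min = 1520, right_y_min = 420, right_x_max = 2120,
    right_y_max = 1020
  )
}

# Build a fixation tibble for one or more trials from a compact description:
# each element of `trials` is list(race, left, right, events) where events is
# a data.frame(onset, offset, x, y).
make_fixations <- function(trials, session_id = "S1", monkey_id = "M1",
                           office = "gubernatorial") {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    ev <- tr$events
    tibble::tibble(
      session_id = session_id, monkey_id = monkey_id, office = office,
      trial_index = i - 1, race_id = tr$race,
      left_candidate_id = tr$left, right_candidate_id = tr$right,
      onset_ms = ev$onset, offset_ms = ev$offset, x_px = ev$x, y_px = ev$y
    )
  })
  dplyr::bind_rows(rows)
}

# Minimal two-candidate election table builder.
make_elections <- function(race_ids, winners_first = TRUE,
                           office = "gubernatorial") {
  n <- length(race_ids)
  cand <- tibble::tibble(
    race_id = rep(race_ids, each = 2),
    office = office,
    year = 2000,
    state = "OH",
    candidate_id = paste0(rep(race_ids, each = 2), c("_a", "_b")),
    name = "x",
    gender = "M",
    birth_year = 1950,
    party = rep(c("D", "R"), n),
    incumbent = 0,
    vote_share_pct = rep(if (winners_first) c(55, 45) else c(45, 55), n),
    winner = rep(if (winners_first) c(1, 0) else c(0, 1), n),
    ref_presidential_margin_pct = 0,
    smile = 1, bald = 0, facial_hair = 0, glasses = 0
  )
  validate_elections(cand)
}

# The hand-verified landmark worked example: ipd 60, cheekbone width 120,
# jaw width 90, face height 150, lower face height 60.
worked_landmarks <- function() {
  tibble::tibble(
    candidate_id = "C1", rater_id = "r1",
    pupil_left_x = 40, pupil_left_y = 50,
    pupil_right_x = 100, pupil_right_y = 50,
    zygion_left_x = 10, zygion_left_y = 80,
    zygion_right_x = 130, zygion_right_y = 80,
    gonion_left_x = 25, gonion_left_y = 140,
    gonion_right_x = 115, gonion_right_y = 140,
    face_top_x = 70, face_top_y = 20,
    lower_face_top_x = 70, lower_face_top_y = 110,
    chin_bottom_x = 70, chin_bottom_y = 170
  )
}

# Small, fast simulation configuration for pipeline-level tests.
small_config <- function(seed = 42, ...) {
  sim_config(seed = seed, n_gubernatorial = 20L, n_senatorial = 10L,
             n_monkeys = 2L, sessions_per_monkey = 1L, ...)
}
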