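# Relating gaze and facial metrics to vote share and outcomes: correlations
# with Fisher-z confidence intervals, single-control partial correlations,
# the joint jaw + competence linear model, candidate age, state-lean
# classification, and stratified group summaries.

#' Correlation with 95% confidence interval
#'
#' Pearson's r (or Spearman's rho when normality cannot be assumed), with a
#' two-sided p-value and a 95% confidence interval from the Fisher
#' z-transform. For Spearman the same Fisher interval is applied to rho as a
#' large-sample approximation.
#'
#' @param x,y Equal-length numeric vectors, each non-constant, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list: `estimate`, `ci_lower`, `ci_upper`, `p_value`, `n`,
#'   `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    gp_validation_error("correlate: lengths differ")
  }
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) gp_degenerate_error("correlate: need n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    gp_degenerate_error("correlate: constant input vector")
  }
  ht <- suppressWarnings(cor.test(x, y, method = method))
  r <- unname(ht$estimate)
  ci <- gp_fisher_ci(r, n)
  list(estimate = r, ci_lower = ci[1], ci_upper = ci[2],
       p_value = unname(ht$p.value), n = n, method = method)
}

# Fisher z-transform 95% CI for a correlation; eff_n is the effective sample
# size entering the z standard error (n for plain, n - k for k controls).
gp_fisher_ci <- function(r, eff_n, level = 0.95) {
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  se <- 1 / sqrt(eff_n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Partial correlation with a single control variable
#'
#' Pearson correlation between the residuals of `x` on `control` and of `y`
#' on `control`, with a t-based p-value on n - 3 degrees of freedom and a
#' Fisher-z 95% confidence interval.
#'
#' @param x,y,control Equal-length numeric vectors, n >= 4.
#' @return A list: `estimate`, `ci_lower`, `ci_upper`, `p_value`, `n`, `df`.
#' @export
partial_correlate <- function(x, y, control) {
  keep <- complete.cases(x, y, control)
  x <- x[keep]
  y <- y[keep]
  control <- control[keep]
  n <- length(x)
  if (n < 4) gp_degenerate_error("partial_correlate: need n >= 4")
  if (sd(control) == 0) {
    gp_degenerate_error("partial_correlate: constant control variable")
  }
  rx <- resid(lm(x ~ control))
  ry <- resid(lm(y ~ control))
  rel_tol <- 1e-12
  if (stats::var(rx) < rel_tol * stats::var(x) ||
      stats::var(ry) < rel_tol * stats::var(y)) {
    gp_degenerate_error(
      "partial_correlate: control is collinear with x or y (residual variance ~ 0)"
    )
  }
  r <- cor(rx, ry)
  df <- n - 3
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df)
  ci <- gp_fisher_ci(r, n - 1) # one control uses up one observation of information
  list(estimate = r, ci_lower = ci[1], ci_upper = ci[2], p_value = p,
       n = n, df = df)
}

#' Joint linear model of vote share on jaw prominence and competence
#'
#' Ordinary least squares fit of vote share on an intercept, jaw prominence,
#' and perceived competence: the two-predictor model testing whether facial
#' masculinity and competence each uniquely contribute to vote share.
#'
#' @param vote_share Numeric response (percent).
#' @param jaw_prominence,competence Numeric predictors, not collinear.
#' @return A list: `intercept`, `coef_jaw`, `coef_competence`, their standard
#'   errors and 95% confidence intervals, `r_squared`, `n`.
#' @export
fit_joint_model <- function(vote_share, jaw_prominence, competence) {
  keep <- complete.cases(vote_share, jaw_prominence, competence)
  y <- vote_share[keep]
  j <- jaw_prominence[keep]
  c_ <- competence[keep]
  n <- length(y)
  if (n < 4) gp_degenerate_error("fit_joint_model: need n >= 4")
  if (sd(j) == 0 || sd(c_) == 0 || abs(cor(j, c_)) > 1 - 1e-10) {
    gp_degenerate_error("fit_joint_model: collinear or constant predictors")
  }
  fit <- lm(y ~ j + c_)
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  ci <- stats::confint(fit, level = 0.95)
  list(
    intercept = unname(cf[1]),
    coef_jaw = unname(cf["j"]),
    coef_competence = unname(cf["c_"]),
    se_jaw = unname(se["j"]),
    se_competence = unname(se["c_"]),
    ci_jaw = unname(ci["j", ]),
    ci_competence = unname(ci["c_", ]),
    r_squared = summary(fit)$r.squared,
    n = n
  )
}

#' Candidate age at election
#'
#' Election year minus birth year; errors on negative results.
#'
#' @param birth_year,election_year Calendar years (vectorized).
#' @return Integer ages in years.
#' @export
candidate_age <- function(birth_year, election_year) {
  age <- election_year - birth_year
  if (any(age < 0)) {
    gp_validation_error("candidate_age: birth year after election year")
  }
  age
}

#' Classify state lean from the reference presidential margin
#'
#' The margin is signed, positive = Republican. A state is a swing state iff
#' the absolute margin is strictly below 10 points; red iff margin >= 10;
#' blue iff margin <= -10. The three labels partition all finite margins.
#'
#' @param margin Signed percent margin (vectorized, finite).
#' @return Character vector in `c("blue", "swing", "red")`.
#' @export
classify_state_lean <- function(margin) {
  if (any(!is.finite(margin))) {
    gp_validation_error("classify_state_lean: margin must be finite")
  }
  dplyr::case_when(
    abs(margin) < 10 ~ "swing",
    margin >= 10 ~ "red",
    TRUE ~ "blue"
  )
}

#' Stratified group summary with contrasts
#'
#' Per-group mean, SEM, and n. With exactly two groups, a two-sided rank-sum
#' contrast; with three or more, a one-way analysis of variance followed by
#' Tukey's honestly-significant-difference pairwise comparisons.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector (same length); every level must be non-empty.
#' @return A list: `summary` tibble (`group`, `n`, `mean`, `sem`), `test`
#'   (`"rank_sum"` or `"anova"`), `p_value` (omnibus), and for >= 3 groups a
#'   `tukey` tibble of pairwise contrasts.
#' @export
stratified_summary <- function(values, group) {
  keep <- complete.cases(values, group)
  values <- values[keep]
  group <- as.factor(group[keep])
  counts <- table(group)
  if (any(counts == 0)) {
    gp_validation_error(sprintf(
      "stratified_summary: empty group '%s'", names(counts)[counts == 0][1]
    ))
  }
  summary_tbl <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(values = values, group = group),
                    .data$group),
    n = dplyr::n(),
    mean = mean(.data$values),
    sem = sd(.data$values) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  k <- nlevels(group)
  if (k < 2) {
    return(list(summary = summary_tbl, test = "none", p_value = NA_real_))
  }
  if (k == 2) {
    lv <- levels(group)
    ht <- unpaired_gaze_test(values[group == lv[1]], values[group == lv[2]])
    return(list(summary = summary_tbl, test = "rank_sum",
                p_value = ht$p_value))
  }
  fit <- aov(values ~ group)
  p_omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$group
  tukey <- tibble::tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"], ci_lower = tk[, "lwr"], ci_upper = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  list(summary = summary_tbl, test = "anova", p_value = p_omnibus,
       tukey = tukey)
}
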