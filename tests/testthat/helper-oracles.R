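# independent oracles: brute-force counterparts of the package's
# rank/searched-based routines, kept deliberately naive

# AUC as the all-pairs Mann-Whitney count: P(case > control) + 0.5 P(tie)
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

brute_se_sp <- function(scores, labels, cutoff) {
  flag <- scores >= cutoff
  c(se = sum(flag & labels == 1) / sum(labels == 1),
    sp = sum(!flag & labels == 0) / sum(labels == 0))
}

brute_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  c(u[1] - 0.5, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 0.5)
}

# exhaustive max(se + sp); first (smallest) maximizer on ties
brute_optimal <- function(scores, labels) {
  cands <- brute_cutoffs(scores)
  best <- cands[1]; bestj <- -Inf
  for (c in cands) {
    v <- brute_se_sp(scores, labels, c)
    if (v["se"] + v["sp"] > bestj + 1e-12) {
      bestj <- v["se"] + v["sp"]; best <- c
    }
  }
  best
}

brute_constrained <- function(scores, labels, constraint, level) {
  cands <- brute_cutoffs(scores)
  feas <- c()
  for (c in cands) {
    v <- brute_se_sp(scores, labels, c)
    ok <- if (constraint == "specificity") v["sp"] >= level else v["se"] >= level
    if (ok) feas <- c(feas, c)
  }
  if (length(feas) == 0) return(NA_real_)
  if (constraint == "specificity") min(feas) else max(feas)
}

# a toy individual table from explicit vectors, other columns zeroed
toy_table <- function(diabetic, sex = 0, age_band = 3, obese = 0, smoker = 0,
                      inactive = 0) {
  n <- length(diabetic)
  rep_out <- function(x) if (length(x) == 1) rep(x, n) else x
  as_individual_table(data.frame(
    id = seq_len(n), sex = rep_out(sex), age_band = rep_out(age_band),
    obese = rep_out(obese), smoker = rep_out(smoker),
    inactive = rep_out(inactive), diabetic = diabetic))
}

# the printed 2020 points definition, for hand-summed score checks
printed_score_2020 <- function() {
  score_definition(
    name = "printed 2020 score", year = 2020,
    covariables = list(
      sex = c(female = 0, male = 2),
      age_band = c("15-19" = 0, "20-24" = 6, "25-29" = 10, "30-34" = 10,
                   "35-39" = 14, "40-44" = 15, "45-49" = 18, "50-54" = 20,
                   "55-59" = 25, "60-64" = 25, "65-69" = 24, "70-74" = 26,
                   "75-79" = 24),
      obese = c("non-obese" = 0, obese = 14),
      smoker = c("non-smoker" = 0, smoker = 3),
      inactive = c(active = 0, inactive = 5)))
}

# printed (beta, points) pairs of the three yearly multivariable models;
# `half` marks rows where 10 * beta falls exactly on a half-integer, where
# the printed points reflect the unrounded fitted coefficient
printed_beta_points <- function() {
  mk <- function(year, beta, points) data.frame(year = year, beta = beta, points = points)
  tab <- rbind(
    mk(2020, c(0.59, 1.02, 0.97, 1.42, 1.54, 1.79, 2.02, 2.46, 2.46, 2.39, 2.62, 2.45,
               0.20, 1.40, 0.31, 0.53),
       c(6, 10, 10, 14, 15, 18, 20, 25, 25, 24, 26, 24, 2, 14, 3, 5)),
    mk(2030, c(0.42, 0.79, 0.88, 1.05, 1.33, 1.75, 1.96, 2.00, 2.37, 2.28, 2.36, 2.02,
               0.06, 1.39, 0.36, 0.42),
       c(4, 8, 9, 11, 13, 17, 20, 20, 24, 23, 24, 20, 1, 14, 4, 4)),
    mk(2050, c(0.05, 0.31, 0.70, 0.79, 1.25, 1.48, 1.72, 1.91, 1.88, 1.99, 1.77, 2.18,
               0.29, 1.48, 0.22, 0.37),
       c(1, 3, 7, 8, 12, 15, 17, 19, 19, 20, 18, 22, 3, 15, 2, 4)))
  tab$half <- abs(10 * tab$beta - floor(10 * tab$beta) - 0.5) < 1e-9
  tab
}
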