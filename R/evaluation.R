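check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
}

# tie-corrected Mann-Whitney AUC via midranks; equals the trapezoidal area
# under the empirical ROC curve
auc_mw <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# empirical ROC step curve: one point per distinct score threshold
roc_points <- function(scores, labels) {
  u <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tp <- vapply(u, function(c) sum(scores >= c & labels == 1), numeric(1))
  fp <- vapply(u, function(c) sum(scores >= c & labels == 0), numeric(1))
  data.frame(threshold = c(Inf, u),
             sensitivity = c(0, tp / n1),
             specificity = c(1, 1 - fp / n0))
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' The AUC is the tie-corrected Mann-Whitney statistic: the probability
#' that a randomly chosen diabetic scores above a randomly chosen
#' non-diabetic, ties counted one half. It equals the trapezoidal area
#' under the empirical ROC step curve. The confidence interval is a
#' stratified percentile bootstrap: cases and controls are resampled
#' separately, keeping class sizes fixed.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels 0/1 outcome, both classes present.
#' @param conf.level confidence level.
#' @param boot number of bootstrap resamples (0 skips the interval).
#' @param seed RNG seed for the bootstrap; fixed seed gives identical CIs.
#' @return object of class `roc_curve`: `auc`, `auc_ci`, `roc` (data frame
#'   of achievable sensitivity/specificity pairs), class counts.
#' @export
roc_auc <- function(scores, labels, conf.level = 0.95, boot = 2000, seed = 1L) {
  check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  auc <- auc_mw(scores, labels)
  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    cases <- scores[labels == 1]; controls <- scores[labels == 0]
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    reps <- vapply(seq_len(boot), function(i) {
      s <- c(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
      l <- rep(c(1, 0), c(length(cases), length(controls)))
      auc_mw(s, l)
    }, numeric(1))
    a <- (1 - conf.level) / 2
    ci <- unname(stats::quantile(reps, c(a, 1 - a), type = 7))
  }
  structure(list(auc = auc, auc_ci = ci, roc = roc_points(scores, labels),
                 n_cases = sum(labels == 1), n_controls = sum(labels == 0),
                 conf.level = conf.level, boot = boot, seed = seed),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f", x$auc))
  if (!anyNA(x$auc_ci)) cat(sprintf(" (%.0f%% CI %.3f-%.3f)", 100 * x$conf.level,
                                    x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf(" | %d cases, %d controls\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Confusion statistics at a score cut-off
#'
#' Classification rule: score >= cut-off is flagged as high risk. Returns
#' the confusion counts, sensitivity, specificity, PPV, NPV, and the
#' proportion flagged for testing, each with a Wilson score interval.
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcome.
#' @param cutoff decision threshold (half-integers between adjacent integer
#'   scores are typical).
#' @param conf.level confidence level for the Wilson intervals.
#' @return object of class `cutoff_confusion`.
#' @export
confusion_at <- function(scores, labels, cutoff, conf.level = 0.95) {
  check_two_classes(labels)
  flag <- scores >= cutoff
  tp <- sum(flag & labels == 1); fp <- sum(flag & labels == 0)
  fn <- sum(!flag & labels == 1); tn <- sum(!flag & labels == 0)
  n <- length(scores)
  prop <- function(x, m) if (m > 0) x / m else NA_real_
  structure(list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 sensitivity = prop(tp, tp + fn), specificity = prop(tn, tn + fp),
                 ppv = prop(tp, tp + fp), npv = prop(tn, tn + fn),
                 flagged = (tp + fp) / n, prevalence = (tp + fn) / n,
                 sensitivity_ci = wilson_ci(tp, tp + fn, conf.level),
                 specificity_ci = wilson_ci(tn, tn + fp, conf.level),
                 ppv_ci = wilson_ci(tp, tp + fp, conf.level),
                 npv_ci = wilson_ci(tn, tn + fn, conf.level),
                 flagged_ci = wilson_ci(tp + fp, n, conf.level),
                 conf.level = conf.level),
            class = "cutoff_confusion")
}

#' @export
print.cutoff_confusion <- function(x, ...) {
  pc <- function(v, ci) sprintf("%.1f%% (%.1f-%.1f)", 100 * v, 100 * ci[1], 100 * ci[2])
  cat(sprintf("Cut-off %.1f (flag: score >= cut-off), n = %d, prevalence %.1f%%\n",
              x$cutoff, x$n, 100 * x$prevalence))
  cat("  sensitivity ", pc(x$sensitivity, x$sensitivity_ci),
      " | specificity ", pc(x$specificity, x$specificity_ci), "\n", sep = "")
  cat("  PPV ", pc(x$ppv, x$ppv_ci), " | NPV ", pc(x$npv, x$npv_ci), "\n", sep = "")
  cat("  proportion needing testing ", pc(x$flagged, x$flagged_ci), "\n", sep = "")
  invisible(x)
}

# candidate cut-offs: midpoints between adjacent distinct scores plus one
# beyond each extreme (so "flag everyone" and "flag no one" are reachable)
candidate_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  c(u[1] - 0.5, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 0.5)
}

#' Optimal cut-off maximizing sensitivity + specificity
#'
#' Evaluates every achievable cut-off (midpoints between adjacent distinct
#' observed scores, plus one beyond each extreme) and returns the one
#' maximizing the Youden-style sum of sensitivity and specificity. Ties are
#' broken toward the smallest cut-off, favouring sensitivity in the
#' screening context.
#'
#' @inheritParams confusion_at
#' @return a `cutoff_confusion` with attribute `policy = "max-se-sp"`.
#' @export
optimal_cutoff <- function(scores, labels, conf.level = 0.95) {
  check_two_classes(labels)
  cands <- candidate_cutoffs(scores)
  j <- vapply(cands, function(c) {
    flag <- scores >= c
    sum(flag & labels == 1) / sum(labels == 1) +
      sum(!flag & labels == 0) / sum(labels == 0)
  }, numeric(1))
  best <- cands[which.max(j)] # which.max takes the first (smallest) maximizer
  out <- confusion_at(scores, labels, best, conf.level)
  attr(out, "policy") <- "max-se-sp"
  out
}

#' Cut-off under a sensitivity or specificity constraint
#'
#' For `specificity >= level`: the smallest cut-off meeting the constraint
#' (specificity is non-decreasing in the cut-off, so this maximizes
#' sensitivity subject to it). For `sensitivity >= level`: the largest
#' cut-off meeting it (sensitivity is non-increasing, so this maximizes
#' specificity). Errors, reporting the best achievable value, if no cut-off
#' satisfies the constraint.
#'
#' @inheritParams confusion_at
#' @param constraint which operating characteristic is constrained.
#' @param level required minimum, in (0, 1); `0` degenerates to the extreme
#'   cut-off.
#' @return a `cutoff_confusion` with a `policy` attribute such as
#'   `"sp-ge:0.9"`; also reports the missed-case fraction `1 - sensitivity`
#'   via the returned sensitivity.
#' @export
constrained_cutoff <- function(scores, labels,
                               constraint = c("specificity", "sensitivity"),
                               level, conf.level = 0.95) {
  check_two_classes(labels)
  constraint <- match.arg(constraint)
  if (level < 0 || level >= 1) stop("'level' must lie in [0, 1)", call. = FALSE)
  cands <- candidate_cutoffs(scores)
  vals <- vapply(cands, function(c) {
    flag <- scores >= c
    if (constraint == "specificity") sum(!flag & labels == 0) / sum(labels == 0)
    else sum(flag & labels == 1) / sum(labels == 1)
  }, numeric(1))
  ok <- vals >= level
  if (!any(ok)) {
    stop(sprintf("no cut-off achieves %s >= %.3f (best achievable: %.3f)",
                 constraint, level, max(vals)), call. = FALSE)
  }
  best <- if (constraint == "specificity") min(cands[ok]) else max(cands[ok])
  out <- confusion_at(scores, labels, best, conf.level)
  attr(out, "policy") <- sprintf("%s-ge:%g", substr(constraint, 1, 2), level)
  out
}

#' Predictive values and testing proportion from test characteristics
#'
#' Analytic identities linking sensitivity, specificity, and prevalence:
#' `PPV = se p / (se p + (1 - sp)(1 - p))`,
#' `NPV = sp (1 - p) / (sp (1 - p) + (1 - se) p)`, and the proportion
#' flagged for testing `pi = se p + (1 - sp)(1 - p)`. A 0/0 ratio is
#' reported as `NA` (not estimable).
#'
#' @param sensitivity,specificity,prevalence proportions in `[0, 1]`.
#' @return list with `ppv`, `npv`, `flagged`.
#' @examples
#' # high-risk screening at ~19% prevalence
#' predictive_values(0.790, 0.668, 0.192)
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  for (v in c(sensitivity, specificity, prevalence)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("sensitivity, specificity and prevalence must lie in [0, 1]", call. = FALSE)
    }
  }
  se <- sensitivity; sp <- specificity; p <- prevalence
  flagged <- se * p + (1 - sp) * (1 - p)
  ppv <- if (flagged > 0) se * p / flagged else NA_real_
  nflag <- sp * (1 - p) + (1 - se) * p
  npv <- if (nflag > 0) sp * (1 - p) / nflag else NA_real_
  list(ppv = ppv, npv = npv, flagged = flagged)
}

#' Testing yield per population stratum
#'
#' The yield is the number of individuals that must be tested in a stratum
#' to find one diabetes case: the inverse of the stratum's diabetes
#' prevalence. Works on an individual table (counting rows) or directly on
#' a `compartment_state` (weighting by occupancy). Strata with no diabetes
#' are flagged not-estimable; empty strata are skipped with a warning.
#'
#' @param x an `individual_table` or `compartment_state`.
#' @param by grouping columns among `sex`, `age_band`, `obese`, `smoker`,
#'   `inactive` (e.g. `c("sex", "age_band", "obese")` for the
#'   single-factor-by-age view).
#' @param ... unused.
#' @return data frame with the grouping columns, `n`, `cases`,
#'   `prevalence`, `yield`, and logical `estimable`.
#' @export
testing_yield <- function(x, by = c("sex", "age_band"), ...) UseMethod("testing_yield")

yield_from_counts <- function(df, by) {
  bad <- setdiff(by, c("sex", "age_band", "obese", "smoker", "inactive"))
  if (length(bad)) stop("cannot stratify by: ", paste(bad, collapse = ", "), call. = FALSE)
  key <- interaction(df[by], drop = FALSE, lex.order = TRUE)
  tot <- tapply(df$.w, key, sum)
  cas <- tapply(df$.w * df$diabetic, key, sum)
  keys <- do.call(rbind, strsplit(names(tot), ".", fixed = TRUE))
  out <- as.data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  for (cl in by) out[[cl]] <- as.integer(out[[cl]])
  out$n <- as.numeric(tot); out$cases <- as.numeric(cas)
  empty <- is.na(out$n) | out$n == 0
  if (any(empty)) {
    warning(sprintf("%d empty stratum/strata skipped", sum(empty)))
    out <- out[!empty, , drop = FALSE]
  }
  out$prevalence <- out$cases / out$n
  out$estimable <- out$prevalence > 0
  out$yield <- ifelse(out$estimable, 1 / out$prevalence, NA_real_)
  rownames(out) <- NULL
  out
}

#' @rdname testing_yield
#' @export
testing_yield.individual_table <- function(x, by = c("sex", "age_band"), ...) {
  df <- as.data.frame(x)
  df$.w <- 1
  yield_from_counts(df, by)
}

#' @rdname testing_yield
#' @export
testing_yield.compartment_state <- function(x, by = c("sex", "age_band"), ...) {
  df <- as.data.frame(x)
  df$.w <- df$count
  yield_from_counts(df, by)
}

#' Full diagnostic performance report for a scored table
#'
#' Ties together ROC/AUC, cut-off choice under a stated policy, and the
#' confusion statistics at that cut-off — one row of the conventional
#' score-performance table.
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcome.
#' @param policy `"max-se-sp"` (default, maximize sensitivity +
#'   specificity), `"sp-ge"` or `"se-ge"` with `level` giving the
#'   constraint.
#' @param level constraint level for the constrained policies.
#' @param boot,seed,conf.level bootstrap settings for the AUC interval, as
#'   in [roc_auc()].
#' @return object of class `performance_report`: `roc` (a `roc_curve`),
#'   `confusion` (a `cutoff_confusion`), `policy`.
#' @export
score_performance <- function(scores, labels, policy = c("max-se-sp", "sp-ge", "se-ge"),
                              level = 0.9, boot = 2000, seed = 1L, conf.level = 0.95) {
  policy <- match.arg(policy)
  roc <- roc_auc(scores, labels, conf.level = conf.level, boot = boot, seed = seed)
  confusion <- switch(policy,
                      "max-se-sp" = optimal_cutoff(scores, labels, conf.level),
                      "sp-ge" = constrained_cutoff(scores, labels, "specificity", level, conf.level),
                      "se-ge" = constrained_cutoff(scores, labels, "sensitivity", level, conf.level))
  structure(list(roc = roc, confusion = confusion,
                 policy = attr(confusion, "policy")),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  print(x$roc)
  cat(sprintf("Cut-off policy: %s\n", x$policy))
  print(x$confusion)
  invisible(x)
}

#' @describeIn score_performance ROC curve plot with the AUC in the legend.
#' @param x a `performance_report`.
#' @export
plot.performance_report <- function(x, ...) {
  r <- x$roc$roc
  graphics::plot(1 - r$specificity, r$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::points(1 - x$confusion$specificity, x$confusion$sensitivity, pch = 19)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$roc$auc))
  invisible(x)
}

#' One-row summary of a performance report
#'
#' @param report a `performance_report`.
#' @param name row label.
#' @return one-row data frame mirroring the conventional performance-table
#'   columns (AUC with CI, sensitivity, specificity, PPV, NPV, cut-off,
#'   proportion needing testing).
#' @export
performance_row <- function(report, name = "score") {
  cc <- report$confusion
  data.frame(score = name,
             auc = report$roc$auc,
             auc_lo = report$roc$auc_ci[1], auc_hi = report$roc$auc_ci[2],
             sensitivity = cc$sensitivity, specificity = cc$specificity,
             ppv = cc$ppv, npv = cc$npv, cutoff = cc$cutoff,
             proportion_tested = cc$flagged,
             stringsAsFactors = FALSE)
}

#' Compare several score definitions on one sample
#'
#' Applies each definition to the table — restricted to the covariables the
#' table shares with the definition — re-optimizes its cut-off by maximum
#' sensitivity + specificity, and reports AUC, sensitivity and specificity
#' per score: the cross-score comparison layout.
#'
#' @param table an `individual_table`.
#' @param definitions a list of `score_definition`s (named or using each
#'   definition's own name).
#' @param boot,seed bootstrap settings for the AUC intervals.
#' @return data frame with one row per definition.
#' @export
compare_scores <- function(table, definitions, boot = 2000, seed = 1L) {
  stopifnot(inherits(table, "individual_table"))
  if (inherits(definitions, "score_definition")) definitions <- list(definitions)
  nms <- names(definitions)
  if (is.null(nms)) nms <- vapply(definitions, function(d) d$name, character(1))
  rows <- lapply(seq_along(definitions), function(i) {
    def <- definitions[[i]]
    shared <- intersect(names(def$covariables), covariable_names())
    if (length(shared) == 0) {
      stop(sprintf("definition '%s' shares no covariables with the table", def$name),
           call. = FALSE)
    }
    if (length(shared) < length(def$covariables)) {
      def$covariables <- def$covariables[shared]
    }
    sc <- apply_score(table, def)
    rep <- score_performance(sc, table$diabetic, boot = boot, seed = seed)
    performance_row(rep, nms[i])
  })
  do.call(rbind, rows)
}
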