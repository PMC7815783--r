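test_that("AUC handles the canonical toy cases", {
  # perfectly ordered by label
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), boot = 0)$auc, 1.0)
  # ties only
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5), boot = 0)$auc, 0.5)
  # 4 case-control pairs by hand: 3 wins + 1 loss out of 4
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1), boot = 0)$auc, 0.75)
  expect_error(roc_auc(1:5, rep(1, 5), boot = 0), "both")
})

test_that("AUC equals the all-pairs Mann-Whitney count and pROC agrees", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(20:300, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n, mean = 2 * labels), 1) # heavy ties
    expect_equal(roc_auc(scores, labels, boot = 0)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # independent library cross-check on one table
  labels <- rbinom(400, 1, 0.25)
  scores <- rpois(400, lambda = 8 + 6 * labels)
  expect_equal(roc_auc(scores, labels, boot = 0)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("the ROC curve is a step curve from (0,0) to (1,1) matching the AUC", {
  set.seed(5)
  labels <- rbinom(200, 1, 0.3)
  scores <- rpois(200, 4 + 3 * labels)
  r <- roc_auc(scores, labels, boot = 0)
  fpr <- 1 - r$roc$specificity; tpr <- r$roc$sensitivity
  expect_equal(c(fpr[1], tpr[1]), c(0, 0))
  expect_equal(c(fpr[length(fpr)], tpr[length(tpr)]), c(1, 1))
  expect_true(all(diff(fpr) >= 0) && all(diff(tpr) >= 0))
  trapezoid <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  expect_equal(trapezoid, r$auc, tolerance = 1e-12)
})

test_that("optimal cut-off maximizes se + sp with the smallest-cutoff tie-break", {
  cc <- optimal_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(cc$cutoff, 2.5)
  expect_equal(cc$sensitivity, 1)
  expect_equal(cc$specificity, 1)

  # uninformative constant score: se + sp = 1 everywhere, lowest midpoint wins
  flat <- optimal_cutoff(rep(3, 20), rep(c(0, 1), 10))
  expect_equal(flat$cutoff, 2.5)
  expect_equal(flat$sensitivity + flat$specificity, 1)

  # tied scores across classes, verified against exhaustive search
  s <- c(1, 1, 2, 3); l <- c(0, 1, 0, 1)
  expect_equal(optimal_cutoff(s, l)$cutoff, brute_optimal(s, l))
})

test_that("optimal and constrained cut-offs match exhaustive search on random tables", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(30:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.15, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- rpois(n, 6 + 4 * labels)
    expect_equal(optimal_cutoff(scores, labels)$cutoff, brute_optimal(scores, labels))
    want <- brute_constrained(scores, labels, "specificity", 0.9)
    if (!is.na(want)) {
      got <- constrained_cutoff(scores, labels, "specificity", 0.9)
      expect_equal(got$cutoff, want)
      expect_gte(got$specificity, 0.9)
    }
  }
})

test_that("constrained cut-offs honour their contracts", {
  scores <- c(1, 2, 3, 4); labels <- c(0, 0, 1, 1)
  # level 0 degenerates to the extreme cut-offs
  expect_equal(constrained_cutoff(scores, labels, "specificity", 0)$cutoff, 0.5)
  expect_equal(constrained_cutoff(scores, labels, "sensitivity", 0)$cutoff, 4.5)
  # perfect separation: the sp >= 0.9 cut-off coincides with the optimum
  expect_equal(constrained_cutoff(scores, labels, "specificity", 0.9)$cutoff,
               optimal_cutoff(scores, labels)$cutoff)
  # with the beyond-extreme candidates, se >= 0.99 resolves to flag-everyone
  flat <- constrained_cutoff(rep(1, 10), rep(c(0, 1), 5), "sensitivity", 0.99)
  expect_equal(flat$sensitivity, 1)
  expect_equal(flat$flagged, 1)

  # 1000-row synthetic table: returned sp >= 0.9 and minimal among feasible
  tab <- generate_individuals(builtin_fixture(2020, n = 1000, seed = 8))
  sc <- apply_score(tab, printed_score_2020())
  got <- constrained_cutoff(sc, tab$diabetic, "specificity", 0.9)
  expect_gte(got$specificity, 0.9)
  expect_equal(got$cutoff, brute_constrained(sc, tab$diabetic, "specificity", 0.9))
})

test_that("confusion output satisfies the exact analytic identities", {
  set.seed(13)
  labels <- rbinom(500, 1, 0.2)
  scores <- rpois(500, 5 + 4 * labels)
  for (c in c(3.5, 6.5, 9.5)) {
    cc <- confusion_at(scores, labels, c)
    p <- cc$prevalence
    expect_equal(cc$flagged,
                 cc$sensitivity * p + (1 - cc$specificity) * (1 - p), tolerance = 1e-12)
    pv <- predictive_values(cc$sensitivity, cc$specificity, p)
    expect_equal(pv$ppv, cc$ppv, tolerance = 1e-12)
    expect_equal(pv$npv, cc$npv, tolerance = 1e-12)
    expect_equal(pv$flagged, cc$flagged, tolerance = 1e-12)
  }
  # the flagged proportion is non-increasing in the cut-off
  cuts <- sort(unique(scores)) + 0.5
  flags <- vapply(cuts, function(c) confusion_at(scores, labels, c)$flagged, numeric(1))
  expect_true(all(diff(flags) <= 0))
})

test_that("predictive values reproduce hand and boundary cases", {
  pv <- predictive_values(1, 1, 0.3)
  expect_equal(c(pv$ppv, pv$npv, pv$flagged), c(1, 1, 0.3))
  # 0/0: nothing flagged
  expect_true(is.na(predictive_values(0, 1, 0.5)$ppv))
  expect_error(predictive_values(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("testing yields are inverse stratum prevalences", {
  # hand-built stratum: 3 diabetic of 79
  tab <- toy_table(diabetic = rep(c(1, 0), c(3, 76)), sex = 0, age_band = 3, obese = 1)
  y <- testing_yield(tab, by = c("sex", "age_band"))
  expect_equal(y$yield, 79 / 3, tolerance = 1e-12)
  expect_equal(round(y$yield, 1), 26.3)

  # p = 0.5 and p = 1
  tab2 <- toy_table(diabetic = c(1, 0, 1, 1), age_band = c(3, 3, 4, 4))
  y2 <- testing_yield(tab2, by = "age_band")
  expect_equal(y2$yield[y2$age_band == 3], 2.0)
  expect_equal(y2$yield[y2$age_band == 4], 1.0)

  # not-estimable stratum flagged, not dropped
  tab3 <- toy_table(diabetic = c(0, 0, 1), age_band = c(5, 5, 6))
  y3 <- testing_yield(tab3, by = "age_band")
  expect_false(y3$estimable[y3$age_band == 5])
  expect_true(is.na(y3$yield[y3$age_band == 5]))

  # occupancy-weighted yields from a compartment state match hand arithmetic
  counts <- array(0, dim = c(2L, 20L, 2L, 2L, 2L, 2L))
  counts[1, 4, 2, 1, 1, 2] <- 3; counts[1, 4, 2, 1, 1, 1] <- 76
  st <- compartment_state(2020, counts)
  suppressWarnings(ys <- testing_yield(st, by = c("sex", "age_band", "obese")))
  hit <- ys[ys$sex == 0 & ys$age_band == 3 & ys$obese == 1, ]
  expect_equal(hit$yield, 79 / 3, tolerance = 1e-12)
})

test_that("bootstrap AUC intervals are seed-deterministic and cover the point", {
  tab <- generate_individuals(builtin_fixture(2020, n = 1500, seed = 17))
  sc <- apply_score(tab, printed_score_2020())
  r1 <- roc_auc(sc, tab$diabetic, boot = 400, seed = 7)
  r2 <- roc_auc(sc, tab$diabetic, boot = 400, seed = 7)
  r3 <- roc_auc(sc, tab$diabetic, boot = 400, seed = 8)
  expect_identical(r1$auc_ci, r2$auc_ci)
  expect_false(identical(r1$auc_ci, r3$auc_ci))
  expect_true(r1$auc_ci[1] <= r1$auc && r1$auc <= r1$auc_ci[2])
})

test_that("compare_scores reproduces itself and ranks nested scores sanely", {
  tab <- generate_individuals(builtin_fixture(2020, n = 3000, seed = 23))
  full <- printed_score_2020()
  obesity_only <- score_definition("obesity only",
                                   list(obese = c("non-obese" = 0, obese = 1)))
  zero <- score_definition("all zero", list(obese = c("non-obese" = 0, obese = 0)))
  cmp <- compare_scores(tab, list(full, full, obesity_only, zero), boot = 100, seed = 3)
  expect_equal(cmp[1, -1], cmp[2, -1], ignore_attr = TRUE) # identical rows
  expect_gte(cmp$auc[1], cmp$auc[3]) # full linear predictor beats one covariable
  expect_equal(cmp$auc[4], 0.5)      # uninformative score
  expect_identical(names(cmp)[1:2], c("score", "auc"))
})

test_that("score_performance ties ROC, policy and confusion together", {
  tab <- generate_individuals(builtin_fixture(2020, n = 2000, seed = 29))
  sc <- apply_score(tab, printed_score_2020())
  rep1 <- score_performance(sc, tab$diabetic, boot = 100, seed = 2)
  expect_s3_class(rep1, "performance_report")
  expect_identical(rep1$policy, "max-se-sp")
  expect_equal(rep1$confusion$cutoff, optimal_cutoff(sc, tab$diabetic)$cutoff)
  rep2 <- score_performance(sc, tab$diabetic, policy = "sp-ge", level = 0.9,
                            boot = 0)
  expect_gte(rep2$confusion$specificity, 0.9)
  row <- performance_row(rep1, "x")
  expect_identical(nrow(row), 1L)
  expect_true(all(c("auc", "cutoff", "proportion_tested") %in% names(row)))
})
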