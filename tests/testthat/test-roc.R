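test_that("ROC vertices collapse ties and span (0,0) to (1,1)", {
  roc <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_s3_class(roc, "cp_roc")
  expect_equal(roc$points$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(roc$points$tpr, c(0, 0.5, 1, 1, 1))
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))

  # complete ties: the diagonal segment
  tied <- roc_curve(rep(2, 6), c(1, 0, 1, 0, 0, 1))
  expect_equal(tied$points$fpr, c(0, 1))
  expect_equal(tied$points$tpr, c(0, 1))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "event and a non-event")
  expect_error(roc_curve(c(1, NA), c(0, 1)), "finite")
})

test_that("trapezoidal area, rank statistic and pair counting agree", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- sample(4:12, 1)
      # coarse alphabet forces heavy ties
      scores <- sample(1:4, n, replace = TRUE)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      expect_equal(auc(scores, labels),
                   roc_curve(scores, labels)$auc, tolerance = 1e-12)
      expect_identical(auc(scores, labels),
                       auc_pair_oracle(scores, labels))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    scores <- rnorm(80)
    labels <- rbinom(80, 1, plogis(scores))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
  })
})

test_that("AUC is invariant to increasing transforms and flips under negation", {
  withr::with_seed(11, {
    scores <- rnorm(50)
    labels <- c(1, 0, rbinom(48, 1, 0.4))
    a <- auc(scores, labels)
    expect_identical(auc(exp(scores), labels), a)
    expect_true(auc_scale_invariance_check(scores, labels, 7.3))
    expect_true(auc_scale_invariance_check(scores, labels, 1))
    expect_equal(auc(-scores, labels), 1 - a, tolerance = 1e-12)
    expect_error(auc_scale_invariance_check(scores, labels, -1), "positive")
  })
})

test_that("Youden threshold matches exhaustive search with documented tie-breaks", {
  # perfect separation: smallest score achieving J = 1
  roc <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(optimal_threshold(roc), 3)
  m <- classification_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1), 3)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  # degenerate diagonal warns
  expect_warning(optimal_threshold(roc_curve(rep(1, 4), c(0, 1, 0, 1))),
                 "diagonal")

  withr::with_seed(13, {
    for (rep in 1:40) {
      n <- sample(8:20, 1)
      scores <- round(runif(n, 0, 10), 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
      roc <- roc_curve(scores, labels)
      expect_equal(optimal_threshold(roc), youden_oracle(scores, labels))
    }
  })
})

test_that("classification metrics are hand-countable fractions", {
  scores <- c(10, 20, 30, 40, 50, 60, 70, 80)
  labels <- c(0, 0, 0, 1, 0, 1, 1, 1)
  m <- classification_metrics(scores, labels, 45)
  # at threshold 45: TP 3, FN 1, TN 4, FP 0... recount: predicted positive
  # are 50,60,70,80 -> TP {60,70,80}=3, FP {50}=1, TN {10,20,30}=3, FN {40}=1
  expect_equal(m[, c("tp", "fp", "tn", "fn")],
               tibble::tibble(tp = 3L, fp = 1L, tn = 3L, fn = 1L))
  expect_equal(m$accuracy, 6 / 8)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 3 / 4)

  low <- classification_metrics(scores, labels, 0)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
})

test_that("bootstrap CI is seeded, ordered, and degenerate when separation is perfect", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  ci <- auc_ci(scores, labels, reps = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))

  withr::with_seed(3, {
    s <- rnorm(60)
    l <- c(1, 0, rbinom(58, 1, 0.3))
  })
  a <- auc_ci(s, l, reps = 300, seed = 8)
  b <- auc_ci(s, l, reps = 300, seed = 8)
  expect_identical(a, b)
  expect_lte(a[["low"]], a[["high"]])
  expect_lte(a[["low"]], auc(s, l))
  expect_gte(a[["high"]], auc(s, l))
  expect_error(auc_ci(s, l, reps = 50), "at least 100")
})

test_that("bootstrap interval covers the null AUC at roughly nominal rate", {
  covered <- withr::with_seed(77, {
    vapply(1:20, function(i) {
      s <- rnorm(200)
      l <- rep(c(0, 1), 100)
      ci <- auc_ci(s, l, reps = 200, seed = i)
      ci[["low"]] <= 0.5 && 0.5 <= ci[["high"]]
    }, logical(1))
  })
  expect_gte(sum(covered), 16)
})

test_that("cohort evaluation bundles AUC, threshold and metrics coherently", {
  cohort <- generate_cohort(simulation_config(n = 400, seed = 15))
  ev <- evaluate_cohort(cohort, published_weights, reps = 200, seed = 2)
  g <- glance(ev)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$auc,
               auc(con_perform_score(cohort$age, cohort$heart_rate,
                                     cohort$pao2, published_weights),
                   cohort$died_30d))
  expect_true(g$auc_low <= g$auc && g$auc <= g$auc_high)
  expect_true(all(unlist(g[, c("accuracy", "sensitivity", "specificity")]) >= 0))
  expect_true(all(unlist(g[, c("accuracy", "sensitivity", "specificity")]) <= 1))
  # the discrete comparator runs through the same interface
  evd <- evaluate_cohort(cohort, weights = NULL, ci = FALSE)
  expect_equal(evd$score, "PERFORM")
  expect_true(evd$threshold %in% 0:12)
  # tidy() returns the ROC polyline
  expect_named(tidy(ev), c("threshold", "fpr", "tpr"))
})
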