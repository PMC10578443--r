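test_that("metric identities and edge conventions hold", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(m[c("accuracy", "f1", "precision", "recall",
                          "roc_auc")]), c(1, 1, 1, 1, 1))
  # no positive predictions: precision and F1 are 0 by convention
  m0 <- compute_metrics(c(0.1, 0.2, 0.3), c(0, 1, 0))
  expect_identical(unname(m0[c("precision", "recall", "f1")]), c(0, 0, 0))
  # F1 harmonic-mean identity on a mixed case
  mm <- compute_metrics(c(0.9, 0.4, 0.8, 0.2, 0.7), c(1, 1, 0, 0, 1))
  p <- mm[["precision"]]; r <- mm[["recall"]]
  expect_equal(mm[["f1"]], 2 * p * r / (p + r))
})

test_that("AUC equals pairwise concordance and is monotone-invariant", {
  set.seed(8)
  scores <- c(0.1, 0.4, 0.4, 0.6, 0.8, 0.95)
  labels <- c(0, 0, 1, 0, 1, 1)
  expect_equal(e4episodes:::auc_rank(scores, labels),
               oracle_auc(scores, labels))
  sweep <- roc_threshold_sweep(scores, labels)
  expect_equal(sweep$auc, oracle_auc(scores, labels))
  # strictly monotone transform leaves AUC unchanged
  expect_equal(e4episodes:::auc_rank(qlogis(scores), labels),
               e4episodes:::auc_rank(scores, labels))
  # independent implementation cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    s2 <- runif(40); l2 <- rbinom(40, 1, 0.4)
    expect_equal(e4episodes:::auc_rank(s2, l2),
                 as.numeric(pROC::auc(pROC::roc(l2, s2, quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1)))))
  }
})

test_that("ROC sweep reports operating points at recall targets", {
  sweep <- roc_threshold_sweep(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                               c(1, 1, 1, 0, 0, 0))
  expect_equal(sweep$auc, 1)
  expect_equal(sweep$operating_points$fpr[
    sweep$operating_points$recall_target == 0.9], 0)
  expect_error(roc_threshold_sweep(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("random split plans partition rows across outer test folds", {
  tbl <- make_feature_tbl(n = 100, seed = 9)
  plan <- make_split_plan(tbl, "random", seed = 2, n_folds = 10)
  test_idx <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_identical(sort(test_idx), seq_len(100))           # each row once
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_identical(sort(c(f$train, f$test)), seq_len(100))
  }
})

test_that("participant plans are leave-one-subject-out", {
  tbl <- make_feature_tbl(n = 100, n_participants = 8, seed = 10)
  plan <- make_split_plan(tbl, "participant", seed = 1)
  expect_length(plan$folds, 8)
  for (f in plan$folds) {
    expect_identical(unique(tbl$participant[f$test]), f$participant)
    expect_false(f$participant %in% tbl$participant[f$train])
  }
  few <- tbl[tbl$participant %in% unique(tbl$participant)[1:2], ]
  expect_error(make_split_plan(few, "participant"), ">= 3 participants")
})

test_that("temporal plans split 75/12.5/12.5 by observation day", {
  # a 40-day participant: train days 0-29, validation 30-34, test 35-39
  sp <- e4episodes:::split_days_751212(0:39)
  expect_identical(sp$train, 0:29)
  expect_identical(sp$validation, 30:34)
  expect_identical(sp$test, 35:39)
  # 8 days: boundaries round so validation and test stay non-empty
  sp8 <- e4episodes:::split_days_751212(0:7)
  expect_identical(sp8$train, 0:5)
  expect_identical(sp8$validation, 6L)
  expect_identical(sp8$test, 7L)

  tbl <- make_feature_tbl(n = 200, n_participants = 3, n_days = 16, seed = 11)
  plan <- make_split_plan(tbl, "temporal", seed = 1, n_reps = 10)
  expect_length(plan$folds, 10)
  f <- plan$folds[[1]]
  # per-participant temporal ordering: max train day < min val <= min test
  for (p in unique(tbl$participant)) {
    trd <- tbl$day_index[intersect(f$train, which(tbl$participant == p))]
    vad <- tbl$day_index[intersect(f$validation, which(tbl$participant == p))]
    ted <- tbl$day_index[intersect(f$test, which(tbl$participant == p))]
    if (length(vad)) expect_lt(max(trd), min(vad))
    if (length(ted) && length(vad)) expect_lte(min(vad), min(ted))
  }
  expect_length(intersect(f$train, c(f$validation, f$test)), 0)
  # the hold-out is identical across repetitions
  expect_identical(plan$folds[[1]]$test, plan$folds[[10]]$test)
})

test_that("personalized plans skip participants with few observation days", {
  tbl <- make_feature_tbl(n = 150, n_participants = 3, n_days = 12, seed = 12)
  tbl$day_index[tbl$participant == "P01"] <-
    tbl$day_index[tbl$participant == "P01"] %% 4  # < 8 distinct days
  expect_message(
    plan <- make_split_plan(tbl, "personalized", seed = 1, n_reps = 3),
    "skipping participant P01")
  expect_true(all(vapply(plan$folds, `[[`, "", "participant") != "P01"))
})

test_that("nested CV selects by inner accuracy and weights participant folds", {
  tbl <- make_feature_tbl(n = 140, n_participants = 4, signal_strength = 3,
                          seed = 13)
  plan <- make_split_plan(tbl, "random", seed = 3, n_folds = 4)
  res <- run_nested_cv(tbl, plan, models = c("lr", "rf"),
                       grids = list(lr = data.frame(lambda = 1e-3),
                                    rf = data.frame(num_trees = 100, mtry = 3)),
                       seed = 5, inner_k = 3)
  expect_identical(nrow(res$folds), 4L)
  expect_true(all(res$folds$model %in% c("lr", "rf")))
  expect_true(all(res$summary$mean[res$summary$metric != "baseline"] >= 0))
  # a strong signal is learned
  acc <- res$summary$mean[res$summary$metric == "accuracy"]
  base <- res$summary$mean[res$summary$metric == "baseline"]
  expect_gt(acc, base)

  pplan <- make_split_plan(tbl, "participant", seed = 3)
  pres <- run_nested_cv(tbl, pplan, models = "rf",
                        grids = list(rf = data.frame(num_trees = 100, mtry = 3)),
                        seed = 5)
  w <- pres$folds$n_test / sum(pres$folds$n_test)
  expect_equal(sum(w), 1)
  expect_equal(pres$summary$mean[pres$summary$metric == "accuracy"],
               sum(w * pres$folds$accuracy))
})

test_that("personal-vs-temporal comparison matches closed-form t statistics", {
  reps <- 10
  personal <- data.frame(participant = "A", rep = 1:reps,
                         accuracy = rep(0.6, reps))
  temporal <- personal
  out <- compare_personal_vs_temporal(personal, temporal,
                                      metrics = "accuracy")
  expect_identical(out$mean_increase, 0)
  expect_identical(out$p_value, 1)

  temporal2 <- personal; temporal2$accuracy <- personal$accuracy + 0.05
  out2 <- compare_personal_vs_temporal(personal, temporal2, "accuracy")
  expect_equal(out2$mean_increase, 0.05)

  set.seed(14)
  pa <- data.frame(participant = "A", rep = 1:reps,
                   accuracy = 0.6 + rnorm(reps, 0, 0.03))
  tb <- data.frame(participant = "A", rep = 1:reps,
                   accuracy = pa$accuracy + 0.04 + rnorm(reps, 0, 0.01))
  out3 <- compare_personal_vs_temporal(pa, tb, "accuracy")
  d <- tb$accuracy - pa$accuracy
  t_stat <- mean(d) / (sd(d) / sqrt(reps))
  expect_equal(out3$p_value, 2 * pt(-abs(t_stat), reps - 1))
  expect_error(compare_personal_vs_temporal(pa[1:5, ], tb, "accuracy"),
               "unequal repetition")
})

test_that("down-sampling matches other participants to the target volume", {
  tbl <- make_feature_tbl(n = 120, n_participants = 4, seed = 15)
  tgt <- unique(tbl$participant)[1]
  out <- downsample_other_participants(tbl, tgt, seed = 2)
  n_tgt <- sum(tbl$participant == tgt)
  expect_identical(sum(out$participant == tgt), n_tgt)     # target untouched
  expect_lte(abs(sum(out$participant != tgt) - n_tgt), 1)
  # label proportions of the others preserved within one row
  oth <- tbl[tbl$participant != tgt, ]
  kept <- out[out$participant != tgt, ]
  expected_pos <- round(n_tgt * mean(oth$label == "event"))
  expect_lte(abs(sum(kept$label == "event") - expected_pos), 1)
  # equal-size participants: nothing to remove for a tiny target
  one <- tbl[c(which(tbl$participant == tgt)[1],
               which(tbl$participant != tgt)), ]
  out2 <- downsample_other_participants(one, tgt, seed = 3)
  expect_identical(sum(out2$participant != tgt), 1L)
})
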