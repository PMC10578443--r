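test_that("oversampling equalizes classes by duplicating positives only", {
  x <- matrix(seq_len(80), ncol = 2)
  y <- c(rep(1, 10), rep(0, 30))
  os <- oversample_positives(x, y, seed = 1)
  expect_identical(sum(os$y == 1), 30L)
  expect_identical(sum(os$y == 0), 30L)
  # the negative-row multiset is untouched
  expect_identical(os$x[os$y == 0, ], x[y == 0, ])
  # duplicated rows are genuine copies of positive rows
  expect_true(all(os$x[os$y == 1, 1] %in% x[y == 1, 1]))

  # balanced input unchanged
  yb <- rep(c(0, 1), 10)
  osb <- oversample_positives(x[1:20, ], yb, seed = 1)
  expect_identical(osb$x, x[1:20, ])

  # 1 positive / 5 negatives: the positive row appears 5 times
  y15 <- c(1, rep(0, 5))
  os15 <- oversample_positives(x[1:6, ], y15, seed = 2)
  expect_identical(sum(os15$y == 1), 5L)
  expect_true(all(os15$x[os15$y == 1, 1] == x[1, 1]))

  expect_error(oversample_positives(x, rep(0, 40)), "both classes")
  # determinism
  expect_identical(oversample_positives(x, y, seed = 9),
                   oversample_positives(x, y, seed = 9))
})

test_that("all four model kinds fit, score in [0,1] and are seed-deterministic", {
  tbl <- make_feature_tbl(n = 160, signal_strength = 3, seed = 2)
  cols <- feature_columns(tbl)
  x <- as.matrix(tbl[, cols]); y <- as.integer(tbl$label == "event")
  for (kind in c("lr", "rf", "nn", "merf")) {
    m1 <- fit_model(kind, x, y, cluster = tbl$participant, seed = 11)
    m2 <- fit_model(kind, x, y, cluster = tbl$participant, seed = 11)
    s1 <- predict_scores(m1, x, tbl$participant)
    s2 <- predict_scores(m2, x, tbl$participant)
    expect_true(all(s1 >= 0 & s1 <= 1))
    expect_identical(s1, s2)
  }
  xna <- x; xna[1, 1] <- NA
  expect_error(fit_model("lr", xna, y), "non-finite")
})

test_that("logistic regression separates a separable toy set perfectly", {
  set.seed(3)
  x <- cbind(bvp.slope = c(rnorm(30, -3), rnorm(30, 3)), bvp.sd = rnorm(60))
  y <- rep(c(0, 1), each = 30)
  m <- fit_model("lr", x, y, hyper = list(lambda = 1e-5), seed = 1)
  expect_identical(predict_labels(m, x), as.integer(y))
  # monotone in the active feature
  grid <- cbind(bvp.slope = seq(-3, 3, length.out = 9), bvp.sd = 0)
  expect_true(all(diff(predict_scores(m, grid)) > 0))
})

test_that("models have chance-level cross-validated AUC on permuted labels", {
  tbl <- make_feature_tbl(n = 120, signal_strength = 0, seed = 4)
  cols <- feature_columns(tbl)
  aucs <- c()
  for (sd in 1:5) {
    set.seed(sd)
    y <- sample(as.integer(tbl$label == "event"))
    tr <- seq_len(80); te <- 81:120
    m <- fit_model("rf", as.matrix(tbl[tr, cols]), y[tr], seed = sd)
    aucs <- c(aucs, e4episodes:::auc_rank(
      predict_scores(m, as.matrix(tbl[te, cols])), y[te]))
  }
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)) + 0.05)
})

test_that("feature-name mismatches are refused at prediction time", {
  tbl <- make_feature_tbl(n = 60, seed = 5)
  cols <- feature_columns(tbl)
  m <- fit_model("rf", as.matrix(tbl[, cols]),
                 as.integer(tbl$label == "event"), seed = 1)
  bad <- as.matrix(tbl[, cols[-1]])
  expect_error(predict_scores(m, bad), "feature-name mismatch")
})

# ---- mixed-effect random forest -------------------------------------------

test_that("with sigma_b fixed at 0 the MERF equals a plain regression forest", {
  tbl <- make_feature_tbl(n = 150, signal_strength = 2, seed = 6)
  cols <- feature_columns(tbl)
  x <- as.matrix(tbl[, cols]); y <- as.integer(tbl$label == "event")
  mf <- fit_merf(x, y, tbl$participant, num_trees = 100, mtry = 3,
                 sigma_b_init = 0, seed = 21)
  expect_identical(unname(mf$sigma2_b), 0)
  expect_true(all(mf$b == 0))
  rf <- ranger::ranger(x = x, y = as.numeric(y), num.trees = 100, mtry = 3,
                       seed = 21, num.threads = 1)
  expect_lt(max(abs(predict_merf(mf, x, tbl$participant) -
                    predict(rf, data = x, num.threads = 1)$predictions)),
            1e-6)
})

test_that("MERF recovers per-cluster random intercepts", {
  rhos <- vapply(1:5, function(sd) {
    set.seed(sd)
    n_per <- 80
    b_true <- c(-0.3, 0, 0.3)
    cl <- rep(c("A", "B", "C"), each = n_per)
    x <- matrix(rnorm(3 * n_per * 4), ncol = 4,
                dimnames = list(NULL, c("bvp.slope", "bvp.sd", "hr.mean",
                                        "temp.mean")))
    p <- pmin(pmax(0.5 + 0.2 * x[, 1] + rep(b_true, each = n_per), 0.02), 0.98)
    y <- rbinom(length(p), 1, p)
    mf <- fit_merf(x, y, cl, num_trees = 100, mtry = 2, max_iter = 5,
                   seed = sd)
    stats::cor(b_true, mf$b[c("A", "B", "C")], method = "spearman")
  }, 0)
  expect_gt(mean(rhos), 0.9)
})

test_that("unseen clusters fall back to the fixed-effect forest exactly", {
  tbl <- make_feature_tbl(n = 120, intercept_sd = 0.3, seed = 7)
  cols <- feature_columns(tbl)
  x <- as.matrix(tbl[, cols]); y <- as.integer(tbl$label == "event")
  mf <- fit_merf(x, y, tbl$participant, num_trees = 80, seed = 3)
  f_only <- predict_merf(mf, x, cluster = NULL)
  s_unseen <- predict_merf(mf, x, cluster = rep("NEW", nrow(x)))
  expect_identical(s_unseen, f_only)
  # known clusters differ from the forest-only score by exactly b_i
  s_known <- predict_merf(mf, x, tbl$participant)
  expect_equal(s_known - f_only, unname(mf$b[tbl$participant]),
               tolerance = 1e-12)
})

test_that("MERF estimates track the data-generating variance components", {
  # sizeable true intercept variance is detected; its estimate exceeds
  # the estimate under a no-intercept generator
  fit_with_b <- function(int_sd, sd) {
    tbl <- make_feature_tbl(n = 240, n_participants = 6,
                            intercept_sd = int_sd, seed = sd)
    cols <- feature_columns(tbl)
    fit_merf(as.matrix(tbl[, cols]), as.integer(tbl$label == "event"),
             tbl$participant, num_trees = 80, max_iter = 5, seed = sd)
  }
  s_big <- vapply(1:3, function(sd) fit_with_b(1.5, sd)$sigma2_b, 0)
  s_null <- vapply(1:3, function(sd) fit_with_b(0, sd)$sigma2_b, 0)
  expect_gt(mean(s_big), mean(s_null))
  m <- fit_with_b(1.5, 1)
  expect_true(all(is.finite(m$gll_trace)))
  expect_gt(m$sigma2, 0)
})
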