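# Nested cross-validation under four generalization scenarios, metric
# computation, and the comparative analyses built on top: temporal vs
# personalized models, down-sampled generalized models, and ROC
# operating points.

#' Classification metrics for one set of scored rows
#'
#' Accuracy, precision, recall, F1 and ROC-AUC at a fixed decision
#' threshold, plus the majority-guess baseline accuracy of the same
#' rows. Precision is 0 when no positive predictions are made; F1 is 0
#' when precision + recall is 0; AUC is `NA` when only one class is
#' present.
#'
#' @param scores numeric scores in [0, 1].
#' @param labels binary labels (1 = event).
#' @param threshold decision threshold.
#' @return Named numeric vector.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  auc <- if (length(unique(labels)) == 2) auc_rank(scores, labels) else NA_real_
  c(accuracy = acc, f1 = f1, precision = prec, recall = rec, roc_auc = auc,
    baseline = max(mean(labels), 1 - mean(labels)))
}

# AUC as the pairwise concordance probability (ties count 1/2),
# computed from ranks.
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ---- split plans -----------------------------------------------------------

# per-participant 75 / 12.5 / 12.5 split over distinct observation days:
# the 75% boundary rounds down and the 87.5% boundary rounds up, so both
# validation and test are non-empty whenever a participant has >= 8 days.
split_days_751212 <- function(day_index) {
  u <- sort(unique(day_index))
  D <- length(u)
  n_tr <- floor(0.75 * D)
  n_va_end <- ceiling(0.875 * D)
  list(train = u[seq_len(n_tr)],
       validation = u[setdiff(seq_len(n_va_end), seq_len(n_tr))],
       test = u[setdiff(seq_len(D), seq_len(n_va_end))])
}

#' Build a cross-validation split plan
#'
#' Four scenarios mirroring distinct clinical uses of an event
#' detector:
#' * `"random"`: stratified k-fold over windows (outer layer); inner
#'   model selection uses k-fold within each outer training set.
#' * `"participant"`: leave-one-subject-out outer folds; the inner
#'   layer rotates one held-out training participant as validation.
#' * `"temporal"`: for every participant the first 75% of observation
#'   days train, the next 12.5% validate, the final 12.5% test; one
#'   fixed hold-out evaluated over `n_reps` repetitions whose
#'   variability comes from oversampling and model seeds.
#' * `"personalized"`: the temporal split applied within each single
#'   participant (participants with fewer than 8 distinct observation
#'   days are skipped with a message).
#'
#' @param tbl feature table with `participant`, `day_index`, `label`.
#' @param scenario one of the four scenario names.
#' @param seed RNG seed for random fold assignment.
#' @param n_folds outer folds for the random scenario.
#' @param n_reps repetitions for temporal / personalized scenarios.
#' @return An object of class `split_plan`: list of folds, each with
#'   `train`, `validation` (possibly `NULL`), `test` row indices, a
#'   repetition index and (where applicable) the test participant.
#' @export
make_split_plan <- function(tbl, scenario = c("random", "participant",
                                              "temporal", "personalized"),
                            seed = 1L, n_folds = 10, n_reps = 10) {
  scenario <- match.arg(scenario)
  n <- nrow(tbl)
  y <- as.integer(tbl$label == "event")
  folds <- list()
  if (scenario == "random") {
    k <- max(2, min(n_folds, sum(y == 1), sum(y == 0)))
    assign <- seeded(seed, {
      a <- integer(n)
      for (cl in unique(y)) {
        ii <- which(y == cl)
        a[ii] <- sample(rep_len(seq_len(k), length(ii)))
      }
      a
    })
    for (f in seq_len(k)) {
      folds[[f]] <- list(train = which(assign != f),
                         validation = NULL,
                         test = which(assign == f), rep = 1L,
                         participant = NA_character_)
    }
  } else if (scenario == "participant") {
    parts <- unique(tbl$participant)
    if (length(parts) < 3) stop("participant scenario needs >= 3 participants")
    for (p in parts) {
      folds[[length(folds) + 1]] <- list(
        train = which(tbl$participant != p),
        validation = NULL,
        test = which(tbl$participant == p), rep = 1L, participant = p)
    }
  } else if (scenario == "temporal") {
    tr <- va <- te <- integer(0)
    for (p in unique(tbl$participant)) {
      ii <- which(tbl$participant == p)
      sp <- split_days_751212(tbl$day_index[ii])
      tr <- c(tr, ii[tbl$day_index[ii] %in% sp$train])
      va <- c(va, ii[tbl$day_index[ii] %in% sp$validation])
      te <- c(te, ii[tbl$day_index[ii] %in% sp$test])
    }
    for (r in seq_len(n_reps)) {
      folds[[r]] <- list(train = tr, validation = va, test = te,
                         rep = r, participant = NA_character_)
    }
  } else { # personalized
    for (p in unique(tbl$participant)) {
      ii <- which(tbl$participant == p)
      if (length(unique(tbl$day_index[ii])) < 8) {
        message("personalized scenario: skipping participant ", p,
                " (< 8 observation days)")
        next
      }
      sp <- split_days_751212(tbl$day_index[ii])
      for (r in seq_len(n_reps)) {
        folds[[length(folds) + 1]] <- list(
          train = ii[tbl$day_index[ii] %in% sp$train],
          validation = ii[tbl$day_index[ii] %in% sp$validation],
          test = ii[tbl$day_index[ii] %in% sp$test],
          rep = r, participant = p)
      }
    }
  }
  structure(list(scenario = scenario, folds = folds, seed = seed),
            class = "split_plan")
}

# inner-layer folds for model selection within one outer training set
inner_folds <- function(tbl, fold, scenario, seed, inner_k = 10) {
  if (!is.null(fold$validation) && length(fold$validation) > 0) {
    return(list(list(tr = fold$train, va = fold$validation)))
  }
  train <- fold$train
  if (scenario == "participant") {
    parts <- unique(tbl$participant[train])
    return(lapply(parts, function(p) {
      list(tr = train[tbl$participant[train] != p],
           va = train[tbl$participant[train] == p])
    }))
  }
  y <- as.integer(tbl$label[train] == "event")
  k <- max(2, min(inner_k, sum(y == 1), sum(y == 0)))
  assign <- seeded(seed, {
    a <- integer(length(train))
    for (cl in unique(y)) {
      ii <- which(y == cl)
      a[ii] <- sample(rep_len(seq_len(k), length(ii)))
    }
    a
  })
  lapply(seq_len(k), function(f) {
    list(tr = train[assign != f], va = train[assign == f])
  })
}

train_and_score <- function(tbl, tr, eval_rows, kind, hyper, seed) {
  std <- standardize_features(tbl, fit_rows = tr)
  cols <- feature_columns(std)
  xtr <- as.matrix(std[tr, cols, drop = FALSE])
  ytr <- as.integer(std$label[tr] == "event")
  ctr <- std$participant[tr]
  os <- oversample_positives(xtr, ytr, ctr, seed = seed)
  m <- fit_model(kind, os$x, os$y, cluster = os$cluster, hyper = hyper,
                 seed = seed)
  xev <- as.matrix(std[eval_rows, cols, drop = FALSE])
  predict_scores(m, xev, cluster = std$participant[eval_rows])
}

#' Run nested cross-validation over a split plan
#'
#' The inner layer trains every candidate (model kind, hyperparameter
#' row) on each inner-training set — with training-only feature
#' standardization and positive-class oversampling — and selects the
#' candidate with the highest mean inner-validation accuracy. The winner
#' is refit on the full outer training set and evaluated on the held-out
#' test rows. Inner folds whose training set contains a single class are
#' skipped with a message.
#'
#' @param tbl feature table (unstandardized; scaling is fit per split).
#' @param plan a [make_split_plan()] plan.
#' @param models character subset of `c("lr","rf","nn","merf")`.
#' @param grids named list of hyperparameter data.frames, as
#'   [default_hyper_grids()].
#' @param seed base RNG seed; per-fold/rep seeds are derived from it.
#' @param inner_k inner fold count for the random scenario.
#' @return List with `folds` (per-fold metrics and selected model) and
#'   `summary` (per-metric mean and standard error; participant-scenario
#'   means are weighted by each test participant's share of windows).
#' @export
run_nested_cv <- function(tbl, plan, models = c("lr", "rf", "nn", "merf"),
                          grids = default_hyper_grids(), seed = 1L,
                          inner_k = 10) {
  stopifnot(inherits(plan, "split_plan"))
  models <- match.arg(models, c("lr", "rf", "nn", "merf"), several.ok = TRUE)
  out <- list()
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    fseed <- derive_seed(seed, fi)
    inn <- inner_folds(tbl, fold, plan$scenario, seed = fseed,
                       inner_k = inner_k)
    best <- NULL; best_acc <- -Inf
    for (kind in models) {
      grid <- grids[[kind]]
      if (is.null(grid)) grid <- data.frame(.default = TRUE)
      for (gi in seq_len(nrow(grid))) {
        hyper <- as.list(grid[gi, , drop = FALSE])
        accs <- c()
        for (ii in seq_along(inn)) {
          tr <- inn[[ii]]$tr; va <- inn[[ii]]$va
          ytr <- tbl$label[tr]
          if (length(unique(ytr)) < 2 || length(va) == 0) {
            message("inner fold skipped (single class or empty validation)")
            next
          }
          sc <- train_and_score(tbl, tr, va, kind, hyper,
                                seed = derive_seed(fseed, 100 + ii))
          accs <- c(accs, mean((sc > 0.5) ==
                                 (tbl$label[va] == "event")))
        }
        if (length(accs) > 0 && mean(accs) > best_acc) {
          best_acc <- mean(accs)
          best <- list(kind = kind, hyper = hyper)
        }
      }
    }
    if (is.null(best)) next
    outer_train <- unique(c(fold$train, fold$validation))
    sc <- train_and_score(tbl, outer_train, fold$test, best$kind, best$hyper,
                          seed = derive_seed(fseed, 999 + fold$rep))
    met <- compute_metrics(sc, as.integer(tbl$label[fold$test] == "event"))
    out[[length(out) + 1]] <- data.frame(
      fold = fi, rep = fold$rep, participant = fold$participant,
      model = best$kind, inner_accuracy = best_acc,
      n_test = length(fold$test), t(met))
  }
  folds_df <- do.call(rbind, out)
  list(folds = folds_df,
       summary = summarize_cv(folds_df, plan$scenario),
       scenario = plan$scenario)
}

summarize_cv <- function(folds_df, scenario) {
  metrics <- c("accuracy", "f1", "precision", "recall", "roc_auc", "baseline")
  w <- if (scenario == "participant") {
    folds_df$n_test / sum(folds_df$n_test)
  } else rep(1 / nrow(folds_df), nrow(folds_df))
  do.call(rbind, lapply(metrics, function(m) {
    v <- folds_df[[m]]
    ok <- is.finite(v)
    data.frame(metric = m,
               mean = sum(w[ok] * v[ok]) / sum(w[ok]),
               se = stats::sd(v[ok]) / sqrt(sum(ok)),
               n_folds = sum(ok))
  }))
}

# ---- ROC -------------------------------------------------------------------

#' ROC curve with operating points
#'
#' Full threshold sweep over the scores, trapezoid AUC, and the false
#' positive rate required to reach recall targets (default 0.7 and 0.9,
#' the operating points clinically relevant for event detection).
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = event); both classes required.
#' @param recall_targets recall levels at which to report FPR.
#' @return List with `curve` (data.frame threshold/fpr/tpr), `auc`, and
#'   `operating_points` (data.frame recall target, achieved tpr, fpr).
#' @export
roc_threshold_sweep <- function(scores, labels, recall_targets = c(0.7, 0.9)) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes required for ROC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  op <- do.call(rbind, lapply(recall_targets, function(r) {
    ok <- which(tpr >= r)
    data.frame(recall_target = r,
               tpr = if (length(ok)) tpr[min(ok)] else NA_real_,
               fpr = if (length(ok)) fpr[min(ok)] else NA_real_)
  }))
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc, operating_points = op)
}

# ---- comparative analyses --------------------------------------------------

#' Compare personalized with temporal generalized performance
#'
#' For each participant and metric, the mean increase is the temporal
#' (generalized) mean minus the personalized mean over paired
#' repetitions, with a two-sided paired t-test across repetitions.
#' Sample sizes this small make the tests exploratory; p-values are
#' reported uncorrected.
#'
#' @param personal,temporal data.frames with columns `participant`,
#'   `rep` and one column per metric (the `folds` output of
#'   [run_nested_cv()] works directly).
#' @param metrics metric columns to compare.
#' @return data.frame: participant, metric, mean_personal,
#'   mean_temporal, mean_increase, p_value.
#' @export
compare_personal_vs_temporal <- function(personal, temporal,
                                         metrics = c("accuracy", "f1",
                                                     "precision", "recall",
                                                     "roc_auc")) {
  out <- list()
  for (p in intersect(unique(personal$participant),
                      unique(temporal$participant))) {
    a <- personal[personal$participant == p, , drop = FALSE]
    b <- temporal[temporal$participant == p, , drop = FALSE]
    a <- a[order(a$rep), ]; b <- b[order(b$rep), ]
    if (nrow(a) != nrow(b)) stop("unequal repetition counts for ", p)
    if (nrow(a) < 2) stop("need >= 2 repetitions per arm")
    for (m in metrics) {
      d <- b[[m]] - a[[m]]
      pv <- if (stats::sd(d) == 0) {
        if (all(d == 0)) 1 else 0
      } else stats::t.test(d)$p.value
      out[[length(out) + 1]] <- data.frame(
        participant = p, metric = m,
        mean_personal = mean(a[[m]]), mean_temporal = mean(b[[m]]),
        mean_increase = mean(d), p_value = pv)
    }
  }
  do.call(rbind, out)
}

#' Down-sample other participants to the target's data volume
#'
#' Keeps every row of the target participant and subsamples the pooled
#' rows of all other participants — stratified by label so class
#' proportions are preserved within one row — until their total matches
#' the target participant's row count. When the others jointly hold
#' fewer rows than the target, all rows are kept with a message.
#'
#' @param tbl feature table with `participant` and `label`.
#' @param target_participant id of the participant under evaluation.
#' @param seed RNG seed.
#' @return Subset of `tbl`.
#' @export
downsample_other_participants <- function(tbl, target_participant, seed = 1L) {
  stopifnot(length(unique(tbl$participant)) >= 2)
  tgt <- which(tbl$participant == target_participant)
  oth <- which(tbl$participant != target_participant)
  n_target <- length(tgt)
  if (length(oth) <= n_target) {
    message("other participants jointly smaller than target; keeping all")
    return(tbl)
  }
  pos <- oth[tbl$label[oth] == "event"]
  neg <- oth[tbl$label[oth] != "event"]
  n_pos <- round(n_target * length(pos) / length(oth))
  n_neg <- n_target - n_pos
  keep <- seeded(seed, c(sample(pos, min(n_pos, length(pos))),
                         sample(neg, min(n_neg, length(neg)))))
  out <- tbl[sort(c(tgt, keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
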