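# The four classifier families behind one interface: logistic
# regression (ridge-regularized), random forest, a small feedforward
# neural network, and a mixed-effect random forest (merf.R). All models
# consume a standardized numeric feature matrix and binary labels
# (1 = event) and expose scores in [0, 1].

#' Oversample positive rows to balance classes
#'
#' Duplicates positive (event) rows, sampled with replacement, until the
#' positive count equals the negative count. Negative rows are never
#' touched. When the input is already balanced (or positives outnumber
#' negatives) the input is returned unchanged.
#'
#' @param x feature matrix or data.frame.
#' @param y binary labels (0/1) aligned with rows of `x`.
#' @param cluster optional cluster ids aligned with rows.
#' @param seed RNG seed.
#' @return List with `x`, `y`, `cluster` after oversampling.
#' @export
oversample_positives <- function(x, y, cluster = NULL, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("oversampling needs both classes present")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos >= n_neg) return(list(x = x, y = y, cluster = cluster))
  add <- seeded(seed, sample(which(y == 1), n_neg - n_pos, replace = TRUE))
  idx <- c(seq_along(y), add)
  list(x = x[idx, , drop = FALSE], y = y[idx],
       cluster = if (is.null(cluster)) NULL else cluster[idx])
}

#' Default hyperparameter grids
#'
#' Small per-model grids (at most a few points each) so nested
#' cross-validation stays tractable at desk scale; supply your own list
#' of data.frames to widen the search.
#'
#' @return Named list of data.frames, one row per candidate setting.
#' @export
default_hyper_grids <- function() {
  list(
    lr = data.frame(lambda = c(1e-4, 1e-2)),
    rf = data.frame(num_trees = 200, mtry = c(8, 22)),
    nn = data.frame(size = c(16, 64), decay = 0.01, maxit = 150),
    merf = data.frame(num_trees = 200, mtry = 8, max_iter = 4, tol = 1e-3)
  )
}

#' Fit one classifier
#'
#' @param kind `"lr"`, `"rf"`, `"nn"` or `"merf"`.
#' @param x standardized feature matrix (or data.frame of numerics).
#' @param y binary labels, 1 = event.
#' @param cluster participant ids (required for `"merf"`).
#' @param hyper one-row data.frame / named list of hyperparameters; see
#'   [default_hyper_grids()] for the recognized names per model.
#' @param seed RNG seed controlling any training stochasticity.
#' @return An object of class `episode_model` supporting
#'   [predict_scores()] and [predict_labels()].
#' @export
fit_model <- function(kind = c("lr", "rf", "nn", "merf"), x, y,
                      cluster = NULL, hyper = list(), seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  hyper <- as.list(hyper)
  fit <- switch(kind,
    lr = {
      lambda <- hyper$lambda %||% 1e-3
      seeded(seed, glmnet::glmnet(x, factor(y, levels = 0:1),
                                  family = "binomial", alpha = 0,
                                  lambda = lambda))
    },
    rf = {
      ranger::ranger(x = x, y = factor(y, levels = 0:1),
                     num.trees = hyper$num_trees %||% 200,
                     mtry = min(ncol(x), hyper$mtry %||% floor(sqrt(ncol(x)))),
                     probability = TRUE, seed = seed, num.threads = 1)
    },
    nn = {
      seeded(seed, nnet::nnet(x = x, y = y,
                              size = hyper$size %||% 16,
                              decay = hyper$decay %||% 0.01,
                              maxit = hyper$maxit %||% 150,
                              entropy = TRUE, trace = FALSE,
                              MaxNWts = 20000))
    },
    merf = {
      if (is.null(cluster)) stop("merf requires cluster ids")
      fit_merf(x, y, cluster,
               num_trees = hyper$num_trees %||% 200,
               mtry = min(ncol(x), hyper$mtry %||% floor(sqrt(ncol(x)))),
               max_iter = hyper$max_iter %||% 4,
               tol = hyper$tol %||% 1e-3,
               sigma_b_init = hyper$sigma_b_init %||% 0.05,
               seed = seed)
    })
  structure(list(kind = kind, fit = fit, features = colnames(x),
                 hyper = hyper, seed = seed),
            class = "episode_model")
}

#' Predict event scores
#'
#' Scores are probabilities in [0, 1]. The mixed-effect random forest
#' adds the fitted random intercept of known clusters (clipped back into
#' [0, 1]); rows from clusters unseen at training time fall back to the
#' fixed-effect forest alone.
#'
#' @param model an `episode_model`.
#' @param x feature matrix with the training feature columns.
#' @param cluster cluster ids (used by `"merf"` only).
#' @return Numeric scores in [0, 1].
#' @export
predict_scores <- function(model, x, cluster = NULL) {
  x <- as.matrix(x)
  if (!is.null(model$features)) {
    if (!all(model$features %in% colnames(x))) {
      stop("feature-name mismatch between model and prediction rows")
    }
    x <- x[, model$features, drop = FALSE]
  }
  s <- switch(model$kind,
    lr = as.numeric(stats::predict(model$fit, newx = x, type = "response")),
    rf = stats::predict(model$fit, data = x, num.threads = 1)$predictions[, "1"],
    nn = as.numeric(stats::predict(model$fit, x)),
    merf = predict_merf(model$fit, x, cluster))
  pmin(pmax(s, 0), 1)
}

#' @rdname predict_scores
#' @param threshold decision threshold on the score.
#' @export
predict_labels <- function(model, x, cluster = NULL, threshold = 0.5) {
  as.integer(predict_scores(model, x, cluster) > threshold)
}
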