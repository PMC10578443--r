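# Per-observation signed feature attribution for tree ensembles via
# tree-path decomposition: walking each observation down every tree,
# the change in the node's mean training response at each split is
# credited to the split feature. Attributions plus the root value sum
# to the tree's empirical response function (exactly so for forests
# grown on the full sample; under bootstrap resampling the node means
# are recomputed from all training rows, so the decomposition tracks
# the forest's response up to resampling differences). A feature the
# forest never splits on receives exactly zero. A permutation backend
# is available for non-tree models.

# Node values (mean training response per node) for one ranger tree,
# computed by routing the training rows down the split structure.
tree_node_values <- function(ti, x, y) {
  vals <- rep(NA_real_, nrow(ti))
  rows_at <- vector("list", nrow(ti))
  rows_at[[1]] <- seq_len(nrow(x))
  ord <- order(ti$nodeID)  # parents precede children in ranger output
  for (k in ord) {
    rows <- rows_at[[k]]
    if (is.null(rows) || length(rows) == 0) { vals[k] <- NA_real_; next }
    vals[k] <- mean(y[rows])
    if (!ti$terminal[k]) {
      v <- x[rows, ti$splitvarName[k]]
      go_left <- v <= ti$splitval[k]
      rows_at[[ti$leftChild[k] + 1L]] <- rows[go_left]
      rows_at[[ti$rightChild[k] + 1L]] <- rows[!go_left]
    }
  }
  vals
}

attribute_tree <- function(ti, vals, xev, contrib) {
  for (i in seq_len(nrow(xev))) {
    k <- 1L
    while (!ti$terminal[k]) {
      f <- ti$splitvarName[k]
      nxt <- if (xev[i, f] <= ti$splitval[k]) ti$leftChild[k] + 1L else
        ti$rightChild[k] + 1L
      if (is.na(vals[nxt])) break  # no training row reached this child
      contrib[i, f] <- contrib[i, f] + (vals[nxt] - vals[k])
      k <- nxt
    }
  }
  contrib
}

#' Per-observation feature attributions for a tree model
#'
#' @param model an `episode_model` of kind `"rf"` or `"merf"`, or a raw
#'   `ranger` / `merf` fit.
#' @param x_train,y_train the training rows (standardized features and
#'   0/1 labels) used to compute node response values.
#' @param x_eval rows to attribute (defaults to the training rows).
#' @param backend `"tree_path"` (default) or `"permutation"`; tree-path
#'   requires a tree model, otherwise an error instructs the fallback.
#' @param metric for the permutation backend, the score drop measured
#'   (AUC).
#' @param n_perm permutations per feature for the permutation backend.
#' @param seed RNG seed (permutation backend).
#' @return List of class `importance_report` with `attributions`
#'   (matrix rows x features, signed; positive pushes toward the event
#'   class), `bias` (root value), and `ranking` (data.frame of all
#'   features ordered by mean |attribution|).
#' @export
feature_importance <- function(model, x_train, y_train, x_eval = x_train,
                               backend = c("tree_path", "permutation"),
                               metric = "auc", n_perm = 5, seed = 1L) {
  backend <- match.arg(backend)
  x_train <- as.matrix(x_train); x_eval <- as.matrix(x_eval)
  y_train <- as.numeric(y_train)
  forest <- extract_forest(model)
  if (backend == "tree_path") {
    if (is.null(forest)) {
      stop("tree_path attribution requires a tree model; ",
           "use backend = \"permutation\"")
    }
    n_trees <- forest$num.trees
    contrib <- matrix(0, nrow(x_eval), ncol(x_eval),
                      dimnames = list(NULL, colnames(x_eval)))
    bias <- 0
    for (b in seq_len(n_trees)) {
      ti <- ranger::treeInfo(forest, tree = b)
      vals <- tree_node_values(ti, x_train, y_train)
      bias <- bias + vals[1]
      contrib <- attribute_tree(ti, vals, x_eval, contrib)
    }
    contrib <- contrib / n_trees
    bias <- bias / n_trees
  } else {
    scorer <- function(xx) score_any(model, xx)
    base <- auc_rank(scorer(x_eval), y_eval_guess(y_train, x_train, x_eval))
    contrib <- matrix(0, 1, ncol(x_eval),
                      dimnames = list(NULL, colnames(x_eval)))
    seeded(seed, {
      for (j in seq_len(ncol(x_eval))) {
        drops <- replicate(n_perm, {
          xp <- x_eval
          xp[, j] <- sample(xp[, j])
          base - auc_rank(scorer(xp), y_eval_guess(y_train, x_train, x_eval))
        })
        contrib[1, j] <- mean(drops)
      }
    })
    bias <- NA_real_
  }
  mean_abs <- colMeans(abs(contrib))
  ranking <- data.frame(feature = names(mean_abs),
                        mean_abs_attribution = unname(mean_abs))
  ranking <- ranking[order(-ranking$mean_abs_attribution), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(attributions = contrib, bias = bias, ranking = ranking,
                 backend = backend),
            class = "importance_report")
}

extract_forest <- function(model) {
  if (inherits(model, "ranger")) return(model)
  if (inherits(model, "merf")) return(model$forest)
  if (inherits(model, "episode_model")) {
    if (model$kind == "rf") return(model$fit)
    if (model$kind == "merf") return(model$fit$forest)
  }
  NULL
}

score_any <- function(model, x) {
  if (inherits(model, "episode_model")) return(predict_scores(model, x))
  if (inherits(model, "ranger")) {
    p <- stats::predict(model, data = x, num.threads = 1)$predictions
    return(if (is.matrix(p)) p[, ncol(p)] else p)
  }
  if (inherits(model, "merf")) return(predict_merf(model, x))
  stop("unsupported model for permutation importance")
}

# permutation backend needs eval labels; reuse training labels when the
# eval rows are the training rows, else refuse.
y_eval_guess <- function(y_train, x_train, x_eval) {
  if (nrow(x_eval) != length(y_train)) {
    stop("permutation backend needs eval rows equal to training rows")
  }
  y_train
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report> top features by mean |attribution|:\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}
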