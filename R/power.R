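# Learning-curve power analysis: classifier performance as a function
# of training-set size, fit with the inverse power law
# performance(n) = a - b * n^(-c), and extrapolated to estimate the
# data volume needed for a target performance.

#' Fit an inverse power law learning curve
#'
#' Fits `y = a - b * n^(-c)`. Because the model is linear in `(a, b)`
#' once `c` is fixed, `c` is first profiled over a dense grid by
#' constrained linear least squares; the best grid point then seeds a
#' nonlinear polish, alongside a conventional multi-start, and the
#' lowest-residual fit wins. `c` is constrained non-negative.
#' Degenerate inputs (constant `y`) yield `b ~ 0` or `c ~ 0` and are
#' flagged.
#'
#' @param n training-set sizes (positive).
#' @param y performance values, typically in [0, 1].
#' @param c_starts curvature starting values for the multi-start.
#' @param a_bounds bounds on the asymptote `a`; the default `c(0, 1)`
#'   is appropriate for the bounded classification metrics and keeps
#'   the (a, b, c) trade-off well-posed when `c` is small. Use
#'   `c(-Inf, Inf)` for unbounded performance measures.
#' @return List of class `learning_curve_fit` with `a`, `b`, `c`,
#'   `residual_norm`, `degenerate` flag and the fitted function `fun`.
#' @export
fit_learning_curve <- function(n, y, c_starts = c(0.1, 0.3, 0.5, 1, 2),
                               a_bounds = c(0, 1)) {
  stopifnot(length(n) == length(y), all(n > 0), all(is.finite(y)))
  df <- data.frame(n = as.numeric(n), y = as.numeric(y))
  # profile the curvature: for fixed c the problem is linear in (a, b)
  profile_sse <- function(cc) {
    z <- df$n^(-cc)
    fit <- stats::lm(y ~ z, data = df)
    a <- stats::coef(fit)[[1]]; b <- -stats::coef(fit)[[2]]
    if (a < a_bounds[1] || a > a_bounds[2]) {
      a <- min(max(a, a_bounds[1]), a_bounds[2])
      b <- sum(z * (a - df$y)) / sum(z^2)
    }
    list(sse = sum((df$y - a + b * z)^2), a = a, b = b)
  }
  c_grid <- exp(seq(log(0.01), log(5), length.out = 80))
  prof <- lapply(c_grid, profile_sse)
  c_best <- c_grid[which.min(vapply(prof, `[[`, 0, "sse"))]
  best <- NULL
  for (c0 in unique(c(c_best, c_starts))) {
    p0 <- profile_sse(c0)
    a0 <- min(max(p0$a, a_bounds[1]), a_bounds[2])
    b0 <- if (is.finite(p0$b) && p0$b != 0) p0$b else
      max(1e-3, (a0 - min(df$y)) * min(df$n)^c0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a - b * n^(-cc), data = df,
                        start = list(a = a0, b = b0, cc = c0),
                        lower = c(a = a_bounds[1], b = -Inf, cc = 0),
                        upper = c(a = a_bounds[2], b = Inf, cc = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::residuals(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          residual_norm = NA_real_, degenerate = TRUE,
                          fun = NULL),
                     class = "learning_curve_fit"))
  }
  p <- stats::coef(best$fit)
  degenerate <- abs(p[["b"]]) < 1e-8 || p[["cc"]] < 1e-8
  structure(list(a = p[["a"]], b = p[["b"]], c = p[["cc"]],
                 residual_norm = best$rn, degenerate = degenerate,
                 fun = function(nn) p[["a"]] - p[["b"]] * nn^(-p[["cc"]])),
            class = "learning_curve_fit")
}

#' Training-set size needed to reach a target performance
#'
#' Inverts the fitted inverse power law. When the asymptote `a` lies
#' below the target the requirement is unattainable and `NA` is
#' returned with `attainable = FALSE`.
#'
#' @param fit a [fit_learning_curve()] result.
#' @param target desired performance level.
#' @return List with `n_required` and `attainable`.
#' @export
extrapolate_n <- function(fit, target) {
  if (is.na(fit$a) || fit$degenerate) {
    return(list(n_required = NA_real_, attainable = FALSE))
  }
  if (target >= fit$a || fit$b <= 0) {
    return(list(n_required = NA_real_, attainable = FALSE))
  }
  list(n_required = ((fit$a - target) / fit$b)^(-1 / fit$c), attainable = TRUE)
}

#' Learning-curve power analysis on one participant's data
#'
#' Holds the participant's temporal test set fixed, down-samples the
#' training pool to the given fractions by stratified (label-preserving)
#' random sampling — each fraction repeated `n_reps` times, the 100%
#' fraction once — trains a classifier per draw, and fits the inverse
#' power law to every metric as a function of the training-set size.
#'
#' @param tbl feature table of a single participant.
#' @param fractions training fractions to evaluate.
#' @param n_reps repetitions per down-sampled fraction.
#' @param model model kind trained at every draw.
#' @param hyper hyperparameters for the model.
#' @param seed base RNG seed.
#' @return List with `points` (fraction, n_train, rep, metrics) and
#'   `fits` (one `learning_curve_fit` per metric).
#' @export
power_analysis <- function(tbl, fractions = c(0.10, 0.25, 0.50, 0.75, 0.90, 1),
                           n_reps = 10, model = "rf", hyper = list(),
                           seed = 1L) {
  stopifnot(length(unique(tbl$participant)) == 1)
  sp <- split_days_751212(tbl$day_index)
  train_pool <- which(tbl$day_index %in% c(sp$train, sp$validation))
  test <- which(tbl$day_index %in% sp$test)
  y_pool <- tbl$label[train_pool]
  if (length(unique(y_pool)) < 2 || length(test) == 0) {
    stop("participant lacks both classes in the training pool or has no test days")
  }
  pts <- list()
  for (f in fractions) {
    reps <- if (f >= 1) 1L else n_reps
    for (r in seq_len(reps)) {
      sub <- if (f >= 1) train_pool else seeded(derive_seed(seed, 1000 * f + r), {
        unlist(lapply(split(train_pool, y_pool), function(ii) {
          sample(ii, max(1, round(f * length(ii))))
        }))
      })
      if (length(unique(tbl$label[sub])) < 2) next
      sc <- train_and_score(tbl, sub, test, model, hyper,
                            seed = derive_seed(seed, 5000 * f + r))
      met <- compute_metrics(sc, as.integer(tbl$label[test] == "event"))
      pts[[length(pts) + 1]] <- data.frame(fraction = f, n_train = length(sub),
                                           rep = r, t(met))
    }
  }
  points <- do.call(rbind, pts)
  metrics <- c("accuracy", "f1", "precision", "recall", "roc_auc")
  fits <- lapply(stats::setNames(metrics, metrics), function(m) {
    ok <- is.finite(points[[m]])
    fit_learning_curve(points$n_train[ok], points[[m]][ok])
  })
  list(points = points, fits = fits)
}
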