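# Mixed-effect random forest with per-cluster random intercepts,
# estimated by expectation-maximization-style alternation: the forest
# captures the fixed-effect function f(X) and a scalar intercept b_i per
# participant captures cluster heterogeneity,
#
#   y_ij = f(x_ij) + b_i + e_ij,   b_i ~ N(0, sigma_b^2),
#                                  e_ij ~ N(0, sigma^2).
#
# Classification is handled via regression on the 0/1 response with
# scores clipped into [0, 1]. For a random intercept the E-step has the
# closed form b_i = sigma_b^2 * sum(r_i) / (sigma^2 + n_i sigma_b^2)
# with r_i the fixed-effect residuals of cluster i; the M-step refits
# the forest on y - b and updates both variance components. With
# sigma_b_init = 0 the intercepts stay exactly zero and the model
# coincides with a plain random forest fit on the same data and seed.

#' Fit a mixed-effect random forest
#'
#' @param x numeric feature matrix.
#' @param y numeric response; for event classification the 0/1 labels.
#' @param cluster cluster (participant) id per row; at least 2 distinct
#'   clusters are required.
#' @param num_trees,mtry forest size and features per split.
#' @param max_iter maximum EM-style iterations.
#' @param tol relative change in the generalized log-likelihood (GLL)
#'   criterion below which iteration stops.
#' @param sigma_b_init initial random-intercept variance; 0 pins the
#'   intercepts at zero (plain-forest limit).
#' @param seed RNG seed passed to every forest refit.
#' @return An object of class `merf` with the fitted forest, the
#'   per-cluster intercepts `b`, variance components `sigma2` and
#'   `sigma2_b`, the GLL trace and a convergence flag.
#' @export
fit_merf <- function(x, y, cluster, num_trees = 200, mtry = NULL,
                     max_iter = 10, tol = 1e-3, sigma_b_init = 0.05,
                     seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  cluster <- as.character(cluster)
  ids <- unique(cluster)
  if (length(ids) < 2) stop("merf needs at least 2 clusters")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  idx <- split(seq_along(y), cluster)
  n_i <- vapply(idx, length, 0L)

  b <- stats::setNames(rep(0, length(ids)), ids)
  sigma2 <- max(stats::var(y), 1e-6)
  sigma2_b <- sigma_b_init
  gll_trace <- numeric(0)
  converged <- FALSE
  forest <- NULL

  for (it in seq_len(max_iter)) {
    # M-step part 1: refit forest on y minus current intercepts
    ystar <- y - b[cluster]
    forest <- ranger::ranger(x = x, y = ystar, num.trees = num_trees,
                             mtry = min(ncol(x), mtry), seed = seed,
                             num.threads = 1)
    f <- stats::predict(forest, data = x, num.threads = 1)$predictions

    # E-step: BLUP of the random intercepts given current variances
    r_sum <- vapply(idx, function(ii) sum(y[ii] - f[ii]), 0)
    b_new <- if (sigma2_b > 0) {
      sigma2_b * r_sum / (sigma2 + n_i * sigma2_b)
    } else rep(0, length(ids))
    names(b_new) <- names(idx)

    # M-step part 2: variance components
    eps <- y - f - b_new[cluster]
    if (sigma2_b > 0) {
      shrink <- sigma2_b * sigma2 / (sigma2 + n_i * sigma2_b)  # Var(b_i | y)
      tr_vinv <- n_i / sigma2 - sigma2_b * n_i / (sigma2 * (sigma2 + n_i * sigma2_b))
      sigma2_new <- (sum(eps^2) +
                       sigma2 * sum(n_i - sigma2 * tr_vinv)) / length(y)
      sigma2_b_new <- mean(b_new[names(idx)]^2 + shrink)
    } else {
      sigma2_new <- mean(eps^2)
      sigma2_b_new <- 0
    }
    sigma2_new <- max(sigma2_new, 1e-8)

    # GLL convergence criterion
    gll <- 0
    for (k in seq_along(idx)) {
      ii <- idx[[k]]
      e_k <- eps[ii]
      gll <- gll + sum(e_k^2) / sigma2_new +
        (if (sigma2_b_new > 0) b_new[k]^2 / sigma2_b_new + log(sigma2_b_new) else 0) +
        length(ii) * log(sigma2_new)
    }
    gll_trace <- c(gll_trace, gll)
    b <- b_new; sigma2 <- sigma2_new; sigma2_b <- sigma2_b_new
    if (it > 1) {
      rel <- abs(gll_trace[it] - gll_trace[it - 1]) /
        max(abs(gll_trace[it - 1]), 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
  }

  structure(list(forest = forest, b = b, sigma2 = sigma2,
                 sigma2_b = sigma2_b, gll_trace = gll_trace,
                 converged = converged, clusters = names(b)),
            class = "merf")
}

#' Predict from a mixed-effect random forest
#'
#' Known clusters receive `f(x) + b_i`; unseen clusters receive the
#' fixed-effect forest prediction alone.
#'
#' @param object a fitted `merf`.
#' @param x feature matrix.
#' @param cluster cluster ids; `NULL` treats all rows as unseen.
#' @return Numeric predictions (not yet clipped to [0, 1]).
#' @export
predict_merf <- function(object, x, cluster = NULL) {
  f <- stats::predict(object$forest, data = as.matrix(x),
                      num.threads = 1)$predictions
  if (is.null(cluster)) return(f)
  cluster <- as.character(cluster)
  add <- ifelse(cluster %in% names(object$b), object$b[cluster], 0)
  f + unname(add)
}

#' @export
print.merf <- function(x, ...) {
  cat(sprintf("<merf> %d clusters, sigma2 = %.4g, sigma2_b = %.4g, %s\n",
              length(x$b), x$sigma2, x$sigma2_b,
              if (x$converged) "converged" else "max iterations reached"))
  invisible(x)
}
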