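#' Soft-thresholding operator
#'
#' The elementary kernel of coordinate-descent LASSO:
#' `sign(z) * max(|z| - t, 0)`.
#'
#' @param z numeric value(s).
#' @param t non-negative threshold.
#' @return the soft-thresholded value(s).
#' @export
soft_threshold <- function(z, t) {
  if (any(t < 0)) abort("threshold must be non-negative")
  sign(z) * pmax(abs(z) - t, 0)
}

# internal: center/scale a design matrix; norms use the 1/n convention so the
# coordinate updates simplify on the standardized scale
prep_design <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("design matrix must have no missing cells")
  if (standardize) {
    cm <- colMeans(x)
    xc <- sweep(x, 2, cm)
    sn <- sqrt(colMeans(xc^2))
    if (any(sn == 0)) abort("constant predictor column cannot be scaled")
    xs <- sweep(xc, 2, sn, "/")
    list(x = xs, center = cm, scale = sn, norms2 = rep(1, ncol(x)))
  } else {
    list(x = x, center = rep(0, ncol(x)), scale = rep(1, ncol(x)),
         norms2 = colMeans(x^2))
  }
}

#' Fit the LASSO by cyclic coordinate descent
#'
#' Minimizes `(1/2n) * sum((y - intercept - X b)^2) + lambda * sum(|b|)` with
#' cyclic coordinate descent, zero initialization and deterministic updates.
#' By default predictors are internally centered and scaled (and the response
#' centered); coefficients are reported back on the scale of the input
#' columns.
#'
#' @param x predictor matrix (or data frame of numerics), no missing cells.
#' @param y numeric response.
#' @param lambda a single penalty or a decreasing sequence (warm starts are
#'   used along a sequence).
#' @param tol convergence tolerance on the maximum coefficient update
#'   (internal scale), default 1e-8.
#' @param max_iter maximum full sweeps per lambda.
#' @param standardize internally center/scale predictors? Default `TRUE`.
#' @param intercept fit an intercept (by centering `y`)? Default `TRUE`.
#' @return for a single lambda, a list with `coefficients` (named),
#'   `intercept`, `lambda`, `iters`; for a sequence, the same with a
#'   coefficient matrix (predictors x lambdas).
#' @examples
#' x <- matrix(rnorm(200), 50, 4); y <- x[, 1] * 0.5 + rnorm(50, 0, 0.1)
#' lasso_fit(x, y, lambda = 0.05)$coefficients
#' @export
lasso_fit <- function(x, y, lambda, tol = 1e-8, max_iter = 100000L,
                      standardize = TRUE, intercept = TRUE) {
  if (length(y) < 2) abort("need at least 2 observations")
  if (any(lambda < 0)) abort("lambda must be non-negative")
  if (is.unsorted(rev(lambda))) {
    abort("a lambda sequence must be decreasing (warm starts)")
  }
  d <- prep_design(x, standardize)
  if (nrow(d$x) != length(y)) abort("nrow(x) must equal length(y)")
  my <- if (intercept) mean(y) else 0
  yc <- y - my
  fit <- cd_lasso_path(d$x, yc, as.numeric(lambda), d$norms2, tol,
                       as.integer(max_iter))
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)[1]
    abort(
      message = sprintf("coordinate descent did not converge at lambda = %g within %d sweeps",
                        lambda[bad], max_iter),
      class = "clpn_lasso_nonconvergence",
      last_iterate = fit$beta[, bad] / d$scale)
  }
  beta <- fit$beta / d$scale          # back to input-column scale
  cn <- colnames(as.matrix(x)) %||% paste0("x", seq_len(ncol(d$x)))
  rownames(beta) <- cn
  b0 <- my - as.numeric(crossprod(beta, d$center))
  if (length(lambda) == 1) {
    list(coefficients = stats::setNames(beta[, 1], cn), intercept = b0[1],
         lambda = lambda, iters = fit$iters[1])
  } else {
    list(coefficients = beta, intercept = b0, lambda = lambda,
         iters = fit$iters)
  }
}

#' Karush-Kuhn-Tucker residuals of a LASSO solution
#'
#' For each predictor, computes the gradient of the smooth part,
#' `g_j = (1/n) x_j' (y - intercept - X b)` on the internally standardized
#' scale, and returns the maximum violation of the stationarity conditions:
#' `|g_j| <= lambda` for zero coefficients and `g_j = lambda * sign(b_j)`
#' for nonzero ones.
#'
#' @inheritParams lasso_fit
#' @param beta named coefficient vector on the input-column scale.
#' @param b0 intercept.
#' @param lambda the penalty the solution was fitted at.
#' @return the maximum KKT violation (0 means exact stationarity).
#' @export
lasso_kkt <- function(x, y, beta, b0, lambda, standardize = TRUE) {
  d <- prep_design(x, standardize)
  beta_std <- beta * d$scale
  r <- y - b0 - as.matrix(x) %*% beta
  g <- as.numeric(crossprod(d$x, r)) / length(y)
  viol <- ifelse(beta_std == 0, pmax(abs(g) - lambda, 0),
                 abs(g - lambda * sign(beta_std)))
  max(viol)
}

#' Build a log-spaced penalty path
#'
#' The first lambda is the smallest penalty that zeroes every coefficient for
#' the given (internally standardized) design:
#' `lambda_max = max_j |<x_j, y - mean(y)>| / n`. The grid is log-spaced down
#' to `ratio_min * lambda_max`.
#'
#' @inheritParams lasso_fit
#' @param n_lambdas grid length (default 100).
#' @param ratio_min ratio of the smallest to the largest lambda
#'   (default 1e-3).
#' @return an object of class `clpn_penalty_path`: list with `lambdas`,
#'   `lambda_max`, `n_lambdas`, `ratio_min`.
#' @export
build_lambda_path <- function(x, y, n_lambdas = 100L, ratio_min = 1e-3,
                              standardize = TRUE) {
  if (sd(y) == 0) abort("response is constant; no penalty path exists")
  d <- prep_design(x, standardize)
  yc <- y - mean(y)
  lambda_max <- max(abs(as.numeric(crossprod(d$x, yc))) / length(y))
  lambdas <- exp(seq(log(lambda_max), log(ratio_min * lambda_max),
                     length.out = n_lambdas))
  structure(list(lambdas = lambdas, lambda_max = lambda_max,
                 n_lambdas = as.integer(n_lambdas), ratio_min = ratio_min),
            class = "clpn_penalty_path")
}

#' Select the LASSO penalty by k-fold cross-validation
#'
#' Participants are partitioned into `k` folds by a seeded permutation; for
#' each fold the full path is fitted on the remaining data (warm starts) and
#' held-out squared error is recorded per lambda. The default rule returns
#' the lambda minimizing mean held-out error (`"min"`); `"one_se"` returns
#' the largest lambda whose mean error is within one standard error of the
#' minimum.
#'
#' @inheritParams lasso_fit
#' @param path a [build_lambda_path()] result, or `NULL` to build one.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param rule `"min"` (default) or `"one_se"`.
#' @return list with `lambda` (selected), `rule`, `cv_curve` (tibble:
#'   `lambda`, `mean_error`, `se`), `fold_id`.
#' @export
cv_select_lambda <- function(x, y, path = NULL, k = 10L, seed = 1L,
                             rule = c("min", "one_se"), tol = 1e-8,
                             max_iter = 100000L) {
  rule <- match.arg(rule)
  n <- length(y)
  if (k > n) abort("k must not exceed the number of observations")
  if (is.null(path)) path <- build_lambda_path(x, y)
  lambdas <- path$lambdas
  x <- as.matrix(x)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  errs <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- fold_id != f
    fit <- lasso_fit(x[tr, , drop = FALSE], y[tr], lambdas,
                     tol = tol, max_iter = max_iter)
    pred <- sweep(x[!tr, , drop = FALSE] %*% fit$coefficients, 2,
                  -fit$intercept)
    errs[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  mean_err <- colMeans(errs)
  se <- apply(errs, 2, sd) / sqrt(k)
  i_min <- which.min(mean_err)
  i_sel <- if (rule == "min") i_min else {
    which(mean_err <= mean_err[i_min] + se[i_min])[1]
  }
  list(lambda = lambdas[i_sel], rule = rule,
       cv_curve = tibble::tibble(lambda = lambdas, mean_error = mean_err,
                                 se = se),
       fold_id = fold_id)
}
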