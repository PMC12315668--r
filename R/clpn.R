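#' Estimate a cross-lagged panel network for one wave pair
#'
#' Runs one node-wise LASSO regression per node: the wave-(t+1) score of each
#' node is regressed on all five node scores at wave t plus the covariates
#' measured at wave t (age by default; optionally gender). Covariates are
#' predictors only and are never regressed on ("predictor-only" asymmetry).
#' The penalty for each regression is selected by k-fold cross-validation on
#' a log-spaced path; the analysis sample is the set of participants with
#' complete data for all variables used in the pair, and all variables are
#' standardized on that sample before fitting.
#'
#' @param data processed node table (the `data` element of
#'   [preprocess_panel()], or any tibble with `participant_id`, `wave`,
#'   the five node columns, `age`, `gender`).
#' @param wave_pair integer pair `c(t, t+1)`, either `c(1, 2)` or `c(2, 3)`.
#' @param covariates character vector of wave-t covariates; default `"age"`,
#'   use `c("age", "gender")` for the gender sensitivity model.
#' @param k CV folds (default 10).
#' @param seed integer seed (fold assignment).
#' @param n_lambdas,ratio_min penalty path controls.
#' @param rule penalty selection rule, `"min"` (default) or `"one_se"`.
#' @return an object of class `clpn_network`: list with `matrix` (5x5 source
#'   x target lagged coefficients, autoregressive on the diagonal),
#'   `covariate_effects` (covariates x targets), `lambdas_by_target`,
#'   `cv_curves`, `n_used`, `nodes`, `wave_pair`, `covariates`.
#' @examples
#' panel <- simulate_cohort(generator_config(n_participants = 400, seed = 11))
#' net <- fit_clpn(preprocess_panel(panel)$data, c(1, 2), seed = 1)
#' round(net$matrix, 2)
#' @export
fit_clpn <- function(data, wave_pair = c(1, 2), covariates = "age",
                     k = 10L, seed = 1L, n_lambdas = 100L, ratio_min = 1e-3,
                     rule = c("min", "one_se")) {
  rule <- match.arg(rule)
  nodes <- clpn_nodes()
  if (length(wave_pair) != 2 || wave_pair[2] != wave_pair[1] + 1) {
    abort("wave_pair must be consecutive, e.g. c(1, 2)")
  }
  if (any(nodes %in% covariates)) abort("covariates cannot be network nodes")

  wide <- build_pair_frame(data, wave_pair, covariates)
  n_used <- nrow(wide)
  src_cols <- paste0(nodes, "_t")
  tgt_cols <- paste0(nodes, "_t1")
  pred_cols <- c(src_cols, covariates)

  # standardize every variable on the pair analysis sample
  for (v in c(pred_cols, tgt_cols)) {
    if (sd(wide[[v]]) == 0) {
      abort(paste0("variable '", v, "' is constant in the analysis sample"))
    }
    wide[[v]] <- zscore(wide[[v]])$values
  }
  x <- as.matrix(wide[pred_cols])

  mat <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  cov_eff <- matrix(0, length(covariates), length(nodes),
                    dimnames = list(covariates, nodes))
  lambdas <- stats::setNames(numeric(length(nodes)), nodes)
  cv_curves <- list()
  regressions <- list()
  for (j in seq_along(nodes)) {
    yv <- wide[[tgt_cols[j]]]
    path <- build_lambda_path(x, yv, n_lambdas = n_lambdas,
                              ratio_min = ratio_min)
    sel <- cv_select_lambda(x, yv, path = path, k = k, seed = seed,
                            rule = rule)
    fit <- lasso_fit(x, yv, sel$lambda)
    mat[, j] <- fit$coefficients[src_cols]
    cov_eff[, j] <- fit$coefficients[covariates]
    lambdas[j] <- sel$lambda
    cv_curves[[nodes[j]]] <- sel$cv_curve
    regressions[[nodes[j]]] <- list(
      target = nodes[j], coefficients = fit$coefficients,
      intercept = fit$intercept, selected_lambda = sel$lambda,
      cv_curve = sel$cv_curve)
  }

  structure(
    list(wave_pair = wave_pair, nodes = nodes, matrix = mat,
         covariate_effects = cov_eff, covariates = covariates,
         lambdas_by_target = lambdas, cv_curves = cv_curves,
         node_regressions = regressions, n_used = n_used,
         k = k, seed = seed, rule = rule,
         design = list(x = x, targets = wide[tgt_cols])),
    class = "clpn_network")
}

# complete-case wide frame for one wave pair: node scores at t and t+1 plus
# wave-t covariates
build_pair_frame <- function(data, wave_pair, covariates) {
  nodes <- clpn_nodes()
  need <- c("participant_id", "wave", nodes, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("data lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  t0 <- dplyr::filter(data, .data$wave == wave_pair[1])
  t1 <- dplyr::filter(data, .data$wave == wave_pair[2])
  wide <- dplyr::inner_join(
    dplyr::select(t0, "participant_id", dplyr::all_of(c(nodes, covariates))),
    dplyr::select(t1, "participant_id", dplyr::all_of(nodes)),
    by = "participant_id", suffix = c("_t", "_t1"))
  names(wide)[match(covariates, names(wide))] <- covariates
  wide <- wide[complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 20) {
    abort("fewer than 20 complete cases for this wave pair")
  }
  wide
}

#' @export
print.clpn_network <- function(x, digits = 2, ...) {
  cat("<clpn_network> waves", paste(x$wave_pair, collapse = "->"),
      "| n =", x$n_used, "\n")
  cat("lagged coefficients (source rows -> target columns):\n")
  print(round(x$matrix, digits))
  cat("covariate effects:\n")
  print(round(x$covariate_effects, digits))
  cat("density:", round(network_density(x), 3),
      "| penalty rule:", x$rule, "\n")
  invisible(x)
}

#' Tidy a cross-lagged network into an edge list
#'
#' @param x a `clpn_network`.
#' @param ... unused.
#' @return a tibble with `source`, `target`, `weight`, `type` (`lagged`,
#'   `autoregressive`, or `covariate`) and `wave_pair`.
#' @method tidy clpn_network
#' @export
tidy.clpn_network <- function(x, ...) {
  wp <- paste(x$wave_pair, collapse = "->")
  lag <- tidyr::expand_grid(source = x$nodes, target = x$nodes) |>
    dplyr::mutate(weight = as.numeric(x$matrix[cbind(.data$source, .data$target)]),
                  type = ifelse(.data$source == .data$target,
                                "autoregressive", "lagged"))
  cov <- tidyr::expand_grid(source = x$covariates, target = x$nodes) |>
    dplyr::mutate(weight = as.numeric(
      x$covariate_effects[cbind(.data$source, .data$target)]),
      type = "covariate")
  dplyr::bind_rows(lag, cov) |>
    dplyr::mutate(wave_pair = wp)
}

#' One-row summary of a fitted cross-lagged network
#'
#' @param x a `clpn_network`.
#' @param ... unused.
#' @return a tibble with wave pair, sample size, node count, density and the
#'   number of nonzero cross-lagged, autoregressive and covariate effects.
#' @method glance clpn_network
#' @export
glance.clpn_network <- function(x, ...) {
  e <- tidy(x)
  tibble::tibble(
    wave_pair = paste(x$wave_pair, collapse = "->"),
    n_used = x$n_used,
    n_nodes = length(x$nodes),
    density = network_density(x),
    n_lagged_nonzero = sum(e$weight != 0 & e$type == "lagged"),
    n_autoregressive_nonzero = sum(e$weight != 0 & e$type == "autoregressive"),
    n_covariate_nonzero = sum(e$weight != 0 & e$type == "covariate"),
    penalty_rule = x$rule)
}

#' Heatmap of estimated cross-lagged coefficients
#'
#' @param object a `clpn_network`.
#' @param ... unused.
#' @return a ggplot object: source x target tile map, covariate rows included.
#' @method autoplot clpn_network
#' @export
autoplot.clpn_network <- function(object, ...) {
  edges <- tidy(object) |>
    dplyr::mutate(source = factor(.data$source,
                                  levels = rev(c(object$nodes, object$covariates))),
                  target = factor(.data$target, levels = object$nodes))
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$target, y = .data$source,
                                      fill = .data$weight)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$weight == 0, "", sprintf("%.2f", .data$weight))),
      size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(
      title = paste("Cross-lagged network, waves",
                    paste(object$wave_pair, collapse = " → ")),
      x = paste0("target (wave ", object$wave_pair[2], ")"),
      y = paste0("source (wave ", object$wave_pair[1], ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
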