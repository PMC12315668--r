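#' Nonparametric bootstrap of cross-lagged edge weights
#'
#' Resamples participants with replacement (same n), refits the full
#' estimation pipeline on each replicate — standardization on the resample,
#' penalty path, k-fold cross-validated penalty selection, LASSO — and
#' summarizes every directed edge's resampling distribution: mean, SD,
#' 2.5/97.5 percentile interval and the proportion of replicates in which the
#' edge is nonzero (inclusion proportion). Replicates that fail to fit are
#' recorded and skipped; more than 10% failures is an error.
#'
#' @param data processed node table (see [fit_clpn()]).
#' @param wave_pair integer pair `c(t, t+1)`.
#' @param b number of bootstrap replicates (default 1000).
#' @param seed integer seed; replicate resamples and CV fold seeds are derived
#'   from it deterministically.
#' @param ... further arguments passed to [fit_clpn()] (e.g. `covariates`,
#'   `k`, `rule`, `n_lambdas`).
#' @return an object of class `clpn_bootstrap`: list with `edge_summaries`
#'   (tibble: `source`, `target`, `type`, `mean`, `sd`, `lower`, `upper`,
#'   `inclusion_proportion`), `b`, `b_failed`, `seed`, `wave_pair`, and the
#'   per-replicate draws array `draws`.
#' @examples
#' \donttest{
#' panel <- simulate_cohort(generator_config(n_participants = 300, seed = 4))
#' pp <- preprocess_panel(panel)
#' bs <- bootstrap_network(pp$data, c(1, 2), b = 20, seed = 9, n_lambdas = 40)
#' dplyr::arrange(bs$edge_summaries, dplyr::desc(inclusion_proportion))
#' }
#' @export
bootstrap_network <- function(data, wave_pair = c(1, 2), b = 1000L,
                              seed = 1L, ...) {
  ids <- unique(data$participant_id)
  n <- length(ids)
  draws_meta <- withr::with_seed(seed, list(
    resamples = replicate(b, sample(ids, n, replace = TRUE),
                          simplify = FALSE),
    cv_seeds = sample.int(2147483646L, b)))

  point0 <- fit_clpn(data, wave_pair, seed = stage_seed(seed, "fit"), ...)
  nodes <- point0$nodes
  covs <- point0$covariates
  p <- length(nodes) + length(covs)
  draws <- array(NA_real_, c(p, length(nodes), b),
                 dimnames = list(c(nodes, covs), nodes, NULL))
  failures <- 0L
  for (r in seq_len(b)) {
    boot_data <- resample_panel(data, draws_meta$resamples[[r]])
    fit <- tryCatch(
      fit_clpn(boot_data, wave_pair, seed = draws_meta$cv_seeds[r], ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
      next
    }
    draws[seq_along(nodes), , r] <- fit$matrix
    draws[length(nodes) + seq_along(covs), , r] <- fit$covariate_effects
  }
  if (failures > 0.10 * b) {
    abort(sprintf("bootstrap failed in %d of %d replicates (> 10%%)",
                  failures, b))
  }

  summaries <- tidyr::expand_grid(source = c(nodes, covs), target = nodes) |>
    dplyr::mutate(
      type = dplyr::case_when(
        .data$source %in% covs ~ "covariate",
        .data$source == .data$target ~ "autoregressive",
        TRUE ~ "lagged"),
      mean = NA_real_, sd = NA_real_, lower = NA_real_, upper = NA_real_,
      inclusion_proportion = NA_real_)
  for (i in seq_len(nrow(summaries))) {
    v <- draws[summaries$source[i], summaries$target[i], ]
    v <- v[!is.na(v)]
    summaries$mean[i] <- mean(v)
    summaries$sd[i] <- sd(v)
    summaries$lower[i] <- unname(quantile(v, 0.025, type = 7))
    summaries$upper[i] <- unname(quantile(v, 0.975, type = 7))
    summaries$inclusion_proportion[i] <- mean(v != 0)
  }

  structure(
    list(edge_summaries = summaries, b = as.integer(b), b_failed = failures,
         seed = seed, wave_pair = wave_pair, nodes = nodes,
         covariates = covs, draws = draws),
    class = "clpn_bootstrap")
}

# participant-level resample: duplicated participants get distinct ids so
# downstream joins keep one record per participant x wave
resample_panel <- function(data, sampled_ids) {
  idx <- split(seq_len(nrow(data)), data$participant_id)
  rows <- unlist(idx[sampled_ids], use.names = FALSE)
  out <- data[rows, , drop = FALSE]
  reps <- vapply(idx[sampled_ids], length, integer(1))
  out$participant_id <- rep(sprintf("B%06d", seq_along(sampled_ids)), reps)
  out
}

#' @export
print.clpn_bootstrap <- function(x, ...) {
  cat("<clpn_bootstrap> waves", paste(x$wave_pair, collapse = "->"),
      "| b =", x$b, "(", x$b_failed, "failed )\n")
  top <- dplyr::slice_max(x$edge_summaries, .data$inclusion_proportion, n = 5,
                          with_ties = FALSE)
  print(top)
  invisible(x)
}

#' @method tidy clpn_bootstrap
#' @export
tidy.clpn_bootstrap <- function(x, ...) {
  dplyr::mutate(x$edge_summaries,
                wave_pair = paste(x$wave_pair, collapse = "->"))
}

#' @method glance clpn_bootstrap
#' @export
glance.clpn_bootstrap <- function(x, ...) {
  tibble::tibble(wave_pair = paste(x$wave_pair, collapse = "->"),
                 b = x$b, b_failed = x$b_failed,
                 n_edges = nrow(x$edge_summaries),
                 mean_interval_width = mean(x$edge_summaries$upper -
                                              x$edge_summaries$lower))
}

#' Join bootstrap summaries with the point network
#'
#' Produces the edge accuracy table: point estimate, bootstrap mean,
#' percentile interval, inclusion proportion, and a flag for edges whose
#' interval excludes zero.
#'
#' @param result a [bootstrap_network()] result.
#' @param point_network the corresponding [fit_clpn()] network (same nodes
#'   and covariates).
#' @return a tibble with one row per directed edge (including covariate
#'   edges).
#' @export
summarize_edges <- function(result, point_network) {
  stopifnot(inherits(result, "clpn_bootstrap"),
            inherits(point_network, "clpn_network"))
  if (!identical(result$nodes, point_network$nodes) ||
      !identical(result$covariates, point_network$covariates)) {
    abort("bootstrap result and point network have different node sets")
  }
  pts <- tidy(point_network) |>
    dplyr::select("source", "target", point = "weight")
  dplyr::left_join(result$edge_summaries, pts,
                   by = c("source", "target")) |>
    dplyr::mutate(excludes_zero = .data$lower > 0 | .data$upper < 0) |>
    dplyr::relocate("point", .after = "type")
}

#' Bootstrap edge accuracy plot
#'
#' Point estimates with percentile intervals, edges ordered by point weight
#' (the standard edge-accuracy display for network models).
#'
#' @param object a `clpn_bootstrap`.
#' @param point_network optional matching `clpn_network` to overlay point
#'   estimates.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot clpn_bootstrap
#' @export
autoplot.clpn_bootstrap <- function(object, point_network = NULL, ...) {
  tab <- if (is.null(point_network)) {
    dplyr::mutate(object$edge_summaries, point = .data$mean)
  } else {
    summarize_edges(object, point_network)
  }
  tab <- dplyr::mutate(tab,
                       edge = paste(.data$source, "→", .data$target)) |>
    dplyr::arrange(.data$point) |>
    dplyr::mutate(edge = factor(.data$edge, levels = .data$edge))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$point, y = .data$edge)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            height = 0, color = "grey40") +
    ggplot2::geom_point(color = "#2166ac") +
    ggplot2::labs(x = "edge weight (bootstrap 95% percentile interval)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
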