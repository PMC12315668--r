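#' Density of a cross-lagged network
#'
#' The proportion of nonzero entries in the nodes x nodes lagged coefficient
#' matrix (autoregressive diagonal included, covariate rows excluded). On a
#' 5-node network each cell is 1/25 = 4% of density, so e.g. 18 and 23
#' nonzero cells give densities of 0.72 and 0.92. "Nonzero" means exactly
#' nonzero: the LASSO produces exact zeros, so no epsilon threshold is
#' applied.
#'
#' @param network a `clpn_network`, or a square numeric matrix.
#' @return a proportion in `[0, 1]`.
#' @export
network_density <- function(network) {
  m <- if (inherits(network, "clpn_network")) network$matrix else network
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("need a square lagged matrix")
  mean(m != 0)
}

#' Compare two cross-lagged networks
#'
#' Descriptive between-network comparison: densities, support overlap
#' (Jaccard index over nonzero lagged cells), Pearson correlation of the
#' vectorized lagged weights, and the list of edges nonzero in both networks
#' with opposite signs.
#'
#' @param a,b `clpn_network` objects with identical node sets.
#' @return a list of class `clpn_comparison` with elements `density_a`,
#'   `density_b`, `jaccard`, `weight_correlation`, `sign_flips` (tibble).
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "clpn_network"), inherits(b, "clpn_network"))
  if (!identical(a$nodes, b$nodes)) abort("networks have different node sets")
  ma <- a$matrix; mb <- b$matrix
  sa <- ma != 0; sb <- mb != 0
  union_n <- sum(sa | sb)
  jaccard <- if (union_n == 0) 1 else sum(sa & sb) / union_n
  wc <- if (sd(as.numeric(ma)) == 0 || sd(as.numeric(mb)) == 0) {
    NA_real_
  } else {
    cor(as.numeric(ma), as.numeric(mb))
  }
  flips <- tidyr::expand_grid(source = a$nodes, target = a$nodes) |>
    dplyr::mutate(weight_a = as.numeric(ma[cbind(.data$source, .data$target)]),
                  weight_b = as.numeric(mb[cbind(.data$source, .data$target)])) |>
    dplyr::filter(.data$weight_a * .data$weight_b < 0)
  structure(list(density_a = network_density(ma), density_b = network_density(mb),
                 jaccard = jaccard, weight_correlation = wc,
                 sign_flips = flips,
                 wave_pair_a = a$wave_pair, wave_pair_b = b$wave_pair),
            class = "clpn_comparison")
}

#' @export
print.clpn_comparison <- function(x, ...) {
  cat("<clpn_comparison>\n")
  cat(sprintf(" densities: %.2f vs %.2f | support Jaccard: %.2f | weight r: %.2f\n",
              x$density_a, x$density_b, x$jaccard, x$weight_correlation))
  if (nrow(x$sign_flips)) {
    cat(" sign-flipped edges:\n"); print(x$sign_flips)
  }
  invisible(x)
}

#' Classify executive-function/psychopathology links as risk factor,
#' consequence, both, or none
#'
#' For every (executive-function node, symptom node) pair, the presence of
#' directed edges decides the label: only EF -> symptom nonzero means the EF
#' deficit acts as a *risk factor* for the symptom domain; only
#' symptom -> EF nonzero means the EF deficit is a *consequence*; both
#' directions nonzero means *both*; neither means *none*. Labels are based on
#' edge presence, not sign; the two directed weights are carried as evidence.
#' Optionally, an edge only counts when its bootstrap inclusion proportion
#' reaches `inclusion_threshold`.
#'
#' @param network a `clpn_network`.
#' @param ef_nodes executive-function node names (default: working memory and
#'   the two inhibitory-control indices).
#' @param symptom_nodes symptom node names (default internalizing and
#'   externalizing); must not overlap `ef_nodes`.
#' @param bootstrap optional [bootstrap_network()] result for the same
#'   network.
#' @param inclusion_threshold minimum inclusion proportion for an edge to
#'   count (requires `bootstrap`).
#' @return a tibble of class `clpn_accounts`: `ef_node`, `symptom_node`,
#'   `label`, `ef_to_symptom`, `symptom_to_ef`, `wave_pair`.
#' @export
classify_accounts <- function(network,
                              ef_nodes = c("working_memory",
                                           "inhibition_speed",
                                           "inhibition_accuracy"),
                              symptom_nodes = c("internalizing",
                                                "externalizing"),
                              bootstrap = NULL,
                              inclusion_threshold = NULL) {
  stopifnot(inherits(network, "clpn_network"))
  if (length(intersect(ef_nodes, symptom_nodes))) {
    abort("ef_nodes and symptom_nodes must not overlap")
  }
  absent <- setdiff(c(ef_nodes, symptom_nodes), network$nodes)
  if (length(absent)) {
    abort(paste0("nodes not in network: ", paste(absent, collapse = ", ")))
  }
  included <- function(src, tgt) {
    w <- network$matrix[src, tgt]
    if (w == 0) return(FALSE)
    if (!is.null(inclusion_threshold)) {
      if (is.null(bootstrap)) abort("inclusion_threshold requires a bootstrap result")
      ip <- bootstrap$edge_summaries$inclusion_proportion[
        bootstrap$edge_summaries$source == src &
          bootstrap$edge_summaries$target == tgt]
      return(ip >= inclusion_threshold)
    }
    TRUE
  }
  out <- tidyr::expand_grid(ef_node = ef_nodes, symptom_node = symptom_nodes) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      forward = included(.data$ef_node, .data$symptom_node),
      backward = included(.data$symptom_node, .data$ef_node),
      label = dplyr::case_when(
        .data$forward & .data$backward ~ "both",
        .data$forward ~ "risk_factor",
        .data$backward ~ "consequence",
        TRUE ~ "none"),
      ef_to_symptom = network$matrix[.data$ef_node, .data$symptom_node],
      symptom_to_ef = network$matrix[.data$symptom_node, .data$ef_node]) |>
    dplyr::ungroup() |>
    dplyr::select(-"forward", -"backward") |>
    dplyr::mutate(wave_pair = paste(network$wave_pair, collapse = "->"))
  class(out) <- c("clpn_accounts", class(out))
  out
}

#' Parameter-recovery experiment against generator truth
#'
#' For each sample size in `n_grid` and each replication: simulate a cohort
#' from `config` (with attrition per the configuration), preprocess it, fit
#' the cross-lagged network for `wave_pair`, and score the estimated lagged
#' matrix against the generating one. Metrics per replication: sensitivity
#' (true nonzero edges estimated nonzero), specificity (true zero edges
#' estimated zero), sign accuracy (detected true edges with the correct
#' sign), and the correlation between true and estimated weights on the true
#' support. Aggregated with Monte-Carlo standard errors.
#'
#' @param config a [generator_config()] (its `n_participants` is overridden
#'   by `n_grid`).
#' @param reps replications per condition (>= 2).
#' @param n_grid vector of cohort sizes.
#' @param seed integer seed; per-rep seeds derived deterministically.
#' @param wave_pair which wave pair to score (default `c(1, 2)`).
#' @param apply_attrition apply the configured attrition model per rep?
#'   Default `TRUE`.
#' @param ... passed to [fit_clpn()].
#' @return a tibble of class `clpn_recovery` (one row per condition x
#'   metric: `n`, `metric`, `value`, `mc_se`, `reps`), with per-rep results
#'   in attribute `"per_rep"`.
#' @export
run_recovery_experiment <- function(config, reps = 10L, n_grid = 1000L,
                                    seed = 1L, wave_pair = c(1, 2),
                                    apply_attrition = TRUE, ...) {
  stopifnot(inherits(config, "clpn_generator_config"), reps >= 2)
  truth <- config$true_network$lag[[paste(wave_pair, collapse = "_")]]
  per_rep <- list()
  for (n in n_grid) {
    failures <- 0L
    for (r in seq_len(reps)) {
      rep_seed <- stage_seed(seed + 7919 * r + n, "recovery")
      cfg <- config
      cfg$n_participants <- as.integer(n)
      cfg$seed <- rep_seed
      res <- tryCatch({
        panel <- simulate_cohort(cfg)
        if (apply_attrition) {
          panel <- apply_attrition(panel, cfg$attrition,
                                   seed = stage_seed(rep_seed, "attrition"))
        }
        pp <- preprocess_panel(panel)
        net <- fit_clpn(pp$data, wave_pair,
                        seed = stage_seed(rep_seed, "folds"), ...)
        score_recovery(truth, net$matrix)
      }, error = function(e) NULL)
      if (is.null(res)) {
        failures <- failures + 1L
        next
      }
      per_rep[[length(per_rep) + 1]] <- dplyr::mutate(res, n = n, rep = r)
    }
    if (failures > 0.20 * reps) {
      abort(sprintf("recovery experiment failed in %d of %d reps at n = %d",
                    failures, reps, n))
    }
  }
  per_rep <- dplyr::bind_rows(per_rep)
  out <- per_rep |>
    tidyr::pivot_longer(-c("n", "rep"), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$n, .data$metric) |>
    dplyr::summarise(
      reps = sum(!is.na(.data$value)),
      mc_se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      value = mean(.data$value, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::relocate("value", .before = "mc_se")
  attr(out, "per_rep") <- per_rep
  attr(out, "wave_pair") <- wave_pair
  class(out) <- c("clpn_recovery", class(out))
  out
}

#' Score an estimated lagged matrix against the generating truth
#'
#' @param truth,estimate square matrices with identical dimnames.
#' @return one-row tibble: `sensitivity`, `specificity`, `sign_accuracy`,
#'   `weight_correlation`.
#' @export
score_recovery <- function(truth, estimate) {
  stopifnot(identical(dim(truth), dim(estimate)))
  tv <- as.numeric(truth); ev <- as.numeric(estimate)
  nz <- tv != 0
  detected <- nz & ev != 0
  tibble::tibble(
    sensitivity = if (any(nz)) mean(ev[nz] != 0) else NA_real_,
    specificity = if (any(!nz)) mean(ev[!nz] == 0) else NA_real_,
    sign_accuracy = if (any(detected)) {
      mean(sign(ev[detected]) == sign(tv[detected]))
    } else NA_real_,
    weight_correlation = if (sum(nz) >= 3 && sd(ev[nz]) > 0) {
      cor(tv[nz], ev[nz])
    } else NA_real_)
}
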