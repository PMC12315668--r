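#' Write a panel dataset to CSV
#'
#' Two dialects: `"wide"` (one row per participant x wave, one column per
#' measure) and `"long"` (one row per participant x wave x variable with
#' columns `participant_id`, `wave`, `variable`, `value`, `group`, `age`,
#' `gender`, `instrument`).
#'
#' @param data a panel tibble.
#' @param path output file.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(data, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  out <- tibble::as_tibble(as.data.frame(data))
  out <- out[setdiff(names(out), "dropout_wave")]
  if (dialect == "long") {
    out <- tidyr::pivot_longer(out, dplyr::all_of(clpn_measures()),
                               names_to = "variable", values_to = "value") |>
      dplyr::select("participant_id", "wave", "variable", "value", "group",
                    "age", "gender", "instrument")
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a panel dataset from CSV
#'
#' Accepts the two dialects written by [write_panel_table()]; the dialect is
#' detected from the header when `dialect = "auto"`. Duplicate
#' (participant, wave) records and unknown variable names are errors.
#'
#' @param path CSV file.
#' @param dialect `"auto"` (default), `"wide"` or `"long"`.
#' @return a `clpn_panel` tibble in wide form.
#' @export
read_panel_table <- function(path, dialect = c("auto", "wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # base parser: correctly-rounded doubles, so write -> read round-trips exactly
  raw <- tibble::as_tibble(utils::read.csv(path, na.strings = "",
                                           stringsAsFactors = FALSE))
  if (dialect == "auto") {
    dialect <- if ("variable" %in% names(raw)) "long" else "wide"
  }
  if (dialect == "long") {
    need <- c("participant_id", "wave", "variable", "value")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) {
      abort(paste0("long dialect lacks columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    unknown <- setdiff(unique(raw$variable), clpn_measures())
    if (length(unknown)) {
      abort(paste0("unknown variable names: ", paste(unknown, collapse = ", ")))
    }
    dup <- raw |>
      dplyr::count(.data$participant_id, .data$wave, .data$variable) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      abort(paste0("duplicated participant-wave records: ",
                   paste(utils::head(paste(dup$participant_id, dup$wave,
                                           sep = "/"), 5), collapse = ", ")))
    }
    out <- tidyr::pivot_wider(raw, names_from = "variable",
                              values_from = "value")
  } else {
    need <- c("participant_id", "wave", clpn_measures())
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) {
      abort(paste0("wide dialect lacks columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    dup <- raw |>
      dplyr::count(.data$participant_id, .data$wave) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      abort(paste0("duplicated participant-wave rows: ",
                   paste(utils::head(paste(dup$participant_id, dup$wave,
                                           sep = "/"), 5), collapse = ", ")))
    }
    out <- raw
  }
  out <- dplyr::arrange(out, .data$participant_id, .data$wave)
  out <- dplyr::relocate(out, "participant_id", "wave", "group", "gender",
                         "age", "instrument")
  class(out) <- c("clpn_panel", class(out))
  out
}

#' Assemble a pipeline configuration
#'
#' @param generator a [generator_config()], or a path to a panel CSV to load
#'   instead of simulating.
#' @param covariates covariates for estimation (default `"age"`).
#' @param k CV folds.
#' @param rule penalty selection rule.
#' @param n_lambdas penalty path length.
#' @param b bootstrap replicates (`0` skips the bootstrap stage).
#' @param seed single integer seed; per-stage seeds are derived from it.
#' @param out_dir output directory for artifacts.
#' @return a list of class `clpn_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            covariates = "age", k = 10L, rule = "min",
                            n_lambdas = 100L, b = 1000L, seed = 1L,
                            out_dir = tempfile("clpn_run_")) {
  structure(list(generator = generator, covariates = covariates, k = k,
                 rule = rule, n_lambdas = n_lambdas, b = as.integer(b),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "clpn_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> apply attrition -> preprocess -> fit both
#' wave-pair networks -> bootstrap (optional) -> evaluate (densities,
#' network comparison, account classification), writing all artifacts and a
#' run manifest (stage seeds, row counts, per-file MD5 hashes) to
#' `config$out_dir`. Two runs with the same configuration produce
#' byte-identical edge lists.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "clpn_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), parent = e)
    })
  }

  panel <- stage("simulate", {
    if (is.character(config$generator)) {
      read_panel_table(config$generator)
    } else {
      gen <- config$generator
      gen$seed <- stage_seed(seed, "simulate")
      p <- simulate_cohort(gen)
      apply_attrition(p, gen$attrition, seed = stage_seed(seed, "attrition"))
    }
  })
  write_panel_table(panel, file.path(config$out_dir, "cohort_wide.csv"))

  networks <- list()
  boots <- list()
  accounts <- list()
  for (wp in list(c(1, 2), c(2, 3))) {
    key <- paste0("w", wp[1], wp[2])
    pp <- stage(paste0("preprocess_", key),
                preprocess_panel(panel,
                                 require_wave3_symptoms = wp[1] == 2))
    if (wp[1] == 1) {
      readr::write_csv(pp$data, file.path(config$out_dir, "nodes_w12_sample.csv"))
      jsonlite::write_json(
        list(n_input = pp$report$n_input,
             n_after_complete_case = pp$report$n_after_complete_case,
             n_outlier_cells_removed = as.list(pp$report$n_outlier_cells_removed),
             standardization_params = pp$report$standardization_params),
        file.path(config$out_dir, "preprocess_report.json"),
        auto_unbox = TRUE, digits = NA)
    }
    net <- stage(paste0("fit_", key),
                 fit_clpn(pp$data, wp, covariates = config$covariates,
                          k = config$k, seed = stage_seed(seed + wp[1], "fit"),
                          n_lambdas = config$n_lambdas, rule = config$rule))
    networks[[key]] <- net
    readr::write_csv(tidy(net), file.path(config$out_dir,
                                          paste0("edges_", key, ".csv")))
    utils::write.csv(net$matrix,
                     file.path(config$out_dir, paste0("matrix_", key, ".csv")))
    jsonlite::write_json(
      list(wave_pair = net$wave_pair, nodes = net$nodes,
           matrix = net$matrix, covariate_effects = net$covariate_effects,
           lambdas_by_target = as.list(net$lambdas_by_target),
           n_used = net$n_used, density = network_density(net)),
      file.path(config$out_dir, paste0("network_", key, ".json")),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

    if (config$b > 0) {
      bs <- stage(paste0("bootstrap_", key),
                  bootstrap_network(pp$data, wp, b = config$b,
                                    seed = stage_seed(seed + wp[1], "bootstrap"),
                                    covariates = config$covariates,
                                    k = config$k, n_lambdas = config$n_lambdas,
                                    rule = config$rule))
      boots[[key]] <- bs
      readr::write_csv(summarize_edges(bs, net),
                       file.path(config$out_dir,
                                 paste0("edge_accuracy_", key, ".csv")))
    }
    acc <- classify_accounts(net)
    accounts[[key]] <- acc
    readr::write_csv(acc, file.path(config$out_dir,
                                    paste0("accounts_", key, ".csv")))
  }

  comparison <- compare_networks(networks$w12, networks$w23)
  jsonlite::write_json(
    list(density_w12 = comparison$density_a, density_w23 = comparison$density_b,
         jaccard = comparison$jaccard,
         weight_correlation = comparison$weight_correlation),
    file.path(config$out_dir, "comparison.json"), auto_unbox = TRUE,
    digits = NA)

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    seed = seed,
    stage_seeds = list(simulate = stage_seed(seed, "simulate"),
                       attrition = stage_seed(seed, "attrition"),
                       fit_w12 = stage_seed(seed + 1, "fit"),
                       fit_w23 = stage_seed(seed + 2, "fit")),
    bootstrap_b = config$b,
    bootstrap_skipped = config$b == 0,
    n_participants = dplyr::n_distinct(panel$participant_id),
    n_rows = nrow(panel),
    density = list(w12 = network_density(networks$w12),
                   w23 = network_density(networks$w23)),
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(panel = panel, networks = networks, bootstraps = boots,
                 accounts = accounts, comparison = comparison,
                 manifest = manifest, out_dir = config$out_dir))
}

#' Write a generator configuration to a YAML file
#'
#' Serializes the scalar fields, lag matrices and seeds so a run can be
#' reproduced from its recorded configuration.
#'
#' @param config a [generator_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "clpn_generator_config"))
  yaml::write_yaml(list(
    n_participants = config$n_participants,
    high_risk_fraction = config$high_risk_fraction,
    risk_mean_shift = as.list(config$risk_mean_shift),
    age_mean_by_wave = config$age_mean_by_wave,
    age_sd = config$age_sd,
    male_fraction = config$male_fraction,
    seed = config$seed,
    lag_w12 = apply(config$true_network$lag$`1_2`, 1, as.list),
    lag_w23 = apply(config$true_network$lag$`2_3`, 1, as.list),
    innovation_sd = as.list(config$true_network$innovation_sd),
    age_effects = as.list(config$true_network$age_effects),
    attrition = list(
      internalizing_coef = config$attrition$internalizing_coef,
      target_attrition = config$attrition$target_attrition)), path)
  invisible(path)
}
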