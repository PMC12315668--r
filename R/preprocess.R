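#' Variable specification for preprocessing
#'
#' Describes one observed measure: its role, whether it must be inverted so
#' that higher scores mean better performance, its aggregation group (e.g. the
#' two span indicators forming the working-memory composite), the instrument
#' it comes from, and the waves at which it is available.
#'
#' @param name variable name.
#' @param role one of `"symptom"`, `"cognitive"`, `"covariate"`.
#' @param orientation `"keep"` or `"invert"`; inversion is only valid for
#'   cognitive measures.
#' @param aggregation_group optional label; variables sharing a label are
#'   averaged after standardization.
#' @param instrument `"cbcl"`, `"abcl"` or `"task"`.
#' @param wave_availability integer waves at which the variable is measured.
#' @return an object of class `clpn_variable_spec`.
#' @export
variable_spec <- function(name, role = c("symptom", "cognitive", "covariate"),
                          orientation = c("keep", "invert"),
                          aggregation_group = NULL,
                          instrument = "task",
                          wave_availability = 1:3) {
  role <- match.arg(role)
  orientation <- match.arg(orientation)
  if (orientation == "invert" && role != "cognitive") {
    abort("orientation = 'invert' is only valid for cognitive variables")
  }
  structure(list(name = name, role = role, orientation = orientation,
                 aggregation_group = aggregation_group,
                 instrument = instrument,
                 wave_availability = wave_availability),
            class = "clpn_variable_spec")
}

#' Default variable specifications for the six observed measures
#' @return a named list of [variable_spec()] objects.
#' @export
default_variable_specs <- function() {
  list(
    internalizing = variable_spec("internalizing", "symptom", "keep",
                                  instrument = "cbcl"),
    externalizing = variable_spec("externalizing", "symptom", "keep",
                                  instrument = "cbcl"),
    digit_backward = variable_spec("digit_backward", "cognitive", "keep",
                                   aggregation_group = "working_memory"),
    corsi_backward = variable_spec("corsi_backward", "cognitive", "keep",
                                   aggregation_group = "working_memory"),
    gng_rt = variable_spec("gng_rt", "cognitive", "invert"),
    gng_commissions = variable_spec("gng_commissions", "cognitive", "invert"))
}

#' Remove univariate outliers by single-pass z-score
#'
#' Cells whose absolute z-score (computed once, on the non-missing values) is
#' greater than or equal to `threshold` are set missing. A zero-SD input
#' yields no removals with a warning.
#'
#' @param values numeric vector, possibly with `NA`s.
#' @param threshold z-score cutoff (default 4).
#' @return a list with `values` (outliers set `NA`) and `n_removed`.
#' @examples
#' remove_outliers(c(rnorm(20), 50))$n_removed
#' @export
remove_outliers <- function(values, threshold = 4) {
  if (threshold <= 0) abort("threshold must be positive")
  ok <- !is.na(values)
  if (sum(ok) < 3) abort("need at least 3 non-missing values")
  s <- sd(values[ok])
  if (s == 0) {
    warn("zero SD: no outliers removed")
    return(list(values = values, n_removed = 0L))
  }
  z <- (values - mean(values[ok])) / s
  out <- ok & abs(z) >= threshold
  values[out] <- NA
  list(values = values, n_removed = sum(out))
}

#' Invert a cognitive measure so that higher scores mean better performance
#'
#' Arithmetic negation, applied before standardization (z-scoring makes
#' negate-then-scale and scale-then-negate equivalent). Missing values are
#' preserved.
#'
#' @param values numeric vector.
#' @param spec a [variable_spec()] with `orientation = "invert"`.
#' @return the negated vector.
#' @export
invert_orientation <- function(values, spec) {
  stopifnot(inherits(spec, "clpn_variable_spec"))
  if (spec$orientation != "invert") {
    abort(paste0("variable '", spec$name, "' is not marked for inversion"))
  }
  -values
}

#' Aggregate the two backward-span indicators into one working-memory score
#'
#' Each indicator is z-standardized on its non-missing values, then the two
#' z-scores are averaged per participant. A participant missing either
#' indicator gets a missing aggregate (no single-indicator fallback).
#'
#' @param digit_backward,corsi_backward aligned numeric vectors.
#' @return numeric vector of aggregate scores.
#' @examples
#' aggregate_working_memory(c(2, 4, 6), c(6, 4, 2))  # opposite ranks cancel
#' @export
aggregate_working_memory <- function(digit_backward, corsi_backward) {
  stopifnot(length(digit_backward) == length(corsi_backward))
  zs <- lapply(list(digit_backward, corsi_backward), function(x) {
    if (sum(!is.na(x)) < 3) abort("need at least 3 non-missing values per indicator")
    if (sd(x, na.rm = TRUE) == 0) abort("zero-SD span indicator cannot be standardized")
    zscore(x)
  })
  out <- (zs[[1]]$values + zs[[2]]$values) / 2
  out[is.na(digit_backward) | is.na(corsi_backward)] <- NA
  attr(out, "standardization") <- tibble::tibble(
    variable = c("digit_backward", "corsi_backward"),
    mean = c(zs[[1]]$mean, zs[[2]]$mean),
    sd = c(zs[[1]]$sd, zs[[2]]$sd))
  out
}

#' Harmonize symptom scores across instruments by within-instrument z-scoring
#'
#' CBCL and ABCL raw scores live on different scales; each instrument subgroup
#' is standardized separately before entering the model, so both subgroups
#' have mean 0 and SD 1 after harmonization.
#'
#' @param scores numeric vector of raw symptom scores.
#' @param instrument_labels character vector (`"cbcl"`/`"abcl"`) per entry.
#' @return the harmonized scores.
#' @export
harmonize_scales <- function(scores, instrument_labels) {
  stopifnot(length(scores) == length(instrument_labels))
  out <- rep(NA_real_, length(scores))
  params <- list()
  for (ins in unique(instrument_labels[!is.na(instrument_labels)])) {
    idx <- !is.na(instrument_labels) & instrument_labels == ins
    vals <- scores[idx]
    if (sum(!is.na(vals)) < 3) {
      abort(paste0("instrument subgroup '", ins, "' has fewer than 3 scores"))
    }
    if (sd(vals, na.rm = TRUE) == 0) {
      abort(paste0("instrument subgroup '", ins, "' has zero SD"))
    }
    zs <- zscore(vals)
    out[idx] <- zs$values
    params[[ins]] <- tibble::tibble(instrument = ins, mean = zs$mean, sd = zs$sd)
  }
  attr(out, "standardization") <- dplyr::bind_rows(params)
  out
}

#' Complete-case inclusion filter
#'
#' Participants missing any required variable at wave 1 are removed entirely.
#' For the waves 2->3 analysis, participants must additionally have
#' non-missing wave-3 symptom scales.
#'
#' @param data a panel tibble (one row per participant x wave).
#' @param required_wave1_variables variables that must be non-missing at
#'   wave 1.
#' @param require_wave3_symptoms also require non-missing wave-3
#'   internalizing/externalizing? Default `FALSE`.
#' @return the filtered panel.
#' @export
complete_case_filter <- function(data, required_wave1_variables = clpn_measures(),
                                 require_wave3_symptoms = FALSE) {
  missing_vars <- setdiff(required_wave1_variables, names(data))
  if (length(missing_vars)) {
    abort(paste0("required variables absent from data: ",
                 paste(missing_vars, collapse = ", ")))
  }
  w1 <- dplyr::filter(data, .data$wave == 1)
  keep <- w1$participant_id[complete.cases(w1[required_wave1_variables])]
  if (require_wave3_symptoms) {
    w3 <- dplyr::filter(data, .data$wave == 3)
    keep3 <- w3$participant_id[complete.cases(w3[c("internalizing", "externalizing")])]
    keep <- intersect(keep, keep3)
  }
  if (length(keep) == 0) abort("complete-case filter removed every participant")
  out <- dplyr::filter(data, .data$participant_id %in% keep)
  restore_panel_attrs(out, data)
}

#' Standardize node scores, by default within wave
#'
#' Each listed variable is z-scored on its non-missing values, within wave
#' when `per_wave` is `TRUE` (pooled otherwise).
#'
#' @param data panel tibble.
#' @param vars variables to standardize.
#' @param per_wave standardize within wave? Default `TRUE`.
#' @return the panel with standardized variables; the means/SDs used are
#'   attached as attribute `"standardization_params"` (a tibble).
#' @export
standardize_nodes <- function(data, vars, per_wave = TRUE) {
  params <- list()
  for (v in vars) {
    groups <- if (per_wave) unique(data$wave) else list(unique(data$wave))
    for (g in groups) {
      idx <- data$wave %in% g
      vals <- data[[v]][idx]
      if (sum(!is.na(vals)) < 3) {
        abort(paste0("node '", v, "' has fewer than 3 values in wave ",
                     paste(g, collapse = "/")))
      }
      if (sd(vals, na.rm = TRUE) == 0) {
        abort(paste0("node '", v, "' has zero SD in wave ",
                     paste(g, collapse = "/")))
      }
      zs <- zscore(vals)
      data[[v]][idx] <- zs$values
      params[[length(params) + 1]] <- tibble::tibble(
        variable = v, wave = paste(g, collapse = "/"),
        mean = zs$mean, sd = zs$sd)
    }
  }
  attr(data, "standardization_params") <- dplyr::bind_rows(params)
  data
}

#' Preprocess a raw panel into the analysis-ready node table
#'
#' Applies, in order: (1) single-pass outlier removal (|z| >= `threshold`,
#' per variable per wave) on the go/no-go summaries; (2) inversion of the two
#' inhibitory-control indices so higher = better; (3) aggregation of the two
#' backward spans into one working-memory composite (per wave); (4)
#' within-instrument harmonization of the symptom scales (per wave); (5)
#' complete-case inclusion on the wave-1 measures (optionally also wave-3
#' symptoms); (6) per-wave z-standardization of the five nodes on the
#' analysis sample. No imputation is performed.
#'
#' @param data a raw panel (e.g. from [simulate_cohort()]).
#' @param outlier_threshold z cutoff for step (1), default 4.
#' @param require_wave3_symptoms passed to [complete_case_filter()]; set
#'   `TRUE` when the waves 2->3 network is the analysis of interest.
#' @param specs variable specifications (default [default_variable_specs()]).
#' @return a list of class `clpn_preprocessed` with elements `data` (node
#'   tibble: `participant_id`, `wave`, `group`, `gender`, `age`, five node
#'   columns) and `report` (a replayable [preprocess report][preprocess_report]).
#' @examples
#' panel <- simulate_cohort(generator_config(n_participants = 200, seed = 5))
#' pp <- preprocess_panel(panel)
#' pp$report$n_after_complete_case
#' @export
preprocess_panel <- function(data, outlier_threshold = 4,
                             require_wave3_symptoms = FALSE,
                             specs = default_variable_specs()) {
  n_input <- dplyr::n_distinct(data$participant_id)
  removed <- c(gng_rt = 0L, gng_commissions = 0L)

  # (1) outliers, per variable per wave, on the task summaries
  for (v in names(removed)) {
    for (w in sort(unique(data$wave))) {
      idx <- data$wave == w
      if (sum(!is.na(data[[v]][idx])) < 3) next
      res <- remove_outliers(data[[v]][idx], outlier_threshold)
      data[[v]][idx] <- res$values
      removed[[v]] <- removed[[v]] + res$n_removed
    }
  }

  # (2) invert inhibitory-control indices
  data$inhibition_speed <- invert_orientation(data$gng_rt, specs$gng_rt)
  data$inhibition_accuracy <- invert_orientation(data$gng_commissions,
                                                 specs$gng_commissions)

  # (3) working-memory composite, per wave
  scale_params <- list()
  data$working_memory <- NA_real_
  for (w in sort(unique(data$wave))) {
    idx <- data$wave == w
    agg <- aggregate_working_memory(data$digit_backward[idx],
                                    data$corsi_backward[idx])
    data$working_memory[idx] <- agg
    scale_params[[length(scale_params) + 1]] <- dplyr::mutate(
      attr(agg, "standardization"), wave = w, step = "wm_indicator",
      instrument = NA_character_)
  }

  # (4) instrument harmonization of symptom scales, per wave
  for (v in c("internalizing", "externalizing")) {
    for (w in sort(unique(data$wave))) {
      idx <- data$wave == w & !is.na(data$instrument)
      h <- harmonize_scales(data[[v]][idx], data$instrument[idx])
      data[[v]][idx] <- h
      data[[v]][data$wave == w & is.na(data$instrument)] <- NA
      scale_params[[length(scale_params) + 1]] <- dplyr::mutate(
        attr(h, "standardization"), variable = v, wave = w, step = "harmonize")
    }
  }

  # (5) inclusion rules
  data <- complete_case_filter(data, clpn_measures(),
                               require_wave3_symptoms = require_wave3_symptoms)
  n_cc <- dplyr::n_distinct(data$participant_id)

  # (6) per-wave standardization of the nodes on the analysis sample
  data <- standardize_nodes(data, clpn_nodes(), per_wave = TRUE)
  node_params <- dplyr::mutate(attr(data, "standardization_params"),
                               wave = as.integer(.data$wave), step = "node",
                               instrument = NA_character_)
  std_params <- dplyr::bind_rows(c(scale_params, list(node_params)))

  keep_cols <- c("participant_id", "wave", "group", "gender", "age",
                 if ("dropout_wave" %in% names(data)) "dropout_wave",
                 clpn_nodes())
  nodes_tbl <- restore_panel_attrs(
    dplyr::select(data, dplyr::all_of(keep_cols)), data)

  report <- structure(
    list(n_input = n_input,
         n_after_complete_case = n_cc,
         n_outlier_cells_removed = removed,
         outlier_threshold = outlier_threshold,
         require_wave3_symptoms = require_wave3_symptoms,
         standardization_params = std_params),
    class = "clpn_preprocess_report")

  structure(list(data = nodes_tbl, report = report),
            class = "clpn_preprocessed")
}

#' @export
print.clpn_preprocessed <- function(x, ...) {
  r <- x$report
  cat("<clpn_preprocessed>\n")
  cat(" participants:", r$n_input, "->", r$n_after_complete_case,
      "after complete-case inclusion\n")
  cat(" outlier cells removed:",
      paste(names(r$n_outlier_cells_removed), r$n_outlier_cells_removed,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Replay a recorded preprocessing transformation on raw data
#'
#' Re-applies the exact transformation described by a preprocessing report
#' (outlier rule, inversion, recorded standardization means/SDs, inclusion
#' rule) to a raw panel. On the original raw input this reproduces the
#' processed node table bit-for-bit, which is the report's audit guarantee.
#'
#' @param data raw panel.
#' @param report a `clpn_preprocess_report`.
#' @return the reprocessed node tibble.
#' @export
replay_preprocess <- function(data, report) {
  stopifnot(inherits(report, "clpn_preprocess_report"))
  p <- report$standardization_params
  zx <- function(x, m, s) (x - m) / s
  for (v in c("gng_rt", "gng_commissions")) {
    for (w in sort(unique(data$wave))) {
      idx <- data$wave == w
      if (sum(!is.na(data[[v]][idx])) < 3) next
      data[[v]][idx] <- remove_outliers(data[[v]][idx],
                                        report$outlier_threshold)$values
    }
  }
  data$inhibition_speed <- -data$gng_rt
  data$inhibition_accuracy <- -data$gng_commissions
  data$working_memory <- NA_real_
  for (w in sort(unique(data$wave))) {
    idx <- data$wave == w
    pw <- dplyr::filter(p, .data$step == "wm_indicator", .data$wave == w)
    zd <- zx(data$digit_backward[idx],
             pw$mean[pw$variable == "digit_backward"],
             pw$sd[pw$variable == "digit_backward"])
    zc <- zx(data$corsi_backward[idx],
             pw$mean[pw$variable == "corsi_backward"],
             pw$sd[pw$variable == "corsi_backward"])
    data$working_memory[idx] <- (zd + zc) / 2
  }
  for (v in c("internalizing", "externalizing")) {
    for (w in sort(unique(data$wave))) {
      ph <- dplyr::filter(p, .data$step == "harmonize", .data$wave == w,
                          .data$variable == v)
      for (i in seq_len(nrow(ph))) {
        idx <- data$wave == w & !is.na(data$instrument) &
          data$instrument == ph$instrument[i]
        data[[v]][idx] <- zx(data[[v]][idx], ph$mean[i], ph$sd[i])
      }
      data[[v]][data$wave == w & is.na(data$instrument)] <- NA
    }
  }
  data <- complete_case_filter(data, clpn_measures(),
                               require_wave3_symptoms = report$require_wave3_symptoms)
  for (v in clpn_nodes()) {
    for (w in sort(unique(data$wave))) {
      pn <- dplyr::filter(p, .data$step == "node", .data$wave == w,
                          .data$variable == v)
      idx <- data$wave == w
      data[[v]][idx] <- zx(data[[v]][idx], pn$mean, pn$sd)
    }
  }
  keep_cols <- c("participant_id", "wave", "group", "gender", "age",
                 if ("dropout_wave" %in% names(data)) "dropout_wave",
                 clpn_nodes())
  tibble::as_tibble(as.data.frame(
    dplyr::select(data, dplyr::all_of(keep_cols))))
}

#' Access the preprocessing report
#'
#' The report records input/retained counts, outlier removals per variable
#' and every standardization mean/SD used, so the transformation is fully
#' replayable.
#'
#' @param x a `clpn_preprocessed` object.
#' @return the `clpn_preprocess_report`.
#' @export
preprocess_report <- function(x) {
  stopifnot(inherits(x, "clpn_preprocessed"))
  x$report
}
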