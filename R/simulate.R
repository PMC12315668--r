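#' Simulate a three-wave at-risk cohort with known cross-lagged dynamics
#'
#' Generates a synthetic panel emulating a high-risk adolescent cohort
#' followed over three waves. Latent node scores follow the first-order
#' recursion `z[t+1] = t(B[t]) %*% z[t] + age effect + innovation`, where the
#' `B[t]` are the configured lag matrices; the high-risk stratum receives the
#' configured mean shifts; observed scores (two backward-span indicators,
#' go/no-go summaries, CBCL/ABCL broad-band raw scores) are produced by the
#' measurement model. Wave-3 records of participants aged 18 or older are
#' assigned the adult instrument (`abcl`); all other symptom records are
#' `cbcl`. No attrition is applied here; see [apply_attrition()].
#'
#' The returned tibble has one row per participant x wave and carries the
#' generating configuration and the latent scores as attributes (for
#' validation against ground truth).
#'
#' @param config a [generator_config()].
#' @param keep_latents keep the latent node array (and innovations) as
#'   attributes? Default `TRUE`.
#' @return a `clpn_panel` tibble with columns `participant_id`, `wave`,
#'   `group`, `gender`, `age`, `instrument`, and the six observed measures.
#' @examples
#' panel <- simulate_cohort(generator_config(n_participants = 200, seed = 7))
#' dplyr::count(panel, wave, group)
#' @export
simulate_cohort <- function(config, keep_latents = TRUE) {
  stopifnot(inherits(config, "clpn_generator_config"))
  n <- config$n_participants
  tn <- config$true_network
  nodes <- tn$nodes
  k <- length(nodes)
  meas <- config$measurement

  withr::with_seed(config$seed, {
    group <- ifelse(runif(n) < config$high_risk_fraction, "high_risk", "community")
    gender <- rbinom(n, 1L, config$male_fraction)
    age_offset <- rnorm(n, 0, config$age_sd)

    z <- array(NA_real_, c(n, k, 3), dimnames = list(NULL, nodes, NULL))
    innov <- vector("list", 3)
    hr <- as.numeric(group == "high_risk")
    innov[[1]] <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, nodes))
    z[, , 1] <- innov[[1]] + hr %o% config$risk_mean_shift
    for (t in 1:2) {
      eps <- matrix(rnorm(n * k), n, k) %*% diag(tn$innovation_sd, k)
      colnames(eps) <- nodes
      innov[[t + 1]] <- eps
      z[, , t + 1] <- z[, , t] %*% tn$lag[[t]] +
        age_offset %o% tn$age_effects +
        hr %o% (0.3 * config$risk_mean_shift) +
        eps
    }

    rows <- vector("list", 3)
    for (w in 1:3) {
      age_w <- config$age_mean_by_wave[w] + age_offset
      instrument <- ifelse(w == 3 & age_w >= 18, "abcl", "cbcl")
      obs <- measure_wave(z[, , w], wave = w, instrument = instrument,
                          meas = meas)
      rows[[w]] <- tibble::tibble(
        participant_id = sprintf("P%05d", seq_len(n)),
        wave = w, group = group, gender = gender,
        age = age_w, instrument = instrument) |>
        dplyr::bind_cols(obs)
    }
    panel <- dplyr::arrange(dplyr::bind_rows(rows), .data$participant_id, .data$wave)

    attr(panel, "config") <- config
    if (keep_latents) {
      attr(panel, "latents") <- z
      attr(panel, "innovations") <- innov
      attr(panel, "age_offset") <- age_offset
    }
    class(panel) <- c("clpn_panel", class(panel))
    panel
  })
}

# Observed measures for one wave, given the n x nodes latent matrix.
# Latents are scaled (not centered) by their realized wave SD so that group
# and wave mean structure survives into the observed scores; indicator noise
# for the two spans is set from the correlation target, so that
# cor(digit, corsi) ~= wm_indicator_cor_target by construction.
measure_wave <- function(zw, wave, instrument, meas) {
  n <- nrow(zw)
  trend <- meas$wave_trends[, wave]
  core <- sweep(zw, 2, -trend)           # z + trend
  s <- apply(core, 2, sd)
  core <- sweep(core, 2, s, "/")         # unit-SD latent cores

  # working-memory span indicators
  L <- meas$wm_indicator_loading
  rho <- meas$wm_indicator_cor_target
  noise_sd <- L * sqrt((1 - rho) / rho)
  ind_scale <- sqrt(L^2 / rho)           # SD of L*core + noise
  wm <- core[, "working_memory"]
  digit_std <- (L * wm + rnorm(n, 0, noise_sd)) / ind_scale
  corsi_std <- (L * wm + rnorm(n, 0, noise_sd)) / ind_scale
  digit <- meas$span_mean$digit[wave] + meas$span_sd$digit * digit_std
  corsi <- meas$span_mean$corsi[wave] + meas$span_sd$corsi * corsi_std

  gng <- gonogo_draw(core[, "inhibition_speed"], core[, "inhibition_accuracy"],
                     meas, wave)

  sym <- lapply(c("internalizing", "externalizing"), function(v) {
    std <- sqrt(meas$symptom_reliability) * core[, v] +
      sqrt(1 - meas$symptom_reliability) * rnorm(n)
    out <- numeric(n)
    for (ins in unique(instrument)) {
      sc <- meas$symptom_scale[[ins]][[v]]
      idx <- instrument == ins
      out[idx] <- pmax(0, sc$mean[wave] + sc$sd[wave] * std[idx])
    }
    out
  })

  tibble::tibble(internalizing = sym[[1]], externalizing = sym[[2]],
                 digit_backward = digit, corsi_backward = corsi,
                 gng_rt = gng$gng_rt, gng_commissions = gng$gng_commissions)
}

# go/no-go summaries from standardized latent speed/accuracy, using the
# current RNG state; RT decreasing in speed, commission errors binomial with
# probability decreasing in accuracy
gonogo_draw <- function(speed, accuracy, meas, wave) {
  n <- length(speed)
  rel <- meas$rt_reliability
  rt <- meas$rt_mean[wave] -
    meas$rt_sd * (sqrt(rel) * speed + sqrt(1 - rel) * rnorm(n))
  rt <- pmax(rt, 150)
  p <- plogis(qlogis(meas$gng_base_error_rate) - meas$gng_error_slope * accuracy)
  errors <- rbinom(n, meas$gng_trials, p)
  tibble::tibble(gng_rt = rt, gng_commissions = errors)
}

#' Simulate go/no-go task summaries from latent inhibition scores
#'
#' Draws per-participant mean correct-go reaction time (ms) and commission
#' error counts (binomial over the task's no-go trials) from standardized
#' latent inhibition-speed and inhibition-accuracy scores. Error probability
#' decreases in latent accuracy; RT decreases in latent speed.
#'
#' @param speed,accuracy numeric vectors of standardized latent scores.
#' @param measurement a [measurement_model()].
#' @param seed integer seed.
#' @param wave which wave's RT scale to use (default 1).
#' @return a tibble with columns `gng_rt` and `gng_commissions`.
#' @export
simulate_gonogo_summaries <- function(speed, accuracy,
                                      measurement = measurement_model(),
                                      seed = 1L, wave = 1) {
  stopifnot(length(speed) == length(accuracy))
  withr::with_seed(seed, gonogo_draw(speed, accuracy, measurement, wave))
}

#' Apply informative attrition to a simulated cohort
#'
#' Each participant drops out at most once, with probability
#' `plogis(intercept + internalizing_coef * z(internalizing at wave 1))`;
#' dropouts are assigned wave 2 or wave 3 with equal probability and are
#' missing all measured variables from that wave onward (monotone dropout).
#' When the model's intercept is `NULL` it is calibrated by root finding so
#' the marginal dropout probability equals `target_attrition` on this sample.
#'
#' @param data a `clpn_panel` with complete wave-1 internalizing scores.
#' @param model an [attrition_model()].
#' @param seed integer seed.
#' @return the panel with post-dropout cells set to `NA` and an added
#'   `dropout_wave` column (`NA` for completers).
#' @examples
#' panel <- simulate_cohort(generator_config(n_participants = 300, seed = 2))
#' panel <- apply_attrition(panel, attrition_model(), seed = 3)
#' mean(!is.na(dplyr::filter(panel, wave == 1)$dropout_wave))
#' @export
apply_attrition <- function(data, model = attrition_model(), seed = 1L) {
  stopifnot(inherits(model, "clpn_attrition_model"))
  w1 <- dplyr::filter(data, .data$wave == 1)
  if (anyNA(w1$internalizing)) {
    abort("wave-1 internalizing must be present for all participants")
  }
  target <- model$target_attrition
  if (identical(model$intercept, NULL) && target == 0) {
    out <- dplyr::mutate(data, dropout_wave = NA_integer_)
    return(restore_panel_attrs(out, data))
  }
  zi <- zscore(w1$internalizing)$values
  cf <- model$internalizing_coef
  b0 <- model$intercept
  if (is.null(b0)) {
    f <- function(b) mean(plogis(b + cf * zi)) - target
    if (f(-30) > 0 || f(30) < 0) {
      abort("target_attrition unreachable given internalizing_coef")
    }
    b0 <- uniroot(f, c(-30, 30), tol = 1e-10)$root
  }
  p <- plogis(b0 + cf * zi)

  withr::with_seed(seed, {
    dropped <- runif(length(p)) < p
    dw <- rep(NA_integer_, length(p))
    dw[dropped] <- sample(c(2L, 3L), sum(dropped), replace = TRUE)
  })
  drop_tab <- tibble::tibble(participant_id = w1$participant_id,
                             dropout_wave = dw)
  out <- dplyr::left_join(data, drop_tab, by = "participant_id")
  masked <- !is.na(out$dropout_wave) & out$wave >= out$dropout_wave
  for (v in c(clpn_measures(), "age")) out[[v]][masked] <- NA
  out$instrument[masked] <- NA_character_
  out <- restore_panel_attrs(out, data)
  attr(out, "attrition") <- list(model = model, intercept_used = b0,
                                 realized_rate = mean(dropped), seed = seed)
  out
}

# dplyr verbs strip custom attributes; carry them across explicitly
restore_panel_attrs <- function(new, old) {
  for (a in c("config", "latents", "innovations", "age_offset", "attrition")) {
    if (!is.null(attr(old, a))) attr(new, a) <- attr(old, a)
  }
  if (!inherits(new, "clpn_panel")) class(new) <- c("clpn_panel", class(new))
  new
}

#' Simulate a cohort and apply its configured attrition in one call
#'
#' Stage seeds are expanded deterministically from the configuration seed.
#'
#' @param config a [generator_config()].
#' @return a `clpn_panel` with attrition applied.
#' @export
simulate_study <- function(config) {
  panel <- simulate_cohort(config)
  apply_attrition(panel, config$attrition,
                  seed = stage_seed(config$seed, "attrition"))
}
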