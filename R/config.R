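#' Ground-truth cross-lagged dynamics for the cohort generator
#'
#' A `true_network` holds the generative dynamics of the simulated cohort: two
#' square matrices of standardized cross-lagged and autoregressive coefficients
#' (one per wave pair, rows = source node at wave t, columns = target node at
#' wave t+1), per-node innovation standard deviations, and per-node age
#' effects. All quantities are on the latent z-score scale.
#'
#' Both lag matrices must have spectral radius below 1 so the latent dynamics
#' are non-explosive.
#'
#' @param lag_w12,lag_w23 square numeric matrices (nodes x nodes) of
#'   standardized coefficients for waves 1->2 and 2->3; `lag_w23` defaults to
#'   `lag_w12`.
#' @param innovation_sd per-node residual standard deviations (z-units),
#'   recycled to the number of nodes.
#' @param age_effects per-node coefficient of (within-wave centered) age on
#'   each wave-(t+1) node, in z-units per year.
#' @param nodes ordered node names.
#' @return an object of class `clpn_true_network`.
#' @export
true_network <- function(lag_w12 = default_lag_matrix(1),
                         lag_w23 = NULL,
                         innovation_sd = 0.8,
                         age_effects = c(0, 0, 0.03, 0.03, 0.03),
                         nodes = clpn_nodes()) {
  if (is.null(lag_w23)) lag_w23 <- lag_w12
  k <- length(nodes)
  for (m in list(lag_w12, lag_w23)) {
    if (!is.matrix(m) || nrow(m) != k || ncol(m) != k) {
      abort("lag matrices must be square with dimension = number of nodes")
    }
    rho <- max(Mod(eigen(m, only.values = TRUE)$values))
    if (rho >= 1) {
      abort(sprintf("lag matrix has spectral radius %.3f >= 1 (explosive dynamics)", rho))
    }
  }
  innovation_sd <- rep_len(innovation_sd, k)
  age_effects <- rep_len(age_effects, k)
  if (any(innovation_sd <= 0)) abort("innovation_sd must be positive")
  dimnames(lag_w12) <- dimnames(lag_w23) <- list(nodes, nodes)
  structure(
    list(nodes = nodes,
         lag = list(`1_2` = lag_w12, `2_3` = lag_w23),
         innovation_sd = stats::setNames(innovation_sd, nodes),
         age_effects = stats::setNames(age_effects, nodes)),
    class = "clpn_true_network")
}

#' Default generative lag matrix for a wave pair
#'
#' Encodes the qualitative dynamics expected in an at-risk adolescent cohort:
#' moderate autoregression on every node, inhibitory control protecting
#' against later externalizing problems, symptoms eroding later working
#' memory, and reciprocal working-memory/inhibition links. The waves 2->3
#' matrix is denser, with symptom-to-inhibition and between-symptom effects
#' added.
#'
#' @param wave_pair 1 for waves 1->2, 2 for waves 2->3.
#' @return a 5x5 numeric matrix (source rows, target columns).
#' @export
default_lag_matrix <- function(wave_pair = 1) {
  nodes <- clpn_nodes()
  m <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  if (wave_pair == 1) {
    diag(m) <- c(0.45, 0.45, 0.35, 0.35, 0.30)
    m["internalizing", "working_memory"] <- -0.15
    m["externalizing", "internalizing"] <- 0.10
    m["externalizing", "working_memory"] <- -0.15
    m["working_memory", "inhibition_speed"] <- 0.15
    m["working_memory", "inhibition_accuracy"] <- 0.15
    m["inhibition_speed", "externalizing"] <- -0.15
    m["inhibition_speed", "working_memory"] <- 0.10
    m["inhibition_accuracy", "externalizing"] <- -0.15
    m["inhibition_accuracy", "working_memory"] <- 0.10
  } else {
    diag(m) <- c(0.50, 0.50, 0.40, 0.40, 0.35)
    m["internalizing", "externalizing"] <- -0.10
    m["internalizing", "working_memory"] <- -0.10
    m["externalizing", "internalizing"] <- 0.15
    m["externalizing", "working_memory"] <- -0.10
    m["externalizing", "inhibition_speed"] <- -0.10
    m["externalizing", "inhibition_accuracy"] <- -0.15
    m["working_memory", "inhibition_speed"] <- 0.15
    m["working_memory", "inhibition_accuracy"] <- 0.15
    m["inhibition_speed", "externalizing"] <- -0.15
    m["inhibition_speed", "working_memory"] <- 0.10
    m["inhibition_accuracy", "internalizing"] <- -0.10
    m["inhibition_accuracy", "externalizing"] <- -0.15
    m["inhibition_accuracy", "working_memory"] <- 0.10
  }
  m
}

#' Measurement model mapping latent constructs to observed task scores
#'
#' Governs how latent node scores become observed measures: two
#' working-memory span indicators with a target cross-indicator correlation,
#' go/no-go summaries (mean correct-go reaction time in ms and commission
#' errors out of the task's 25 no-go trials), and CBCL/ABCL broad-band
#' symptom raw scores with instrument-specific scales. Wave trends are
#' additive latent mean shifts applied at measurement time, emulating
#' steady cognitive improvement and shifting symptom levels across waves.
#'
#' @param wm_indicator_loading common loading of the backward digit-span and
#'   backward corsi-span indicators on latent working memory.
#' @param wm_indicator_cor_target intended correlation between the two span
#'   indicators (default 0.46); indicator noise is calibrated per wave so the
#'   realized correlation matches this target.
#' @param span_mean,span_sd per-wave means and SDs of the two span scores, as
#'   a list with elements `digit` and `corsi` (length-3 vectors) and numeric
#'   SDs.
#' @param rt_mean,rt_sd,rt_reliability per-wave mean correct-go RT (ms), its
#'   SD, and the proportion of observed RT variance carried by the latent
#'   inhibition-speed score.
#' @param gng_trials number of no-go trials (25).
#' @param gng_base_error_rate commission-error probability at average latent
#'   inhibition accuracy.
#' @param gng_error_slope logit decrease in error probability per latent
#'   accuracy z-unit.
#' @param symptom_scale per-instrument, per-wave raw-score means and SDs for
#'   the two broad-band scales, a nested list (see defaults).
#' @param symptom_reliability proportion of observed symptom variance carried
#'   by the latent score.
#' @param wave_trends nodes x 3 matrix of additive per-wave latent mean
#'   shifts (z-units).
#' @return an object of class `clpn_measurement_model`.
#' @export
measurement_model <- function(wm_indicator_loading = 0.8,
                              wm_indicator_cor_target = 0.46,
                              span_mean = list(digit = c(4.2, 5.0, 5.8),
                                               corsi = c(4.5, 5.2, 5.9)),
                              span_sd = list(digit = 1.3, corsi = 1.2),
                              rt_mean = c(620, 540, 470),
                              rt_sd = 90,
                              rt_reliability = 0.70,
                              gng_trials = 25L,
                              gng_base_error_rate = 0.30,
                              gng_error_slope = 0.9,
                              symptom_scale = default_symptom_scale(),
                              symptom_reliability = 0.85,
                              wave_trends = default_wave_trends()) {
  if (wm_indicator_cor_target <= 0 || wm_indicator_cor_target >= 1) {
    abort("wm_indicator_cor_target must be in (0, 1)")
  }
  if (gng_base_error_rate <= 0 || gng_base_error_rate >= 1) {
    abort("gng_base_error_rate must be in (0, 1)")
  }
  if (any(rt_mean <= 0) || rt_sd <= 0) abort("RT scale must be positive")
  if (rt_reliability <= 0 || rt_reliability > 1 ||
      symptom_reliability <= 0 || symptom_reliability > 1) {
    abort("reliabilities must be in (0, 1]")
  }
  structure(
    list(wm_indicator_loading = wm_indicator_loading,
         wm_indicator_cor_target = wm_indicator_cor_target,
         span_mean = span_mean, span_sd = span_sd,
         rt_mean = rt_mean, rt_sd = rt_sd, rt_reliability = rt_reliability,
         gng_trials = as.integer(gng_trials),
         gng_base_error_rate = gng_base_error_rate,
         gng_error_slope = gng_error_slope,
         symptom_scale = symptom_scale,
         symptom_reliability = symptom_reliability,
         wave_trends = wave_trends),
    class = "clpn_measurement_model")
}

#' @rdname measurement_model
#' @export
default_symptom_scale <- function() {
  list(
    cbcl = list(internalizing = list(mean = c(11.0, 12.5, 14.0), sd = c(7.5, 8.0, 9.0)),
                externalizing = list(mean = c(13.0, 14.5, 12.5), sd = c(8.5, 9.0, 8.0))),
    abcl = list(internalizing = list(mean = c(NA, NA, 12.0), sd = c(NA, NA, 9.5)),
                externalizing = list(mean = c(NA, NA, 10.0), sd = c(NA, NA, 7.5))))
}

#' @rdname measurement_model
#' @export
default_wave_trends <- function() {
  nodes <- clpn_nodes()
  m <- rbind(internalizing = c(0, 0.10, 0.20),
             externalizing = c(0, 0.15, -0.05),
             working_memory = c(0, 0.30, 0.60),
             inhibition_speed = c(0, 0.30, 0.60),
             inhibition_accuracy = c(0, 0.30, 0.60))
  colnames(m) <- paste0("wave", 1:3)
  m[nodes, , drop = FALSE]
}

#' Informative attrition model
#'
#' Dropout is a single event per participant: the probability of ever dropping
#' out follows a logistic model on standardized wave-1 internalizing symptoms,
#' with a negative coefficient by default so that higher internalizing
#' predicts a *lower* probability of dropout. Age, gender, externalizing and
#' cognition have zero effect. The intercept is normally left `NULL` and
#' calibrated at application time so the marginal dropout rate matches
#' `target_attrition`.
#'
#' @param internalizing_coef effect of standardized wave-1 internalizing on
#'   the dropout logit (default -0.35; must be <= 0).
#' @param intercept dropout logit at average internalizing; `NULL` to
#'   calibrate against `target_attrition`.
#' @param target_attrition marginal dropout proportion (default 0.3514).
#' @return an object of class `clpn_attrition_model`.
#' @export
attrition_model <- function(internalizing_coef = -0.35,
                            intercept = NULL,
                            target_attrition = 0.3514) {
  if (internalizing_coef > 0) {
    abort("internalizing_coef must be <= 0: higher internalizing lowers dropout")
  }
  if (target_attrition < 0 || target_attrition >= 1) {
    abort("target_attrition must be in [0, 1)")
  }
  structure(
    list(internalizing_coef = internalizing_coef, intercept = intercept,
         target_attrition = target_attrition),
    class = "clpn_attrition_model")
}

#' Configuration of the synthetic three-wave cohort generator
#'
#' Bundles everything [simulate_cohort()] needs: sample size, high-risk
#' oversampling fraction, per-node mean shifts for the high-risk group, wave
#' ages, the true dynamics, the measurement model and the attrition model.
#' Identical configurations (including the seed) yield bit-identical cohorts.
#'
#' @param n_participants cohort size at wave 1 (>= 10).
#' @param high_risk_fraction probability of high-risk membership
#'   (default 0.6089).
#' @param risk_mean_shift per-node additive latent shift for the high-risk
#'   group (z-units; positive for symptoms, negative for cognition).
#' @param age_mean_by_wave mean age in years at each wave
#'   (defaults 10.20, 13.48, 18.20).
#' @param age_sd SD of the participant-level age offset (years).
#' @param male_fraction probability of the male gender code.
#' @param seed integer seed governing all randomness.
#' @param true_network a [true_network()].
#' @param measurement a [measurement_model()].
#' @param attrition an [attrition_model()].
#' @return an object of class `clpn_generator_config`.
#' @export
generator_config <- function(n_participants = 2000,
                             high_risk_fraction = 0.6089,
                             risk_mean_shift = c(internalizing = 0.6,
                                                 externalizing = 0.6,
                                                 working_memory = -0.25,
                                                 inhibition_speed = -0.2,
                                                 inhibition_accuracy = -0.3),
                             age_mean_by_wave = c(10.20, 13.48, 18.20),
                             age_sd = 0.65,
                             male_fraction = 0.53,
                             seed = 1L,
                             true_network = clpnet::true_network(),
                             measurement = measurement_model(),
                             attrition = attrition_model()) {
  if (n_participants < 10) abort("n_participants < 10 is degenerate downstream")
  if (high_risk_fraction <= 0 || high_risk_fraction >= 1) {
    abort("high_risk_fraction must be in (0, 1)")
  }
  if (length(age_mean_by_wave) != 3 || any(diff(age_mean_by_wave) <= 0)) {
    abort("age_mean_by_wave must be three increasing ages")
  }
  stopifnot(inherits(true_network, "clpn_true_network"),
            inherits(measurement, "clpn_measurement_model"),
            inherits(attrition, "clpn_attrition_model"))
  risk_mean_shift <- risk_mean_shift[true_network$nodes]
  if (anyNA(risk_mean_shift)) abort("risk_mean_shift must name every node")
  structure(
    list(n_participants = as.integer(n_participants),
         high_risk_fraction = high_risk_fraction,
         risk_mean_shift = risk_mean_shift,
         age_mean_by_wave = age_mean_by_wave,
         age_sd = age_sd,
         male_fraction = male_fraction,
         seed = as.integer(seed),
         true_network = true_network,
         measurement = measurement,
         attrition = attrition),
    class = "clpn_generator_config")
}

#' Sparse ground truth with uniform effect magnitude, for recovery studies
#'
#' Builds a `true_network` in which every nonzero lagged effect has magnitude
#' `effect`: autoregression on all five nodes plus four cross-lagged edges
#' (inhibition accuracy and speed protecting against externalizing, working
#' memory supporting inhibition accuracy, externalizing eroding working
#' memory), identical for both wave pairs. Useful for support-recovery
#' experiments where detection must be attributed to a known effect size.
#'
#' @param effect absolute effect size of every nonzero edge (default 0.3).
#' @param age_effects passed to [true_network()]; zero by default here.
#' @return a `clpn_true_network`.
#' @export
recovery_true_network <- function(effect = 0.3, age_effects = 0) {
  nodes <- clpn_nodes()
  m <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  diag(m) <- effect
  m["inhibition_accuracy", "externalizing"] <- -effect
  m["inhibition_speed", "externalizing"] <- -effect
  m["working_memory", "inhibition_accuracy"] <- effect
  m["externalizing", "working_memory"] <- -effect
  true_network(lag_w12 = m, lag_w23 = m, age_effects = age_effects)
}

#' All-noise ground truth: no dynamics, no age effects
#'
#' @return a `clpn_true_network` with zero lag matrices, for null-soundness
#'   checks of the estimator.
#' @export
null_true_network <- function() {
  z <- matrix(0, 5, 5, dimnames = list(clpn_nodes(), clpn_nodes()))
  true_network(lag_w12 = z, lag_w23 = z, age_effects = 0)
}

#' @export
print.clpn_true_network <- function(x, ...) {
  cat("<clpn_true_network>", length(x$nodes), "nodes\n")
  cat("nonzero lagged effects: waves 1->2:", sum(x$lag$`1_2` != 0),
      "| waves 2->3:", sum(x$lag$`2_3` != 0), "\n")
  invisible(x)
}

#' @export
print.clpn_generator_config <- function(x, ...) {
  cat("<clpn_generator_config>\n")
  cat(" n =", x$n_participants,
      "| high-risk fraction =", x$high_risk_fraction,
      "| target attrition =", x$attrition$target_attrition, "\n")
  cat(" wave ages:", paste(x$age_mean_by_wave, collapse = ", "),
      "| seed =", x$seed, "\n")
  invisible(x)
}
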