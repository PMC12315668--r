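test_that("identical configuration yields bit-identical cohorts", {
  cfg <- generator_config(n_participants = 120, seed = 314)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "latents"), attr(b, "latents"))
})

test_that("high-risk fraction, attrition and span correlation calibrate", {
  cfg <- generator_config(n_participants = 5000, seed = 2718)
  panel <- simulate_cohort(cfg)
  w1 <- dplyr::filter(panel, wave == 1)

  p <- cfg$high_risk_fraction
  se_p <- sqrt(p * (1 - p) / 5000)
  expect_lt(abs(mean(w1$group == "high_risk") - p), 3 * se_p)

  r <- cor(w1$digit_backward, w1$corsi_backward)
  se_r <- (1 - 0.46^2) / sqrt(5000 - 3)
  expect_lt(abs(r - 0.46), 3 * se_r)

  dropped <- apply_attrition(panel, cfg$attrition, seed = 11)
  rate <- mean(!is.na(dplyr::filter(dropped, wave == 1)$dropout_wave))
  se_a <- sqrt(0.3514 * (1 - 0.3514) / 5000)
  expect_lt(abs(rate - 0.3514), 3 * se_a)
})

test_that("null dynamics produce cross-wave independence", {
  cfg <- generator_config(n_participants = 4000, seed = 5,
                          true_network = null_true_network(),
                          risk_mean_shift = rep(0, 5) |>
                            stats::setNames(clpn_nodes()))
  panel <- simulate_cohort(cfg)
  w1 <- dplyr::filter(panel, wave == 1)
  w2 <- dplyr::filter(panel, wave == 2)
  for (v in c("internalizing", "digit_backward", "gng_rt")) {
    for (u in c("externalizing", "corsi_backward")) {
      expect_lt(abs(cor(w1[[v]], w2[[u]])), 0.05)
    }
  }
})

test_that("a single planted edge is recovered by OLS on the latent scores", {
  nodes <- clpn_nodes()
  m <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  m["inhibition_accuracy", "externalizing"] <- -0.3
  cfg <- generator_config(n_participants = 20000, seed = 8675309,
                          true_network = true_network(lag_w12 = m,
                                                      age_effects = 0),
                          risk_mean_shift = rep(0, 5) |>
                            stats::setNames(nodes))
  panel <- simulate_cohort(cfg)
  z <- attr(panel, "latents")
  fit <- ols_oracle(z[, , 1], z[, "externalizing", 2])
  beta_acc <- fit[1 + which(nodes == "inhibition_accuracy")]
  expect_lt(abs(beta_acc - (-0.3)), 0.03)
  # other latent coefficients are null
  expect_lt(max(abs(fit[1 + which(nodes != "inhibition_accuracy")])), 0.03)
})

test_that("vectorized dynamics equal a per-participant loop oracle", {
  cfg <- generator_config(n_participants = 20, seed = 77)
  panel <- simulate_cohort(cfg)
  z <- attr(panel, "latents")
  innov <- attr(panel, "innovations")
  offset <- attr(panel, "age_offset")
  hr <- as.numeric(dplyr::filter(panel, wave == 1)$group == "high_risk")
  tn <- cfg$true_network
  for (t in 1:2) {
    B <- tn$lag[[t]]
    for (i in 1:20) {
      for (j in seq_along(tn$nodes)) {
        expected <- sum(B[, j] * z[i, , t]) +
          offset[i] * tn$age_effects[j] +
          hr[i] * 0.3 * cfg$risk_mean_shift[j] +
          innov[[t + 1]][i, j]
        expect_equal(unname(z[i, j, t + 1]), unname(expected),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("attrition is calibrated, monotone and informative", {
  cfg <- generator_config(n_participants = 8000, seed = 404)
  panel <- simulate_cohort(cfg)

  # zero internalizing effect still hits the target rate
  flat <- attrition_model(internalizing_coef = 0, target_attrition = 0.3514)
  d1 <- apply_attrition(panel, flat, seed = 1)
  rate <- mean(!is.na(dplyr::filter(d1, wave == 1)$dropout_wave))
  expect_lt(abs(rate - 0.3514), 2 * sqrt(0.3514 * 0.6486 / 8000))

  # target 0 is the identity
  d0 <- apply_attrition(panel, attrition_model(target_attrition = 0), seed = 1)
  expect_identical(d0$internalizing, panel$internalizing)
  expect_true(all(is.na(d0$dropout_wave)))

  # a logistic refit recovers the generating coefficient
  strong <- attrition_model(internalizing_coef = -0.5)
  d2 <- apply_attrition(panel, strong, seed = 3)
  w1 <- dplyr::filter(d2, wave == 1)
  glmfit <- stats::glm(!is.na(dropout_wave) ~ scale(internalizing),
                       family = stats::binomial, data = w1)
  est <- summary(glmfit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - (-0.5)), 2 * est["Std. Error"])

  # monotone missingness: missing from the dropout wave onward, complete before
  long_na <- dplyr::filter(d2, !is.na(dropout_wave))
  expect_true(all(is.na(long_na$internalizing[long_na$wave >= long_na$dropout_wave])))
  expect_true(all(!is.na(long_na$internalizing[long_na$wave < long_na$dropout_wave])))
})

test_that("go/no-go summaries respect their supports and limits", {
  meas <- measurement_model()
  # saturating accuracy eliminates commission errors
  lim <- simulate_gonogo_summaries(rep(0, 50), rep(1e6, 50), meas, seed = 1)
  expect_true(all(lim$gng_commissions == 0))
  # binomial mean at average accuracy
  draws <- simulate_gonogo_summaries(rep(0, 10000), rep(0, 10000), meas, seed = 2)
  p0 <- meas$gng_base_error_rate
  se <- sqrt(25 * p0 * (1 - p0) / 10000)
  expect_lt(abs(mean(draws$gng_commissions) - 25 * p0), 2 * se)
  expect_true(all(draws$gng_commissions >= 0 & draws$gng_commissions <= 25))
  expect_true(all(draws$gng_rt > 0))
})

test_that("wave-3 adults are assigned the adult instrument", {
  panel <- tiny_panel(n = 400, seed = 12)
  w3 <- dplyr::filter(panel, wave == 3)
  expect_true(all(w3$instrument[w3$age >= 18] == "abcl"))
  expect_true(all(w3$instrument[w3$age < 18] == "cbcl"))
  expect_true(all(dplyr::filter(panel, wave < 3)$instrument == "cbcl"))
})
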