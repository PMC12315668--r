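test_that("single-pass z-score outlier removal matches brute force", {
  set.seed(1)
  base <- seq(1, 19, length.out = 19) * 0.55  # SD about 3
  vals <- c(base, 60)
  z <- abs(vals - mean(vals)) / sd(vals)
  expect_true(z[20] >= 4)  # the planted cell is extreme in a single pass
  res <- remove_outliers(vals, threshold = 4)
  expect_identical(res$n_removed, 1L)
  expect_true(is.na(res$values[20]))
  expect_identical(res$values[1:19], vals[1:19])

  # all values within one SD: identity
  tight <- rnorm(30)
  expect_identical(remove_outliers(tight)$n_removed, 0L)

  # constant vector: zero-SD rule, warning, no removals
  expect_warning(resc <- remove_outliers(rep(3, 10)), "zero SD")
  expect_identical(resc$values, rep(3, 10))
  expect_identical(resc$n_removed, 0L)
})

test_that("orientation inversion is negation, preserves missing, self-inverts", {
  spec <- variable_spec("gng_rt", "cognitive", "invert")
  x <- c(500, 600, NA)
  expect_identical(invert_orientation(x, spec), c(-500, -600, NA))
  expect_identical(invert_orientation(invert_orientation(x, spec), spec), x)
  # correlation with a third variable flips sign exactly
  set.seed(2)
  rt <- rnorm(50, 500, 40); third <- rt * 0.5 + rnorm(50)
  expect_equal(cor(invert_orientation(rt, spec), third), -cor(rt, third))
  # inversion is only defined for variables marked invert
  expect_error(invert_orientation(x, variable_spec("d", "cognitive", "keep")),
               "not marked")
  expect_error(variable_spec("internalizing", "symptom", "invert"),
               "only valid for cognitive")
})

test_that("working-memory aggregation is the mean of indicator z-scores", {
  x <- c(2, 4, 6)
  expect_equal(as.numeric(aggregate_working_memory(x, x)),
               as.numeric(scale(x)))
  expect_equal(as.numeric(aggregate_working_memory(c(2, 4, 6), c(6, 4, 2))),
               c(0, 0, 0))
  # one missing indicator: aggregate missing
  agg <- aggregate_working_memory(c(2, 4, 6, NA), c(6, 4, 2, 1))
  expect_true(is.na(agg[4]))
  expect_error(aggregate_working_memory(rep(1, 5), 1:5), "zero-SD")

  # variance-of-mean algebra: perfectly correlated -> SD 1;
  # uncorrelated -> SD sqrt(1/2)
  set.seed(3)
  a <- rnorm(4000); b <- rnorm(4000)
  expect_equal(sd(aggregate_working_memory(a, 2 * a + 5)), 1, tolerance = 1e-9)
  expect_equal(sd(aggregate_working_memory(a, b)), sqrt(1 / 2),
               tolerance = 0.05)
})

test_that("instrument harmonization standardizes each subgroup separately", {
  set.seed(4)
  x <- rnorm(30, 10, 3)
  expect_equal(harmonize_scales(x, rep("cbcl", 30)),
               as.numeric(scale(x)), ignore_attr = TRUE)

  scores <- c(1, 2, 3, 10, 20, 30)
  labels <- c(rep("cbcl", 3), rep("abcl", 3))
  h <- harmonize_scales(scores, labels)
  expect_equal(h[1:3], (c(1, 2, 3) - 2) / sd(c(1, 2, 3)), ignore_attr = TRUE)
  expect_equal(h[4:6], (c(10, 20, 30) - 20) / sd(c(10, 20, 30)),
               ignore_attr = TRUE)
  expect_equal(mean(h[1:3]), 0)
  expect_equal(mean(h[4:6]), 0)
  expect_error(harmonize_scales(c(1, 1, 1, 4, 5, 6), labels), "zero SD")
})

test_that("complete-case filter matches a brute-force row scan", {
  panel <- tiny_panel(n = 60, seed = 21)
  # identity when nothing is missing
  expect_identical(nrow(complete_case_filter(panel)), nrow(panel))

  # plant missingness in 3 participants' wave-1 cognitive scores
  ids <- unique(panel$participant_id)[c(3, 10, 44)]
  panel$gng_rt[panel$participant_id %in% ids & panel$wave == 1] <- NA
  kept <- complete_case_filter(panel)
  expect_identical(dplyr::n_distinct(kept$participant_id), 57L)
  expect_false(any(ids %in% kept$participant_id))

  # randomized nested missingness: compare against an exhaustive scan
  set.seed(7)
  for (v in clpn_measures()) {
    hit <- sample(nrow(panel), 4)
    panel[[v]][hit] <- NA
  }
  got <- complete_case_filter(panel, require_wave3_symptoms = TRUE)
  w1 <- dplyr::filter(panel, wave == 1)
  w3 <- dplyr::filter(panel, wave == 3)
  scan_keep <- vapply(unique(panel$participant_id), function(id) {
    r1 <- w1[w1$participant_id == id, clpn_measures()]
    r3 <- w3[w3$participant_id == id, c("internalizing", "externalizing")]
    !anyNA(r1) && !anyNA(r3)
  }, logical(1))
  expect_setequal(unique(got$participant_id),
                  unique(panel$participant_id)[scan_keep])

  # empty result is an explicit error
  panel$internalizing[panel$wave == 1] <- NA
  expect_error(complete_case_filter(panel), "every participant")
})

test_that("node standardization is per wave, idempotent, and guarded", {
  panel <- tiny_panel(n = 80, seed = 31)
  std <- standardize_nodes(panel, c("internalizing", "gng_rt"), per_wave = TRUE)
  for (w in 1:3) {
    v <- std$internalizing[std$wave == w]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  again <- standardize_nodes(std, c("internalizing"), per_wave = TRUE)
  expect_equal(again$internalizing, std$internalizing, tolerance = 1e-12)

  # per-wave and pooled differ when wave means differ
  pooled <- standardize_nodes(panel, "digit_backward", per_wave = FALSE)
  perwave <- standardize_nodes(panel, "digit_backward", per_wave = TRUE)
  expect_gt(max(abs(pooled$digit_backward - perwave$digit_backward)), 0.01)

  panel$gng_rt <- 400
  expect_error(standardize_nodes(panel, "gng_rt"), "zero SD")
})

test_that("preprocessing is order-insensitive and replayable", {
  panel <- apply_attrition(tiny_panel(n = 150, seed = 41),
                           attrition_model(), seed = 6)
  pp <- preprocess_panel(panel)

  # shuffling participants changes no output value
  set.seed(8)
  shuffled <- panel[sample(nrow(panel)), ]
  pp2 <- preprocess_panel(shuffled)
  a <- dplyr::arrange(pp$data, participant_id, wave)
  b <- dplyr::arrange(pp2$data, participant_id, wave)
  expect_equal(as.data.frame(a), as.data.frame(b))

  # replaying the recorded transformation reproduces the table bit-for-bit
  replayed <- replay_preprocess(panel, pp$report)
  expect_identical(as.data.frame(replayed)[clpn_nodes()],
                   as.data.frame(pp$data)[clpn_nodes()])
})

test_that("after preprocessing, higher cognitive scores mean better latents", {
  panel <- tiny_panel(n = 600, seed = 51)
  z <- attr(panel, "latents")
  pp <- preprocess_panel(panel)
  w1 <- dplyr::filter(pp$data, wave == 1)
  ord <- match(w1$participant_id, sprintf("P%05d", seq_len(600)))
  expect_gt(cor(w1$working_memory, z[ord, "working_memory", 1]), 0.3)
  expect_gt(cor(w1$inhibition_speed, z[ord, "inhibition_speed", 1]), 0.3)
  expect_gt(cor(w1$inhibition_accuracy, z[ord, "inhibition_accuracy", 1]), 0.3)
})

test_that("the report counts outliers and records the sample sizes", {
  panel <- tiny_panel(n = 100, seed = 61)
  panel$gng_rt[panel$wave == 2][1] <- 5000  # plant an extreme RT
  pp <- preprocess_panel(panel)
  expect_gte(pp$report$n_outlier_cells_removed[["gng_rt"]], 1)
  expect_identical(pp$report$n_input, 100L)
  expect_lte(pp$report$n_after_complete_case, pp$report$n_input)
  expect_true(all(c("variable", "wave", "mean", "sd", "step") %in%
                    names(pp$report$standardization_params)))
})
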