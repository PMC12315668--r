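nodes5 <- clpn_nodes()

test_that("network density counts nonzero lagged cells over n_nodes^2", {
  zero <- matrix(0, 5, 5, dimnames = list(nodes5, nodes5))
  expect_identical(network_density(zero), 0)
  m18 <- zero; m18[sample.int(25, 18)] <- runif(18, -1, 1)
  expect_equal(network_density(m18), 0.72)
  m23 <- zero; m23[sample.int(25, 23)] <- runif(23, -1, 1)
  expect_equal(network_density(m23), 0.92)
  # invariant to relabeling and to sign flips
  perm <- sample(5)
  expect_equal(network_density(m18[perm, perm]), network_density(m18))
  expect_equal(network_density(-m18), network_density(m18))
  # covariate rows are excluded by construction (matrix is nodes x nodes)
  net <- fake_network(m18)
  expect_equal(network_density(net), 0.72)
})

test_that("network comparison matches exhaustive enumeration", {
  a <- fake_network(matrix(c(0.5, 0, -0.2, 0), 2, 2,
                           dimnames = list(c("n1", "n2"), c("n1", "n2"))))
  b <- fake_network(matrix(c(0.5, 0.1, 0, 0), 2, 2,
                           dimnames = list(c("n1", "n2"), c("n1", "n2"))))
  cmp <- compare_networks(a, b)
  # supports: a = {11, 21}, b = {11, 12}; intersection 1, union 3
  expect_equal(cmp$jaccard, 1 / 3)
  expect_equal(cmp$density_a, 0.5)
  expect_equal(cmp$density_b, 0.5)
  expect_identical(nrow(cmp$sign_flips), 0L)

  self <- compare_networks(a, a)
  expect_equal(self$jaccard, 1)
  expect_equal(self$weight_correlation, 1)

  empty <- fake_network(matrix(0, 2, 2,
                               dimnames = list(c("n1", "n2"), c("n1", "n2"))))
  expect_equal(compare_networks(empty, b)$jaccard, 0)

  flipped <- fake_network(matrix(c(-0.5, 0, -0.2, 0), 2, 2,
                                 dimnames = list(c("n1", "n2"), c("n1", "n2"))))
  expect_identical(nrow(compare_networks(a, flipped)$sign_flips), 1L)

  c3 <- fake_network(matrix(0, 5, 5, dimnames = list(nodes5, nodes5)))
  expect_error(compare_networks(a, c3), "different node sets")
})

test_that("account classification follows the directed-edge pattern", {
  m <- matrix(0, 5, 5, dimnames = list(nodes5, nodes5))
  m["inhibition_accuracy", "externalizing"] <- -0.2   # risk factor
  m["externalizing", "working_memory"] <- -0.15       # consequence
  m["inhibition_speed", "internalizing"] <- -0.1      # both (with reverse)
  m["internalizing", "inhibition_speed"] <- -0.1
  acc <- classify_accounts(fake_network(m))
  lab <- function(ef, sy) acc$label[acc$ef_node == ef & acc$symptom_node == sy]
  expect_identical(lab("inhibition_accuracy", "externalizing"), "risk_factor")
  expect_identical(lab("working_memory", "externalizing"), "consequence")
  expect_identical(lab("inhibition_speed", "internalizing"), "both")
  expect_identical(lab("working_memory", "internalizing"), "none")
  # classification depends only on the signed support pattern
  m2 <- m * 3.7
  expect_identical(classify_accounts(fake_network(m2))$label, acc$label)
  # evidence columns carry the directed weights
  expect_equal(acc$ef_to_symptom[acc$ef_node == "inhibition_accuracy" &
                                   acc$symptom_node == "externalizing"], -0.2)
  expect_error(classify_accounts(fake_network(m), ef_nodes = "internalizing"),
               "must not overlap")
})

test_that("a bootstrap inclusion filter can veto weak edges", {
  m <- matrix(0, 5, 5, dimnames = list(nodes5, nodes5))
  m["inhibition_accuracy", "externalizing"] <- -0.2
  net <- fake_network(m)
  fake_bs <- structure(list(
    edge_summaries = tidy(net) |>
      dplyr::mutate(inclusion_proportion =
                      ifelse(source == "inhibition_accuracy" &
                               target == "externalizing", 0.4, 1))),
    class = "clpn_bootstrap")
  acc <- classify_accounts(net, bootstrap = fake_bs, inclusion_threshold = 0.8)
  expect_identical(acc$label[acc$ef_node == "inhibition_accuracy" &
                               acc$symptom_node == "externalizing"], "none")
  acc2 <- classify_accounts(net, bootstrap = fake_bs, inclusion_threshold = 0.3)
  expect_identical(acc2$label[acc2$ef_node == "inhibition_accuracy" &
                                acc2$symptom_node == "externalizing"],
                   "risk_factor")
})

test_that("recovery scoring handles the degenerate corners", {
  truth <- recovery_true_network(0.3)$lag$`1_2`
  self <- score_recovery(truth, truth)
  expect_equal(self$sensitivity, 1)
  expect_equal(self$specificity, 1)
  expect_equal(self$sign_accuracy, 1)
  allzero <- score_recovery(truth, truth * 0)
  expect_equal(allzero$sensitivity, 0)
  expect_equal(allzero$specificity, 1)
  expect_true(is.na(allzero$sign_accuracy))
})

test_that("the recovery experiment aggregates metrics with MC errors", {
  cfg <- generator_config(n_participants = 300, seed = 1,
                          true_network = recovery_true_network(0.3))
  rec <- run_recovery_experiment(cfg, reps = 3, n_grid = 300, seed = 21,
                                 n_lambdas = 40)
  expect_s3_class(rec, "clpn_recovery")
  expect_setequal(unique(rec$metric),
                  c("sensitivity", "specificity", "sign_accuracy",
                    "weight_correlation"))
  vals <- rec$value[rec$metric != "weight_correlation"]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(rec$reps == 3))
  per_rep <- attr(rec, "per_rep")
  expect_identical(nrow(per_rep), 3L)
})

test_that("recovery sensitivity does not degrade as n grows", {
  cfg <- generator_config(n_participants = 400, seed = 2,
                          true_network = recovery_true_network(0.3))
  rec <- run_recovery_experiment(cfg, reps = 4, n_grid = c(400, 1600),
                                 seed = 33, n_lambdas = 50)
  sens <- rec[rec$metric == "sensitivity", ]
  expect_gte(sens$value[sens$n == 1600], sens$value[sens$n == 400] - 0.1)
})

test_that("estimator properties under the one-SE rule: sparse and sensitive", {
  cfg <- generator_config(n_participants = 1500, seed = 3,
                          true_network = recovery_true_network(0.3))
  rec <- run_recovery_experiment(cfg, reps = 8, n_grid = 1500, seed = 44,
                                 rule = "one_se")
  sens <- rec$value[rec$metric == "sensitivity"]
  spec <- rec$value[rec$metric == "specificity"]
  expect_gte(sens, 0.8)         # |beta| = 0.3 edges are detected
  expect_lte(1 - spec, 0.3)     # false-edge rate stays controlled
})
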