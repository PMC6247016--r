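test_that("descriptive change statistics follow the per-state mean profile", {
  # three states with group means 0.1, 0.3, 0.2 for the single feature
  md <- make_md(rep(c("A", "B"), 3), rep(0:2, each = 2))
  vals <- matrix(c(0.05, 0.15, 0.25, 0.35, 0.15, 0.25), ncol = 1,
                 dimnames = list(rownames(md), "f1"))
  st <- feature_descriptive_stats(feature_table(vals), md)
  expect_equal(st$net_avg_change, 0.1)
  expect_equal(st$cumulative_avg_increase, 0.2)
  expect_equal(st$cumulative_avg_decrease, -0.1)
  expect_equal(st$cumulative_avg_increase + st$cumulative_avg_decrease,
               st$net_avg_change)

  const <- matrix(0.25, nrow = 6, ncol = 1,
                  dimnames = list(rownames(md), "f1"))
  cs <- feature_descriptive_stats(feature_table(const), md)
  expect_equal(cs$variance, 0)
  expect_equal(cs$cv, 0)
  expect_equal(cs$net_avg_change, 0)
  expect_equal(cs$cumulative_avg_increase, 0)

  one_state <- make_md(c("A", "B"), c(3, 3))
  zeros <- matrix(c(0, 0), ncol = 1, dimnames = list(rownames(one_state), "f1"))
  expect_warning(zs <- feature_descriptive_stats(feature_table(zeros),
                                                 one_state), "single state")
  expect_true(is.na(zs$cv))  # zero mean: CV undefined
  expect_equal(zs$net_avg_change, 0)
})

test_that("descriptive statistics match a brute-force oracle on random tables", {
  set.seed(23)
  md <- make_md(rep(sprintf("S%d", 1:8), each = 5), rep(c(0, 2, 3, 7, 9), 8))
  vals <- matrix(rexp(40 * 12), nrow = 40,
                 dimnames = list(rownames(md), sprintf("F%02d", 1:12)))
  got <- feature_descriptive_stats(feature_table(vals), md)
  want <- oracle_descriptive_stats(vals, md$month)
  expect_equal(got, want, tolerance = 1e-10)
  # identity holds for every feature
  expect_equal(got$cumulative_avg_increase + got$cumulative_avg_decrease,
               got$net_avg_change, tolerance = 1e-9)
})

test_that("a perfectly informative feature dominates the model", {
  set.seed(4)
  n <- 60
  md <- make_md(rep(sprintf("S%02d", 1:10), each = 6), rep(0:5, 10))
  vals <- matrix(runif(n * 8, 0, 5), nrow = n,
                 dimnames = list(rownames(md), sprintf("F%d", 1:8)))
  vals[, "F1"] <- md$month  # the target itself, zero noise
  res <- feature_volatility(feature_table(vals), md,
                            regressor_config(seed = 1, cv_folds = 3))
  expect_equal(res$importances$feature[1], "F1")
  expect_gt(res$importances$importance[1], 0.5)
  expect_gte(res$accuracy[["r_squared"]], 0.99)
  expect_equal(sum(res$importances$importance), 1, tolerance = 1e-9)
})

test_that("the pipeline is deterministic under a fixed seed", {
  sim <- simulate_cohort(cohort_design(12, 0:4, seed = 2),
                         effect_spec(n_features = 25, n_planted = 3,
                                     feature_model = "gaussian"))
  cfg <- regressor_config(seed = 7, cv_folds = 3)
  r1 <- feature_volatility(sim$table, sim$metadata, cfg)
  r2 <- feature_volatility(sim$table, sim$metadata, cfg)
  expect_identical(r1$importances, r2$importances)
  expect_identical(r1$accuracy, r2$accuracy)
  r3 <- feature_volatility(sim$table, sim$metadata,
                           regressor_config(seed = 8, cv_folds = 3))
  expect_false(identical(r1$accuracy, r3$accuracy))
})

test_that("permuting test-set targets changes accuracy but not the model", {
  set.seed(5)
  n <- 45
  # one sample per subject so test-set states can be shuffled freely
  md <- make_md(sprintf("S%02d", 1:n), rep(0:4, length.out = n))
  vals <- matrix(runif(n * 20), nrow = n,
                 dimnames = list(rownames(md), sprintf("F%02d", 1:20)))
  vals[, 1:3] <- vals[, 1:3] + md$month
  tab <- feature_table(vals)
  cfg <- regressor_config(seed = 9, cv_folds = 3)
  r1 <- feature_volatility(tab, md, cfg)
  test_ids <- r1$predictions$sample_id
  md2 <- as.data.frame(md)
  set.seed(1)
  md2[test_ids, "month"] <- sample(md2[test_ids, "month"])
  md2 <- sample_metadata(md2, "month", "subject")
  r2 <- feature_volatility(tab, md2, cfg)
  expect_identical(r1$importances$feature, r2$importances$feature)
  expect_identical(r1$importances$importance, r2$importances$importance)
  expect_identical(r1$predictions$predicted, r2$predictions$predicted)
  expect_false(identical(r1$accuracy[["mse"]], r2$accuracy[["mse"]]))
})

test_that("alternate estimators run and find the informative feature", {
  set.seed(6)
  n <- 40
  md <- make_md(rep(sprintf("S%02d", 1:8), each = 5), rep(0:4, 8))
  vals <- matrix(runif(n * 6, 0, 3), nrow = n,
                 dimnames = list(rownames(md), sprintf("F%d", 1:6)))
  vals[, "F2"] <- md$month
  for (est in c("extra-trees", "gradient-boosting", "elastic-net")) {
    res <- feature_volatility(feature_table(vals), md,
                              regressor_config(seed = 3, estimator = est,
                                               cv_folds = 3,
                                               n_estimators = 50))
    expect_equal(res$importances$feature[1], "F2")
    expect_gte(res$accuracy[["r_squared"]], 0.8)
  }
})

test_that("guard rails: small cohorts and constant targets are rejected", {
  md <- make_md(rep("A", 5), 0:4)
  vals <- matrix(1, 5, 3, dimnames = list(rownames(md), c("a", "b", "c")))
  expect_error(feature_volatility(feature_table(vals), md,
                                  regressor_config(seed = 1)),
               "at least 20 samples")
  md2 <- make_md(sprintf("S%d", 1:40), rep(5, 40))
  vals2 <- matrix(runif(80), 40, 2,
                  dimnames = list(rownames(md2), c("a", "b")))
  expect_error(suppressWarnings(
    feature_volatility(feature_table(vals2), md2, regressor_config(seed = 1))),
    "constant")
  expect_error(regressor_config(seed = 1, test_fraction = 1.5))
  expect_error(regressor_config(), "seed")
})

test_that("subject-grouped splitting keeps whole subjects out of training", {
  sim <- simulate_cohort(cohort_design(15, 0:4, seed = 8),
                         effect_spec(n_features = 15, n_planted = 2,
                                     feature_model = "gaussian"))
  res <- feature_volatility(sim$table, sim$metadata,
                            regressor_config(seed = 4, cv_folds = 3),
                            group_by_subject = TRUE)
  test_subjects <- unique(sub("\\..*$", "", res$predictions$sample_id))
  md <- as.data.frame(sim$metadata)
  # every sample of a test subject is in the test set
  for (s in test_subjects) {
    expect_true(all(rownames(md)[md$subject == s] %in%
                      res$predictions$sample_id))
  }
})
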