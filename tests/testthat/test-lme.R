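test_that("formula construction is canonical and override passes through", {
  spec <- lme_spec("metric", fixed_effects = c("delivery", "diet", "sex"),
                   state_column = "month")
  expect_equal(lme_formula(spec), "metric ~ delivery + diet + sex + month")
  spec2 <- lme_spec("metric", fixed_effects = c("delivery", "diet", "sex"),
                    interactions = "delivery:diet", state_column = "month")
  expect_equal(lme_formula(spec2),
               "metric ~ delivery + diet + sex + delivery:diet + month")
  spec3 <- lme_spec("y", formula_override = "y ~ month")
  expect_equal(lme_formula(spec3), "y ~ month")
  expect_error(lme_formula(lme_spec("y")), "state column")
})

test_that("unknown columns in the model specification are named in the error", {
  sim <- simulate_cohort(cohort_design(10, 0:4, seed = 1), effect_spec())
  expect_error(fit_lme(sim$metadata, lme_spec("y", fixed_effects = "nope")),
               "nope")
  expect_error(fit_lme(sim$metadata, lme_spec("absent")), "absent")
})

test_that("treatment-coded terms carry [T.level] labels against the first level", {
  sim <- simulate_cohort(
    cohort_design(30, 0:5, groups = list(delivery = c(cesarean = 0.5,
                                                      vaginal = 0.5),
                                         diet = c(bd = 0.5, fd = 0.5)),
                  seed = 42),
    effect_spec(fixed_intercept = 1, fixed_slope = 0.3))
  res <- fit_lme(sim$metadata,
                 lme_spec("y", fixed_effects = c("delivery", "diet", "sex"),
                          interactions = "delivery:diet"))
  expect_equal(res$fixed_effects$term,
               c("(Intercept)", "delivery [T.vaginal]", "diet [T.fd]",
                 "sex [T.male]", "delivery [T.vaginal]:diet [T.fd]", "month"))
  # P values are the exact two-tailed normal tail of the Z-score
  expect_equal(res$fixed_effects$p,
               2 * pnorm(-abs(res$fixed_effects$z)), tolerance = 1e-12)
  expect_equal(res$fixed_effects$z,
               res$fixed_effects$estimate / res$fixed_effects$se,
               tolerance = 1e-12)
  tab <- lme_table(res)
  expect_equal(tab$term[tab$section == "Random effects"],
               c("Intercept (subject ID)", "Slope (change per state)",
                 "Covariance (intercept, time)", "Residual variance"))
})

test_that("the degenerate zero-variance limit matches ordinary least squares", {
  set.seed(8)
  n_sub <- 40
  md <- make_md(rep(sprintf("S%02d", 1:n_sub), each = 5),
                rep(0:4, n_sub),
                y = NA_real_,
                grp = rep(sample(c("a", "b"), n_sub, replace = TRUE), each = 5))
  # no subject-level structure at all: y depends only on fixed effects + noise
  md$y <- 1 + 0.5 * md$month + 0.8 * (md$grp == "b") + rnorm(nrow(md), 0, 1)
  res <- suppressWarnings(fit_lme(md, lme_spec("y", fixed_effects = "grp")))
  ols <- coef(lm(y ~ grp + month, data = as.data.frame(md)))
  expect_equal(unname(res$fixed_effects$estimate), unname(ols),
               tolerance = 1e-3)
})

test_that("fixed estimates recover planted effects in simulation", {
  slopes <- sapply(1:10, function(seed) {
    sim <- simulate_cohort(cohort_design(100, 0:9, seed = seed),
                           effect_spec(fixed_intercept = 2, fixed_slope = 0.5,
                                       random_intercept_sd = 1,
                                       residual_sd = 0.5))
    res <- fit_lme(sim$metadata, lme_spec("y"))
    fe <- res$fixed_effects
    c(est = fe$estimate[fe$term == "month"], se = fe$se[fe$term == "month"],
      ri = res$random_effects[["intercept_variance"]])
  })
  expect_lt(abs(median(slopes["est", ]) - 0.5), 3 * median(slopes["se", ]))
  expect_lt(abs(median(slopes["ri", ]) - 1), 0.3)  # variance within 30%
})

test_that("scaling the response rescales estimates but not Z or P", {
  sim <- simulate_cohort(cohort_design(25, 0:5, seed = 5),
                         effect_spec(fixed_slope = 0.4))
  res1 <- fit_lme(sim$metadata, lme_spec("y", fixed_effects = "delivery"))
  md2 <- as.data.frame(sim$metadata)
  md2$y <- md2$y * 10
  md2 <- sample_metadata(md2, "month", "subject")
  res2 <- fit_lme(md2, lme_spec("y", fixed_effects = "delivery"))
  expect_equal(res2$fixed_effects$estimate, 10 * res1$fixed_effects$estimate,
               tolerance = 1e-6)
  expect_equal(res2$fixed_effects$se, 10 * res1$fixed_effects$se,
               tolerance = 1e-6)
  expect_equal(res2$fixed_effects$z, res1$fixed_effects$z, tolerance = 1e-6)
  expect_equal(res2$fixed_effects$p, res1$fixed_effects$p, tolerance = 1e-6)
})

test_that("relabeling subjects leaves all estimates unchanged", {
  sim <- simulate_cohort(cohort_design(20, 0:5, seed = 6), effect_spec())
  res1 <- fit_lme(sim$metadata, lme_spec("y"))
  md2 <- as.data.frame(sim$metadata)
  perm <- setNames(sample(unique(md2$subject)), unique(md2$subject))
  md2$subject <- unname(perm[md2$subject])
  md2 <- sample_metadata(md2, "month", "subject")
  res2 <- fit_lme(md2, lme_spec("y"))
  expect_equal(res2$fixed_effects$estimate, res1$fixed_effects$estimate,
               tolerance = 1e-8)
  expect_equal(res2$residual_variance, res1$residual_variance,
               tolerance = 1e-8)
})

test_that("singular fits return converged = FALSE with advice, not an error", {
  set.seed(30)
  # every subject sees the identical trajectory: the between-subject
  # variance components sit exactly at the zero boundary
  md <- make_md(rep(sprintf("S%d", 1:6), each = 4), rep(0:3, 6),
                y = rep(rnorm(4), 6))
  expect_warning(res <- fit_lme(md, lme_spec("y", include_random_slope = TRUE)),
                 "random slope")
  expect_false(res$converged)
  expect_true(is.finite(res$fixed_effects$estimate[1]))
  cmd <- make_md(rep("AB", 8), c(0:3, 0:3), y = rep(1, 8))
  expect_error(fit_lme(cmd, lme_spec("y")), "constant")
})
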