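test_that("default cohort matches the study's group structure", {
  atlas <- build_atlas("tau_suvr")
  cfg <- cohort_config(atlas, seed = 3)
  sim <- simulate_cohort(cfg)
  subj <- unique(sim$measures[, c("subject_id", "diagnosis")])
  expect_equal(nrow(subj), 113)
  expect_equal(as.vector(table(subj$diagnosis)[c("CN", "MCI", "AD")]),
               c(72, 23, 18))
  expect_equal(nrow(sim$measures), 113 * 76)
  expect_true(all(sim$measures$baseline > 0))
  expect_true(all(sim$measures$followup > 0))
  expect_true(all(sim$measures$interval_days > 0))
  # interval distribution located near the configured median
  med <- median(tapply(sim$measures$interval_days,
                       sim$measures$subject_id, unique))
  expect_lt(abs(med - 418) / 418, 0.15)
})

test_that("same seed gives identical cohorts; different seeds differ", {
  atlas <- make_synthetic_atlas(6, 3)
  cfg <- cohort_config(atlas, n_per_group = c(5, 3, 2), seed = 11)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  cfg$seed <- 12L
  s3 <- simulate_cohort(cfg)
  expect_false(identical(s1$measures$baseline, s3$measures$baseline))
})

test_that("follow-up back-computation reproduces drawn rates exactly", {
  for (mod in c("tau_suvr", "cortical_thickness")) {
    atlas <- make_synthetic_atlas(5, 2, modality = mod)
    cfg <- cohort_config(atlas, n_per_group = c(6, 3, 3), seed = 4)
    sim <- simulate_cohort(cfg)
    m <- sim$measures
    recovered <- relative_rate(m$baseline, m$followup, m$interval_days,
                               mod)
    expect_lt(max(abs(recovered - sim$truth$rate)), 1e-10)
    # and assembly normalizes those same rates
    obs <- assemble_observations(m, atlas)
    expect_lt(max(abs(obs$x * attr(obs, "scale") - sim$truth$rate)),
              1e-10)
  }
})

test_that("null-effect configuration makes groups exchangeable", {
  atlas <- make_synthetic_atlas(4, 2)
  cfg <- cohort_config(atlas, n_per_group = c(40, 40, 40), seed = 9,
                       mu_group = c(CN = 0.02, MCI = 0.02, AD = 0.02),
                       network_effect_sd = 1e-12, roi_effect_sd = 1e-12)
  sim <- simulate_cohort(cfg)
  obs <- assemble_observations(sim$measures, atlas)
  gm <- tapply(obs$x, obs$diagnosis, mean)
  expect_lt(max(gm) - min(gm), 0.05)
  # implied slopes are ~0
  tab <- implied_coefficient_table(sim$truth, attr(obs, "scale"))
  expect_lt(max(abs(tab$slope)), 1e-6)
})

test_that("implied coefficients match the Gaussian-mixture closed form", {
  expect_equal(implied_coefficients(0, 1, 1, 1/3, 1/3),
               c(intercept = -0.5, slope = 1))
  expect_equal(implied_coefficients(0, 0, 1, 1/3, 1/3),
               c(intercept = 0, slope = 0))
  expect_equal(implied_coefficients(0, 1, 1, 0.5, 0.25),
               c(intercept = -0.5 + log(0.5), slope = 1))
  expect_error(implied_coefficients(0, 1, 0, 0.5, 0.5), "sigma")
  expect_error(implied_coefficients(0, 1, 1, 0, 1), "probabilities")
})

test_that("large-sample logistic regression converges to the implied
           coefficients", {
  # independent oracle: simulate two equal-variance Gaussian classes and
  # fit a plain logistic regression with glm()
  set.seed(17)
  n <- 4e4
  x <- c(rnorm(n, 0, 1), rnorm(n, 1, 1))
  y <- rep(0:1, each = n)
  fit <- glm(y ~ x, family = binomial())
  expect_lt(abs(coef(fit)[1] - (-0.5)), 0.05)
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
})

test_that("invalid cohort configurations are rejected", {
  atlas <- make_synthetic_atlas(4, 2)
  expect_error(cohort_config(atlas, within_cell_sd = 0), "positive")
  expect_error(cohort_config(atlas, within_cell_sd = -1), "positive")
  expect_error(cohort_config(atlas, n_per_group = c(0, 5, 5)), ">= 1")
  expect_error(cohort_config(atlas, roi_effect_sd = -0.1), "nonnegative")
})
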