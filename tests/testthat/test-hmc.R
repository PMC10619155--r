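test_that("default configuration retains 4,000 draws and samples cleanly", {
  cfg <- sampler_config()
  expect_equal(cfg$n_chains * (cfg$n_iterations - cfg$n_warmup), 4000L)
  expect_error(sampler_config(n_iterations = 500, n_warmup = 600))
  expect_error(sampler_config(n_chains = 1))

  # model 1 on strongly separated toy data, full default configuration
  tc <- toy_cohort(n_roi = 3, n_net = 3, n = c(10, 5, 5), seed = 41,
                   mu_group = c(CN = 0.01, MCI = 0.06, AD = 0.16))
  st <- structure_from_obs(1, tc$obs)
  fit <- sample_posterior(st, prior_config("weakly_informative"),
                          tc$obs, sampler_config(seed = 42))
  expect_equal(n_draws(fit), 4000L)
  expect_equal(dim(fit$draws), c(1000L, 4L, 4L))
  expect_true(all(is.finite(fit$lp)))
  expect_equal(divergence_count(fit), 0)
  dr <- diagnostics_report(fit)
  expect_lte(dr$max_rhat, 1.05)
  assign("fit1_default", list(tc = tc, st = st, fit = fit),
         envir = neuropool_test_env())
})

test_that("posterior slope sign matches a separated cohort in >99% of
           draws and contracts with more data", {
  env <- neuropool_test_env()
  fit <- env$fit1_default$fit
  tc <- env$fit1_default$tc
  # AD mean rate exceeds CN by construction, so the AD slope is positive
  truth <- implied_coefficient_table(tc$sim$truth,
                                     attr(tc$obs, "scale"))
  expect_true(all(truth$slope[truth$category == "AD"] > 0))
  ad_slope <- draws_matrix(fit)[, "b1[AD]"]
  expect_gt(mean(ad_slope > 0), 0.99)

  # contraction: pooled-slope error shrinks as n grows
  pooled_truth <- mean(truth$slope[truth$category == "AD"])
  err <- sapply(c(60, 600), function(n_cn) {
    tcb <- toy_cohort(n_roi = 3, n_net = 3,
                      n = c(n_cn, n_cn %/% 2, n_cn %/% 2), seed = 43,
                      network_effect_sd = 1e-9, roi_effect_sd = 1e-9)
    stb <- structure_from_obs(1, tcb$obs)
    fitb <- sample_posterior(stb, prior_config("weakly_informative"),
                             tcb$obs,
                             sampler_config(n_iterations = 500,
                                            n_warmup = 250, seed = 44))
    tr <- implied_coefficient_table(tcb$sim$truth, attr(tcb$obs, "scale"))
    abs(mean(draws_matrix(fitb)[, "b1[AD]"]) -
          mean(tr$slope[tr$category == "AD"]))
  })
  expect_lt(err[2], err[1])
})

test_that("identical seed and input reproduce the draw arrays exactly", {
  tc <- toy_cohort(n_roi = 3, n_net = 3, n = c(6, 3, 3), seed = 51)
  st <- structure_from_obs(1, tc$obs)
  cfg <- sampler_config(n_iterations = 300, n_warmup = 150, seed = 52)
  pri <- prior_config("weakly_informative")
  f1 <- sample_posterior(st, pri, tc$obs, cfg)
  f2 <- sample_posterior(st, pri, tc$obs, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$log_lik, f2$log_lik)
  cfg$seed <- 53L
  f3 <- sample_posterior(st, pri, tc$obs, cfg)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("uninformative data return the prior for the slopes", {
  atlas <- make_synthetic_atlas(2, 2)
  m <- data.frame(subject_id = rep(sprintf("s%d", 1:60), each = 2),
                  diagnosis = rep(rep(c("CN", "MCI", "AD"), each = 20),
                                  each = 2),
                  roi_index = rep(1:2, 60),
                  baseline = 2, followup = 2, interval_days = 400)
  m$followup[1] <- 2.2  # one nonzero rate so normalization is defined
  obs <- assemble_observations(m, atlas)
  obs$x <- 0 * obs$x    # flat predictor: no information on slopes
  st <- structure_from_obs(1, obs)
  fit <- sample_posterior(st, prior_config(), obs,
                          sampler_config(seed = 54))
  sl <- draws_matrix(fit)[, c("b1[MCI]", "b1[AD]")]
  expect_lt(abs(sd(sl[, 1]) - 0.2) / 0.2, 0.1)
  expect_lt(abs(sd(sl[, 2]) - 0.2) / 0.2, 0.1)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(61)
  good <- matrix(rnorm(4000), 1000, 4)
  r <- split_rhat(good)
  expect_gt(r, 0.999)
  expect_lt(r, 1.01)
  bad <- cbind(matrix(rnorm(2000, 0), 1000, 2),
               matrix(rnorm(2000, 10), 1000, 2))
  expect_gt(split_rhat(bad), 1.5)
  expect_true(is.na(split_rhat(matrix(1, 100, 4))))
  expect_error(split_rhat(matrix(rnorm(4), 2, 2)), "at least 4")
  expect_true(is.finite(folded_split_rhat(good)))
})

test_that("MCSE scales as sd/sqrt(ESS) and reacts to autocorrelation", {
  set.seed(62)
  iid <- matrix(rnorm(10000), 2500, 4)
  expect_lt(abs(mcse_mean(iid) - 0.01), 0.004)
  expect_identical(mcse_mean(rep(2, 500)), 0)
  # AR(1) with rho = 0.9 inflates the MCSE well above the iid value
  ar <- matrix(0, 2500, 4)
  for (ch in 1:4) {
    e <- rnorm(2500)
    xs <- filter(e, 0.9, method = "recursive")
    ar[, ch] <- as.numeric(xs) * sqrt(1 - 0.9^2)
  }
  expect_gt(mcse_mean(ar), 2.5 * mcse_mean(iid))
  # ESS sanity: iid close to the draw count, never wildly above
  expect_gt(ess_mean(iid), 5000)
  expect_lt(ess_mean(iid), 12000)
  expect_true(is.finite(ess_bulk(iid)))
  expect_true(is.finite(ess_tail(iid)))
})

test_that("divergence accounting requires sampler statistics", {
  env <- neuropool_test_env()
  fit <- env$fit1_default$fit
  broken <- fit
  broken$stats <- NULL
  expect_error(divergence_count(broken), "statistics")
})
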