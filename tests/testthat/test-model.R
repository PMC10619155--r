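test_that("parameter counts enumerate the four model layouts", {
  expect_equal(parameter_dim(model_structure(1)), 4L)
  expect_equal(parameter_dim(model_structure(2, n_roi = 76)), 312L)
  expect_equal(parameter_dim(model_structure(3, n_net = 8)), 40L)
  expect_equal(parameter_dim(model_structure(4, n_roi = 76, n_net = 8,
                                             roi_network = rep(1:8, length.out = 76))),
               8L + 32L + 4L + 304L)
  for (lev in 1:4) {
    st <- model_structure(lev, n_roi = 6, n_net = 3,
                          roi_network = rep(1:3, 2))
    expect_equal(length(param_names(st)), parameter_dim(st))
    expect_false(anyDuplicated(param_names(st)) > 0)
  }
  expect_error(model_structure(4, n_roi = 1, n_net = 1), "more than one")
})

test_that("linear predictors follow the additive structure", {
  row <- list(x = 0.5, roi_index = 2L, network_id = 1L)
  st1 <- model_structure(1)
  p1 <- params_from_theta(c(0.1, 0.1, 0.4, 0.4), st1)
  expect_equal(linear_predictor(p1, st1, row, "CN"), 0)
  expect_equal(linear_predictor(p1, st1, row, "AD"), 0.1 + 0.4 * 0.5)

  # nested model: network term + ROI deviation, intercept and slope
  st4 <- model_structure(4, n_roi = 3, n_net = 2,
                         roi_network = c(1L, 1L, 2L))
  theta <- numeric(parameter_dim(st4))
  names(theta) <- param_names(st4)
  # network 1 coefficients via hyper-means (z = 0), deviations via tau*zr
  theta["mu0_net[AD]"] <- 0.2
  theta["mu1_net[AD]"] <- 0.3
  theta["log_tau0[AD]"] <- log(0.05)
  theta["log_tau1[AD]"] <- log(0.1)
  theta["zr0_roi[AD,2]"] <- -1   # deviation -0.05
  theta["zr1_roi[AD,2]"] <- 1    # deviation +0.1
  p4 <- params_from_theta(theta, st4)
  lam <- linear_predictor(p4, st4, list(x = 1, roi_index = 2L,
                                        network_id = 1L), "AD")
  expect_equal(unname(lam), (0.2 - 0.05) + (0.3 + 0.1) * 1)
  expect_error(linear_predictor(p4, st4, list(x = 1, roi_index = 9L,
                                              network_id = 1L), "AD"),
               "out of range")
})

test_that("softmax is stable, normalized, and shift invariant", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(0, log(2), log(3))), c(1, 2, 3) / 6)
  big <- softmax(c(0, 1000, 0))
  expect_equal(big[2], 1, tolerance = 1e-12)
  expect_false(any(is.nan(big)))
  expect_error(softmax(c(0, Inf, 1)), "finite")
  set.seed(3)
  for (rep in 1:50) {
    lam <- rnorm(3, sd = 100)
    p <- softmax(lam)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_equal(softmax(lam + rnorm(1, sd = 50)), p, tolerance = 1e-9)
  }
})

test_that("pointwise log-likelihood matches the categorical density", {
  st <- model_structure(1)
  # pi = (0.5, 0.3, 0.2) at x = 0 via intercepts log(p_j / p_CN)
  p <- params_from_theta(c(log(0.3 / 0.5), log(0.2 / 0.5), 0, 0), st)
  rows <- data.frame(x = 0, roi_index = 1L, network_id = 1L,
                     diagnosis = factor("MCI", levels = c("CN", "MCI", "AD")))
  expect_equal(unname(pointwise_loglik(p, st, rows)), log(0.3))
  # uniform case: N rows at lambda = 0
  p0 <- params_from_theta(rep(0, 4), st)
  rowsN <- data.frame(x = rnorm(25), roi_index = 1L, network_id = 1L,
                      diagnosis = factor(sample(c("CN", "MCI", "AD"), 25,
                                                TRUE),
                                         levels = c("CN", "MCI", "AD")))
  expect_equal(sum(pointwise_loglik(p0, st, rowsN)), -25 * log(3))
  # extreme coefficients stay finite
  pbig <- params_from_theta(c(500, -500, 0, 0), st)
  ll <- pointwise_loglik(pbig, st, rowsN)
  expect_true(all(is.finite(ll)))
  expect_true(all(ll <= 0))
  expect_error(pointwise_loglik(p0, st, rowsN[0, ]), "nonempty")
})

test_that("log-prior handles support boundaries and the pooling limit", {
  st1 <- model_structure(1)
  pri <- prior_config()
  p0 <- params_from_theta(rep(0, 4), st1)
  # maximal at the mode of the symmetric priors
  expect_equal(log_prior(p0, st1, pri),
               2 * dnorm(0, 0, 0.05, log = TRUE) +
                 2 * dnorm(0, 0, 0.2, log = TRUE))
  expect_gt(log_prior(p0, st1, pri),
            log_prior(params_from_theta(c(0.1, 0, 0, 0), st1), st1, pri))

  st2 <- model_structure(2, n_roi = 3)
  mk <- function(sig, bdev = 0) {
    th <- numeric(parameter_dim(st2))
    th[5:8] <- log(sig)
    th[9] <- bdev / sig  # one coefficient displaced from its hyper-mean
    params_from_theta(th, st2)
  }
  # sd < 0 rejects with -Inf rather than erroring
  p <- mk(0.1)
  p$sigma0[1] <- -0.1
  expect_identical(log_prior(p, st2, pri), -Inf)
  # Half-Normal density is finite at sd -> 0+
  expect_true(is.finite(neuropool:::half_normal_lpdf(1e-12, 0.05)))
  expect_identical(neuropool:::half_normal_lpdf(-1e-9, 0.05), -Inf)
  # shrinking hyper-sd concentrates the prior on the pooled configuration:
  # displacing a coefficient from the hyper-mean gets infinitely penalized
  gap <- function(sig) {
    log_prior(mk(sig, bdev = 0.1), st2, pri) -
      log_prior(mk(sig, bdev = 0), st2, pri)
  }
  gaps <- vapply(c(0.1, 0.03, 0.01), gap, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], -40)
})

test_that("compiled gradient matches finite differences of the R mirror", {
  tc <- toy_cohort(n_roi = 4, n_net = 2, n = c(6, 3, 3), seed = 13)
  pri <- prior_config("weakly_informative")
  set.seed(14)
  for (lev in 1:4) {
    st <- structure_from_obs(lev, tc$obs)
    lp_grad <- neuropool:::make_lp_grad(st, pri, tc$obs)
    fR <- function(th) log_posterior_unconstrained(th, st, pri, tc$obs)
    for (rep in 1:3) {
      theta <- rnorm(parameter_dim(st), 0, 0.4)
      g <- lp_grad(theta)
      expect_equal(g$lp, fR(theta), tolerance = 1e-10)
      ng <- num_grad(fR, theta)
      expect_lt(max(abs(g$grad - ng) / pmax(abs(ng), 1)), 1e-5)
    }
  }
})

test_that("model nesting: zero deviations reduce model 4 to model 3 and
           one ROI reduces model 2 to model 1", {
  tc <- toy_cohort(n_roi = 4, n_net = 2, n = c(6, 3, 3), seed = 23)
  st3 <- structure_from_obs(3, tc$obs)
  st4 <- structure_from_obs(4, tc$obs)
  set.seed(24)
  th3 <- rnorm(parameter_dim(st3), 0, 0.5)
  th4 <- c(th3, rnorm(4), rep(0, 4 * 4))  # log_tau arbitrary, zr = 0
  ll3 <- pointwise_loglik(params_from_theta(th3, st3), st3, tc$obs)
  ll4 <- pointwise_loglik(params_from_theta(th4, st4), st4, tc$obs)
  expect_equal(ll4, ll3, tolerance = 1e-12)

  atlas1 <- make_synthetic_atlas(1, 1)
  sim1 <- simulate_cohort(cohort_config(atlas1, n_per_group = c(4, 2, 2),
                                        seed = 25))
  obs1 <- assemble_observations(sim1$measures, atlas1)
  st1 <- structure_from_obs(1, obs1)
  st2 <- structure_from_obs(2, obs1)
  b <- c(0.3, -0.2, 1.1, 0.6)
  th2 <- c(b, log(c(1, 1, 1, 1)), rep(0, 4))  # mu = b, z = 0
  expect_equal(
    pointwise_loglik(params_from_theta(th2, st2), st2, obs1),
    pointwise_loglik(params_from_theta(b, st1), st1, obs1),
    tolerance = 1e-12)
})
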