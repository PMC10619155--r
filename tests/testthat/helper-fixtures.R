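# Shared fixtures, built lazily in code and memoized so expensive fits
# are sampled once per test run.

.fixtures <- new.env(parent = emptyenv())

neuropool_test_env <- function() .fixtures

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# keep np_obs attributes when subsetting rows
subset_obs <- function(obs, idx) {
  out <- obs[idx, , drop = FALSE]
  for (at in c("scale", "modality", "n_roi", "n_net", "roi_network")) {
    attr(out, at) <- attr(obs, at)
  }
  out
}

toy_cohort <- function(n_roi = 6, n_net = 3, n = c(12, 6, 6), seed = 5,
                       ...) {
  atlas <- make_synthetic_atlas(n_roi, n_net)
  sim <- simulate_cohort(cohort_config(atlas, n_per_group = n,
                                       seed = seed, ...))
  obs <- assemble_observations(sim$measures, atlas)
  list(atlas = atlas, sim = sim, obs = obs)
}

# a hand-built fit whose draws are fully prescribed (for deterministic
# predictive and curve tests); zero divergences, no log-lik unless asked
fake_fit <- function(structure, theta_rows, obs, n_chains = 2,
                     with_loglik = FALSE) {
  d <- parameter_dim(structure)
  stopifnot(ncol(theta_rows) == d)
  n_keep <- nrow(theta_rows)
  draws <- array(NA_real_, c(n_keep, n_chains, d),
                 dimnames = list(NULL, NULL, param_names(structure)))
  for (ch in seq_len(n_chains)) draws[, ch, ] <- theta_rows
  stats <- lapply(seq_len(n_chains), function(ch) {
    data.frame(divergent = rep(FALSE, n_keep),
               tree_depth = 1L, accept_stat = 1, energy = 0,
               step_size = 0.1)
  })
  fit <- structure(list(draws = draws, stats = stats,
                        structure = structure,
                        priors = prior_config(), config = NULL,
                        data = obs, scale = attr(obs, "scale"),
                        modality = attr(obs, "modality")),
                   class = "np_fit")
  if (with_loglik) {
    fit$log_lik <- neuropool:::mlr_pointwise_ll_cpp(
      draws_matrix(fit), structure$model_number, structure$n_roi,
      structure$n_net, as.integer(obs$diagnosis), as.numeric(obs$x),
      as.integer(obs$roi_index), as.integer(obs$network_id))
  }
  fit
}

# shared small model-1 fit (1,200 retained draws) on a toy cohort
small_fit1 <- function() {
  fixture("small_fit1", function() {
    tc <- toy_cohort()
    st <- structure_from_obs(1, tc$obs)
    fit <- sample_posterior(st, prior_config("weakly_informative"),
                            tc$obs,
                            sampler_config(n_iterations = 600,
                                           n_warmup = 300, seed = 21))
    list(tc = tc, st = st, fit = fit)
  })
}

# shared small model-4 fit on a 12-ROI / 4-network cohort
small_fit4 <- function() {
  fixture("small_fit4", function() {
    atlas <- make_synthetic_atlas(12, 4)
    sim <- simulate_cohort(cohort_config(atlas,
                                         n_per_group = c(12, 5, 5),
                                         seed = 31))
    obs <- assemble_observations(sim$measures, atlas)
    st <- structure_from_obs(4, obs)
    fit <- sample_posterior(st, prior_config("weakly_informative"), obs,
                            sampler_config(n_iterations = 600,
                                           n_warmup = 300, seed = 32))
    list(atlas = atlas, sim = sim, obs = obs, st = st, fit = fit)
  })
}

num_grad <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h
    tm[k] <- tm[k] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}
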