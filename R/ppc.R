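# Prior predictive simulation and posterior predictive checks for the
# categorical outcome.

#' Prior predictive simulation
#'
#' Draws parameters from the priors only (no data), pushes them through
#' the softmax link over a grid of normalized inputs, and summarizes the
#' implied distribution of class probabilities.  With the default tight
#' priors every category's mean predicted probability sits at 1/3: the
#' model is fair, treating all diagnostic outcomes as equally likely
#' a priori.  The fairness check passes when each category's mean lies
#' in 1/3 +- 0.02.
#'
#' @param structure an `np_structure`.
#' @param priors an `np_priors`.
#' @param input_grid normalized input values (default 101 points on
#'   \[-1, 1\]).
#' @param n_draws number of prior draws (>= 1000).
#' @param seed RNG seed.
#' @return list of class `np_prior_pred`: `category_mean`,
#'   `category_sd` (length-3, CN/MCI/AD), `draws` (n_draws x 3 matrix of
#'   grid-averaged class probabilities), `fair` (logical), `tolerance`.
#' @export
prior_predictive <- function(structure, priors,
                             input_grid = seq(-1, 1, length.out = 101),
                             n_draws = 4000, seed = 1) {
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  hier <- structure$level != "complete_pooling"
  nested <- structure$level == "nested"
  # groups are exchangeable a priori, so one representative group
  # coefficient per draw characterizes the prior predictive distribution
  draw_coef <- function(n, mean_scale, sd_scale, nested_scale) {
    if (!hier) return(stats::rnorm(n, 0, mean_scale))
    mu <- stats::rnorm(n, 0, mean_scale)
    sg <- abs(stats::rnorm(n, 0, sd_scale))
    b <- mu + sg * stats::rnorm(n)
    if (nested) b <- b + abs(stats::rnorm(n, 0, nested_scale)) *
        stats::rnorm(n)
    b
  }
  probs <- matrix(0, n_draws, 3, dimnames = list(NULL, DIAGNOSES))
  b0 <- cbind(draw_coef(n_draws, if (hier) priors$group_mean_intercept_scale
                        else priors$intercept_scale,
                        priors$group_sd_intercept_scale,
                        priors$nested_roi_intercept_scale),
              draw_coef(n_draws, if (hier) priors$group_mean_intercept_scale
                        else priors$intercept_scale,
                        priors$group_sd_intercept_scale,
                        priors$nested_roi_intercept_scale))
  b1 <- cbind(draw_coef(n_draws, if (hier) priors$group_mean_slope_scale
                        else priors$slope_scale,
                        priors$group_sd_slope_scale,
                        priors$nested_roi_slope_scale),
              draw_coef(n_draws, if (hier) priors$group_mean_slope_scale
                        else priors$slope_scale,
                        priors$group_sd_slope_scale,
                        priors$nested_roi_slope_scale))
  for (x in input_grid) {
    l1 <- b0[, 1] + b1[, 1] * x
    l2 <- b0[, 2] + b1[, 2] * x
    m <- pmax(0, pmax(l1, l2))
    denom <- exp(-m) + exp(l1 - m) + exp(l2 - m)
    probs <- probs + cbind(exp(-m), exp(l1 - m), exp(l2 - m)) / denom
  }
  probs <- probs / length(input_grid)
  tol <- 0.02
  cm <- colMeans(probs)
  structure(list(category_mean = cm,
                 category_sd = apply(probs, 2, stats::sd),
                 draws = probs,
                 fair = all(abs(cm - 1 / 3) <= tol),
                 tolerance = tol),
            class = "np_prior_pred")
}

#' Posterior predictive replication
#'
#' Draws replicated outcome vectors from the fitted model: for each
#' replicate a posterior draw is selected, per-observation class
#' probabilities are computed, and outcomes are sampled from the
#' multinomial likelihood.  The summary compares replicated per-class
#' counts with the observed counts and reports a posterior predictive
#' p-value per class (the fraction of replicates with a count at least
#' as large as observed); a well-fitting model yields p-values away from
#' 0 and 1.
#'
#' @param fit an `np_fit`.
#' @param rows observation table (defaults to the fitted data; must be
#'   the same size).
#' @param n_reps number of replicated datasets (default 1000).
#' @param seed RNG seed.
#' @return list of class `np_ppc`: `y_rep` (n_reps x n outcome matrix,
#'   coded 1 = CN, 2 = MCI, 3 = AD), `rep_counts` (n_reps x 3),
#'   `observed_counts`, `p_value` (per class), `group_class_freq`
#'   (mean replicated class frequencies within each observed diagnosis
#'   group).
#' @export
posterior_predictive <- function(fit, rows = fit$data, n_reps = 1000,
                                 seed = 1) {
  if (nrow(rows) != nrow(fit$data)) {
    stop("rows size does not match the fitted data")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  dm <- draws_matrix(fit)
  S <- nrow(dm)
  n <- nrow(rows)
  pick <- sample.int(S, n_reps, replace = n_reps > S)
  y_rep <- matrix(NA_integer_, n_reps, n)
  st <- fit$structure
  for (r in seq_len(n_reps)) {
    p <- mlr_probs_cpp(dm[pick[r], ], st$model_number, st$n_roi,
                       st$n_net, as.numeric(rows$x),
                       as.integer(rows$roi_index),
                       as.integer(rows$network_id))
    uu <- stats::runif(n)
    y_rep[r, ] <- 1L + (uu > p[, 1]) + (uu > p[, 1] + p[, 2])
  }
  rep_counts <- t(apply(y_rep, 1, tabulate, nbins = 3))
  colnames(rep_counts) <- DIAGNOSES
  obs <- tabulate(as.integer(rows$diagnosis), nbins = 3)
  names(obs) <- DIAGNOSES
  p_value <- vapply(1:3, function(j) mean(rep_counts[, j] >= obs[j]),
                    numeric(1))
  names(p_value) <- DIAGNOSES
  grp <- as.integer(rows$diagnosis)
  group_class_freq <- t(vapply(1:3, function(g) {
    sub <- y_rep[, grp == g, drop = FALSE]
    tabulate(as.vector(sub), nbins = 3) / length(sub)
  }, numeric(3)))
  dimnames(group_class_freq) <- list(DIAGNOSES, DIAGNOSES)
  structure(list(y_rep = y_rep, rep_counts = rep_counts,
                 observed_counts = obs, p_value = p_value,
                 group_class_freq = group_class_freq),
            class = "np_ppc")
}
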