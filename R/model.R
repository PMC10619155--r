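#' Model structure: which pooling level is active
#'
#' Defines one of the four multinomial logistic model structures:
#' \describe{
#'   \item{model 1 `"complete_pooling"`}{one global intercept and slope
#'     per non-reference category.}
#'   \item{model 2 `"roi"`}{intercept/slope vary by ROI, partially pooled
#'     through a Gaussian group distribution with unknown mean and sd.}
#'   \item{model 3 `"network"`}{as model 2 but grouped by functional
#'     network (subcortical ROIs form an extra network for tau).}
#'   \item{model 4 `"nested"`}{network-level coefficients as in model 3
#'     plus ROI-specific deviations with their own (Half-Normal
#'     hyper-prior) sds.}
#' }
#' The outcome has J = 3 categories (CN, MCI, AD) with CN fixed as the
#' reference (its linear predictor is 0), and K = 1 predictor (the
#' normalized relative annualized rate).
#'
#' @param level `"complete_pooling"`, `"roi"`, `"network"`, `"nested"`,
#'   or a model number 1-4.
#' @param n_roi,n_net number of ROIs / network clusters.
#' @param roi_network integer vector mapping each ROI to its network
#'   (required for level `"nested"` prediction targets; taken from the
#'   atlas/observations).
#' @return list of class `np_structure`.
#' @seealso [structure_from_obs()]
#' @export
model_structure <- function(level, n_roi = NULL, n_net = NULL,
                            roi_network = NULL) {
  levels <- c("complete_pooling", "roi", "network", "nested")
  if (is.numeric(level)) level <- levels[level]
  level <- match.arg(level, levels)
  model_number <- match(level, levels)
  if (level %in% c("roi", "nested") &&
      (is.null(n_roi) || n_roi < 1)) {
    stop("level '", level, "' requires n_roi >= 1")
  }
  if (level %in% c("network", "nested") &&
      (is.null(n_net) || n_net < 1)) {
    stop("level '", level, "' requires n_net >= 1")
  }
  if (level == "nested" && (n_roi <= 1 || n_net <= 1)) {
    stop("nested structure needs more than one ROI and network")
  }
  if (!is.null(roi_network) && !is.null(n_roi)) {
    stopifnot(length(roi_network) == n_roi)
  }
  structure(list(level = level, model_number = model_number,
                 n_categories = 3L, n_predictors = 1L,
                 n_roi = if (is.null(n_roi)) 0L else as.integer(n_roi),
                 n_net = if (is.null(n_net)) 0L else as.integer(n_net),
                 roi_network = as.integer(roi_network),
                 reference = "CN"),
            class = "np_structure")
}

#' Model structure matching an observation table
#' @param level pooling level (see [model_structure()]).
#' @param obs an `np_obs` observation table.
#' @return `np_structure` with dimensions taken from `obs`.
#' @export
structure_from_obs <- function(level, obs) {
  model_structure(level,
                  n_roi = attr(obs, "n_roi"),
                  n_net = attr(obs, "n_net"),
                  roi_network = attr(obs, "roi_network"))
}

#' Prior configuration
#'
#' Scales of all prior distributions (scale = standard deviation, not
#' variance).  Model 1 uses `Normal(0, 0.05)` intercept and
#' `Normal(0, 0.2)` slope priors; in the hierarchical models the group
#' means get Gaussian priors and the group sds Half-Normal priors.  The
#' `"default"` preset mirrors the model-1 scales at every level (these
#' tight scales are what makes the prior predictive distribution fair
#' across the three diagnostic groups); the `"weakly_informative"`
#' preset widens them for simulation studies where the prior must not
#' dominate the likelihood (parameter-recovery checks).
#'
#' @param preset `"default"` or `"weakly_informative"`.
#' @param intercept_scale,slope_scale model-1 (global) prior scales.
#' @param group_mean_intercept_scale,group_mean_slope_scale Gaussian
#'   prior scales on the group-level means (models 2-4).
#' @param group_sd_intercept_scale,group_sd_slope_scale Half-Normal prior
#'   scales on the group-level sds (models 2-4).
#' @param nested_roi_intercept_scale,nested_roi_slope_scale Half-Normal
#'   prior scales on the nested ROI-deviation sds (model 4); default half
#'   the network-level sd scales.
#' @return list of class `np_priors`.
#' @export
prior_config <- function(preset = c("default", "weakly_informative"),
                         intercept_scale = NULL,
                         slope_scale = NULL,
                         group_mean_intercept_scale = NULL,
                         group_mean_slope_scale = NULL,
                         group_sd_intercept_scale = NULL,
                         group_sd_slope_scale = NULL,
                         nested_roi_intercept_scale = NULL,
                         nested_roi_slope_scale = NULL) {
  preset <- match.arg(preset)
  base <- if (preset == "default") {
    list(intercept_scale = 0.05, slope_scale = 0.2,
         group_mean_intercept_scale = 0.05,
         group_mean_slope_scale = 0.2,
         group_sd_intercept_scale = 0.05,
         group_sd_slope_scale = 0.2,
         nested_roi_intercept_scale = 0.025,
         nested_roi_slope_scale = 0.1)
  } else {
    list(intercept_scale = 2, slope_scale = 5,
         group_mean_intercept_scale = 2,
         group_mean_slope_scale = 5,
         group_sd_intercept_scale = 1,
         group_sd_slope_scale = 2,
         nested_roi_intercept_scale = 0.5,
         nested_roi_slope_scale = 1)
  }
  user <- list(intercept_scale = intercept_scale,
               slope_scale = slope_scale,
               group_mean_intercept_scale = group_mean_intercept_scale,
               group_mean_slope_scale = group_mean_slope_scale,
               group_sd_intercept_scale = group_sd_intercept_scale,
               group_sd_slope_scale = group_sd_slope_scale,
               nested_roi_intercept_scale = nested_roi_intercept_scale,
               nested_roi_slope_scale = nested_roi_slope_scale)
  for (nm in names(user)) if (!is.null(user[[nm]])) base[[nm]] <- user[[nm]]
  if (any(unlist(base) <= 0)) stop("all prior scales must be positive")
  structure(base, class = "np_priors")
}

# scales vector handed to the compiled log-posterior:
# (int, slope, gm0, gm1, gs0, gs1, nd0, nd1)
prior_scales_vec <- function(priors) {
  c(priors$intercept_scale, priors$slope_scale,
    priors$group_mean_intercept_scale, priors$group_mean_slope_scale,
    priors$group_sd_intercept_scale, priors$group_sd_slope_scale,
    priors$nested_roi_intercept_scale, priors$nested_roi_slope_scale)
}

n_groups <- function(structure) {
  switch(structure$level,
         complete_pooling = 0L,
         roi = structure$n_roi,
         network = structure$n_net,
         nested = structure$n_net)
}

#' Number of free parameters of a model structure
#'
#' Counts all sampled parameters (reference-category coefficients are
#' fixed at zero and excluded): model 1 has 4; models 2/3 have
#' `4 * G + 8` for G groups (per-group intercepts and slopes for MCI and
#' AD plus 8 hyper-parameters); model 4 adds `4 * n_roi + 4` nested
#' ROI-deviation parameters.
#'
#' @param structure an `np_structure`.
#' @return integer parameter count.
#' @export
parameter_dim <- function(structure) {
  switch(structure$level,
         complete_pooling = 4L,
         roi = 8L + 4L * structure$n_roi,
         network = 8L + 4L * structure$n_net,
         nested = 8L + 4L * structure$n_net + 4L + 4L * structure$n_roi)
}

#' Names of the unconstrained parameter vector
#'
#' The sampler works on an unconstrained vector: hierarchical
#' coefficients are non-centered (`coef = mu + sigma * z`) and sds are
#' log-transformed.  This function documents the layout; it matches the
#' compiled log-posterior exactly.
#'
#' @param structure an `np_structure`.
#' @return character vector of length [parameter_dim()].
#' @export
param_names <- function(structure) {
  cats <- NONREF
  hyper <- function(tag) {
    c(sprintf("mu0_%s[%s]", tag, cats), sprintf("mu1_%s[%s]", tag, cats),
      sprintf("log_sigma0_%s[%s]", tag, cats),
      sprintf("log_sigma1_%s[%s]", tag, cats))
  }
  zblock <- function(what, tag, G) {
    c(sprintf("%s0_%s[%s,%d]", what, tag,
              rep(cats, each = G), rep(seq_len(G), 2)),
      sprintf("%s1_%s[%s,%d]", what, tag,
              rep(cats, each = G), rep(seq_len(G), 2)))
  }
  switch(structure$level,
    complete_pooling = c(sprintf("b0[%s]", cats), sprintf("b1[%s]", cats)),
    roi = c(hyper("roi"), zblock("z", "roi", structure$n_roi)),
    network = c(hyper("net"), zblock("z", "net", structure$n_net)),
    nested = c(hyper("net"), zblock("z", "net", structure$n_net),
               sprintf("log_tau0[%s]", cats),
               sprintf("log_tau1[%s]", cats),
               zblock("zr", "roi", structure$n_roi)))
}

#' Convert an unconstrained parameter vector to natural parameters
#'
#' @param theta numeric vector in the [param_names()] layout.
#' @param structure an `np_structure`.
#' @return named list of natural-scale parameters: model 1 `b0`, `b1`
#'   (length-2, MCI/AD); models 2/3 add `mu0`, `mu1`, `sigma0`, `sigma1`
#'   and 2 x G coefficient matrices `b0`, `b1`; model 4 has network
#'   matrices `b0_net`, `b1_net`, deviation sds `tau0`, `tau1`, and
#'   2 x n_roi deviation matrices `d0`, `d1`.
#' @export
params_from_theta <- function(theta, structure) {
  stopifnot(length(theta) == parameter_dim(structure))
  cats <- NONREF
  two <- function(v) stats::setNames(v, cats)
  if (structure$level == "complete_pooling") {
    return(list(b0 = two(theta[1:2]), b1 = two(theta[3:4])))
  }
  G <- n_groups(structure)
  mu0 <- two(theta[1:2]); mu1 <- two(theta[3:4])
  sigma0 <- two(exp(theta[5:6])); sigma1 <- two(exp(theta[7:8]))
  z0 <- matrix(theta[8 + seq_len(2 * G)], nrow = 2, byrow = TRUE,
               dimnames = list(cats, NULL))
  z1 <- matrix(theta[8 + 2 * G + seq_len(2 * G)], nrow = 2, byrow = TRUE,
               dimnames = list(cats, NULL))
  b0 <- mu0 + sigma0 * z0
  b1 <- mu1 + sigma1 * z1
  if (structure$level != "nested") {
    return(list(mu0 = mu0, mu1 = mu1, sigma0 = sigma0, sigma1 = sigma1,
                z0 = z0, z1 = z1, b0 = b0, b1 = b1))
  }
  off <- 8 + 4 * G
  U <- structure$n_roi
  tau0 <- two(exp(theta[off + 1:2])); tau1 <- two(exp(theta[off + 3:4]))
  zr0 <- matrix(theta[off + 4 + seq_len(2 * U)], nrow = 2, byrow = TRUE,
                dimnames = list(cats, NULL))
  zr1 <- matrix(theta[off + 4 + 2 * U + seq_len(2 * U)], nrow = 2,
                byrow = TRUE, dimnames = list(cats, NULL))
  list(mu0 = mu0, mu1 = mu1, sigma0 = sigma0, sigma1 = sigma1,
       z0 = z0, z1 = z1, b0_net = b0, b1_net = b1,
       tau0 = tau0, tau1 = tau1, zr0 = zr0, zr1 = zr1,
       d0 = tau0 * zr0, d1 = tau1 * zr1)
}

#' Linear predictor for one observation and category
#'
#' Returns the linear propensity `lambda` of a category: 0 for the CN
#' reference, `intercept + slope * x` otherwise, with intercept and slope
#' resolved at the structure's pooling level (for the nested model the
#' network term and the ROI deviation term are added).
#'
#' @param params natural parameters from [params_from_theta()].
#' @param structure an `np_structure`.
#' @param row list or one-row data.frame with `x`, `roi_index`,
#'   `network_id`.
#' @param category `"CN"`, `"MCI"` or `"AD"`.
#' @return scalar linear predictor.
#' @export
linear_predictor <- function(params, structure, row, category) {
  category <- match.arg(category, DIAGNOSES)
  if (category == "CN") return(0)
  x <- row$x
  switch(structure$level,
    complete_pooling =
      params$b0[[category]] + params$b1[[category]] * x,
    roi = {
      u <- row$roi_index
      if (u < 1 || u > structure$n_roi) stop("roi index out of range")
      params$b0[category, u] + params$b1[category, u] * x
    },
    network = {
      v <- row$network_id
      if (v < 1 || v > structure$n_net) stop("network index out of range")
      params$b0[category, v] + params$b1[category, v] * x
    },
    nested = {
      u <- row$roi_index; v <- row$network_id
      if (u < 1 || u > structure$n_roi) stop("roi index out of range")
      if (v < 1 || v > structure$n_net) stop("network index out of range")
      (params$b0_net[category, v] + params$d0[category, u]) +
        (params$b1_net[category, v] + params$d1[category, u]) * x
    })
}

#' Softmax inverse link
#'
#' Maps J linear propensities to the probability simplex,
#' `p_j = exp(lambda_j) / sum_m exp(lambda_m)`, computed with
#' max-subtraction so large propensities cannot overflow.
#'
#' @param lambdas numeric vector of finite linear propensities.
#' @return probability vector of the same length, summing to 1.
#' @export
softmax <- function(lambdas) {
  if (any(!is.finite(lambdas))) stop("softmax requires finite inputs")
  e <- exp(lambdas - max(lambdas))
  e / sum(e)
}

# lambda matrix (n x 3) for an observation table, vectorized
lambda_matrix <- function(params, structure, rows) {
  x <- rows$x
  n <- length(x)
  lam <- matrix(0, n, 3, dimnames = list(NULL, DIAGNOSES))
  for (category in NONREF) {
    lam[, category] <- switch(structure$level,
      complete_pooling =
        params$b0[[category]] + params$b1[[category]] * x,
      roi = params$b0[category, rows$roi_index] +
        params$b1[category, rows$roi_index] * x,
      network = params$b0[category, rows$network_id] +
        params$b1[category, rows$network_id] * x,
      nested = (params$b0_net[category, rows$network_id] +
                  params$d0[category, rows$roi_index]) +
        (params$b1_net[category, rows$network_id] +
           params$d1[category, rows$roi_index]) * x)
  }
  lam
}

#' Class probabilities for an observation table
#' @inheritParams linear_predictor
#' @param rows an `np_obs` table (or data.frame with `x`, `roi_index`,
#'   `network_id`).
#' @return n x 3 matrix of class probabilities (columns CN, MCI, AD).
#' @export
class_probabilities <- function(params, structure, rows) {
  lam <- lambda_matrix(params, structure, rows)
  m <- pmax(lam[, 1], pmax(lam[, 2], lam[, 3]))
  e <- exp(lam - m)
  e / rowSums(e)
}

#' Pointwise log-likelihood
#'
#' Log-probability of each observed outcome under the multinomial
#' likelihood, `log pi[i, y_i]`, computed via log-sum-exp so entries are
#' large-negative but finite even for extreme coefficients.  The total
#' log-likelihood is the sum.
#'
#' @inheritParams class_probabilities
#' @return numeric vector of per-observation log-probabilities (all <= 0).
#' @export
pointwise_loglik <- function(params, structure, rows) {
  if (nrow(rows) == 0) stop("rows must be nonempty")
  lam <- lambda_matrix(params, structure, rows)
  m <- pmax(lam[, 1], pmax(lam[, 2], lam[, 3]), 0)
  lse <- m + log(rowSums(exp(lam - m)))
  lam[cbind(seq_len(nrow(lam)), as.integer(rows$diagnosis))] - lse
}

half_normal_lpdf <- function(s, scale) {
  ifelse(s < 0, -Inf,
         log(2) - log(scale) - 0.5 * log(2 * pi) - s^2 / (2 * scale^2))
}

normal_lpdf <- function(x, mean, sd) {
  stats::dnorm(x, mean, sd, log = TRUE)
}

#' Joint log-prior density
#'
#' Natural-scale log-prior: model 1 puts `Normal(0, intercept_scale)` on
#' intercepts and `Normal(0, slope_scale)` on slopes; models 2-4 put
#' Gaussian priors on group coefficients given their hyper-mean and
#' hyper-sd, Gaussian priors on hyper-means, and Half-Normal priors on
#' hyper-sds (model 4 also on the nested ROI-deviation sds).  A
#' non-positive sd returns `-Inf` (rejection) rather than an error, so
#' samplers can treat the boundary gracefully.
#'
#' @inheritParams linear_predictor
#' @param priors an `np_priors`.
#' @return joint log-density (up to constants that are consistent across
#'   calls).
#' @export
log_prior <- function(params, structure, priors) {
  if (structure$level == "complete_pooling") {
    return(sum(normal_lpdf(params$b0, 0, priors$intercept_scale)) +
             sum(normal_lpdf(params$b1, 0, priors$slope_scale)))
  }
  if (any(params$sigma0 < 0) || any(params$sigma1 < 0)) return(-Inf)
  if (any(params$sigma0 == 0) || any(params$sigma1 == 0)) {
    # degenerate but valid limit: coefficient prior collapses to a point
    # mass at the hyper-mean; density of the sd itself remains finite
    b0 <- if (structure$level == "nested") params$b0_net else params$b0
    b1 <- if (structure$level == "nested") params$b1_net else params$b1
    if (any(b0 != params$mu0) || any(b1 != params$mu1)) return(-Inf)
  }
  lp <- sum(normal_lpdf(params$mu0, 0, priors$group_mean_intercept_scale)) +
    sum(normal_lpdf(params$mu1, 0, priors$group_mean_slope_scale)) +
    sum(half_normal_lpdf(params$sigma0, priors$group_sd_intercept_scale)) +
    sum(half_normal_lpdf(params$sigma1, priors$group_sd_slope_scale))
  b0 <- if (structure$level == "nested") params$b0_net else params$b0
  b1 <- if (structure$level == "nested") params$b1_net else params$b1
  if (all(params$sigma0 > 0)) {
    lp <- lp + sum(normal_lpdf(b0, params$mu0, params$sigma0))
  }
  if (all(params$sigma1 > 0)) {
    lp <- lp + sum(normal_lpdf(b1, params$mu1, params$sigma1))
  }
  if (structure$level == "nested") {
    if (any(params$tau0 < 0) || any(params$tau1 < 0)) return(-Inf)
    lp <- lp +
      sum(half_normal_lpdf(params$tau0,
                           priors$nested_roi_intercept_scale)) +
      sum(half_normal_lpdf(params$tau1, priors$nested_roi_slope_scale))
    if (all(params$tau0 > 0)) {
      lp <- lp + sum(normal_lpdf(params$d0, 0, params$tau0))
    } else if (any(params$d0 != 0)) return(-Inf)
    if (all(params$tau1 > 0)) {
      lp <- lp + sum(normal_lpdf(params$d1, 0, params$tau1))
    } else if (any(params$d1 != 0)) return(-Inf)
  }
  lp
}

#' Log-posterior on the unconstrained scale (pure-R reference)
#'
#' Mirror of the compiled log-posterior used by the sampler: non-centered
#' hierarchical coefficients (`z ~ Normal(0, 1)`), log-transformed sds
#' with the log Jacobian included.  Kept in R as an independent reference
#' for gradient checks and cross-validation of the compiled code.
#'
#' @param theta unconstrained parameter vector ([param_names()] layout).
#' @param structure an `np_structure`.
#' @param priors an `np_priors`.
#' @param rows an `np_obs` table.
#' @return scalar log-posterior density (up to a constant).
#' @export
log_posterior_unconstrained <- function(theta, structure, priors, rows) {
  p <- params_from_theta(theta, structure)
  ll <- sum(pointwise_loglik(p, structure, rows))
  if (structure$level == "complete_pooling") {
    lp <- sum(normal_lpdf(p$b0, 0, priors$intercept_scale)) +
      sum(normal_lpdf(p$b1, 0, priors$slope_scale))
    return(ll + lp)
  }
  lp <- sum(normal_lpdf(p$mu0, 0, priors$group_mean_intercept_scale)) +
    sum(normal_lpdf(p$mu1, 0, priors$group_mean_slope_scale)) +
    sum(half_normal_lpdf(p$sigma0, priors$group_sd_intercept_scale)) +
    sum(log(p$sigma0)) +
    sum(half_normal_lpdf(p$sigma1, priors$group_sd_slope_scale)) +
    sum(log(p$sigma1)) +
    sum(normal_lpdf(p$z0, 0, 1)) + sum(normal_lpdf(p$z1, 0, 1))
  if (structure$level == "nested") {
    lp <- lp +
      sum(half_normal_lpdf(p$tau0, priors$nested_roi_intercept_scale)) +
      sum(log(p$tau0)) +
      sum(half_normal_lpdf(p$tau1, priors$nested_roi_slope_scale)) +
      sum(log(p$tau1)) +
      sum(normal_lpdf(p$zr0, 0, 1)) + sum(normal_lpdf(p$zr1, 0, 1))
  }
  ll + lp
}
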