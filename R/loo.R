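# PSIS-LOO: Pareto smoothed importance sampling estimate of leave-one-out
# expected log pointwise predictive density, with generalized Pareto tail
# fitting by the profile-posterior-mean method and the standard 0.5 / 0.7
# reliability thresholds on the shape parameter k.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fit a generalized Pareto distribution to sample exceedances
#'
#' Profile-likelihood posterior-mean estimator of the GPD shape `k` and
#' scale `sigma` (location fixed at zero), with the weak shape prior
#' used by standard PSIS implementations (shape shrunk toward 0.5 with
#' prior weight 10 pseudo-observations).
#'
#' @param x positive exceedances.
#' @param wip apply the weak shape prior (default `TRUE`).
#' @return list with `k` (shape) and `sigma` (scale).
#' @export
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) stop("need at least 5 exceedances to fit the tail")
  prior <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(b) mean(log1p(-b * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w_j <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])),
                    numeric(1))
  theta_hat <- sum(theta * w_j)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (wip) k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)
  list(k = k, sigma = sigma)
}

# GPD quantile function, location 0
qgpd0 <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smooth one vector of log importance weights
#'
#' The `M = min(0.2 S, 3 sqrt(S))` largest weights are replaced by
#' expected order statistics of a generalized Pareto distribution fitted
#' to their exceedances over the tail cutoff, then all weights are
#' truncated at the raw maximum.  Smoothing is a monotone transform
#' within the tail: the weight order is preserved.
#'
#' @param lw vector of log importance weights.
#' @return list with `lw` (smoothed, shifted so `max(lw) = 0`) and `k`
#'   (tail shape; `Inf` when the tail is degenerate or too short to fit).
#' @export
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (length(unique(lw[tail_ids])) < 5 || sum(exceed > 0) < 5) {
    return(list(lw = lw, k = Inf))
  }
  fit <- gpd_fit(exceed[exceed > 0])
  p <- (rank(lw[tail_ids], ties.method = "first") - 0.5) / M
  smoothed <- log(qgpd0(p, fit$k, fit$sigma) + exp(cutoff))
  lw[tail_ids] <- pmin(smoothed, 0)  # truncate at the raw maximum (=0)
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Estimates leave-one-out cross-validation from a single posterior fit:
#' for each observation the importance ratios `1 / p(y_i | theta_s)` are
#' Pareto-smoothed and used to reweight the pointwise likelihood,
#' `elpd_i = log( sum_s w_s p(y_i | theta_s) / sum_s w_s )`.  The
#' per-observation Pareto shape `k` diagnoses reliability (`k < 0.5`
#' good, `k > 0.7` unreliable).  The Monte Carlo standard error of
#' `elpd_loo` combines per-observation delta-method variances deflated by
#' the relative efficiency of the likelihood draws.
#'
#' @param fit an `np_fit` with a stored pointwise log-likelihood matrix.
#' @return list of class `np_loo`: `pointwise` (per-observation elpd),
#'   `elpd_loo`, `se_elpd_loo` (`sqrt(n * var(pointwise))`),
#'   `pareto_k`, `mcse_elpd_loo`, `n`.
#' @export
psis_loo <- function(fit) {
  if (is.null(fit$log_lik)) stop("fit has no pointwise log-likelihood")
  ll <- fit$log_lik
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihoods")
  S <- nrow(ll); n <- ncol(ll)
  n_keep <- dim(fit$draws)[1]; n_chain <- dim(fit$draws)[2]
  pointwise <- numeric(n)
  k <- numeric(n)
  mcse2 <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw
    k[i] <- sm$k
    lse <- logsumexp(lw)
    pointwise[i] <- logsumexp(lw + ll[, i]) - lse
    # delta-method MCSE of elpd_i, deflated by the relative efficiency
    # of the (autocorrelated) likelihood draws
    w <- exp(lw - lse)
    a <- exp(ll[, i])
    mu <- sum(w * a)
    r_eff <- .ess_basic(matrix(a, n_keep, n_chain)) / S
    if (!is.finite(r_eff) || r_eff <= 0) r_eff <- 1
    mcse2[i] <- sum(w^2 * (a - mu)^2) / mu^2 / r_eff
  }
  structure(list(pointwise = pointwise,
                 elpd_loo = sum(pointwise),
                 se_elpd_loo = sqrt(n * stats::var(pointwise)),
                 pareto_k = k,
                 mcse_elpd_loo = sqrt(sum(mcse2)),
                 n = n),
            class = "np_loo")
}

#' @export
print.np_loo <- function(x, ...) {
  cat(sprintf("elpd_loo %.3f (se %.3f), n = %d\n",
              x$elpd_loo, x$se_elpd_loo, x$n))
  cat(sprintf("max Pareto k %.3f; mcse(elpd_loo) %.4f\n",
              max(x$pareto_k), x$mcse_elpd_loo))
  invisible(x)
}

#' Exact leave-one-out cross-validation by refitting
#'
#' Brute-force oracle: refits the model n times, each time holding out
#' one observation, and evaluates the posterior-mean predictive density
#' of the held-out point.  Used to validate [psis_loo()] on small
#' problems.
#'
#' @param structure,priors,rows,config as in [sample_posterior()].
#' @return list with `pointwise` elpd, `elpd_loo`, and `mcse` (combined
#'   Monte Carlo error of the n held-out predictive estimates).
#' @export
exact_loo <- function(structure, priors, rows, config) {
  n <- nrow(rows)
  pointwise <- numeric(n)
  mcse2 <- numeric(n)
  for (i in seq_len(n)) {
    train <- rows[-i, , drop = FALSE]
    for (at in c("scale", "modality", "n_roi", "n_net", "roi_network")) {
      attr(train, at) <- attr(rows, at)
    }
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    fit <- sample_posterior(structure, priors, train, cfg_i,
                            store_loglik = FALSE)
    ll_i <- mlr_pointwise_ll_cpp(
      draws_matrix(fit), structure$model_number, structure$n_roi,
      structure$n_net, as.integer(rows$diagnosis[i]),
      as.numeric(rows$x[i]), as.integer(rows$roi_index[i]),
      as.integer(rows$network_id[i]))[, 1]
    S <- length(ll_i)
    a <- exp(ll_i)
    mu <- mean(a)
    pointwise[i] <- log(mu)
    n_keep <- dim(fit$draws)[1]; n_chain <- dim(fit$draws)[2]
    ess <- .ess_basic(matrix(a, n_keep, n_chain))
    if (!is.finite(ess) || ess <= 0) ess <- S
    mcse2[i] <- stats::var(a) / ess / mu^2
  }
  list(pointwise = pointwise, elpd_loo = sum(pointwise),
       mcse = sqrt(sum(mcse2)))
}

#' Model comparison table
#'
#' Ranks models best-first by `elpd_loo` and reports, for each model, the
#' difference to the best model and its standard error computed from the
#' paired pointwise differences, `se_diff = sqrt(n * var(pointwise_m -
#' pointwise_best))`.  Models within the conventional rule of thumb
#' (|elpd_diff| implying `se_diff < 4`) are flagged as having comparable
#' predictive ability.
#'
#' @param loo_results named list of `np_loo` objects computed on the
#'   identical observation set.
#' @return data.frame of class `np_comparison` with columns `model`,
#'   `elpd_diff`, `se_diff`, `elpd_loo`, `se_elpd_loo`, `comparable`.
#' @export
compare_models <- function(loo_results) {
  stopifnot(length(loo_results) >= 1, !is.null(names(loo_results)))
  ns <- vapply(loo_results, function(l) l$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("LOO results computed on different observation sets")
  }
  elpd <- vapply(loo_results, function(l) l$elpd_loo, numeric(1))
  best <- which.max(elpd)
  n <- ns[1]
  rows <- lapply(seq_along(loo_results), function(m) {
    d <- loo_results[[m]]$pointwise - loo_results[[best]]$pointwise
    data.frame(model = names(loo_results)[m],
               elpd_diff = sum(d),
               se_diff = sqrt(n * stats::var(d)),
               elpd_loo = loo_results[[m]]$elpd_loo,
               se_elpd_loo = loo_results[[m]]$se_elpd_loo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$elpd_loo), ]
  out$comparable <- out$se_diff < 4
  rownames(out) <- NULL
  class(out) <- c("np_comparison", "data.frame")
  out
}

#' Write a comparison table to CSV
#' @param comparison an `np_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE)
  invisible(path)
}
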