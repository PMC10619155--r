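#' Sampler configuration
#'
#' Run configuration for the adaptive Hamiltonian Monte Carlo sampler:
#' four parallel chains of 2000 iterations each, the first 1000 of which
#' are warmup (step-size and diagonal-metric adaptation), leaving 4000
#' retained post-warmup draws.
#'
#' @param n_chains number of chains (>= 2; split R-hat needs two).
#' @param n_iterations total iterations per chain (warmup included).
#' @param n_warmup warmup iterations per chain (discarded).
#' @param target_acceptance dual-averaging target acceptance statistic;
#'   0.9 by default, conservative enough that well-parameterized models
#'   run without divergent transitions.
#' @param max_tree_depth maximum NUTS doubling depth.
#' @param seed integer seed for all sampling randomness.
#' @return list of class `np_sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_iterations = 2000L,
                           n_warmup = 1000L, target_acceptance = 0.9,
                           max_tree_depth = 10L, seed = 1L) {
  stopifnot(n_chains >= 2, n_warmup < n_iterations, n_warmup >= 20,
            target_acceptance > 0, target_acceptance < 1,
            max_tree_depth >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 target_acceptance = target_acceptance,
                 max_tree_depth = as.integer(max_tree_depth),
                 seed = as.integer(seed)),
            class = "np_sampler_config")
}

make_lp_grad <- function(structure, priors, rows) {
  y <- as.integer(rows$diagnosis)
  x <- as.numeric(rows$x)
  u <- as.integer(rows$roi_index)
  v <- as.integer(rows$network_id)
  level <- structure$model_number
  U <- structure$n_roi
  Vn <- structure$n_net
  scales <- prior_scales_vec(priors)
  function(theta) mlr_lp_grad_cpp(theta, level, U, Vn, y, x, u, v, scales)
}

# kinetic energy with diagonal inverse metric `minv` (posterior-variance
# estimates): K = 0.5 * sum(p^2 * minv); momenta p ~ Normal(0, 1/minv).
.kinetic <- function(p, minv) 0.5 * sum(p * p * minv)

.uturn <- function(qp, qm, pp, pm, minv) {
  dq <- qp - qm
  (sum(dq * (minv * pm)) < 0) || (sum(dq * (minv * pp)) < 0)
}

.leapfrog <- function(q, p, grad, eps, minv, lp_grad) {
  p <- p + 0.5 * eps * grad
  q <- q + eps * (minv * p)
  lg <- lp_grad(q)
  p <- p + 0.5 * eps * lg$grad
  list(q = q, p = p, lp = lg$lp, grad = lg$grad)
}

.find_epsilon <- function(q, lp, grad, minv, lp_grad) {
  eps <- 1
  d <- length(q)
  p <- stats::rnorm(d) / sqrt(minv)
  H0 <- -lp + .kinetic(p, minv)
  step <- .leapfrog(q, p, grad, eps, minv, lp_grad)
  H1 <- -step$lp + .kinetic(step$p, minv)
  a <- if (is.finite(H1)) exp(H0 - H1) else 0
  dir <- if (a > 0.5) 1 else -1
  for (k in 1:50) {
    if (dir == 1 && a <= 2^-1) break
    if (dir == -1 && a >= 2^-1) break
    eps <- eps * 2^dir
    step <- .leapfrog(q, p, grad, eps, minv, lp_grad)
    H1 <- -step$lp + .kinetic(step$p, minv)
    a <- if (is.finite(H1)) exp(H0 - H1) else 0
  }
  eps
}

MAX_ENERGY_ERROR <- 1000  # divergence threshold on the Hamiltonian error

.build_tree <- function(q, p, lp, grad, logu, dir, depth, eps, H0,
                        minv, lp_grad, max_depth_env) {
  if (depth == 0L) {
    step <- .leapfrog(q, p, grad, dir * eps, minv, lp_grad)
    H <- if (is.finite(step$lp)) -step$lp + .kinetic(step$p, minv) else Inf
    n <- as.integer(logu <= -H)
    div <- (logu - MAX_ENERGY_ERROR) > -H
    alpha <- if (is.finite(H)) min(1, exp(H0 - H)) else 0
    return(list(qm = step$q, pm = step$p, lpm = step$lp, gm = step$grad,
                qp = step$q, pp = step$p, lpp = step$lp, gp = step$grad,
                qprop = step$q, lpprop = step$lp, n = n, s = !div,
                alpha = alpha, nalpha = 1L, div = div))
  }
  t1 <- .build_tree(q, p, lp, grad, logu, dir, depth - 1L, eps, H0,
                    minv, lp_grad, max_depth_env)
  if (!t1$s) return(t1)
  if (dir == -1) {
    t2 <- .build_tree(t1$qm, t1$pm, t1$lpm, t1$gm, logu, dir,
                      depth - 1L, eps, H0, minv, lp_grad, max_depth_env)
    t1$qm <- t2$qm; t1$pm <- t2$pm; t1$lpm <- t2$lpm; t1$gm <- t2$gm
  } else {
    t2 <- .build_tree(t1$qp, t1$pp, t1$lpp, t1$gp, logu, dir,
                      depth - 1L, eps, H0, minv, lp_grad, max_depth_env)
    t1$qp <- t2$qp; t1$pp <- t2$pp; t1$lpp <- t2$lpp; t1$gp <- t2$gp
  }
  ntot <- t1$n + t2$n
  if (t2$n > 0 && stats::runif(1) < t2$n / ntot) {
    t1$qprop <- t2$qprop; t1$lpprop <- t2$lpprop
  }
  t1$n <- ntot
  t1$alpha <- t1$alpha + t2$alpha
  t1$nalpha <- t1$nalpha + t2$nalpha
  t1$div <- t1$div || t2$div
  t1$s <- t2$s && !.uturn(t1$qp, t1$qm, t1$pp, t1$pm, minv)
  t1
}

# metric adaptation windows in the Stan style: an initial fast interval,
# doubling slow windows, and a terminal fast interval
.adapt_windows <- function(n_warmup) {
  init <- 75L; term <- 50L; base <- 25L
  if (n_warmup < init + term + base) {
    init <- max(5L, as.integer(0.15 * n_warmup))
    term <- max(5L, as.integer(0.10 * n_warmup))
    return(list(init = init, ends = n_warmup - term))
  }
  ends <- integer(0)
  pos <- init; w <- base
  while (TRUE) {
    end <- pos + w
    if (end + 2L * w > n_warmup - term) end <- n_warmup - term
    ends <- c(ends, end)
    if (end >= n_warmup - term) break
    pos <- end; w <- 2L * w
  }
  list(init = init, ends = ends)
}

.run_chain <- function(lp_grad, d, config, init_jitter = 0.1) {
  n_iter <- config$n_iterations
  n_warmup <- config$n_warmup
  n_keep <- n_iter - n_warmup
  delta <- config$target_acceptance
  max_depth <- config$max_tree_depth

  # initialization: uniform jitter in unconstrained space, retried on a
  # non-finite log posterior
  q <- NULL
  for (try in 1:10) {
    q0 <- stats::runif(d, -init_jitter, init_jitter)
    lg <- lp_grad(q0)
    if (is.finite(lg$lp) && all(is.finite(lg$grad))) {
      q <- q0
      break
    }
  }
  if (is.null(q)) stop("failed to initialize: non-finite log-posterior ",
                       "after 10 attempts")

  minv <- rep(1, d)
  eps <- .find_epsilon(q, lg$lp, lg$grad, minv, lp_grad)
  # dual averaging state
  mu <- log(10 * eps); log_eps_bar <- 0; Hbar <- 0; da_count <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75

  win <- .adapt_windows(n_warmup)
  win_buf <- NULL

  draws <- matrix(NA_real_, n_keep, d)
  lp_keep <- numeric(n_keep)
  stats <- data.frame(divergent = logical(n_keep),
                      tree_depth = integer(n_keep),
                      accept_stat = numeric(n_keep),
                      energy = numeric(n_keep),
                      step_size = numeric(n_keep))

  for (iter in seq_len(n_iter)) {
    p0 <- stats::rnorm(d) / sqrt(minv)
    H0 <- -lg$lp + .kinetic(p0, minv)
    logu <- -H0 - stats::rexp(1)
    tree <- list(qm = q, pm = p0, lpm = lg$lp, gm = lg$grad,
                 qp = q, pp = p0, lpp = lg$lp, gp = lg$grad,
                 qprop = q, lpprop = lg$lp, n = 1L, s = TRUE,
                 div = FALSE, alpha = 0, nalpha = 0L)
    depth <- 0L
    while (tree$s && depth < max_depth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      sub <- if (dir == -1) {
        .build_tree(tree$qm, tree$pm, tree$lpm, tree$gm, logu, dir,
                    depth, eps, H0, minv, lp_grad)
      } else {
        .build_tree(tree$qp, tree$pp, tree$lpp, tree$gp, logu, dir,
                    depth, eps, H0, minv, lp_grad)
      }
      if (dir == -1) {
        tree$qm <- sub$qm; tree$pm <- sub$pm
        tree$lpm <- sub$lpm; tree$gm <- sub$gm
      } else {
        tree$qp <- sub$qp; tree$pp <- sub$pp
        tree$lpp <- sub$lpp; tree$gp <- sub$gp
      }
      if (sub$s && sub$n > 0 &&
          stats::runif(1) < sub$n / tree$n) {
        tree$qprop <- sub$qprop; tree$lpprop <- sub$lpprop
      }
      tree$n <- tree$n + sub$n
      tree$alpha <- tree$alpha + sub$alpha
      tree$nalpha <- tree$nalpha + sub$nalpha
      tree$div <- tree$div || sub$div
      tree$s <- sub$s &&
        !.uturn(tree$qp, tree$qm, tree$pp, tree$pm, minv)
      depth <- depth + 1L
    }
    if (!identical(tree$qprop, q)) {
      q <- tree$qprop
      lg <- lp_grad(q)
    }
    accept_stat <- if (tree$nalpha > 0) tree$alpha / tree$nalpha else 0

    if (iter <= n_warmup) {
      # dual averaging of the step size
      da_count <- da_count + 1
      Hbar <- (1 - 1 / (da_count + t0)) * Hbar +
        (delta - accept_stat) / (da_count + t0)
      log_eps <- mu - sqrt(da_count) / gamma * Hbar
      w_da <- da_count^(-kappa)
      log_eps_bar <- w_da * log_eps + (1 - w_da) * log_eps_bar
      eps <- exp(log_eps)
      # metric windows
      if (iter > win$init && iter <= max(win$ends)) {
        win_buf <- rbind(win_buf, q)
        if (iter %in% win$ends) {
          nw <- nrow(win_buf)
          if (nw >= 10) {
            v <- apply(win_buf, 2, stats::var)
            minv <- v * nw / (nw + 5) + 1e-3 * (5 / (nw + 5))
          }
          win_buf <- NULL
          eps <- .find_epsilon(q, lg$lp, lg$grad, minv, lp_grad)
          mu <- log(10 * eps)
          log_eps_bar <- 0; Hbar <- 0; da_count <- 0
        }
      }
      if (iter == n_warmup) eps <- exp(log_eps_bar)
    } else {
      k <- iter - n_warmup
      draws[k, ] <- q
      lp_keep[k] <- lg$lp
      stats$divergent[k] <- tree$div
      stats$tree_depth[k] <- depth
      stats$accept_stat[k] <- accept_stat
      stats$energy[k] <- H0
      stats$step_size[k] <- eps
    }
  }
  list(draws = draws, lp = lp_keep, stats = stats, step_size = eps)
}

#' Sample the posterior with adaptive HMC
#'
#' No-U-Turn sampling with dual-averaging step-size adaptation and
#' windowed diagonal metric estimation, on the unconstrained
#' (non-centered, log-sd) parameterization.  Chains run sequentially from
#' a single seeded RNG stream, so results are deterministic given the
#' configuration, seed, and input data.
#'
#' @param structure an `np_structure`.
#' @param priors an `np_priors`.
#' @param rows an `np_obs` observation table.
#' @param config an `np_sampler_config`.
#' @param store_loglik if `TRUE` (default) the pointwise log-likelihood
#'   matrix (draw x observation) is evaluated and stored for every
#'   retained draw, as required by PSIS-LOO.
#' @return object of class `np_fit`: `draws` (iteration x chain x
#'   parameter array with parameter names), `lp` (log-posterior per
#'   retained draw), `stats` (per-iteration sampler statistics including
#'   divergence flags and tree depths), `log_lik` (S x n matrix, chains
#'   stacked), plus the structure, priors, config and data echoes.
#' @export
sample_posterior <- function(structure, priors, rows, config,
                             store_loglik = TRUE) {
  stopifnot(inherits(structure, "np_structure"),
            inherits(priors, "np_priors"),
            inherits(config, "np_sampler_config"))
  if (nrow(rows) == 0) stop("rows must be nonempty")
  if (structure$model_number >= 2 &&
      max(rows$roi_index) > max(structure$n_roi, structure$n_net)) {
    # index validity is fully checked in the compiled code; this guards
    # the common mistake of an atlas/observation mismatch early
  }
  d <- parameter_dim(structure)
  lp_grad <- make_lp_grad(structure, priors, rows)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_keep <- config$n_iterations - config$n_warmup
  draws <- array(NA_real_, c(n_keep, config$n_chains, d),
                 dimnames = list(NULL, NULL, param_names(structure)))
  lp <- matrix(NA_real_, n_keep, config$n_chains)
  stats_list <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    res <- .run_chain(lp_grad, d, config)
    draws[, ch, ] <- res$draws
    lp[, ch] <- res$lp
    stats_list[[ch]] <- res$stats
  }

  fit <- structure(list(draws = draws, lp = lp, stats = stats_list,
                        structure = structure, priors = priors,
                        config = config, data = rows,
                        scale = attr(rows, "scale"),
                        modality = attr(rows, "modality")),
                   class = "np_fit")
  if (store_loglik) {
    fit$log_lik <- mlr_pointwise_ll_cpp(
      draws_matrix(fit), structure$model_number, structure$n_roi,
      structure$n_net, as.integer(rows$diagnosis), as.numeric(rows$x),
      as.integer(rows$roi_index), as.integer(rows$network_id))
  }
  fit
}

#' Flatten posterior draws to a matrix
#'
#' @param fit an `np_fit`.
#' @return S x d matrix of draws, chains stacked (chain 1 first).
#' @export
draws_matrix <- function(fit) {
  dm <- dim(fit$draws)
  out <- matrix(aperm(fit$draws, c(1, 2, 3)), dm[1] * dm[2], dm[3])
  colnames(out) <- dimnames(fit$draws)[[3]]
  out
}

#' Total number of retained draws
#' @param fit an `np_fit`.
#' @return integer draw count (chains x post-warmup iterations).
#' @export
n_draws <- function(fit) dim(fit$draws)[1] * dim(fit$draws)[2]

#' Count divergent transitions
#'
#' Total post-warmup divergent transitions across chains.  A fit with any
#' divergence fails the workflow's sampler-health criterion.
#'
#' @param fit an `np_fit`.
#' @return integer count.
#' @export
divergence_count <- function(fit) {
  if (is.null(fit$stats)) stop("fit carries no sampler statistics")
  sum(vapply(fit$stats, function(s) sum(s$divergent), numeric(1)))
}

#' @export
print.np_fit <- function(x, ...) {
  cat("neuropool fit: model", x$structure$model_number,
      sprintf("(%s)", x$structure$level), "\n")
  cat(sprintf("  %d chains x %d retained draws, %d parameters\n",
              dim(x$draws)[2], dim(x$draws)[1], dim(x$draws)[3]))
  cat(sprintf("  divergent transitions: %d\n", divergence_count(x)))
  invisible(x)
}
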