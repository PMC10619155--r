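# Convergence and accuracy diagnostics: rank-normalized split R-hat,
# bulk/tail effective sample size, and Monte Carlo standard errors,
# following the rank-normalization recommendations of modern MCMC
# practice (each chain split in half; ranks mapped through the normal
# quantile function before variance comparisons).

as_chain_matrix <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  stopifnot(length(dim(draws)) == 2)
  draws
}

.split_chains <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  x <- x[seq_len(2 * half), , drop = FALSE]
  cbind(x[seq_len(half), , drop = FALSE],
        x[half + seq_len(half), , drop = FALSE])
}

.rank_normalize <- function(x) {
  z <- stats::qnorm((rank(as.vector(x)) - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

.rhat_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 2 || m < 2) return(NA_real_)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Each chain is split in half, all draws are rank-normalized (normal
#' quantiles of ranks), and the classic between/within variance ratio is
#' computed on the transformed split chains.  Values near 1 indicate
#' convergence; the workflow gates acceptance at 1.05.  Chains with zero
#' total variance are flagged as undefined (`NA`), not reported as 1.
#'
#' @param draws iterations x chains matrix of draws for one parameter
#'   (a vector is treated as a single chain).
#' @return scalar R-hat, or `NA` if undefined.
#' @export
split_rhat <- function(draws) {
  x <- as_chain_matrix(draws)
  if (nrow(x) < 4) stop("split R-hat needs at least 4 draws per chain")
  if (stats::sd(as.vector(x)) == 0) return(NA_real_)
  sp <- .split_chains(x)
  .rhat_basic(.rank_normalize(sp))
}

#' Folded split R-hat (scale convergence)
#'
#' Split R-hat of the rank-normalized absolute deviations from the
#' median; sensitive to chains that agree in location but not scale.
#'
#' @inheritParams split_rhat
#' @return scalar R-hat, or `NA` if undefined.
#' @export
folded_split_rhat <- function(draws) {
  x <- as_chain_matrix(draws)
  split_rhat(abs(x - stats::median(as.vector(x))))
}

# biased autocovariance (lag 0..N-1, divided by N) via FFT
.autocov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nf <- stats::nextn(2 * n)
  f <- stats::fft(c(x, rep(0, nf - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nf
  ac / n
}

# effective sample size of the mean, Geyer initial monotone sequence on
# paired autocorrelations, combined across chains
.ess_basic <- function(sims) {
  n <- nrow(sims); m <- ncol(sims)
  if (n < 4 || any(!is.finite(sims))) return(NA_real_)
  if (stats::sd(as.vector(sims)) == 0) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) .autocov(sims[, j]),
                 numeric(n))
  acov <- matrix(acov, n, m)
  mean_acov <- rowMeans(acov)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(sims))
  if (var_plus == 0) return(NA_real_)

  rho <- rep(0, n)
  rho[1] <- 1
  rho_even <- 1
  rho_odd <- 1 - (mean_var - mean_acov[2]) / var_plus
  rho[2] <- rho_odd
  t <- 0
  while (t < n - 5 && is.finite(rho_even + rho_odd) &&
         (rho_even + rho_odd > 0)) {
    t <- t + 2
    rho_even <- 1 - (mean_var - mean_acov[t + 1]) / var_plus
    rho_odd <- 1 - (mean_var - mean_acov[t + 2]) / var_plus
    if (is.finite(rho_even + rho_odd) && rho_even + rho_odd >= 0) {
      rho[t + 1] <- rho_even
      rho[t + 2] <- rho_odd
    }
  }
  max_t <- t
  if (is.finite(rho_even) && rho_even > 0) rho[max_t + 1] <- rho_even
  # Geyer initial monotone sequence
  t <- 0
  while (t <= max_t - 4) {
    t <- t + 2
    if (rho[t + 1] + rho[t + 2] > rho[t - 1] + rho[t]) {
      rho[t + 1] <- (rho[t - 1] + rho[t]) / 2
      rho[t + 2] <- rho[t + 1]
    }
  }
  S <- m * n
  tau <- -1 + 2 * sum(rho[seq_len(max(max_t, 1))]) + rho[max_t + 1]
  tau <- max(tau, 1 / log10(S))
  S / tau
}

#' Effective sample size (mean)
#'
#' ESS for estimating the posterior mean, computed on split chains from
#' the combined-chain autocorrelation estimate.
#'
#' @inheritParams split_rhat
#' @return scalar ESS (`NA` when undefined).
#' @export
ess_mean <- function(draws) {
  x <- as_chain_matrix(draws)
  .ess_basic(.split_chains(x))
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalized split chains; measures sampling efficiency
#' in the bulk of the distribution.
#'
#' @inheritParams split_rhat
#' @return scalar ESS (`NA` when undefined).
#' @export
ess_bulk <- function(draws) {
  x <- as_chain_matrix(draws)
  sp <- .split_chains(x)
  if (stats::sd(as.vector(sp)) == 0) return(NA_real_)
  .ess_basic(.rank_normalize(sp))
}

#' Tail effective sample size
#'
#' Minimum of the ESS of the 5% and 95% quantile exceedance indicators;
#' measures sampling efficiency in the tails.
#'
#' @inheritParams split_rhat
#' @return scalar ESS (`NA` when undefined).
#' @export
ess_tail <- function(draws) {
  x <- as_chain_matrix(draws)
  q <- stats::quantile(as.vector(x), c(0.05, 0.95), names = FALSE)
  lo <- .ess_basic(.split_chains((x <= q[1]) * 1))
  hi <- .ess_basic(.split_chains((x >= q[2]) * 1))
  min(lo, hi)
}

#' Monte Carlo standard error of the mean
#'
#' `sd(draws) / sqrt(ESS)`; constant chains have MCSE 0 by convention.
#'
#' @inheritParams split_rhat
#' @return scalar MCSE.
#' @export
mcse_mean <- function(draws) {
  x <- as_chain_matrix(draws)
  s <- stats::sd(as.vector(x))
  if (s == 0) return(0)
  ess <- ess_mean(x)
  if (!is.finite(ess)) return(NA_real_)
  s / sqrt(ess)
}

#' Per-parameter convergence diagnostics for a fit
#'
#' @param fit an `np_fit`.
#' @return list with `parameters` (data.frame: `parameter`, `mean`, `sd`,
#'   `rhat`, `folded_rhat`, `ess_bulk`, `ess_tail`, `mcse`),
#'   `max_rhat`, `min_ess_bulk`, `n_divergent`, and logical `ok`
#'   (no divergences and all R-hat <= 1.05).
#' @export
diagnostics_report <- function(fit) {
  dn <- dimnames(fit$draws)[[3]]
  per <- do.call(rbind, lapply(seq_along(dn), function(k) {
    x <- fit$draws[, , k]
    data.frame(parameter = dn[k],
               mean = mean(x), sd = stats::sd(as.vector(x)),
               rhat = split_rhat(x),
               folded_rhat = folded_split_rhat(x),
               ess_bulk = ess_bulk(x),
               ess_tail = ess_tail(x),
               mcse = mcse_mean(x),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  max_rhat <- max(per$rhat, na.rm = TRUE)
  nd <- divergence_count(fit)
  list(parameters = per,
       max_rhat = max_rhat,
       min_ess_bulk = min(per$ess_bulk, na.rm = TRUE),
       n_divergent = nd,
       ok = nd == 0 && max_rhat <= 1.05)
}
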