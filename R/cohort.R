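#' Synthetic cohort configuration
#'
#' Describes the generative world for [simulate_cohort()]: group sizes
#' matching the study cohort (72 CN, 23 MCI, 18 AD), a modality-specific
#' atlas, inter-scan interval distribution (log-normal located at the
#' observed medians: 418 days for tau-PET, 378 for MRI), and the
#' hierarchical rate model.  Rates are drawn class-conditionally from
#' equal-variance Gaussians,
#' `x ~ Normal(mu_d + a_v(d) + b_u(d), within_cell_sd)`, where the
#' network shifts `a_v` and ROI shifts `b_u` are drawn once per cohort
#' from `Normal(0, network_effect_sd)` / `Normal(0, roi_effect_sd)`.
#' The equal-variance Gaussian construction makes the multinomial-logit
#' model exactly well specified, with true coefficients available in
#' closed form via [implied_coefficients()].
#'
#' Default rate scales are chosen to emulate reported longitudinal
#' dynamics: tau-PET relative SUVR change near +1%/yr (CN), +5%/yr (MCI),
#' +10%/yr (AD) with 10%/yr within-cell spread; cortical thinning rates
#' one order of magnitude smaller.
#'
#' @param atlas an `np_atlas` (real or [make_synthetic_atlas()]).
#' @param n_per_group integer vector `c(CN, MCI, AD)`.
#' @param mu_group class-conditional grand mean rate per diagnosis.
#' @param within_cell_sd residual sd of rates within a (diagnosis, ROI)
#'   cell; must be positive.
#' @param network_effect_sd,roi_effect_sd sds of the network- and
#'   ROI-level mean shifts (0 allowed: no heterogeneity).
#' @param interval_location_days,interval_spread_days median and
#'   inter-quartile width (days) of the log-normal inter-scan interval.
#' @param baseline_location,baseline_sd location and sd of the (positive,
#'   log-normal) baseline measurement distribution.
#' @param seed integer seed governing all draws.
#' @return list of class `np_cohort_config`.
#' @export
cohort_config <- function(atlas,
                          n_per_group = c(CN = 72, MCI = 23, AD = 18),
                          mu_group = NULL,
                          within_cell_sd = NULL,
                          network_effect_sd = NULL,
                          roi_effect_sd = NULL,
                          interval_location_days = NULL,
                          interval_spread_days = NULL,
                          baseline_location = NULL,
                          baseline_sd = NULL,
                          seed = 1L) {
  modality <- attr(atlas, "modality")
  tau <- identical(modality, "tau_suvr")
  defaults <- if (tau) {
    list(mu_group = c(CN = 0.01, MCI = 0.05, AD = 0.10),
         within_cell_sd = 0.10, network_effect_sd = 0.03,
         roi_effect_sd = 0.01, interval_location_days = 418,
         interval_spread_days = 116, baseline_location = 1.2,
         baseline_sd = 0.2)
  } else {
    list(mu_group = c(CN = 0.002, MCI = 0.010, AD = 0.020),
         within_cell_sd = 0.030, network_effect_sd = 0.008,
         roi_effect_sd = 0.003, interval_location_days = 378,
         interval_spread_days = 84, baseline_location = 2.5,
         baseline_sd = 0.15)
  }
  pick <- function(x, key) if (is.null(x)) defaults[[key]] else x
  cfg <- list(
    atlas = atlas,
    modality = modality,
    n_per_group = stats::setNames(as.integer(n_per_group), DIAGNOSES),
    mu_group = stats::setNames(as.numeric(pick(mu_group, "mu_group")),
                               DIAGNOSES),
    within_cell_sd = pick(within_cell_sd, "within_cell_sd"),
    network_effect_sd = pick(network_effect_sd, "network_effect_sd"),
    roi_effect_sd = pick(roi_effect_sd, "roi_effect_sd"),
    interval_location_days = pick(interval_location_days,
                                  "interval_location_days"),
    interval_spread_days = pick(interval_spread_days,
                                "interval_spread_days"),
    baseline_location = pick(baseline_location, "baseline_location"),
    baseline_sd = pick(baseline_sd, "baseline_sd"),
    seed = as.integer(seed)
  )
  if (any(cfg$n_per_group < 1)) stop("group sizes must be >= 1")
  if (cfg$within_cell_sd <= 0) stop("within_cell_sd must be positive")
  if (cfg$network_effect_sd < 0 || cfg$roi_effect_sd < 0) {
    stop("effect sds must be nonnegative")
  }
  if (cfg$baseline_location <= 0 || cfg$baseline_sd <= 0 ||
      cfg$interval_location_days <= 0 || cfg$interval_spread_days <= 0) {
    stop("location/spread parameters must be positive")
  }
  class(cfg) <- "np_cohort_config"
  cfg
}

#' Simulate a synthetic longitudinal cohort
#'
#' Draws a cohort from the hierarchical class-conditional model described
#' in [cohort_config()].  For each subject and ROI a relative annualized
#' rate is drawn, a positive baseline value is drawn, and the follow-up
#' value is back-computed so that [relative_rate()] reproduces the drawn
#' rate exactly.  Deterministic given `config$seed`.
#'
#' @param config an `np_cohort_config`.
#' @return list with `measures` (long-format data.frame matching the
#'   [assemble_observations()] input schema) and `truth` (realized group
#'   means, network and ROI shifts, per-ROI cell means, group
#'   proportions, and the within-cell sd — everything needed by
#'   [implied_coefficient_table()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "np_cohort_config"))
  atlas <- config$atlas
  U <- attr(atlas, "n_roi")
  V <- attr(atlas, "n_net")
  roi_net <- attr(atlas, "roi_network")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  a_net <- matrix(stats::rnorm(V * 3, 0, config$network_effect_sd),
                  nrow = V, dimnames = list(NULL, DIAGNOSES))
  b_roi <- matrix(stats::rnorm(U * 3, 0, config$roi_effect_sd),
                  nrow = U, dimnames = list(NULL, DIAGNOSES))
  cell_mean <- sweep(a_net[roi_net, , drop = FALSE] + b_roi, 2,
                     config$mu_group, "+")

  n <- config$n_per_group
  diagnosis <- rep(DIAGNOSES, times = n)
  n_subj <- sum(n)
  subject_id <- sprintf("S%03d", seq_len(n_subj))

  # one inter-scan interval per subject; log-normal located at the median
  # with sdlog implied by the IQR width
  sdlog <- log((config$interval_location_days +
                  config$interval_spread_days / 2) /
                 config$interval_location_days) / stats::qnorm(0.75)
  interval <- stats::rlnorm(n_subj, log(config$interval_location_days),
                            sdlog)

  idx_subj <- rep(seq_len(n_subj), each = U)
  idx_roi <- rep(seq_len(U), times = n_subj)
  dx <- diagnosis[idx_subj]
  mu <- cell_mean[cbind(idx_roi, match(dx, DIAGNOSES))]
  x <- stats::rnorm(length(mu), mu, config$within_cell_sd)

  bl_sdlog <- config$baseline_sd / config$baseline_location
  baseline <- stats::rlnorm(length(x), log(config$baseline_location),
                            bl_sdlog)
  dt_yr <- interval[idx_subj] / DAYS_PER_YEAR
  sign <- if (config$modality == "tau_suvr") 1 else -1
  growth <- 1 + sign * x * dt_yr
  if (any(growth <= 0)) {
    stop("simulated rate implies non-positive follow-up; ",
         "reduce rate scales or interval spread")
  }
  followup <- baseline * growth

  measures <- data.frame(
    subject_id = subject_id[idx_subj],
    diagnosis = dx,
    roi_label = atlas$roi_label[match(idx_roi, atlas$roi_index)],
    hemisphere = atlas$hemisphere[match(idx_roi, atlas$roi_index)],
    roi_index = idx_roi,
    modality = config$modality,
    baseline = baseline,
    followup = followup,
    interval_days = interval[idx_subj],
    stringsAsFactors = FALSE
  )
  truth <- list(
    rate = x,  # drawn rates, aligned with the measure rows
    mu_group = config$mu_group,
    network_shift = a_net,
    roi_shift = b_roi,
    cell_mean = cell_mean,
    within_cell_sd = config$within_cell_sd,
    group_prob = n / sum(n),
    roi_network = roi_net,
    modality = config$modality,
    seed = config$seed
  )
  list(measures = measures, truth = truth)
}

#' Closed-form multinomial-logit coefficients of a Gaussian mixture
#'
#' For equal-variance Gaussian class-conditionals
#' `x | class j ~ Normal(mu_j, sigma)` with class prior probabilities
#' `p_j`, Bayes' rule yields a multinomial-logit posterior that is linear
#' in `x`, with slope `(mu_j - mu_ref) / sigma^2` and intercept
#' `(mu_ref^2 - mu_j^2) / (2 sigma^2) + log(p_j / p_ref)` relative to the
#' reference class.  These are the exact generative coefficients against
#' which posterior recovery is judged.
#'
#' @param mu_ref,mu_j class-conditional means (reference class and
#'   class `j`).
#' @param sigma common positive class-conditional sd.
#' @param p_ref,p_j class prior probabilities in (0, 1).
#' @return named vector `c(intercept, slope)`.
#' @export
implied_coefficients <- function(mu_ref, mu_j, sigma, p_ref, p_j) {
  if (sigma <= 0) stop("sigma must be positive")
  if (any(c(p_ref, p_j) <= 0) || any(c(p_ref, p_j) >= 1)) {
    stop("probabilities must lie in (0, 1)")
  }
  c(intercept = (mu_ref^2 - mu_j^2) / (2 * sigma^2) + log(p_j / p_ref),
    slope = (mu_j - mu_ref) / sigma^2)
}

#' True per-ROI coefficients of a simulated cohort
#'
#' Applies [implied_coefficients()] to every (ROI, non-reference
#' category) cell of a [simulate_cohort()] ground truth.  `scale` maps
#' the coefficients onto the normalized input axis used by the fitted
#' models (`slope_norm = slope_raw * scale`; intercepts unchanged).
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @param scale normalization scale of the observation table (the
#'   `scale` attribute of the `np_obs`); use 1 for raw units.
#' @return data.frame with columns `roi_index`, `category`, `intercept`,
#'   `slope`.
#' @export
implied_coefficient_table <- function(truth, scale = 1) {
  U <- nrow(truth$cell_mean)
  out <- do.call(rbind, lapply(NONREF, function(cat) {
    co <- t(vapply(seq_len(U), function(u) {
      implied_coefficients(truth$cell_mean[u, "CN"],
                           truth$cell_mean[u, cat],
                           truth$within_cell_sd,
                           truth$group_prob[["CN"]],
                           truth$group_prob[[cat]])
    }, numeric(2)))
    data.frame(roi_index = seq_len(U), category = cat,
               intercept = co[, 1], slope = co[, 2] * scale,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
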