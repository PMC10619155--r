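#' Annualized rate of change
#'
#' Difference between follow-up and baseline values divided by the
#' inter-scan interval expressed in years (days / 365.25).
#'
#' @param baseline,followup measurement values (SUVR is unitless,
#'   cortical thickness in mm).
#' @param interval_days positive inter-scan interval in days.
#' @return rate of change per year.
#' @export
annualized_rate <- function(baseline, followup, interval_days) {
  if (any(!is.finite(interval_days)) || any(interval_days <= 0)) {
    stop("interval_days must be positive: invalid scan pair")
  }
  (followup - baseline) / (interval_days / DAYS_PER_YEAR)
}

#' Relative annualized rate of change of tau-PET SUVR
#'
#' Annualized rate divided by the baseline SUVR, so the rate is expressed
#' as a fraction of baseline uptake per year.
#'
#' @inheritParams annualized_rate
#' @return relative rate per year.
#' @export
relative_rate_suvr <- function(baseline, followup, interval_days) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("baseline must be positive")
  }
  annualized_rate(baseline, followup, interval_days) / baseline
}

#' Relative annualized rate of change of cortical thickness
#'
#' Sign-flipped relative annualized rate, so that cortical thinning
#' (decreasing thickness) yields a positive rate and growth a negative
#' rate.
#'
#' @inheritParams annualized_rate
#' @return relative thinning rate per year.
#' @export
relative_rate_thickness <- function(baseline, followup, interval_days) {
  -relative_rate_suvr(baseline, followup, interval_days)
}

#' Relative rate for a given modality
#' @inheritParams annualized_rate
#' @param modality `"tau_suvr"` or `"cortical_thickness"`.
#' @return relative rate per year (thickness sign-flipped).
#' @export
relative_rate <- function(baseline, followup, interval_days,
                          modality = c("tau_suvr", "cortical_thickness")) {
  modality <- match.arg(modality)
  if (modality == "tau_suvr") {
    relative_rate_suvr(baseline, followup, interval_days)
  } else {
    relative_rate_thickness(baseline, followup, interval_days)
  }
}

#' Normalize rates to [-1, 1]
#'
#' Global max-absolute-value scaling: every value is divided by the
#' largest absolute value in the collection, so the normalized inputs lie
#' in \[-1, 1\] and regression priors can be stated on a common scale.
#' The scale factor is kept so prediction grids can be expressed in raw
#' units.
#'
#' @param rates numeric vector with at least one nonzero finite value.
#' @return list with `x` (normalized values) and `scale` (max absolute
#'   value); `x * scale` recovers the input.
#' @export
normalize_rates <- function(rates) {
  if (length(rates) == 0 || any(!is.finite(rates))) {
    stop("rates must be a nonempty finite numeric vector")
  }
  scale <- max(abs(rates))
  if (scale == 0) {
    stop("all-zero rates: normalization scale undefined")
  }
  list(x = rates / scale, scale = scale)
}

#' Assemble the long-format observation table
#'
#' Joins longitudinal measures to the atlas, computes relative annualized
#' rates for the requested modality, and normalizes them globally to
#' \[-1, 1\].  One row per (subject, ROI) pair; rows with missing baseline,
#' follow-up or interval are dropped with a warning.
#'
#' @param measures data.frame with columns `subject_id`, `diagnosis`
#'   (`"CN"`, `"MCI"` or `"AD"`), `roi_index`, `baseline`, `followup`,
#'   `interval_days` (a `modality` column, if present, must match).
#' @param atlas an `np_atlas` whose modality matches.
#' @param modality `"tau_suvr"` or `"cortical_thickness"`.
#' @return data.frame of class `np_obs` with columns `subject_id`,
#'   `diagnosis` (factor CN < MCI < AD; CN is the reference category),
#'   `roi_index`, `network_id`, `x_raw`, `x`; attributes `scale`,
#'   `modality`, `n_roi`, `n_net`, `roi_network`.
#' @export
assemble_observations <- function(measures, atlas,
                                  modality = attr(atlas, "modality")) {
  modality <- match.arg(modality, MODALITIES)
  if (!identical(attr(atlas, "modality"), modality)) {
    stop("atlas modality does not match requested modality")
  }
  if ("modality" %in% names(measures) &&
      !all(measures$modality == modality)) {
    stop("measures contain rows of a different modality")
  }
  bad_dx <- setdiff(unique(as.character(measures$diagnosis)), DIAGNOSES)
  if (length(bad_dx) > 0) {
    stop("unknown diagnosis label(s): ", paste(bad_dx, collapse = ", "))
  }
  if (!all(measures$roi_index %in% atlas$roi_index)) {
    stop("measures contain roi_index values absent from the atlas")
  }
  complete <- stats::complete.cases(
    measures[, c("baseline", "followup", "interval_days")])
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    warning(sprintf("dropping %d incomplete (subject, ROI) pair(s)",
                    n_drop))
    measures <- measures[complete, , drop = FALSE]
  }
  if (nrow(measures) == 0) stop("no complete measurement rows")
  x_raw <- relative_rate(measures$baseline, measures$followup,
                         measures$interval_days, modality)
  norm <- normalize_rates(x_raw)
  net <- attr(atlas, "roi_network")[measures$roi_index]
  obs <- data.frame(
    subject_id = as.character(measures$subject_id),
    diagnosis = factor(as.character(measures$diagnosis),
                       levels = DIAGNOSES),
    roi_index = as.integer(measures$roi_index),
    network_id = as.integer(net),
    x_raw = x_raw,
    x = norm$x,
    stringsAsFactors = FALSE
  )
  structure(obs,
            class = c("np_obs", "data.frame"),
            scale = norm$scale,
            modality = modality,
            n_roi = attr(atlas, "n_roi"),
            n_net = attr(atlas, "n_net"),
            roi_network = attr(atlas, "roi_network"),
            n_dropped = n_drop)
}

#' Read longitudinal measures from CSV
#'
#' Expected header: `subject_id,diagnosis,roi_label,hemisphere,modality,`
#' `baseline,followup,interval_days`.  ROI labels are resolved to model
#' indices through the atlas.  Files written by [write_measures()] (which
#' already carry `roi_index`) are also accepted.
#'
#' @param path CSV path.
#' @param atlas an `np_atlas` used to resolve `roi_label`/`hemisphere`.
#' @return data.frame of measures with a `roi_index` column.
#' @export
read_measures <- function(path, atlas) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"roi_index" %in% names(m)) {
    key <- paste(atlas$roi_label, atlas$hemisphere)
    idx <- match(paste(m$roi_label, m$hemisphere), key)
    if (anyNA(idx)) stop("unresolvable roi_label/hemisphere in ", path)
    m$roi_index <- atlas$roi_index[idx]
  }
  m
}

#' Write measures or observations to CSV
#' @param x data.frame (measures or `np_obs`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measures <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
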