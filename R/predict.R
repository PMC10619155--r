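# Posterior class-probability curves over a grid of input rates, per
# ROI or per network, with equal-tailed 60% and 89% credible bands.

#' Posterior draws of a target's intercept and slope
#'
#' Resolves the effective (intercept, slope) coefficient pair of a
#' prediction target at each posterior draw: the global coefficients for
#' model 1, ROI coefficients for model 2, network coefficients for
#' models 3 and 4, and network + ROI-deviation sums for ROI targets
#' under model 4 (the only hierarchical structure that supports both
#' levels).
#'
#' @param fit an `np_fit`.
#' @param type `"global"`, `"roi"` or `"network"`.
#' @param id ROI index `u` or network index `v` (ignored for
#'   `"global"`).
#' @return list with S x 2 matrices `b0` and `b1` (columns MCI, AD).
#' @export
coefficient_draws <- function(fit, type = c("global", "roi", "network"),
                              id = NULL) {
  type <- match.arg(type)
  st <- fit$structure
  dm <- draws_matrix(fit)
  pick <- function(name) dm[, name]
  cats <- NONREF
  fail <- function(supported) {
    stop(sprintf(
      "model %d (%s) cannot produce %s-level predictions; %s",
      st$model_number, st$level, type, supported))
  }
  if (type == "global") {
    if (st$level != "complete_pooling") {
      fail("use an ROI or network target for hierarchical structures")
    }
    return(list(b0 = cbind(MCI = pick("b0[MCI]"), AD = pick("b0[AD]")),
                b1 = cbind(MCI = pick("b1[MCI]"), AD = pick("b1[AD]"))))
  }
  grab <- function(prefix, tag, g) {
    sapply(cats, function(cc) {
      dm[, sprintf("mu%s_%s[%s]", prefix, tag, cc)] +
        exp(dm[, sprintf("log_sigma%s_%s[%s]", prefix, tag, cc)]) *
          dm[, sprintf("z%s_%s[%s,%d]", prefix, tag, cc, g)]
    })
  }
  if (type == "roi") {
    u <- as.integer(id)
    if (is.null(id) || u < 1 || u > st$n_roi) stop("roi id out of range")
    if (st$level == "roi") {
      return(list(b0 = grab("0", "roi", u), b1 = grab("1", "roi", u)))
    }
    if (st$level != "nested") {
      fail("only models 2 and 4 carry ROI-level coefficients")
    }
    v <- st$roi_network[u]
    dev <- function(prefix) {
      sapply(cats, function(cc) {
        exp(dm[, sprintf("log_tau%s[%s]", prefix, cc)]) *
          dm[, sprintf("zr%s_roi[%s,%d]", prefix, cc, u)]
      })
    }
    return(list(b0 = grab("0", "net", v) + dev("0"),
                b1 = grab("1", "net", v) + dev("1")))
  }
  # network target
  v <- as.integer(id)
  if (is.null(id) || v < 1 || v > st$n_net) stop("network id out of range")
  if (!st$level %in% c("network", "nested")) {
    fail("only models 3 and 4 carry network-level coefficients")
  }
  list(b0 = grab("0", "net", v), b1 = grab("1", "net", v))
}

default_grid <- function(modality) {
  lim <- switch(modality,
                tau_suvr = c(-0.42, 0.71),
                cortical_thickness = c(-0.26, 0.23),
                c(-1, 1))
  seq(lim[1], lim[2], length.out = 101)
}

#' Posterior prediction curves
#'
#' For every posterior draw and input grid point, computes the softmax
#' class probabilities implied by the target's coefficients, then
#' summarizes pointwise by the posterior mean and equal-tailed credible
#' intervals at the 60% and 89% levels.  The grid is specified in raw
#' rate units (per-year relative change) spanning the observed range of
#' the modality — \[-0.42, 0.71\] for tau-PET, \[-0.26, 0.23\] for
#' cortical thickness — and normalized internally by the scale stored
#' with the fit.
#'
#' @param fit an `np_fit`.
#' @param type,id prediction target (see [coefficient_draws()]).
#' @param grid_raw grid of raw-unit input rates (default 101 points over
#'   the modality's observed range).
#' @param levels credible levels of the two bands (default 0.60, 0.89).
#' @return data.frame of class `np_curve` with columns `target_type`,
#'   `target_id`, `category`, `x_raw`, `x_norm`, `mean`, `lo60`, `hi60`,
#'   `lo89`, `hi89`; attributes `modality` and `levels`.
#' @export
posterior_curves <- function(fit, type = c("global", "roi", "network"),
                             id = NULL, grid_raw = NULL,
                             levels = c(0.6, 0.89)) {
  type <- match.arg(type)
  stopifnot(length(levels) == 2, all(levels > 0 & levels < 1),
            levels[1] < levels[2])
  if (is.null(grid_raw)) grid_raw <- default_grid(fit$modality)
  scale <- if (is.null(fit$scale)) 1 else fit$scale
  grid_norm <- grid_raw / scale
  co <- coefficient_draws(fit, type, id)
  qs <- c((1 - levels[2]) / 2, (1 - levels[1]) / 2,
          1 - (1 - levels[1]) / 2, 1 - (1 - levels[2]) / 2)
  out <- vector("list", length(grid_norm))
  for (g in seq_along(grid_norm)) {
    x <- grid_norm[g]
    l1 <- co$b0[, 1] + co$b1[, 1] * x
    l2 <- co$b0[, 2] + co$b1[, 2] * x
    m <- pmax(0, pmax(l1, l2))
    denom <- exp(-m) + exp(l1 - m) + exp(l2 - m)
    p <- cbind(exp(-m), exp(l1 - m), exp(l2 - m)) / denom
    qm <- apply(p, 2, stats::quantile, probs = qs, names = FALSE)
    out[[g]] <- data.frame(
      target_type = type,
      target_id = if (is.null(id)) NA_integer_ else as.integer(id),
      category = DIAGNOSES,
      x_raw = grid_raw[g], x_norm = x,
      mean = colMeans(p),
      lo60 = qm[2, ], hi60 = qm[3, ],
      lo89 = qm[1, ], hi89 = qm[4, ],
      stringsAsFactors = FALSE)
  }
  curve <- do.call(rbind, out)
  rownames(curve) <- NULL
  structure(curve, class = c("np_curve", "data.frame"),
            modality = fit$modality, levels = levels)
}

#' Grouped curve report
#'
#' Arranges a set of ROI-level prediction curves by functional network,
#' ordering the ROIs within each network by increasing Braak stage
#' (unknown stages last), and attaches the reference lines used in the
#' standard display: a horizontal line at probability 1/3 and a vertical
#' line at input rate 0.
#'
#' @param curves list of `np_curve` objects (ROI targets, one modality).
#' @param atlas the `np_atlas` the fit was built on.
#' @return list of class `np_curve_report`: `groups` (named by network;
#'   each a list of curves ordered by Braak stage), `ordering`
#'   (data.frame of target, network, braak stage), `reference`
#'   (`h = 1/3`, `v = 0`).
#' @export
curve_report <- function(curves, atlas) {
  stopifnot(is.list(curves), length(curves) >= 1)
  mods <- unique(vapply(curves, function(cv) attr(cv, "modality"),
                        character(1)))
  if (length(mods) != 1) stop("curves mix modalities")
  ids <- vapply(curves, function(cv) cv$target_id[1], integer(1))
  pos <- match(ids, atlas$roi_index)
  if (anyNA(pos)) stop("curve target not present in atlas")
  info <- data.frame(target_id = ids,
                     roi_label = atlas$roi_label[pos],
                     network = atlas$network[pos],
                     braak_stage = atlas$braak_stage[pos],
                     stringsAsFactors = FALSE)
  networks <- attr(atlas, "networks")
  groups <- list()
  for (net in networks) {
    in_net <- which(info$network == net)
    if (length(in_net) == 0) {
      groups[[net]] <- list()
      next
    }
    ord <- in_net[order(info$braak_stage[in_net], na.last = TRUE)]
    groups[[net]] <- curves[ord]
  }
  structure(list(groups = groups, ordering = info,
                 reference = list(h = 1 / 3, v = 0)),
            class = "np_curve_report")
}

#' Export a curve as tidy CSV
#' @param curve an `np_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
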