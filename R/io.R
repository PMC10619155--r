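# Self-describing, re-loadable plain-text serialization of fits.

#' Save a fit to a directory
#'
#' Writes the retained draws (one CSV row per draw, chain and iteration
#' columns first), the pointwise log-likelihood matrix, per-iteration
#' sampler statistics, and a JSON metadata file echoing the structure,
#' priors and sampler configuration.
#'
#' @param fit an `np_fit`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_fit <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dm <- draws_matrix(fit)
  n_keep <- dim(fit$draws)[1]
  n_chain <- dim(fit$draws)[2]
  idx <- data.frame(chain = rep(seq_len(n_chain), each = n_keep),
                    iteration = rep(seq_len(n_keep), n_chain))
  utils::write.csv(cbind(idx, dm), file.path(dir, "draws.csv"),
                   row.names = FALSE)
  stats <- do.call(rbind, lapply(seq_along(fit$stats), function(ch) {
    cbind(chain = ch, iteration = seq_len(nrow(fit$stats[[ch]])),
          fit$stats[[ch]])
  }))
  utils::write.csv(stats, file.path(dir, "sampler_stats.csv"),
                   row.names = FALSE)
  if (!is.null(fit$log_lik)) {
    utils::write.csv(fit$log_lik, file.path(dir, "log_lik.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(fit$data), file.path(dir, "data.csv"),
                   row.names = FALSE)
  meta <- list(
    structure = fit$structure[c("level", "model_number", "n_roi",
                                "n_net", "roi_network")],
    priors = unclass(fit$priors),
    config = unclass(fit$config),
    scale = fit$scale,
    modality = fit$modality,
    parameters = param_names(fit$structure))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a fit saved by [save_fit()]
#' @param dir fit directory.
#' @return an `np_fit` (without the original gradient closures; all
#'   posterior summaries, diagnostics, LOO and prediction functions
#'   work on the reloaded object).
#' @export
load_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  st <- model_structure(meta$structure$level,
                        n_roi = meta$structure$n_roi,
                        n_net = meta$structure$n_net,
                        roi_network = meta$structure$roi_network)
  priors <- do.call(prior_config,
                    c(list(preset = "default"), meta$priors))
  cfg <- sampler_config(meta$config$n_chains, meta$config$n_iterations,
                        meta$config$n_warmup,
                        meta$config$target_acceptance,
                        meta$config$max_tree_depth, meta$config$seed)
  dr <- utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  n_chain <- max(dr$chain)
  n_keep <- max(dr$iteration)
  pn <- meta$parameters
  draws <- array(NA_real_, c(n_keep, n_chain, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  for (ch in seq_len(n_chain)) {
    draws[, ch, ] <- as.matrix(dr[dr$chain == ch, pn, drop = FALSE])
  }
  stats_df <- utils::read.csv(file.path(dir, "sampler_stats.csv"))
  stats <- lapply(seq_len(n_chain), function(ch) {
    s <- stats_df[stats_df$chain == ch,
                  c("divergent", "tree_depth", "accept_stat", "energy",
                    "step_size")]
    rownames(s) <- NULL
    s
  })
  rows <- utils::read.csv(file.path(dir, "data.csv"))
  rows$diagnosis <- factor(rows$diagnosis, levels = DIAGNOSES)
  attr(rows, "scale") <- meta$scale
  attr(rows, "modality") <- meta$modality
  fit <- structure(list(draws = draws, stats = stats, structure = st,
                        priors = priors, config = cfg, data = rows,
                        scale = meta$scale, modality = meta$modality),
                   class = "np_fit")
  ll_path <- file.path(dir, "log_lik.csv")
  if (file.exists(ll_path)) {
    fit$log_lik <- as.matrix(utils::read.csv(ll_path))
    dimnames(fit$log_lik) <- NULL
  }
  fit
}
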