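#' ROI atlas construction
#'
#' The package ships a transcription of the right-hemisphere
#' Desikan-Killiany-Tourville (DKT) cortical + Freesurfer subcortical ROI
#' table used for tau-PET SUVR and cortical-thickness extraction, with each
#' cortical ROI matched to its Yeo-7 resting-state network and (where
#' defined) a Braak stage.  `build_atlas()` mirrors that table to both
#' hemispheres and assigns modality-specific model indices:
#' 76 ROIs (62 cortical + 14 subcortical) across 8 network clusters for
#' tau-PET, 62 cortical ROIs across 7 networks for cortical thickness
#' (subcortical ROIs carry no thickness measure).
#'
#' @param modality `"tau_suvr"` or `"cortical_thickness"`.
#' @param source optional path to an atlas CSV with columns
#'   `base_index,roi_label,abbrev,lobe,network,braak_stage,cortical`
#'   describing one hemisphere; defaults to the packaged table.
#' @return A data.frame of class `np_atlas` with one row per
#'   hemisphere-specific ROI: `roi_label`, `abbrev`, `hemisphere`,
#'   `base_index` (1-38 per hemisphere), `roi_index` (unique model index
#'   `u`), `network`, `network_id` (model index `v`), `braak_stage`,
#'   `cortical`.  Attributes `modality`, `n_roi`, `n_net`, `networks`
#'   (id -> name), and `roi_network` (vector mapping `u` to `v`).
#' @export
build_atlas <- function(modality = c("tau_suvr", "cortical_thickness"),
                        source = NULL) {
  modality <- match.arg(modality)
  if (is.null(source)) {
    source <- system.file("extdata", "dkt_yeo_atlas.csv",
                          package = "neuropool", mustWork = TRUE)
  }
  base <- utils::read.csv(source, stringsAsFactors = FALSE)
  required <- c("base_index", "roi_label", "abbrev", "network",
                "braak_stage", "cortical")
  missing <- setdiff(required, names(base))
  if (length(missing) > 0) {
    stop("atlas source lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(base$roi_label)) {
    stop("duplicate ROI labels in atlas source")
  }
  base$cortical <- as.logical(base$cortical)
  if (modality == "cortical_thickness") {
    base <- base[base$cortical, , drop = FALSE]
  }
  # Yeo-7 numbering as used for the network grouping factor; subcortical
  # ROIs form an additional cluster (tau only).
  networks <- c("Visual", "Somatomotor", "DorsalAttention",
                "Salience/VentralAttention", "Limbic", "Control",
                "DefaultMode")
  if (modality == "tau_suvr") networks <- c(networks, "Subcortical")
  unknown <- setdiff(unique(base$network), networks)
  if (length(unknown) > 0) {
    stop("unknown network label(s): ", paste(unknown, collapse = ", "))
  }
  mirror <- function(hemi) {
    out <- base
    out$hemisphere <- hemi
    out
  }
  atlas <- rbind(mirror("right"), mirror("left"))
  n_hemi <- nrow(base)
  atlas$roi_index <- c(seq_len(n_hemi), n_hemi + seq_len(n_hemi))
  atlas$network_id <- match(atlas$network, networks)
  atlas <- atlas[, c("roi_label", "abbrev", "hemisphere", "base_index",
                     "roi_index", "network", "network_id", "braak_stage",
                     "cortical")]
  structure(atlas,
            class = c("np_atlas", "data.frame"),
            modality = modality,
            n_roi = nrow(atlas),
            n_net = length(networks),
            networks = networks,
            roi_network = atlas$network_id[order(atlas$roi_index)])
}

#' Synthetic atlas for reduced-scale experiments
#'
#' Builds a small ROI to network mapping with the same shape as
#' [build_atlas()] output, for simulation studies that do not need the
#' full bilateral brain atlas (e.g. 12 ROIs in 4 networks).  ROIs are
#' assigned to networks in round-robin order so every network is nonempty.
#'
#' @param n_roi number of ROIs (>= n_net).
#' @param n_net number of network clusters.
#' @param modality modality tag carried through to downstream containers.
#' @return An `np_atlas` data.frame; ROI labels are `"SynthROI<k>"` and
#'   networks `"SynthNet<k>"`.
#' @export
make_synthetic_atlas <- function(n_roi, n_net,
                                 modality = c("tau_suvr",
                                              "cortical_thickness")) {
  modality <- match.arg(modality)
  stopifnot(n_roi >= 1, n_net >= 1, n_roi >= n_net)
  networks <- sprintf("SynthNet%d", seq_len(n_net))
  atlas <- data.frame(
    roi_label = sprintf("SynthROI%02d", seq_len(n_roi)),
    abbrev = sprintf("S%02d", seq_len(n_roi)),
    hemisphere = "right",
    base_index = seq_len(n_roi),
    roi_index = seq_len(n_roi),
    network = networks[((seq_len(n_roi) - 1L) %% n_net) + 1L],
    braak_stage = NA_integer_,
    cortical = TRUE,
    stringsAsFactors = FALSE
  )
  atlas$network_id <- match(atlas$network, networks)
  atlas <- atlas[, c("roi_label", "abbrev", "hemisphere", "base_index",
                     "roi_index", "network", "network_id", "braak_stage",
                     "cortical")]
  structure(atlas,
            class = c("np_atlas", "data.frame"),
            modality = modality,
            n_roi = n_roi,
            n_net = n_net,
            networks = networks,
            roi_network = atlas$network_id[order(atlas$roi_index)])
}

#' Look up one ROI in an atlas
#'
#' @param atlas an `np_atlas`.
#' @param roi_label ROI label, e.g. `"Entorhinal"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return single-row data.frame for the ROI.
#' @export
atlas_lookup <- function(atlas, roi_label, hemisphere = "right") {
  hit <- atlas[atlas$roi_label == roi_label &
                 atlas$hemisphere == hemisphere, , drop = FALSE]
  if (nrow(hit) != 1) {
    stop("ROI '", roi_label, "' (", hemisphere, ") not found in atlas")
  }
  hit
}
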