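# iDrArK overlap maps: direction-specific binarised t-maps per metric,
# voxelwise intersection, small-cluster removal, and optional restriction to
# the lobe detected by the lobar asymmetry analysis.

#' Direction-specific significant masks for MD, FA and MK
#'
#' One-tailed voxel-wise t-tests of the patient against the control group
#' (sex and age as nuisance covariates) inside the analysis mask, thresholded
#' at the uncorrected `cfg$voxelwise_p`: MD tests for increase, FA and MK for
#' decrease.
#'
#' @param patient a [parametric_map_set()] with `group = "patient"`
#' @param controls list of control [parametric_map_set()]
#' @param analysis_mask logical array restricting the test
#' @param cfg an [idrark_config()]
#' @param covariates use sex and age as nuisance covariates
#' @return named list of logical volumes `MD`, `FA`, `MK`
#' @export
binarize_direction_maps <- function(patient, controls, analysis_mask,
                                    cfg = idrark_config(), covariates = TRUE) {
  subjects <- c(controls, list(patient))
  group <- c(rep(0, length(controls)), 1)
  sex <- if (covariates) as.numeric(vapply(subjects, `[[`, "", "sex") == "F")
         else NULL
  age <- if (covariates) vapply(subjects, `[[`, 0, "age") else NULL
  idx <- which(analysis_mask)
  d <- dim(analysis_mask)
  out <- list()
  dirs <- c(MD = "greater", FA = "less", MK = "less")
  for (metric in names(dirs)) {
    field <- tolower(metric)
    Y <- vapply(subjects, function(s) s[[field]][idx], numeric(length(idx)))
    des <- glm_design(Y, group, sex = sex, age = age, tail = dirs[[metric]])
    res <- parametric_t_threshold(des, cfg$voxelwise_p)
    m <- array(FALSE, d)
    m[idx[res$sig_mask]] <- TRUE
    out[[metric]] <- m
  }
  out
}

#' Intersect direction masks and remove small clusters
#'
#' Voxelwise AND of the given masks (three for iDrArK, two for the pairwise
#' maps, one for single-metric maps), connected components labelled at
#' `cfg$cluster_connectivity`, and components smaller than
#' `cfg$min_cluster_voxels` removed.
#'
#' @param masks named list of logical volumes on one grid
#' @param cfg an [idrark_config()]
#' @param subject_id optional id carried through
#' @return an `idrark_map`: `mask`, `labels`, `clusters` (data.frame id,
#'   size, centroid i/j/k), `source` (mask names), `restricted_to` (NULL)
#' @export
intersect_and_filter <- function(masks, cfg = idrark_config(),
                                 subject_id = NULL) {
  stopifnot(length(masks) >= 1L)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stop("grid mismatch between masks")
  overlap <- Reduce(`&`, masks)
  structure(c(list(subject_id = subject_id,
                   source = names(masks), restricted_to = NULL),
              relabel_and_filter(overlap, cfg)),
            class = "idrark_map")
}

# Label a binary volume, drop clusters under the size threshold, and build
# the cluster table.
relabel_and_filter <- function(mask, cfg) {
  lab <- label_components(mask, cfg$cluster_connectivity)
  n <- attr(lab, "n_labels")
  if (n > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    drop <- which(sizes < cfg$min_cluster_voxels)
    if (length(drop) > 0L) {
      mask[array(lab %in% drop, dim(mask))] <- FALSE
      lab <- label_components(mask, cfg$cluster_connectivity)
      n <- attr(lab, "n_labels")
      sizes <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer(0)
    }
  } else sizes <- integer(0)
  if (n > 0L) {
    co <- which(lab > 0L, arr.ind = TRUE)
    lb <- lab[lab > 0L]
    clusters <- data.frame(id = seq_len(n), size = as.integer(sizes),
                           i = as.numeric(tapply(co[, 1], lb, mean)),
                           j = as.numeric(tapply(co[, 2], lb, mean)),
                           k = as.numeric(tapply(co[, 3], lb, mean)))
  } else {
    clusters <- data.frame(id = integer(0), size = integer(0),
                           i = numeric(0), j = numeric(0), k = numeric(0))
  }
  list(mask = mask, labels = lab, clusters = clusters)
}

#' Restrict a detection map to the lobe selected by the asymmetry analysis
#'
#' If the lobar result is significant, voxels outside the selected
#' (lobe, hemisphere) atlas region are removed, clusters are relabelled and
#' the minimum-size filter is re-applied; otherwise the map is returned
#' unchanged (whole-brain, one-step use).
#'
#' @param map an [intersect_and_filter()] result
#' @param lobar a [lobar_asymmetry_index()] result for the same subject
#' @param atlas the [lobe_atlas()]
#' @param cfg an [idrark_config()]
#' @return an `idrark_map`, with `restricted_to` set when restriction applied
#' @export
restrict_to_lobe <- function(map, lobar, atlas, cfg = idrark_config()) {
  stopifnot(inherits(map, "idrark_map"), inherits(lobar, "lobar_result"))
  if (!lobar$significant) return(map)
  region <- atlas_region(atlas, lobar$selected$lobe, lobar$selected$hemisphere)
  out <- relabel_and_filter(map$mask & region, cfg)
  structure(c(list(subject_id = map$subject_id, source = map$source,
                   restricted_to = lobar$selected), out),
            class = "idrark_map")
}

#' @export
print.idrark_map <- function(x, ...) {
  cat(sprintf("detection map (%s)%s: %d clusters, %d voxels%s\n",
              paste(x$source %||% "?", collapse = "+"),
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              nrow(x$clusters), sum(x$mask),
              if (is.null(x$restricted_to)) ""
              else sprintf(", restricted to %s (%s)", x$restricted_to$lobe,
                           x$restricted_to$hemisphere)))
  invisible(x)
}
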