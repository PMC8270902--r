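# Lobar Asymmetry Index: aggregate FWE-significant asymmetry voxels per lobe,
# attribute hemispheres by metric direction, select the impaired lobe, and
# score lobar detection across a cohort.

#' Attribute the impaired hemisphere from metric and asymmetry direction
#'
#' In epilepsy MD tends to increase while FA and MK decrease in the impaired
#' tissue. The asymmetry index is right minus left over their sum, so
#' increased MD asymmetry points at the right hemisphere and increased FA/MK
#' asymmetry at the left, and vice versa.
#'
#' @param metric `"MD"`, `"FA"` or `"MK"`
#' @param tail `"greater"` (increased asymmetry) or `"less"`
#' @return `"left"` or `"right"`
#' @export
attribute_hemisphere <- function(metric = c("MD", "FA", "MK"),
                                 tail = c("greater", "less")) {
  metric <- match.arg(metric)
  tail <- match.arg(tail)
  if (metric == "MD") {
    if (tail == "greater") "right" else "left"
  } else {
    if (tail == "greater") "left" else "right"
  }
}

#' Lobar Asymmetry Index from per-tail significant skeleton pairs
#'
#' For each tail, significant pairs are attributed to a hemisphere via
#' [attribute_hemisphere()] and to a lobe via the skeleton's pair lobes.
#' Within each (lobe, hemisphere) cell, connected components of significant
#' skeleton voxels smaller than `cfg$min_cluster_voxels` are discarded.
#' `LAI = surviving significant voxels / skeleton voxels in the lobe`; the
#' (lobe, hemisphere) with the highest LAI is selected (ties broken by higher
#' surviving count, then lobe name, then hemisphere).
#'
#' @param sig_by_tail list with logical vectors `greater` and `less` over
#'   skeleton pairs (from [permutation_fwe()] `sig_mask`)
#' @param skeleton a [build_symmetric_skeleton()] result
#' @param metric the metric the asymmetry was computed from
#' @param cfg an [idrark_config()]
#' @param subject_id optional id carried through
#' @return a `lobar_result`: `metric`, `subject_id`, `lai_table` (data.frame
#'   lobe, hemisphere, n_vx, n_sig, lai), `selected` (list(lobe, hemisphere)
#'   or NULL), `significant`, `sig_pairs` (surviving per-tail logical vectors)
#' @export
lobar_asymmetry_index <- function(sig_by_tail, skeleton,
                                  metric = c("MD", "FA", "MK"),
                                  cfg = idrark_config(), subject_id = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(skeleton, "symmetric_skeleton"),
            all(c("greater", "less") %in% names(sig_by_tail)))
  npair <- nrow(skeleton$pairs)
  lobes <- sort(unique(skeleton$lobe))
  tab <- expand.grid(lobe = lobes, hemisphere = c("left", "right"),
                     stringsAsFactors = FALSE)
  tab <- tab[order(tab$lobe, tab$hemisphere), ]
  tab$n_vx <- vapply(tab$lobe, function(lb) sum(skeleton$lobe == lb), 0L)
  tab$n_sig <- 0L
  surviving <- list(greater = logical(npair), less = logical(npair))

  for (tail in c("greater", "less")) {
    sig <- sig_by_tail[[tail]]
    if (length(sig) != npair) stop("sig mask length does not match skeleton pairs")
    if (!any(sig)) next
    hemi <- attribute_hemisphere(metric, tail)
    for (lb in lobes) {
      in_cell <- sig & skeleton$lobe == lb
      if (!any(in_cell)) next
      keep <- filter_small_pair_clusters(which(in_cell), skeleton, cfg)
      if (length(keep) == 0L) next
      surviving[[tail]][keep] <- TRUE
      i <- which(tab$lobe == lb & tab$hemisphere == hemi)
      tab$n_sig[i] <- tab$n_sig[i] + length(keep)
    }
  }
  tab$lai <- tab$n_sig / tab$n_vx
  significant <- any(tab$n_sig > 0L)
  selected <- NULL
  if (significant) {
    o <- order(-tab$lai, -tab$n_sig, tab$lobe, tab$hemisphere)
    selected <- list(lobe = tab$lobe[o[1]], hemisphere = tab$hemisphere[o[1]])
  }
  structure(list(metric = metric, subject_id = subject_id, lai_table = tab,
                 selected = selected, significant = significant,
                 sig_pairs = surviving),
            class = "lobar_result")
}

# Cluster significant skeleton pairs (by their right-hemisphere voxel
# positions, 26-connectivity restricted to those voxels) and return the pair
# indices that belong to clusters of at least min_cluster_voxels.
filter_small_pair_clusters <- function(pair_idx, skeleton, cfg) {
  d <- skeleton$dim
  m <- array(FALSE, d)
  m[skeleton$pairs[pair_idx, "right"]] <- TRUE
  lab <- label_components(m, cfg$cluster_connectivity)
  sizes <- tabulate(lab[lab > 0])
  lab_at <- lab[skeleton$pairs[pair_idx, "right"]]
  pair_idx[sizes[lab_at] >= cfg$min_cluster_voxels]
}

#' @export
print.lobar_result <- function(x, ...) {
  cat(sprintf("%s-LAI%s: %s\n", x$metric,
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              if (x$significant)
                sprintf("selected %s (%s), max LAI = %.3f",
                        x$selected$lobe, x$selected$hemisphere,
                        max(x$lai_table$lai))
              else "no significant lobar asymmetry"))
  invisible(x)
}

#' Score lobar detection across a cohort
#'
#' `accuracy = SLD / ALD`: subjects whose selected (lobe, hemisphere) matches
#' the truth, over subjects with any significant lobar result. Undefined
#' (NA) when no subject is significant.
#'
#' @param results list of [lobar_asymmetry_index()] results (one per patient)
#' @param truth named list (subject id -> list(lobe, hemisphere)) of the
#'   resection lobe
#' @return a `lobar_evaluation`: `metric`, `sld`, `ald`, `accuracy`
#' @export
evaluate_lobar_cohort <- function(results, truth) {
  sld <- 0L; ald <- 0L
  metric <- NULL
  for (r in results) {
    stopifnot(inherits(r, "lobar_result"))
    metric <- r$metric
    if (!r$significant) next
    ald <- ald + 1L
    tr <- truth[[r$subject_id]]
    if (is.null(tr))
      stop("truth missing for significant subject ", r$subject_id)
    if (identical(r$selected$lobe, tr$lobe) &&
        identical(r$selected$hemisphere, tr$hemisphere))
      sld <- sld + 1L
  }
  structure(list(metric = metric, sld = sld, ald = ald,
                 accuracy = if (ald > 0L) sld / ald else NA_real_),
            class = "lobar_evaluation")
}

#' @export
print.lobar_evaluation <- function(x, ...) {
  cat(sprintf("%s-LAI cohort: SLD = %d, ALD = %d, accuracy = %s\n",
              x$metric %||% "?", x$sld, x$ald,
              if (is.na(x$accuracy)) "undefined"
              else sprintf("%.1f%%", 100 * x$accuracy)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
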