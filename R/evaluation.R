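# Detection-map evaluation against resection zones: eRZ dilation, per-subject
# cluster-level PPV and SD/UD/NS classification, cohort accuracy and
# detection rate, and the one-step vs two-step comparison.

#' Extend a resection zone by a Euclidean ball
#'
#' Morphological dilation by a discrete Euclidean ball of radius
#' `dilation_mm` in world units (per-axis scaling handles anisotropic
#' voxels), accounting for postsurgical brain shift.
#'
#' @param rz logical array, nonempty
#' @param voxel_mm voxel size in mm (scalar or length 3)
#' @param dilation_mm dilation radius in mm (0 returns `rz` unchanged)
#' @return logical array, a superset of `rz`
#' @export
extend_resection_zone <- function(rz, voxel_mm, dilation_mm = 10) {
  if (!any(rz)) stop("resection zone is empty")
  if (dilation_mm < 0) stop("dilation_mm must be >= 0")
  dilate_ball(rz, voxel_mm, dilation_mm)
}

#' Per-subject cluster-level positive predictive value
#'
#' A cluster counts as within the extended resection zone when the majority
#' (> 50%) of its voxels lie inside it. `PPV = NC_eRZ / NC`; subjects are
#' classified SD (PPV >= `cfg$ppv_success_threshold`), UD (below), or NS (no
#' clusters).
#'
#' @param map an [intersect_and_filter()] / [restrict_to_lobe()] result
#' @param erz logical array from [extend_resection_zone()]
#' @param cfg an [idrark_config()]
#' @param method label carried into the result (e.g. `"iDrArK"`, `"MD_FA"`)
#' @return a `detection_result`: `subject_id`, `method`, `nc`, `nc_erz`,
#'   `ppv` (NA when `nc = 0`), `status` (`"SD"`/`"UD"`/`"NS"`)
#' @export
positive_predictive_value <- function(map, erz, cfg = idrark_config(),
                                      method = paste(map$source, collapse = "_")) {
  stopifnot(inherits(map, "idrark_map"))
  if (!identical(dim(map$mask), dim(erz))) stop("grid mismatch with eRZ")
  nc <- nrow(map$clusters)
  if (nc == 0L) {
    res <- list(nc = 0L, nc_erz = 0L, ppv = NA_real_, status = "NS")
  } else {
    inside <- vapply(map$clusters$id, function(id) {
      vox <- map$labels == id
      mean(erz[vox]) > 0.5
    }, TRUE)
    nc_erz <- sum(inside)
    ppv <- nc_erz / nc
    res <- list(nc = nc, nc_erz = as.integer(nc_erz), ppv = ppv,
                status = if (ppv >= cfg$ppv_success_threshold) "SD" else "UD")
  }
  structure(c(list(subject_id = map$subject_id, method = method), res),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("%s%s: %d/%d clusters in eRZ, PPV = %s -> %s\n", x$method,
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              x$nc_erz, x$nc,
              if (is.na(x$ppv)) "NA" else sprintf("%.2f", x$ppv), x$status))
  invisible(x)
}

#' Classification counts to cohort accuracy and detection rate
#'
#' `accuracy = SD / (SD + UD)` (NA when no subject is significant) and
#' `detection rate = (SD + UD) / (SD + UD + NS)`.
#'
#' @param results list of [positive_predictive_value()] results, or a list
#'   with integer fields `sd`, `ud`, `ns` (classification counts)
#' @param method optional label; defaults to the results' common method
#' @return a `cohort_evaluation`: `method`, `sd`, `ud`, `ns`, `accuracy`,
#'   `detection_rate`
#' @export
evaluate_cohort <- function(results, method = NULL) {
  if (!is.null(results$sd)) {
    sd_ <- as.integer(results$sd); ud <- as.integer(results$ud)
    ns <- as.integer(results$ns)
  } else {
    status <- vapply(results, function(r) {
      stopifnot(inherits(r, "detection_result")); r$status
    }, "")
    if (is.null(method)) {
      methods <- unique(vapply(results, `[[`, "", "method"))
      if (length(methods) == 1L) method <- methods
    }
    sd_ <- sum(status == "SD"); ud <- sum(status == "UD")
    ns <- sum(status == "NS")
  }
  structure(list(method = method, sd = sd_, ud = ud, ns = ns,
                 accuracy = if (sd_ + ud > 0L) sd_ / (sd_ + ud) else NA_real_,
                 detection_rate = (sd_ + ud) / (sd_ + ud + ns)),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("%s: SD = %d, UD = %d, NS = %d; accuracy %s, detection rate %s\n",
              x$method %||% "cohort", x$sd, x$ud, x$ns,
              if (is.na(x$accuracy)) "undefined" else pct(x$accuracy),
              pct(x$detection_rate)))
  invisible(x)
}

#' @export
as.data.frame.cohort_evaluation <- function(x, ...) {
  data.frame(method = x$method %||% NA_character_, sd = x$sd, ud = x$ud,
             ns = x$ns, accuracy = x$accuracy,
             detection_rate = x$detection_rate, stringsAsFactors = FALSE)
}

#' Format a proportion as a percentage
#'
#' @param x proportion in `[0, 1]`
#' @param digits decimal places
#' @return character, e.g. `"88.9%"`
#' @export
pct <- function(x, digits = 1) sprintf(paste0("%.", digits, "f%%"), 100 * x)

#' Compare one-step and two-step detection on a subgroup
#'
#' Restricted to the subjects with a significant lobar result, accuracy and
#' detection rate are computed separately for the unrestricted (one-step) and
#' lobe-restricted (two-step) detection results.
#'
#' @param results_unrestricted,results_restricted lists of
#'   [positive_predictive_value()] results keyed implicitly by `subject_id`
#' @param subgroup character vector of subject ids with significant lobar
#'   detection
#' @return data.frame with one row per approach: sd, ud, ns, accuracy,
#'   detection_rate
#' @export
two_step_utility <- function(results_unrestricted, results_restricted,
                             subgroup) {
  pick <- function(results, label) {
    ids <- vapply(results, `[[`, "", "subject_id")
    missing <- setdiff(subgroup, ids)
    if (length(missing) > 0L)
      stop("subgroup subjects missing from the ", label, " results: ",
           paste(missing, collapse = ", "))
    results[ids %in% subgroup]
  }
  one <- evaluate_cohort(pick(results_unrestricted, "one-step"), "one_step")
  two <- evaluate_cohort(pick(results_restricted, "two-step"), "two_step")
  rbind(as.data.frame(one), as.data.frame(two))
}
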