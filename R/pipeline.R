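# End-to-end orchestration: per-patient two-step detection and cohort-level
# evaluation across single-metric, pairwise and full-overlap maps.

method_masks <- list(FA = "FA", MD = "MD", MK = "MK",
                     MD_MK = c("MD", "MK"), MD_FA = c("MD", "FA"),
                     FA_MK = c("FA", "MK"), iDrArK = c("MD", "FA", "MK"))

#' Lobar asymmetry analysis for one patient
#'
#' Builds the symmetric skeleton from the controls' and the patient's FA
#' maps, computes the asymmetry index for every subject, runs the
#' permutation-TFCE-FWE test in both directions, and aggregates the result
#' into a lobar asymmetry index.
#'
#' @param patient a patient [parametric_map_set()]
#' @param controls list of control map sets
#' @param cohort the `idrark_cohort` (for brain mask and atlas)
#' @param metric `"MD"`, `"FA"` or `"MK"`
#' @param cfg an [idrark_config()]
#' @param skeleton optionally reuse a prebuilt skeleton
#' @return a `lobar_result`
#' @export
patient_lai <- function(patient, controls, cohort, metric = "MK",
                        cfg = idrark_config(), skeleton = NULL) {
  subjects <- c(controls, list(patient))
  if (is.null(skeleton)) {
    skeleton <- build_symmetric_skeleton(lapply(subjects, `[[`, "fa"),
                                         cohort$brain_mask, cohort$atlas, cfg)
  }
  ai <- vapply(subjects, function(s) {
    pr <- project_to_skeleton(s, skeleton, metric)
    asymmetry_index(pr$right, pr$left)
  }, numeric(nrow(skeleton$pairs)))
  group <- c(rep(0, length(controls)), 1)
  sex <- as.numeric(vapply(subjects, `[[`, "", "sex") == "F")
  age <- vapply(subjects, `[[`, 0, "age")
  geometry <- list(dim = skeleton$dim, index = skeleton$pairs[, "right"])
  sig <- lapply(c(greater = "greater", less = "less"), function(tl) {
    des <- glm_design(ai, group, sex = sex, age = age, tail = tl)
    permutation_fwe(des, geometry, cfg)$sig_mask
  })
  lobar_asymmetry_index(sig, skeleton, metric, cfg,
                        subject_id = patient$subject_id)
}

#' Two-step detection for one patient
#'
#' Step one: MK lobar asymmetry (or the metrics in `lai_metric`). Step two:
#' direction-specific voxel-wise masks, overlap maps for the requested
#' methods, restriction by the step-one lobe when significant, and PPV
#' scoring against the extended resection zone when available.
#'
#' @param cohort an `idrark_cohort`
#' @param patient_id id of the patient to analyse
#' @param cfg an [idrark_config()]
#' @param methods subset of FA, MD, MK, MD_MK, MD_FA, FA_MK, iDrArK
#' @param lai_metric metric used for the lobar restriction step
#' @param analysis_mask optional mask for the voxel-wise step (defaults to
#'   the cohort brain mask)
#' @param verbose log progress to stderr
#' @return an `idrark_patient_result`: `lobar`, `maps` (unrestricted),
#'   `maps_restricted`, `detection` / `detection_unrestricted` (lists of
#'   `detection_result`, when a resection zone exists), `erz`
#' @export
detect_patient <- function(cohort, patient_id, cfg = idrark_config(),
                           methods = names(method_masks),
                           lai_metric = "MK", analysis_mask = NULL,
                           verbose = FALSE) {
  ids <- vapply(cohort$patients, `[[`, "", "subject_id")
  i <- match(patient_id, ids)
  if (is.na(i)) stop("unknown patient: ", patient_id)
  patient <- cohort$patients[[i]]
  controls <- cohort$controls
  methods <- match.arg(methods, names(method_masks), several.ok = TRUE)
  if (is.null(analysis_mask)) analysis_mask <- cohort$brain_mask

  idrark_log("lobar asymmetry analysis for ", patient_id, verbose = verbose)
  lobar <- patient_lai(patient, controls, cohort, lai_metric, cfg)

  idrark_log("voxel-wise direction maps for ", patient_id, verbose = verbose)
  dir_masks <- binarize_direction_maps(patient, controls, analysis_mask, cfg)
  maps <- lapply(methods, function(m)
    intersect_and_filter(dir_masks[method_masks[[m]]], cfg, patient_id))
  names(maps) <- methods
  maps_restricted <- lapply(maps, restrict_to_lobe, lobar = lobar,
                            atlas = cohort$atlas, cfg = cfg)

  detection <- detection_unrestricted <- NULL
  erz <- NULL
  rz <- cohort$resection_zones[[patient_id]]
  if (!is.null(rz)) {
    erz <- extend_resection_zone(rz, cohort$grid$voxel_mm, cfg$erz_dilation_mm)
    detection <- lapply(methods, function(m)
      positive_predictive_value(maps_restricted[[m]], erz, cfg, method = m))
    detection_unrestricted <- lapply(methods, function(m)
      positive_predictive_value(maps[[m]], erz, cfg, method = m))
    names(detection) <- names(detection_unrestricted) <- methods
  }
  structure(list(subject_id = patient_id, lobar = lobar, maps = maps,
                 maps_restricted = maps_restricted, detection = detection,
                 detection_unrestricted = detection_unrestricted, erz = erz),
            class = "idrark_patient_result")
}

#' Resection lobe from a resection-zone mask
#'
#' The (lobe, hemisphere) holding the largest share of resection-zone voxels,
#' used as ground truth for lobar scoring.
#'
#' @param rz logical array
#' @param atlas a [lobe_atlas()]
#' @return list(lobe, hemisphere)
#' @export
resection_lobe <- function(rz, atlas) {
  lab <- atlas$labels[rz & atlas$labels > 0L]
  if (length(lab) == 0L) stop("resection zone does not intersect the atlas")
  counts <- table(lab)
  best <- as.integer(names(counts)[which.max(counts)])
  i <- match(best, atlas$legend$label)
  list(lobe = atlas$legend$lobe[i], hemisphere = atlas$legend$hemisphere[i])
}

#' Run the full two-step detection over a cohort
#'
#' @param cohort an `idrark_cohort` with resection zones
#' @param cfg an [idrark_config()]
#' @param methods detection maps to evaluate
#' @param lai_metric metric used for the restriction step
#' @param verbose log progress
#' @return an `idrark_run`: `patients` (per-patient results), `evaluation`
#'   (data.frame, one row per method), `lobar_evaluation`, `truth`
#' @export
run_idrark <- function(cohort, cfg = idrark_config(),
                       methods = names(method_masks), lai_metric = "MK",
                       verbose = FALSE) {
  ids <- vapply(cohort$patients, `[[`, "", "subject_id")
  missing_rz <- setdiff(ids, names(cohort$resection_zones))
  if (length(missing_rz) > 0L)
    stop("evaluation requires resection zones; missing for: ",
         paste(missing_rz, collapse = ", "))
  patients <- lapply(ids, function(id)
    detect_patient(cohort, id, cfg, methods, lai_metric, verbose = verbose))
  names(patients) <- ids
  truth <- lapply(cohort$resection_zones, resection_lobe, atlas = cohort$atlas)
  lob_eval <- evaluate_lobar_cohort(lapply(patients, `[[`, "lobar"), truth)
  evaluation <- do.call(rbind, lapply(methods, function(m)
    as.data.frame(evaluate_cohort(lapply(patients, function(p)
      p$detection[[m]]), method = m))))
  structure(list(patients = patients, evaluation = evaluation,
                 lobar_evaluation = lob_eval, truth = truth,
                 methods = methods, cfg = cfg),
            class = "idrark_run")
}

#' @export
print.idrark_run <- function(x, ...) {
  cat(sprintf("idrark run: %d patients, %d methods\n",
              length(x$patients), length(x$methods)))
  print(x$lobar_evaluation)
  print(x$evaluation, row.names = FALSE)
  invisible(x)
}

#' @export
summary.idrark_run <- function(object, ...) {
  cat("Per-patient two-step detection\n")
  for (p in object$patients) {
    sel <- if (p$lobar$significant)
      sprintf("%s (%s)", p$lobar$selected$lobe, p$lobar$selected$hemisphere)
    else "none"
    d <- p$detection[["iDrArK"]]
    cat(sprintf("  %s: lobe %s; iDrArK %s\n", p$subject_id, sel,
                if (is.null(d)) "n/a"
                else sprintf("%s (PPV %s)", d$status,
                             if (is.na(d$ppv)) "NA" else sprintf("%.2f", d$ppv))))
  }
  print(object)
  invisible(object)
}
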