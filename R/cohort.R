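# Cohort data model: per-subject parametric map sets, lobe atlas, masks, and
# the CSV manifest reader/writer.

#' One subject's co-registered parametric maps
#'
#' @param subject_id character scalar
#' @param group `"patient"` or `"control"`
#' @param sex `"M"` or `"F"`
#' @param age years, positive
#' @param md,fa,mk 3-D arrays: mean diffusivity (um^2/ms), fractional
#'   anisotropy (dimensionless, in `[0,1]`), mean kurtosis (dimensionless,
#'   >= 0), all on the same grid
#' @param grid a [voxel_grid()]
#' @param brain_mask optional logical array; value-range invariants are
#'   checked inside it (defaults to the whole volume)
#' @return a `parametric_map_set`
#' @export
parametric_map_set <- function(subject_id, group, sex, age, md, fa, mk, grid,
                               brain_mask = NULL) {
  group <- match.arg(group, c("patient", "control"))
  sex <- match.arg(sex, c("M", "F"))
  if (!is.numeric(age) || length(age) != 1L || age <= 0)
    stop("age must be a positive number for subject ", subject_id)
  for (nm in c("md", "fa", "mk")) {
    v <- get(nm)
    if (!is.array(v) || length(dim(v)) != 3L)
      stop(nm, " must be a 3-D array for subject ", subject_id)
    if (!identical(dim(v), grid$dim))
      stop(nm, " dimensions do not match the grid for subject ", subject_id)
  }
  m <- if (is.null(brain_mask)) TRUE else brain_mask
  if (any(!is.finite(md[m])) || any(!is.finite(fa[m])) || any(!is.finite(mk[m])))
    stop("non-finite map values inside the brain mask for subject ", subject_id)
  if (any(fa[m] < 0) || any(fa[m] > 1))
    stop("FA outside [0, 1] inside the brain mask for subject ", subject_id)
  if (any(md[m] < 0) || any(mk[m] < 0))
    stop("negative MD or MK inside the brain mask for subject ", subject_id)
  structure(list(subject_id = subject_id, group = group, sex = sex, age = age,
                 md = md, fa = fa, mk = mk, grid = grid),
            class = "parametric_map_set")
}

#' Lobe atlas
#'
#' Integer-labelled parcellation of the brain into lobes by hemisphere,
#' left-right symmetric across the midsagittal plane between the two central
#' slices of the first axis.
#'
#' @param labels integer 3-D array, 0 = background
#' @param legend data.frame with columns `label`, `lobe`, `hemisphere`
#'   (`"left"`/`"right"`)
#' @param check_symmetry verify mirror symmetry of the parcellation
#' @return a `lobe_atlas`
#' @export
lobe_atlas <- function(labels, legend, check_symmetry = TRUE) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  req <- c("label", "lobe", "hemisphere")
  if (!all(req %in% names(legend))) stop("legend needs columns label, lobe, hemisphere")
  if (!all(legend$hemisphere %in% c("left", "right")))
    stop("legend hemisphere must be 'left' or 'right'")
  present <- sort(unique(as.integer(labels[labels != 0])))
  if (!all(present %in% legend$label))
    stop("atlas labels missing from legend: ",
         paste(setdiff(present, legend$label), collapse = ", "))
  if (check_symmetry) {
    mir <- mirror_lr(labels)
    key <- function(lab) {
      i <- match(lab, legend$label)
      out <- rep(NA_character_, length(lab))
      nz <- lab != 0
      out[nz] <- legend$lobe[i[nz]]
      out
    }
    if (!identical(key(as.integer(labels)), key(as.integer(mir))))
      stop("atlas is not left-right symmetric in lobe names")
    hemi <- function(lab) {
      i <- match(lab, legend$label)
      out <- rep(NA_character_, length(lab))
      nz <- lab != 0
      out[nz] <- legend$hemisphere[i[nz]]
      out
    }
    h1 <- hemi(as.integer(labels)); h2 <- hemi(as.integer(mir))
    nz <- !is.na(h1)
    if (!all(h1[nz] != h2[nz]))
      stop("mirroring the atlas must swap hemispheres")
  }
  structure(list(labels = labels, legend = legend), class = "lobe_atlas")
}

# (lobe, hemisphere) region mask from an atlas.
atlas_region <- function(atlas, lobe, hemisphere) {
  lab <- atlas$legend$label[atlas$legend$lobe == lobe &
                              atlas$legend$hemisphere == hemisphere]
  array(atlas$labels %in% lab, dim(atlas$labels))
}

#' Assemble a validated cohort
#'
#' @param controls,patients lists of [parametric_map_set()]
#' @param brain_mask logical 3-D array on the shared grid
#' @param atlas a [lobe_atlas()]
#' @param resection_zones named list (patient_id -> logical array); may be
#'   empty for prospective use
#' @param grid the shared [voxel_grid()]
#' @return an `idrark_cohort`
#' @export
make_cohort <- function(controls, patients, brain_mask, atlas,
                        resection_zones = list(), grid) {
  subjects <- c(controls, patients)
  if (length(subjects) == 0L) stop("cohort is empty")
  for (s in subjects) {
    if (!inherits(s, "parametric_map_set")) stop("subjects must be parametric_map_set")
    if (!grids_equal(s$grid, grid))
      stop("grid/affine mismatch for subject ", s$subject_id,
           ": all cohort volumes must share one grid (no silent resampling)")
  }
  for (s in controls) if (s$group != "control") stop("non-control in controls list")
  for (s in patients) if (s$group != "patient") stop("non-patient in patients list")
  if (!identical(dim(brain_mask), grid$dim)) stop("brain mask off the shared grid")
  if (!identical(dim(atlas$labels), grid$dim)) stop("atlas off the shared grid")
  pid <- vapply(patients, function(s) s$subject_id, "")
  if (anyDuplicated(c(pid, vapply(controls, function(s) s$subject_id, ""))))
    stop("duplicate subject ids")
  bad <- setdiff(names(resection_zones), pid)
  if (length(bad) > 0)
    stop("resection zones given for unknown patients: ",
         paste(bad, collapse = ", "))
  for (nm in names(resection_zones))
    if (!identical(dim(resection_zones[[nm]]), grid$dim))
      stop("resection zone off the shared grid for patient ", nm)
  structure(list(controls = controls, patients = patients,
                 brain_mask = array(as.logical(brain_mask), grid$dim),
                 atlas = atlas, resection_zones = resection_zones, grid = grid),
            class = "idrark_cohort")
}

#' @export
print.idrark_cohort <- function(x, ...) {
  cat(sprintf("idrark cohort: %d controls, %d patients, grid %s @ %s mm\n",
              length(x$controls), length(x$patients),
              paste(x$grid$dim, collapse = "x"),
              paste(format(x$grid$voxel_mm), collapse = "x")))
  cat(sprintf("  resection zones: %d; atlas regions: %d\n",
              length(x$resection_zones), nrow(x$atlas$legend)))
  invisible(x)
}

#' Read a cohort from a CSV manifest and a directory of NIfTI volumes
#'
#' The manifest has one row per subject with columns `subject_id`, `group`
#' (`patient`/`control`), `sex` (`M`/`F`), `age`, and per-metric file names
#' `md`, `fa`, `mk` (resolved relative to `volumes_dir`), plus an optional
#' `rz` column naming each patient's resection-zone mask. `brain_mask.nii.gz`,
#' `atlas.nii.gz` and `atlas_legend.csv` are expected in `volumes_dir`.
#' A grid or affine mismatch between volumes is an error; no resampling is
#' performed.
#'
#' @param manifest_path path to the manifest CSV
#' @param volumes_dir directory holding the referenced NIfTI files
#' @return an `idrark_cohort`
#' @export
read_cohort <- function(manifest_path, volumes_dir) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "sex", "age", "md", "fa", "mk")
  if (!all(req %in% names(man)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  bad_group <- setdiff(unique(man$group), c("patient", "control"))
  if (length(bad_group) > 0) stop("unknown group token: ", bad_group[1])
  bad_sex <- setdiff(unique(man$sex), c("M", "F"))
  if (length(bad_sex) > 0) stop("unknown sex token: ", bad_sex[1])

  read_vol <- function(sid, metric, fname) {
    p <- file.path(volumes_dir, fname)
    if (!file.exists(p))
      stop("missing ", metric, " volume for subject ", sid, ": ", p)
    read_map(p)
  }
  mask_v <- read_map(file.path(volumes_dir, "brain_mask.nii.gz"))
  grid <- attr(mask_v, "grid")
  brain_mask <- array(mask_v > 0.5, grid$dim)

  atlas_v <- read_map(file.path(volumes_dir, "atlas.nii.gz"))
  legend <- read.csv(file.path(volumes_dir, "atlas_legend.csv"),
                     stringsAsFactors = FALSE)
  atlas <- lobe_atlas(array(as.integer(round(atlas_v)), grid$dim), legend)

  controls <- list(); patients <- list(); rzs <- list()
  for (r in seq_len(nrow(man))) {
    row <- man[r, ]
    vols <- lapply(c(md = "md", fa = "fa", mk = "mk"), function(metric)
      read_vol(row$subject_id, metric, row[[metric]]))
    for (metric in names(vols)) {
      g <- attr(vols[[metric]], "grid")
      if (!grids_equal(g, grid))
        stop("grid/affine mismatch for subject ", row$subject_id,
             " metric ", metric)
    }
    ms <- parametric_map_set(row$subject_id, row$group, row$sex, row$age,
                             md = strip_grid(vols$md), fa = strip_grid(vols$fa),
                             mk = strip_grid(vols$mk), grid = grid,
                             brain_mask = brain_mask)
    if (row$group == "control") controls[[length(controls) + 1L]] <- ms
    else {
      patients[[length(patients) + 1L]] <- ms
      if (!is.null(man$rz) && !is.na(row$rz) && nzchar(row$rz)) {
        rz <- read_vol(row$subject_id, "rz", row$rz)
        if (!grids_equal(attr(rz, "grid"), grid))
          stop("grid/affine mismatch for subject ", row$subject_id, " metric rz")
        rzs[[row$subject_id]] <- array(rz > 0.5, grid$dim)
      }
    }
  }
  make_cohort(controls, patients, brain_mask, atlas, rzs, grid)
}

strip_grid <- function(x) {
  attr(x, "grid") <- NULL
  array(as.numeric(x), dim(x))
}
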