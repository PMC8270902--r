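# Synthetic cohort generator: ellipsoidal phantom anatomy with a mirror-
# symmetric lobe parcellation, smooth approximately left-right symmetric
# MD/FA/MK fields with inter-subject variability, and patients carrying a
# focal lesion (increased MD, reduced FA, reduced MK) and/or a widespread
# lobar deep-WM MK reduction.

#' Build phantom anatomy: brain mask, lobe atlas and deep-WM mask
#'
#' The brain is an ellipsoid symmetric across the midsagittal plane between
#' the two central slices of the first axis (which must have even extent).
#' Each hemisphere is tiled into `n_lobes_per_hemisphere` contiguous sectors
#' by angle in the (y, z) plane, mirror-symmetric by construction. The deep
#' white-matter mask is an interior erosion of the brain mask.
#'
#' @param shape integer length-3 array dimensions (first axis = left-right,
#'   even)
#' @param voxel_mm isotropic voxel size in mm
#' @param n_lobes_per_hemisphere number of lobes per hemisphere
#' @param wm_erosion number of 6-connected erosions defining deep WM
#' @return a `phantom_anatomy` list: `brain_mask`, `atlas` ([lobe_atlas()]),
#'   `wm_mask`, `grid`, `depth` (erosion depth of the brain mask)
#' @export
make_phantom_anatomy <- function(shape = c(40L, 48L, 40L), voxel_mm = 2,
                                 n_lobes_per_hemisphere = 4L,
                                 wm_erosion = 3L) {
  shape <- as.integer(shape)
  if (shape[1] %% 2L != 0L)
    stop("left-right extent must be even so a midsagittal mirror plane exists")
  grid <- voxel_grid(voxel_mm, shape)
  d <- shape
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  ax <- 0.46 * d[1]; ay <- 0.46 * d[2]; az <- 0.46 * d[3]
  ii <- slice.index(array(0, d), 1)
  jj <- slice.index(array(0, d), 2)
  kk <- slice.index(array(0, d), 3)
  r2 <- ((ii - cx) / ax)^2 + ((jj - cy) / ay)^2 + ((kk - cz) / az)^2
  brain <- r2 <= 1
  # symmetric by construction (cx is the mirror plane), but enforce exactly
  brain <- brain & mirror_lr(brain)

  depth <- erosion_depth(brain)
  wm <- depth > wm_erosion

  # lobes: angular sectors in the (y, z) plane, same in both hemispheres
  nl <- as.integer(n_lobes_per_hemisphere)
  ang <- atan2(kk - cz, jj - cy)            # (-pi, pi]
  sector <- pmin(nl, 1L + floor((ang + pi) / (2 * pi / nl)))
  labels <- array(0L, d)
  right <- ii > cx
  labels[brain & right] <- sector[brain & right]            # right: 1..nl
  labels[brain & !right] <- sector[brain & !right] + nl     # left: nl+1..2nl
  lobe_names <- paste0("lobe", sprintf("%02d", seq_len(nl)))
  legend <- data.frame(label = seq_len(2L * nl),
                       lobe = rep(lobe_names, 2),
                       hemisphere = rep(c("right", "left"), each = nl),
                       stringsAsFactors = FALSE)
  atlas <- lobe_atlas(labels, legend)
  structure(list(brain_mask = brain, atlas = atlas, wm_mask = wm,
                 grid = grid, depth = depth),
            class = "phantom_anatomy")
}

# Deterministic symmetric mean fields for the three metrics.
# FA rises with erosion depth (0.45 in deep WM, < 0.2 near the mask edge);
# MD ~ 0.8 um^2/ms and MK ~ 1.0 throughout the brain.
phantom_mean_fields <- function(anatomy) {
  depth <- anatomy$depth
  fa <- 0.45 * pmin(depth / 4, 1)
  fa <- gauss_smooth3d(fa, 0.8)
  fa[!anatomy$brain_mask] <- 0
  md <- array(0, dim(depth)); md[anatomy$brain_mask] <- 0.8
  mk <- array(0, dim(depth)); mk[anatomy$brain_mask] <- 1.0
  list(md = md, fa = fa, mk = mk)
}

# One subject's multiplicative variability field: 1 + cv * standardised
# smooth Gaussian random field, plus independent voxel noise added later.
subject_field <- function(d, cv, smooth_sigma = 2) {
  z <- gauss_smooth3d(array(rnorm(prod(d)), d), smooth_sigma)
  1 + cv * (z / stats::sd(z))
}

#' Simulate a healthy control subject
#'
#' Mean fields (FA about 0.45 in deep WM tapering below 0.2 at the edge, MD
#' about 0.8 um^2/ms, MK about 1.0) are modulated by a smooth subject-specific
#' random field (coefficient of variation `cv`) plus independent voxel noise;
#' the expectation over seeds is left-right symmetric.
#'
#' @param anatomy a [make_phantom_anatomy()] result
#' @param subject_id character id
#' @param seed integer seed; the same seed reproduces the same maps
#' @param cv coefficient of variation of the smooth subject field
#' @param voxel_noise standard deviation of voxel-level noise, as a fraction
#'   of the local mean
#' @param sex,age demographics; defaults drawn from the seed (ages centred
#'   near the late twenties)
#' @return a [parametric_map_set()] with `group = "control"`
#' @export
simulate_control <- function(anatomy, subject_id, seed, cv = 0.03,
                             voxel_noise = 0.01, sex = NULL, age = NULL) {
  set.seed(seed)
  d <- anatomy$grid$dim
  mu <- phantom_mean_fields(anatomy)
  if (is.null(sex)) sex <- sample(c("M", "F"), 1)
  if (is.null(age)) age <- round(runif(1, 22, 36), 1)
  draw <- function(mean_field) {
    f <- mean_field * subject_field(d, cv)
    f <- f * (1 + voxel_noise * array(rnorm(prod(d)), d))
    f[!anatomy$brain_mask] <- 0
    f
  }
  md <- pmax(draw(mu$md), 0)
  fa <- pmin(pmax(draw(mu$fa), 0), 1)
  mk <- pmax(draw(mu$mk), 0)
  parametric_map_set(subject_id, "control", sex, age, md = md, fa = fa,
                     mk = mk, grid = anatomy$grid,
                     brain_mask = anatomy$brain_mask)
}

#' Specify a planted abnormality
#'
#' @param center voxel index triple (1-based) of the lesion centre
#' @param radius_mm lesion ball radius in mm
#' @param delta_md fractional MD increase inside the lesion, in (0, 1)
#' @param delta_fa fractional FA decrease, in (0, 1)
#' @param delta_mk fractional MK decrease, in (0, 1)
#' @param lobar_mk_decrease optional list(lobe, hemisphere, delta): widespread
#'   fractional MK reduction applied to that lobe's deep-WM voxels
#' @return a `lesion_spec`
#' @export
lesion_spec <- function(center, radius_mm, delta_md = 0.2, delta_fa = 0.2,
                        delta_mk = 0.2, lobar_mk_decrease = NULL) {
  stopifnot(length(center) == 3L, radius_mm > 0)
  for (dl in c(delta_md, delta_fa, delta_mk))
    if (dl < 0 || dl >= 1) stop("lesion deltas must lie in [0, 1)")
  if (!is.null(lobar_mk_decrease)) {
    stopifnot(all(c("lobe", "hemisphere", "delta") %in% names(lobar_mk_decrease)))
    if (lobar_mk_decrease$delta <= 0 || lobar_mk_decrease$delta >= 1)
      stop("lobar MK decrease must lie in (0, 1)")
  }
  structure(list(center = as.integer(center), radius_mm = radius_mm,
                 delta_md = delta_md, delta_fa = delta_fa,
                 delta_mk = delta_mk, lobar_mk_decrease = lobar_mk_decrease),
            class = "lesion_spec")
}

# Lesion weight field: 1 inside 0.7*r, cosine taper to 0 at r.
lesion_weight <- function(anatomy, lesion) {
  d <- anatomy$grid$dim
  vox <- anatomy$grid$voxel_mm
  ii <- slice.index(array(0, d), 1)
  jj <- slice.index(array(0, d), 2)
  kk <- slice.index(array(0, d), 3)
  dist <- sqrt(((ii - lesion$center[1]) * vox[1])^2 +
                 ((jj - lesion$center[2]) * vox[2])^2 +
                 ((kk - lesion$center[3]) * vox[3])^2)
  w <- array(0, d)
  r <- lesion$radius_mm
  core <- dist <= 0.7 * r
  edge <- dist > 0.7 * r & dist <= r
  w[core] <- 1
  w[edge] <- 0.5 * (1 + cos(pi * (dist[edge] - 0.7 * r) / (0.3 * r)))
  w
}

#' Simulate a patient with a planted lesion
#'
#' Starts from the control draw for the same seed; inside the lesion ball MD
#' is multiplied by `1 + delta_md`, FA by `1 - delta_fa` and MK by
#' `1 - delta_mk` with a smooth edge taper. If `lobar_mk_decrease` is set, MK
#' is additionally reduced across that lobe's deep-WM voxels. The returned
#' resection zone is the lesion ball itself.
#'
#' @inheritParams simulate_control
#' @param lesion a [lesion_spec()]
#' @return list with elements `maps` (a [parametric_map_set()] with
#'   `group = "patient"`) and `resection_zone` (logical array)
#' @export
simulate_patient <- function(anatomy, lesion, subject_id, seed, cv = 0.03,
                             voxel_noise = 0.01, sex = NULL, age = NULL) {
  stopifnot(inherits(lesion, "lesion_spec"))
  if (!anatomy$brain_mask[lesion$center[1], lesion$center[2], lesion$center[3]])
    stop("lesion centre lies outside the brain mask")
  base <- simulate_control(anatomy, subject_id, seed, cv, voxel_noise,
                           sex = sex, age = age)
  w <- lesion_weight(anatomy, lesion)
  md <- base$md * (1 + lesion$delta_md * w)
  fa <- base$fa * (1 - lesion$delta_fa * w)
  mk <- base$mk * (1 - lesion$delta_mk * w)
  if (!is.null(lesion$lobar_mk_decrease)) {
    lmd <- lesion$lobar_mk_decrease
    region <- atlas_region(anatomy$atlas, lmd$lobe, lmd$hemisphere) &
      anatomy$wm_mask
    mk[region] <- mk[region] * (1 - lmd$delta)
  }
  d <- anatomy$grid$dim
  vox <- anatomy$grid$voxel_mm
  ii <- slice.index(array(0, d), 1)
  jj <- slice.index(array(0, d), 2)
  kk <- slice.index(array(0, d), 3)
  rz <- sqrt(((ii - lesion$center[1]) * vox[1])^2 +
               ((jj - lesion$center[2]) * vox[2])^2 +
               ((kk - lesion$center[3]) * vox[3])^2) <= lesion$radius_mm
  maps <- parametric_map_set(subject_id, "patient", base$sex, base$age,
                             md = md, fa = pmin(pmax(fa, 0), 1), mk = mk,
                             grid = anatomy$grid,
                             brain_mask = anatomy$brain_mask)
  list(maps = maps, resection_zone = rz)
}

#' Simulate a complete cohort
#'
#' @param anatomy a [make_phantom_anatomy()] result
#' @param n_controls number of healthy controls
#' @param lesions named list (patient id -> [lesion_spec()]); may be empty
#' @param seed root seed; per-subject seeds are derived with [derive_seed()]
#' @param ... passed to [simulate_control()] / [simulate_patient()]
#' @return an `idrark_cohort` with resection zones for every patient
#' @export
simulate_cohort <- function(anatomy, n_controls, lesions = list(), seed = 1L,
                            ...) {
  controls <- lapply(seq_len(n_controls), function(i)
    simulate_control(anatomy, sprintf("ctrl%03d", i), derive_seed(seed, i), ...))
  patients <- list(); rzs <- list()
  pid <- names(lesions)
  for (i in seq_along(lesions)) {
    sim <- simulate_patient(anatomy, lesions[[i]], pid[i],
                            derive_seed(seed, 10000L + i), ...)
    patients[[i]] <- sim$maps
    rzs[[pid[i]]] <- sim$resection_zone
  }
  make_cohort(controls, patients, anatomy$brain_mask, anatomy$atlas, rzs,
              anatomy$grid)
}

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' Produces the layout [read_cohort()] expects: per-subject `*_md/fa/mk`
#' volumes, `brain_mask.nii.gz`, `atlas.nii.gz`, `atlas_legend.csv`,
#' per-patient `*_rz` masks and `manifest.csv`.
#'
#' @param cohort an `idrark_cohort`
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- cohort$grid
  rows <- list()
  for (s in c(cohort$controls, cohort$patients)) {
    files <- sprintf("%s_%s.nii.gz", s$subject_id, c("md", "fa", "mk"))
    write_map(s$md, g, file.path(dir, files[1]))
    write_map(s$fa, g, file.path(dir, files[2]))
    write_map(s$mk, g, file.path(dir, files[3]))
    rz_file <- ""
    if (s$subject_id %in% names(cohort$resection_zones)) {
      rz_file <- sprintf("%s_rz.nii.gz", s$subject_id)
      write_map(cohort$resection_zones[[s$subject_id]], g,
                file.path(dir, rz_file))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = s$subject_id, group = s$group, sex = s$sex, age = s$age,
      md = files[1], fa = files[2], mk = files[3], rz = rz_file,
      stringsAsFactors = FALSE)
  }
  write_map(cohort$brain_mask, g, file.path(dir, "brain_mask.nii.gz"))
  write_map(cohort$atlas$labels, g, file.path(dir, "atlas.nii.gz"))
  write.csv(cohort$atlas$legend, file.path(dir, "atlas_legend.csv"),
            row.names = FALSE)
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
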