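# Shared fixtures: a small phantom anatomy and cohort, cached per test run,
# plus constructors for hand-built skeletons and detection maps.

.fixtures <- new.env(parent = emptyenv())

small_anatomy <- function() {
  if (is.null(.fixtures$anatomy))
    .fixtures$anatomy <- make_phantom_anatomy(c(24L, 28L, 24L), 2, 4L)
  .fixtures$anatomy
}

small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    an <- small_anatomy()
    les <- lesion_spec(center = c(17, 20, 13), radius_mm = 7,
                       delta_md = 0.25, delta_fa = 0.25, delta_mk = 0.25)
    .fixtures$cohort <- simulate_cohort(an, n_controls = 12,
                                        lesions = list(pat001 = les),
                                        seed = 2024)
  }
  .fixtures$cohort
}

# Hand-built symmetric skeleton: `n_per_lobe` pairs per lobe, laid out as
# contiguous blocks in the right hemisphere of a dim-d grid, mirrored left.
toy_skeleton <- function(lobes = c("frontal", "temporal"), n_per_lobe = 100L,
                         d = c(24L, 16L, 16L)) {
  pairs <- NULL; lobe <- character(0)
  mask <- array(FALSE, d)
  zoff <- 0L
  for (lb in lobes) {
    # block of 5 x 5 x (n/25) voxels at x = 14..18
    nz <- n_per_lobe / 25L
    co <- as.matrix(expand.grid(i = 14:18, j = 3:7, k = zoff + (1:nz)))
    zoff <- zoff + nz + 2L
    ri <- (co[, 3] - 1) * d[1] * d[2] + (co[, 2] - 1) * d[1] + co[, 1]
    li <- (co[, 3] - 1) * d[1] * d[2] + (co[, 2] - 1) * d[1] +
      (d[1] + 1L - co[, 1])
    pairs <- rbind(pairs, cbind(right = ri, left = li))
    lobe <- c(lobe, rep(lb, nrow(co)))
    mask[ri] <- TRUE; mask[li] <- TRUE
  }
  o <- order(pairs[, "right"])
  structure(list(mask = mask, pairs = pairs[o, ], lobe = lobe[o], dim = d),
            class = "symmetric_skeleton")
}

# Minimal lobar_result for restriction tests.
toy_lobar_result <- function(lobe, hemisphere, significant = TRUE,
                             metric = "MK", subject_id = NULL) {
  structure(list(metric = metric, subject_id = subject_id,
                 lai_table = NULL, significant = significant,
                 selected = if (significant) list(lobe = lobe,
                                                  hemisphere = hemisphere)),
            class = "lobar_result")
}

# Place an axis-aligned cuboid of TRUE into a logical array.
add_box <- function(mask, i, j, k) {
  mask[i, j, k] <- TRUE
  mask
}

# Brute-force Euclidean dilation used as an independent check.
dilate_ball_for_test <- function(mask, voxel_mm, radius_mm) {
  d <- dim(mask)
  voxel_mm <- rep_len(voxel_mm, 3L)
  out <- array(FALSE, d)
  src <- which(mask, arr.ind = TRUE)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    dist2 <- ((src[, 1] - x) * voxel_mm[1])^2 +
      ((src[, 2] - y) * voxel_mm[2])^2 + ((src[, 3] - z) * voxel_mm[3])^2
    if (any(dist2 <= radius_mm^2 + 1e-9)) out[x, y, z] <- TRUE
  }
  out
}
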