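# Symmetric deep white-matter skeleton, metric projection, and the voxel-wise
# asymmetry index AI = (right - left) / (right + left). The skeleton is a
# simplified stand-in for a TBSS-style thinning: the medial core of the
# thresholded mean-FA mask (erosion-depth local maxima within the deepest
# half), which preserves the method's logic on smooth co-registered maps.

#' Build a symmetric deep white-matter skeleton from cohort FA maps
#'
#' The cohort-mean FA volume is thresholded at
#' `cfg$fa_skeleton_threshold` (the WM/GM border) and reduced to a deep-WM
#' medial core: voxels in the deepest half of the erosion-depth transform
#' that are a local depth maximum along at least one axis. The core is
#' symmetrised by intersection with its
#' mirror image about the midsagittal plane, and voxel pairs are enumerated by
#' mirroring right-hemisphere skeleton voxels, ordered lexicographically by
#' right-voxel linear index. A precomputed skeleton mask can be supplied via
#' `skeleton_mask` to bypass the construction (e.g. for real data).
#'
#' @param fa_maps list of >= 2 FA volumes on the shared grid
#' @param brain_mask logical array
#' @param atlas a [lobe_atlas()]; lobes are assigned to pairs by the atlas
#'   label at the right voxel, falling back to the nearest non-background
#'   label
#' @param cfg an [idrark_config()]
#' @param skeleton_mask optional logical array overriding the built skeleton
#'   (it is still symmetrised)
#' @return a `symmetric_skeleton`: `mask`, `pairs` (n x 2 matrix of linear
#'   indices, right then left), `lobe` (per pair), `dim`
#' @export
build_symmetric_skeleton <- function(fa_maps, brain_mask, atlas,
                                     cfg = idrark_config(),
                                     skeleton_mask = NULL) {
  d <- dim(brain_mask)
  if (is.null(skeleton_mask)) {
    if (length(fa_maps) < 2L) stop("need at least 2 FA maps")
    mean_fa <- Reduce(`+`, fa_maps) / length(fa_maps)
    wm <- mean_fa >= cfg$fa_skeleton_threshold & brain_mask
    depth <- erosion_depth(wm)
    core <- max(2L, ceiling(max(depth) / 2))
    skel <- depth >= core & local_axis_max(depth)
  } else {
    skel <- skeleton_mask & brain_mask
  }
  skel <- skel & mirror_lr(skel)
  if (!any(skel))
    stop("skeleton is empty after symmetrisation; ",
         "lower fa_skeleton_threshold or supply a skeleton mask")
  nx <- d[1]
  coords <- which(skel, arr.ind = TRUE)
  right <- coords[coords[, 1] > nx / 2, , drop = FALSE]
  left <- right
  left[, 1] <- mirror_index(right[, 1], nx)
  lin <- function(c3)
    as.integer((c3[, 3] - 1) * d[1] * d[2] + (c3[, 2] - 1) * d[1] + c3[, 1])
  ri <- lin(right); li <- lin(left)
  o <- order(ri)
  pairs <- cbind(right = ri[o], left = li[o])
  lobe <- pair_lobes(right[o, , drop = FALSE], atlas)
  structure(list(mask = skel, pairs = pairs, lobe = lobe, dim = d),
            class = "symmetric_skeleton")
}

# Local maximum of `depth` along at least one axis (>= both axis neighbours).
local_axis_max <- function(depth) {
  d <- dim(depth)
  pad <- function(axis, by) {
    out <- array(-1L, d)
    n <- d[axis]
    src <- lapply(d, seq_len); dst <- src
    if (by == 1L) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
    else { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- depth[src[[1]], src[[2]], src[[3]]]
    out
  }
  res <- array(FALSE, d)
  for (axis in 1:3)
    res <- res | (depth >= pad(axis, 1L) & depth >= pad(axis, -1L))
  res
}

# Lobe name per right-hemisphere voxel; nearest non-background atlas label
# when a skeleton voxel falls on atlas background.
pair_lobes <- function(right_coords, atlas) {
  d <- dim(atlas$labels)
  lab <- atlas$labels[right_coords]
  if (any(lab == 0L)) {
    for (i in which(lab == 0L)) {
      v <- right_coords[i, ]
      for (r in 1:max(d)) {
        xs <- max(1, v[1] - r):min(d[1], v[1] + r)
        ys <- max(1, v[2] - r):min(d[2], v[2] + r)
        zs <- max(1, v[3] - r):min(d[3], v[3] + r)
        box <- atlas$labels[xs, ys, zs]
        if (any(box != 0L)) { lab[i] <- box[box != 0L][1]; break }
      }
    }
  }
  atlas$legend$lobe[match(lab, atlas$legend$label)]
}

#' @export
print.symmetric_skeleton <- function(x, ...) {
  cat(sprintf("symmetric skeleton: %d voxels, %d mirror pairs, %d lobes\n",
              sum(x$mask), nrow(x$pairs), length(unique(x$lobe))))
  invisible(x)
}

#' Sample a metric at the skeleton's mirrored voxel pairs
#'
#' @param map_set a [parametric_map_set()]
#' @param skeleton a [build_symmetric_skeleton()] result
#' @param metric `"MD"`, `"FA"` or `"MK"`
#' @return list with numeric vectors `right` and `left`, aligned to
#'   `skeleton$pairs`
#' @export
project_to_skeleton <- function(map_set, skeleton, metric = c("MD", "FA", "MK")) {
  metric <- match.arg(metric)
  vol <- switch(metric, MD = map_set$md, FA = map_set$fa, MK = map_set$mk)
  if (!identical(dim(vol), skeleton$dim))
    stop("map grid does not match the skeleton")
  r <- vol[skeleton$pairs[, "right"]]
  l <- vol[skeleton$pairs[, "left"]]
  bad <- which(!is.finite(r) | !is.finite(l))
  if (length(bad) > 0)
    stop("non-finite ", metric, " value on skeleton at pair ", bad[1],
         " (voxel index ", skeleton$pairs[bad[1], "right"], ")")
  list(right = r, left = l)
}

#' Voxel-wise asymmetry index
#'
#' `AI = (right - left) / (right + left)` per mirrored voxel pair. For
#' positive inputs AI lies in (-1, 1), is antisymmetric under hemisphere
#' swap, and is invariant to rescaling both hemispheres by a constant.
#'
#' @param right,left numeric vectors of projected metric values
#' @return numeric vector of AI values
#' @export
asymmetry_index <- function(right, left) {
  stopifnot(length(right) == length(left))
  s <- right + left
  if (any(s == 0))
    stop("degenerate voxel pair with right + left = 0 at pair ",
         which(s == 0)[1], "; check masking")
  (right - left) / s
}
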