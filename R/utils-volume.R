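# 3-D volume helpers shared across modules. The left-right axis is always the
# first array dimension; mirroring flips it. All masks are logical arrays.

#' Define the voxel grid shared by a cohort
#'
#' @param voxel_mm numeric length-3 voxel size in mm
#' @param dim integer length-3 array dimensions
#' @param origin world coordinates of voxel (1,1,1); default centres the volume
#' @return a `voxel_grid` list with `voxel_mm`, `dim` and a 4x4 `affine`
#'   mapping 0-based voxel indices to world mm
#' @export
voxel_grid <- function(voxel_mm, dim, origin = -voxel_mm * (dim - 1) / 2) {
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0L), all(voxel_mm > 0))
  affine <- diag(c(voxel_mm, 1))
  affine[1:3, 4] <- origin
  structure(list(voxel_mm = voxel_mm, dim = dim, affine = affine),
            class = "voxel_grid")
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) && max(abs(a$affine - b$affine)) < tol
}

#' Mirror a volume across the midsagittal plane
#'
#' The mirror plane lies between the two central slices of the first (left to
#' right) axis, which therefore must have even extent.
#'
#' @param x a 3-D array
#' @return the array with the first axis reversed
#' @export
mirror_lr <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  if (d[1] %% 2L != 0L)
    stop("left-right extent must be even so a midsagittal mirror plane exists")
  x[d[1]:1, , , drop = FALSE]
}

# Index of the mirrored voxel along axis 1.
mirror_index <- function(i, nx) nx + 1L - i

#' Separable Gaussian smoothing of a 3-D array
#'
#' @param x 3-D numeric array
#' @param sigma kernel standard deviation in voxels (scalar or length 3)
#' @return smoothed array; kernels are truncated at 3 sigma and renormalised,
#'   so edges are handled by mass-preserving truncation
#' @export
gauss_smooth3d <- function(x, sigma) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  sigma <- rep_len(sigma, 3L)
  axis_kernel <- function(n, s) {
    if (s <= 0) return(diag(n))
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- w[ok]
    }
    K / rowSums(K)
  }
  # smooth along axis 1: K %*% unfold_1(x)
  y <- axis_kernel(d[1], sigma[1]) %*% matrix(x, d[1])
  y <- array(y, d)
  # axis 2
  y <- aperm(y, c(2, 1, 3))
  y <- array(axis_kernel(d[2], sigma[2]) %*% matrix(y, d[2]), d[c(2, 1, 3)])
  y <- aperm(y, c(2, 1, 3))
  # axis 3
  y <- aperm(y, c(3, 2, 1))
  y <- array(axis_kernel(d[3], sigma[3]) %*% matrix(y, d[3]), d[c(3, 2, 1)])
  aperm(y, c(3, 2, 1))
}

# One 6-connected binary erosion.
erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, axis, by) {
    r <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1L) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (axis in 1:3) for (by in c(1L, -1L)) out <- out & shift(mask, axis, by)
  out
}

#' Erosion depth of a binary mask
#'
#' Number of successive 6-connected erosions a voxel survives; a discrete
#' depth-from-boundary transform used to define deep white matter.
#'
#' @param mask logical 3-D array
#' @return integer array; 0 outside the mask, >= 1 inside
#' @export
erosion_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    depth[cur] <- k
    cur <- erode6(cur)
  }
  depth
}

# Integer offsets within a Euclidean ball of radius `radius_mm`, in world
# units, for (possibly anisotropic) voxel sizes. Includes the zero offset.
ball_offsets <- function(radius_mm, voxel_mm) {
  voxel_mm <- rep_len(voxel_mm, 3L)
  r <- pmax(0L, floor(radius_mm / voxel_mm))
  g <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3]))
  keep <- (g[, 1] * voxel_mm[1])^2 + (g[, 2] * voxel_mm[2])^2 +
    (g[, 3] * voxel_mm[3])^2 <= radius_mm^2 + 1e-9
  g[keep, , drop = FALSE]
}

# Dilate a logical mask by a Euclidean ball given in world mm.
dilate_ball <- function(mask, voxel_mm, radius_mm) {
  d <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(mask)
  off <- ball_offsets(radius_mm, voxel_mm)
  out <- array(FALSE, d)
  for (k in seq_len(nrow(off))) {
    p <- coords + matrix(off[k, ], nrow(coords), 3, byrow = TRUE)
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    if (any(ok)) out[p[ok, , drop = FALSE]] <- TRUE
  }
  out
}

#' Label connected components of a 3-D mask
#'
#' @param mask logical 3-D array
#' @param connectivity 6, 18 or 26
#' @return integer array of component labels (0 = background) with attribute
#'   `n_labels`
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- .label_components_cpp(as.logical(mask), as.integer(d),
                               as.integer(connectivity))
  n <- attr(lab, "n_labels")
  lab <- array(lab, d)
  attr(lab, "n_labels") <- n
  lab
}
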