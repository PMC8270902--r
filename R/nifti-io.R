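# NIfTI reading/writing via RNifti, carrying the package's voxel_grid.

#' Read a NIfTI volume
#'
#' @param path `.nii` or `.nii.gz` file
#' @return a numeric 3-D array with attribute `grid` (a [voxel_grid()])
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D volume: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vox <- RNifti::pixdim(img)[1:3]
  grid <- voxel_grid(vox, d, origin = aff[1:3, 4])
  grid$affine <- aff
  out <- array(as.numeric(img), d)
  attr(out, "grid") <- grid
  out
}

#' Write a volume to NIfTI
#'
#' Writes `volume` with the grid's voxel size and affine so that a read-back
#' returns identical data (within the stored datatype) and affine.
#'
#' @param volume numeric or logical 3-D array
#' @param grid a [voxel_grid()]
#' @param path output path (`.nii` or `.nii.gz`); the directory must exist
#' @return invisibly, `path`
#' @export
write_map <- function(volume, grid, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  stopifnot(identical(dim(volume), grid$dim))
  img <- RNifti::asNifti(array(as.numeric(volume), grid$dim))
  RNifti::pixdim(img) <- grid$voxel_mm
  aff <- structure(grid$affine, code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}
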