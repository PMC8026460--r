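## NIfTI input/output for volumes and masks.
##
## Internal coordinates are LPS millimetres while the NIfTI xform
## convention is RAS, so the stored affine negates the first two axes;
## reading inverts the conversion, making write/read a round trip.

lpsAffine <- function(spacing, origin) {
  m <- diag(c(-spacing[1], -spacing[2], spacing[3], 1))
  m[1:3, 4] <- c(-origin[1], -origin[2], origin[3])
  m
}

#' Write a volume or mask as NIfTI
#'
#' @param x a [VoxelVolume-class] or [BinaryMask-class] (masks are stored
#'   as 0/1 integers).
#' @param path output file (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "BinaryMask")) {
    arr <- array(as.integer(x@mask), dim(x@mask))
    spacing <- x@spacing; origin <- x@origin
  } else if (is(x, "VoxelVolume")) {
    arr <- x@intensities; spacing <- x@spacing; origin <- x@origin
  } else stop("'x' must be a VoxelVolume or BinaryMask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::`qform<-`(img, structure(lpsAffine(spacing, origin), code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a VoxelVolume
#'
#' @param path NIfTI file.
#' @param mask if TRUE, return a [BinaryMask-class] (non-zero = TRUE).
#' @return a [VoxelVolume-class] (or [BinaryMask-class]) in LPS mm.
#' @export
readVolume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  spacing <- abs(c(x[1, 1], x[2, 2], x[3, 3]))
  origin <- c(-x[1, 4], -x[2, 4], x[3, 4])
  arr <- array(as.vector(img), dim(img))
  if (mask)
    new("BinaryMask", mask = array(arr != 0, dim(arr)), spacing = spacing,
        origin = origin, provenance = list(source = path))
  else
    new("VoxelVolume", intensities = arr, spacing = spacing,
        origin = origin, frame = "LPS")
}
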