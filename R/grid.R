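#' Voxel grid containers
#'
#' `voxel_volume()` wraps a 3D array of CT attenuation values (Hounsfield
#' units, HU) together with its voxel spacing; `hematoma_mask()` wraps an
#' aligned binary segmentation. Grids are treated as axis-aligned: only the
#' voxel spacing of the NIfTI header is interpreted, never the affine
#' rotation, because every quantity computed downstream (volume, surface
#' area, surface regularity, density statistics) is rotation-invariant.
#' Voxel indices are 0-based in physical terms: the centre of voxel
#' `(i,j,k)` (1-based R index) sits at `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param data 3D numeric array (HU for volumes; any numeric for masks,
#'   binarised at 0.5).
#' @param spacing numeric triple of positive voxel edge lengths in mm.
#' @param origin numeric triple, physical coordinate of the first voxel
#'   centre in mm.
#' @return An object of class `voxel_volume` or `hematoma_mask`: a list
#'   with elements `data`, `spacing`, `origin`.
#' @examples
#' v <- voxel_volume(array(60, c(4, 4, 4)), spacing = c(0.5, 0.5, 1))
#' m <- hematoma_mask(array(1, c(4, 4, 4)), spacing = c(0.5, 0.5, 1))
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- squeeze_to_3d(data)
  check_spacing(spacing)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @rdname voxel_volume
#' @export
hematoma_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- squeeze_to_3d(data)
  check_spacing(spacing)
  bin <- array(as.integer(data > 0.5), dim = dim(data))
  structure(list(data = bin, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "hematoma_mask")
}

squeeze_to_3d <- function(data) {
  if (!is.array(data)) stop("grid data must be an array", call. = FALSE)
  d <- dim(data)
  if (length(d) > 3) {
    if (all(d[-(1:3)] == 1L)) {
      dim(data) <- d[1:3]
    } else {
      stop("grid is not 3D (extra non-singleton dimensions)", call. = FALSE)
    }
  }
  if (length(dim(data)) != 3L)
    stop("grid must have 3 dimensions", call. = FALSE)
  if (any(dim(data) < 1L)) stop("grid dimensions must be >= 1", call. = FALSE)
  # strip any foreign attributes (e.g. NIfTI header pointers) so grids
  # compare and serialise as plain arrays
  attributes(data) <- list(dim = dim(data))
  data
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) ||
      any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be three positive finite values (mm)",
         call. = FALSE)
  invisible(spacing)
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  cat("  HU range: ", paste(format(range(x$data)), collapse = " .. "), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.hematoma_mask <- function(x, ...) {
  cat("<hematoma_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, ", sum(x$data), " foreground voxels\n", sep = "")
  invisible(x)
}

nifti_spacing <- function(img) {
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  as.numeric(pd[seq_len(min(3L, length(pd)))])
}

#' Read and write CT volumes and hematoma masks (NIfTI)
#'
#' Thin NIfTI-1 readers/writers built on \pkg{RNifti}. `read_volume()`
#' returns a [voxel_volume]; `read_mask()` binarises at 0.5 and verifies
#' voxel-for-voxel alignment with a reference volume (identical grid shape,
#' header spacing agreeing within 1e-3 mm). Trailing singleton dimensions
#' are squeezed. Writing encodes the spacing in the header; a write/read
#' round trip reproduces data and spacing exactly.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param reference a [voxel_volume] the mask must align with (optional; if
#'   omitted the mask's own header spacing is used).
#' @param volume,mask objects created by [voxel_volume()] / [hematoma_mask()].
#' @return `read_volume()` a `voxel_volume`; `read_mask()` a
#'   `hematoma_mask`; writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  sp <- nifti_spacing(img)
  dat <- squeeze_to_3d(as.array(img))
  if (length(sp) < 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("invalid NIfTI header: non-positive voxel spacing in ", path,
         call. = FALSE)
  voxel_volume(dat, spacing = sp[1:3])
}

#' @rdname read_volume
#' @export
read_mask <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  sp <- nifti_spacing(img)
  dat <- squeeze_to_3d(as.array(img))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "voxel_volume"))
    if (!identical(dim(dat), dim(reference$data)))
      stop("mask/volume misalignment: mask grid ",
           paste(dim(dat), collapse = "x"), " vs reference ",
           paste(dim(reference$data), collapse = "x"), call. = FALSE)
    if (any(abs(sp[1:3] - reference$spacing) > 1e-3))
      stop("mask/volume misalignment: header spacing differs from the ",
           "reference by more than 1e-3 mm", call. = FALSE)
    sp <- reference$spacing
  } else {
    if (length(sp) < 3L || any(!is.finite(sp)) || any(sp <= 0))
      stop("invalid NIfTI header: non-positive voxel spacing in ", path,
           call. = FALSE)
  }
  hematoma_mask(dat, spacing = sp[1:3])
}

write_grid <- function(data, spacing, path, datatype) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  write_grid(volume$data, volume$spacing, path, datatype = "double")
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "hematoma_mask"))
  write_grid(mask$data, mask$spacing, path, datatype = "uint8")
}
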