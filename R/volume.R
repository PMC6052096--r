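#' 3D scalar volume with world-space geometry
#'
#' A `volume3d` is a 3D numeric array plus a 4x4 voxel-index-to-world affine
#' (mm). Voxel indices are 0-based in the geometry convention: world position
#' of voxel `(i,j,k)` is `affine %*% c(i,j,k,1)`. All downstream geometry
#' (surfaces, spherical neighborhoods, deformation fields) lives in world mm,
#' so mm-valued parameters are resolution independent.
#'
#' @param data numeric 3D array, all finite, every axis of length >= 8.
#' @param affine 4x4 voxel-to-world matrix; must be invertible with strictly
#'   positive voxel spacing on every axis.
#' @return A `volume3d` object.
#' @export
volume3d <- function(data, affine = diag(4)) {
  check_grid(data, affine)
  if (!all(is.finite(data))) stop("volume data must be finite")
  structure(list(data = data, affine = affine), class = "volume3d")
}

#' Integer label volume over the mesiotemporal codebook
#'
#' Codebook: 0 = background, 1 = hippocampus (HP), 2 = amygdala (AM),
#' 3 = entorhinal cortex (EC).
#'
#' @param data integer-valued 3D array with values in `0:3`.
#' @param affine 4x4 voxel-to-world matrix (same geometry as the paired
#'   intensity volume).
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, affine = diag(4)) {
  check_grid(data, affine)
  u <- unique(as.vector(data))
  if (!all(u %in% 0:3))
    stop("label values outside codebook {0,1,2,3}: ",
         paste(setdiff(u, 0:3), collapse = ", "))
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = affine), class = "label_volume")
}

#' Binary mask sharing a volume's geometry
#'
#' @param data logical (or 0/1) 3D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, affine = diag(4)) {
  check_grid(data, affine)
  data <- array(as.logical(data), dim(data))
  structure(list(data = data, affine = affine), class = "binary_mask")
}

check_grid <- function(data, affine) {
  if (length(dim(data)) != 3L) stop("non-3D image: data must be a 3D array")
  if (any(dim(data) < 8L)) stop("each axis must have length >= 8")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("non-invertible affine")
  if (any(voxel_spacing(affine) <= 0)) stop("voxel spacing must be positive")
  invisible(TRUE)
}

voxel_spacing <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", class(x)[1],
              paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_spacing(x$affine), 4), collapse = "x")))
  invisible(x)
}

#' @export
print.label_volume <- print.volume3d

#' @export
print.binary_mask <- print.volume3d

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) <= tol
}

# Pipeline geometry restriction: axis-aligned affine (diagonal positive
# spacing + translation). Feature extraction, registration and voxelization
# assume this; I/O and basic containers do not.
assert_axis_aligned <- function(vol) {
  A <- vol$affine[1:3, 1:3]
  if (max(abs(A - diag(diag(A)))) > 1e-9 || any(diag(A) <= 0))
    stop("this operation requires an axis-aligned affine ",
         "(diagonal positive spacing); resample the input first")
  invisible(TRUE)
}

grid_origin <- function(vol) vol$affine[1:3, 4]
grid_spacing <- function(vol) diag(vol$affine[1:3, 1:3])

world_to_voxel <- function(vol, pts) {
  pts <- rbind(t(pts), 1)
  t(solve(vol$affine) %*% pts)[, 1:3, drop = FALSE]
}

voxel_to_world <- function(vol, idx) {
  idx <- rbind(t(idx), 1)
  t(vol$affine %*% idx)[, 1:3, drop = FALSE]
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param type `"intensity"` for a [volume3d()], `"label"` for a
#'   [label_volume()], `"mask"` for a [binary_mask()], or `"auto"` (integer
#'   data with values in the codebook is read as a label, otherwise as an
#'   intensity volume).
#' @return A `volume3d`, `label_volume` or `binary_mask`.
#' @export
read_volume <- function(path, type = c("auto", "intensity", "label", "mask")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("non-3D image: ", path, " has ", length(d), " dims")
  affine <- unclass(RNifti::xform(img))
  data <- array(as.vector(img), d)
  if (type == "auto")
    type <- if (max(abs(data - round(data))) < 1e-9 &&
                all(round(data) %in% 0:3)) "label" else "intensity"
  switch(type,
         intensity = volume3d(data, affine),
         label = label_volume(round(data), affine),
         mask = binary_mask(data != 0, affine))
}

#' Write a volume as NIfTI-1
#'
#' Integer labels and masks round-trip bit-exactly; float volumes round-trip
#' to single precision (<= 1e-6 relative error).
#'
#' @param vol a `volume3d`, `label_volume` or `binary_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  data <- vol$data
  dt <- "float"
  if (inherits(vol, "label_volume") || inherits(vol, "binary_mask")) {
    data <- array(as.integer(data), dim(data))
    dt <- "int16"
  }
  img <- RNifti::asNifti(data)
  img <- RNifti::`pixdim<-`(img, voxel_spacing(vol$affine))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Morphological dilation with a 6-connected structuring element
#'
#' Each iteration is one 6-connected (face-neighbour) binary dilation, the
#' minimal isotropic element on a cubic grid. Used to build the similarity
#' mask (3 iterations of the template label) and the registration mask
#' (5 iterations of the library label union).
#'
#' @param label a `label_volume` or `binary_mask` (any non-zero voxel is
#'   foreground).
#' @param iterations number of dilation passes, >= 1.
#' @return A `binary_mask` that is a superset of the input foreground.
#' @export
dilate_label <- function(label, iterations) {
  stopifnot(length(iterations) == 1L, iterations >= 1)
  fg <- label$data != 0
  if (!any(fg)) stop("empty foreground")
  d <- dim(fg)
  for (it in seq_len(iterations)) {
    out <- fg
    out[-1, , ] <- out[-1, , ] | fg[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | fg[-1, , ]
    out[, -1, ] <- out[, -1, ] | fg[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | fg[, -1, ]
    out[, , -1] <- out[, , -1] | fg[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | fg[, , -1]
    fg <- out
  }
  binary_mask(fg, label$affine)
}

#' Rescale intensities to a target mean/SD within a mask
#'
#' Computes the affine intensity map that gives the within-mask voxels the
#' target mean and SD (z-scoring when the defaults are kept) and applies the
#' same map to every voxel. The segmentation pipeline uses a positive working
#' scale (mean 100, SD 10) so that ratio-based contrast features stay
#' well-defined; see the methods vignette.
#'
#' @param vol a `volume3d`.
#' @param mask a `binary_mask` with >= 100 foreground voxels.
#' @param target_mean,target_sd intensity scale of the output within the mask.
#' @return A `volume3d` with within-mask mean `target_mean`, SD `target_sd`.
#' @export
normalize_intensity <- function(vol, mask, target_mean = 0, target_sd = 1) {
  if (!same_geometry(vol, mask)) stop("mask geometry differs from volume")
  v <- vol$data[mask$data]
  if (length(v) < 100) stop("mask must contain at least 100 voxels")
  s <- stats::sd(v)
  if (s < 1e-12) stop("zero within-mask variance")
  volume3d((vol$data - mean(v)) / s * target_sd + target_mean, vol$affine)
}

#' Trilinear interpolation at world-mm points
#'
#' Points outside the voxel-center hull return `fill`.
#'
#' @param vol a `volume3d`.
#' @param points n x 3 matrix of world-mm coordinates.
#' @param fill value returned for out-of-grid points.
#' @return Numeric vector of length `nrow(points)`.
#' @export
trilinear_sample <- function(vol, points, fill = 0) {
  points <- matrix(points, ncol = 3)
  vx <- world_to_voxel(vol, points)
  cpp_trilinear(as.vector(vol$data), dim(vol$data), vx, fill)
}

#' Per-structure volumes of a label volume in mm^3
#'
#' @param label a `label_volume`.
#' @return Named numeric vector (HP, AM, EC) of structure volumes in mm^3.
#' @export
label_volumes <- function(label) {
  voxvol <- abs(det(label$affine[1:3, 1:3]))
  counts <- tabulate(label$data + 1L, nbins = 4L)[2:4]
  stats::setNames(counts * voxvol, c("HP", "AM", "EC"))
}

structure_codes <- c(HP = 1L, AM = 2L, EC = 3L)

as_structure_code <- function(structure) {
  if (is.character(structure)) {
    if (!structure %in% names(structure_codes))
      stop("unknown structure: ", structure)
    structure_codes[[structure]]
  } else as.integer(structure)
}
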