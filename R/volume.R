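# Labeled/scalar 3D volumes with a voxel-to-mm affine.
#
# The affine follows the NIfTI convention: it maps 0-based voxel indices to
# world (mm) coordinates, so R array element [1,1,1] sits at the affine
# translation. Only orthogonal (axis-aligned) affines are produced by the
# generator; the transforms below are general.

#' Construct a brain volume
#'
#' A minimal container for a 3D scalar or binary grid plus its voxel-to-mm
#' affine, used for hippocampus masks, difference maps, disease contrasts
#' and topic masks.
#'
#' @param data 3D numeric or logical array.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(data, affine) {
  if (length(dim(data)) != 3) abort("`data` must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) abort("`affine` must be 4x4")
  if (abs(det(affine)) < 1e-12) abort("`affine` must be invertible")
  structure(list(data = data, affine = affine), class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("<brain_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ",
      paste(signif(voxel_size(x), 3), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Voxel edge lengths in mm
#' @param volume A [brain_volume()].
#' @return Numeric length-3 vector.
#' @export
voxel_size <- function(volume) {
  sqrt(colSums(volume$affine[1:3, 1:3]^2))
}

#' Convert world (mm) coordinates to continuous 1-based voxel indices
#' @param volume A [brain_volume()].
#' @param xyz Matrix (n x 3) or length-3 vector of mm coordinates.
#' @return n x 3 matrix of 1-based voxel coordinates (continuous).
#' @export
world_to_voxel <- function(volume, xyz) {
  xyz <- rbind_coords(xyz)
  inv <- solve(volume$affine)
  v <- cbind(xyz, 1) %*% t(inv)
  v[, 1:3, drop = FALSE] + 1
}

#' Convert 1-based voxel indices to world (mm) coordinates
#' @param volume A [brain_volume()].
#' @param ijk Matrix (n x 3) or length-3 vector of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- rbind_coords(ijk)
  w <- cbind(ijk - 1, 1) %*% t(volume$affine)
  w[, 1:3, drop = FALSE]
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 3) abort("coordinates must have 3 columns")
  as.matrix(x)
}

# mm coordinates of every voxel center with value above a threshold.
volume_points <- function(volume, threshold = 0.5) {
  idx <- which(volume$data > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(), 0, 3))
  voxel_to_world(volume, idx)
}

# Euclidean distance (mm) from every voxel center to the nearest voxel of
# the mask (0 inside the mask). Exact separable transform in compiled code.
distance_to_mask <- function(volume, threshold = 0.5) {
  mask <- volume$data > threshold
  d <- .edt3d(as.logical(mask), dim(mask), voxel_size(volume))
  dim(d) <- dim(mask)
  brain_volume(d, volume$affine)
}

# Trilinear value lookup at world coordinates; NA outside the grid.
sample_volume_at <- function(volume, xyz) {
  v <- world_to_voxel(volume, xyz)
  dm <- dim(volume$data)
  out <- rep(NA_real_, nrow(v))
  for (i in seq_len(nrow(v))) {
    p <- v[i, ]
    if (any(p < 1) || any(p > dm)) next
    lo <- pmin(floor(p), dm - 1)
    lo <- pmax(lo, 1)
    f <- p - lo
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      if (wgt > 0) {
        acc <- acc + wgt * volume$data[lo[1] + dx, lo[2] + dy, lo[3] + dz]
      }
    }
    out[i] <- acc
  }
  out
}

#' Read a NIfTI file as a brain volume
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [brain_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  brain_volume(array(as.numeric(img), dim(img)), RNifti::xform(img))
}

#' Write a brain volume to NIfTI
#' @param volume A [brain_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- voxel_size(volume)
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
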