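# Curvilinear axis skeleton extraction and sample position assignment.

#' Extract the longitudinal-axis skeleton of a labeled volume
#'
#' Operationalizes a medial-axis extraction from chamfer (distance) maps:
#' the mask is resampled to `upsample_mm`, an outward distance map up to
#' `chamfer_extent_mm` is binarized into a smooth blob, an inward distance
#' map is computed inside the blob, and the ridge of that map (non-maximum
#' suppression of its values along the local gradient direction) is taken as
#' the skeleton. The ridge is masked with the original volume, resampled to
#' native resolution and returned ordered from posterior to anterior
#' (increasing y).
#'
#' @param volume Binary [brain_volume()]; must be nonempty and thicker than
#'   2 voxels somewhere (an interior ridge must exist).
#' @param chamfer_extent_mm Outward distance (mm) used to build the blob.
#' @param upsample_mm Working resolution (mm) for the distance maps.
#' @return A tibble of class `skeleton_path` with columns `x`, `y`, `z`
#'   (mm, sorted by `y`) and `depth` (inward distance at the ridge voxel).
#' @export
skeletonize_volume <- function(volume, chamfer_extent_mm = 10,
                               upsample_mm = 0.5) {
  stopifnot(inherits(volume, "brain_volume"))
  if (!any(volume$data > 0.5)) abort("empty mask: nothing to skeletonize")

  # working grid: mask bounding box + chamfer extent, isotropic upsample_mm
  pts <- volume_points(volume)
  margin <- chamfer_extent_mm + 2
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / upsample_mm)) + 1L
  affine <- diag(c(rep(upsample_mm, 3), 1))
  affine[1:3, 4] <- lo
  grid <- brain_volume(array(0, dims), affine)

  # nearest-neighbor resample of the source mask onto the working grid
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  ctr <- voxel_to_world(grid, ijk)
  src <- round(world_to_voxel(volume, ctr))
  sd_ <- dim(volume$data)
  inside <- src[, 1] >= 1 & src[, 1] <= sd_[1] &
    src[, 2] >= 1 & src[, 2] <= sd_[2] &
    src[, 3] >= 1 & src[, 3] <= sd_[3]
  mask_up <- rep(FALSE, prod(dims))
  mask_up[inside] <- volume$data[src[inside, , drop = FALSE]] > 0.5
  dim(mask_up) <- dims

  grid$data <- array(as.numeric(mask_up), dims)
  d_out <- distance_to_mask(grid)
  blob <- d_out$data <= chamfer_extent_mm

  grid$data <- array(as.numeric(!blob), dims)
  d_in <- distance_to_mask(grid)$data  # distance to blob surface, inside blob

  ridge <- ridge_voxels(d_in, mask_up, upsample_mm)
  if (nrow(ridge) == 0) {
    abort("no interior ridge: mask is thinner than 2 voxels everywhere")
  }
  mm <- voxel_to_world(grid, ridge[, 1:3, drop = FALSE])
  depth <- ridge[, 4]

  # resample to the native grid: collapse ridge points onto source voxels,
  # keeping the deepest point per voxel, then prune shoulder points (branch
  # pruning: within each native-resolution slab along y keep points close to
  # the maximal depth)
  nat <- round(world_to_voxel(volume, mm))
  key <- paste(nat[, 1], nat[, 2], nat[, 3])
  keep <- !duplicated(key[order(-depth)])
  ord <- order(-depth)[keep]
  mm <- voxel_to_world(volume, nat[ord, , drop = FALSE])
  depth <- depth[ord]
  vy <- voxel_size(volume)[2]
  bin <- round(mm[, 2] / vy)
  keep2 <- unlist(lapply(split(seq_along(bin), bin), function(i) {
    i[depth[i] >= max(depth[i]) - upsample_mm]
  }), use.names = FALSE)
  mm <- mm[keep2, , drop = FALSE]
  depth <- depth[keep2]

  out <- tibble(x = mm[, 1], y = mm[, 2], z = mm[, 3], depth = depth)
  out <- dplyr::arrange(out, .data$y, .data$x, .data$z)
  class(out) <- c("skeleton_path", class(out))
  out
}

# Non-maximum suppression of the inward distance map along its gradient.
# Returns voxel indices (inside `mask`) whose distance is a local maximum
# along the gradient direction, plus their depth.
ridge_voxels <- function(d_in, mask, step_mm) {
  dims <- dim(d_in)
  idx <- which(mask & d_in > step_mm)
  if (length(idx) == 0) return(matrix(numeric(), 0, 4))
  ijk <- arrayInd(idx, dims)
  interior <- ijk[, 1] > 1 & ijk[, 1] < dims[1] &
    ijk[, 2] > 1 & ijk[, 2] < dims[2] &
    ijk[, 3] > 1 & ijk[, 3] < dims[3]
  ijk <- ijk[interior, , drop = FALSE]
  if (nrow(ijk) == 0) return(matrix(numeric(), 0, 4))
  at <- function(di, dj, dk) {
    d_in[cbind(ijk[, 1] + di, ijk[, 2] + dj, ijk[, 3] + dk)]
  }
  gx <- (at(1, 0, 0) - at(-1, 0, 0)) / 2
  gy <- (at(0, 1, 0) - at(0, -1, 0)) / 2
  gz <- (at(0, 0, 1) - at(0, 0, -1)) / 2
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  gn[gn < 1e-12] <- 1
  ux <- gx / gn
  uy <- gy / gn
  uz <- gz / gn
  d0 <- at(0, 0, 0)
  fwd <- trilinear_at(d_in, ijk[, 1] + ux, ijk[, 2] + uy, ijk[, 3] + uz)
  bwd <- trilinear_at(d_in, ijk[, 1] - ux, ijk[, 2] - uy, ijk[, 3] - uz)
  tol <- 1e-9
  is_ridge <- d0 >= fwd - tol & d0 >= bwd - tol
  cbind(ijk[is_ridge, , drop = FALSE], d0[is_ridge])
}

trilinear_at <- function(arr, x, y, z) {
  dims <- dim(arr)
  x <- pmin(pmax(x, 1), dims[1])
  y <- pmin(pmax(y, 1), dims[2])
  z <- pmin(pmax(z, 1), dims[3])
  x0 <- pmin(floor(x), dims[1] - 1); fx <- x - x0
  y0 <- pmin(floor(y), dims[2] - 1); fy <- y - y0
  z0 <- pmin(floor(z), dims[3] - 1); fz <- z - z0
  g <- function(dx, dy, dz) arr[cbind(x0 + dx, y0 + dy, z0 + dz)]
  (1 - fx) * (1 - fy) * (1 - fz) * g(0, 0, 0) +
    fx * (1 - fy) * (1 - fz) * g(1, 0, 0) +
    (1 - fx) * fy * (1 - fz) * g(0, 1, 0) +
    (1 - fx) * (1 - fy) * fz * g(0, 0, 1) +
    fx * fy * (1 - fz) * g(1, 1, 0) +
    fx * (1 - fy) * fz * g(1, 0, 1) +
    (1 - fx) * fy * fz * g(0, 1, 1) +
    fx * fy * fz * g(1, 1, 1)
}

#' Assign each sample a position along the longitudinal axis
#'
#' Each sample's axis position is the y-coordinate (anterior-posterior, mm)
#' of its nearest skeleton point (Euclidean distance in world space, both
#' hemispheres pooled). Ties are broken toward the more posterior (lower y)
#' skeleton point. Samples lying more than `exclusion_mm` outside the
#' labeled volume are flagged excluded and carry no position.
#'
#' @param samples Tibble with `x`, `y`, `z` columns in mm.
#' @param skeleton A `skeleton_path` from [skeletonize_volume()] (any tibble
#'   with `x`, `y`, `z` works).
#' @param volume The labeled [brain_volume()] used for the exclusion rule;
#'   `NULL` skips it.
#' @param exclusion_mm Maximum allowed distance (mm) outside the volume.
#' @return `samples` with `position` (mm), `dist_to_volume` (mm) and
#'   `excluded` columns added.
#' @export
assign_axis_positions <- function(samples, skeleton, volume = NULL,
                                  exclusion_mm = 3) {
  if (!all(c("x", "y", "z") %in% names(samples))) {
    abort("`samples` must have x/y/z coordinate columns")
  }
  if (nrow(skeleton) == 0) abort("`skeleton` is empty")
  xyz <- as.matrix(samples[, c("x", "y", "z")])
  sk <- as.matrix(skeleton[, c("x", "y", "z")])

  d2 <- outer(rowSums(xyz^2), rowSums(sk^2), "+") - 2 * xyz %*% t(sk)
  d2[d2 < 0] <- 0
  pos <- vapply(seq_len(nrow(xyz)), function(i) {
    di <- d2[i, ]
    cand <- which(di <= min(di) + 1e-9)
    min(sk[cand, 2])  # tie-break: most posterior (lowest y)
  }, numeric(1))

  dist_vol <- rep(0, nrow(xyz))
  if (!is.null(volume)) {
    dmap <- distance_to_mask(volume)
    dist_vol <- sample_volume_at(dmap, xyz)
    # outside the distance grid: fall back to distance to nearest mask point
    if (anyNA(dist_vol)) {
      mp <- volume_points(volume)
      nai <- which(is.na(dist_vol))
      for (i in nai) {
        dist_vol[i] <- sqrt(min(colSums((t(mp) - xyz[i, ])^2)))
      }
    }
  }
  excluded <- dist_vol > exclusion_mm
  samples$position <- ifelse(excluded, NA_real_, pos)
  samples$dist_to_volume <- dist_vol
  samples$excluded <- excluded
  samples
}
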