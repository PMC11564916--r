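# Interpolation and grid resampling. The trilinear/nearest sampling kernel
# lives in src/kernels.cpp; everything here is geometry bookkeeping.

# Sample a raw array at continuous 0-based voxel coordinates.
interp_at_voxel <- function(values, vx, fill, mode = c("trilinear",
                                                       "nearest")) {
  mode <- match.arg(mode)
  c_interp3(as.double(values), dim(values),
            vx[, 1], vx[, 2], vx[, 3], fill,
            if (mode == "trilinear") 0L else 1L)
}

#' Sample a volume at world coordinates
#'
#' @param vol A `scalar_volume` or `structure_mask`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param mode `"trilinear"` or `"nearest"`; masks always use nearest.
#' @param fill Value returned outside the grid.
#' @return Numeric vector of length n.
#' @export
sample_at_world <- function(vol, pts, mode = c("trilinear", "nearest"),
                            fill = 0) {
  mode <- match.arg(mode)
  if (inherits(vol, "structure_mask")) mode <- "nearest"
  interp_at_voxel(vol$values, world_to_voxel(as_grid_of(vol), pts), fill,
                  mode)
}

grid_world_extent <- function(grid) {
  # world-aligned bounding box of all voxel centres
  corners <- as.matrix(expand.grid(c(0, grid$shape[1] - 1),
                                   c(0, grid$shape[2] - 1),
                                   c(0, grid$shape[3] - 1)))
  w <- voxel_to_world(grid, corners)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Resample a volume or mask onto a target grid
#'
#' Values are sampled at the world coordinates of the target voxel centres.
#' Out-of-field voxels are filled with `fill` (0 by default, conservative
#' for dose). Masks are resampled with nearest-neighbour interpolation and
#' stay binary.
#'
#' @param vol A `scalar_volume` or `structure_mask`.
#' @param target Target `grid_spec`.
#' @param mode `"trilinear"` or `"nearest"`; forced to nearest for masks.
#' @param fill Fill value for out-of-field voxels (dose: 0 Gy; images: the
#'   background intensity).
#' @return A `scalar_volume` or `structure_mask` on `target`.
#' @export
resample_to_grid <- function(vol, target, mode = c("trilinear", "nearest"),
                             fill = 0) {
  mode <- match.arg(mode)
  src <- as_grid_of(vol)
  es <- grid_world_extent(src); et <- grid_world_extent(target)
  if (any(es["hi", ] < et["lo", ] | et["hi", ] < es["lo", ]))
    stop("source and target grids do not overlap in world space")
  is_mask <- inherits(vol, "structure_mask")
  if (is_mask) mode <- "nearest"
  vx <- world_to_voxel(src, grid_points_world(target))
  vals <- interp_at_voxel(vol$values, vx, fill, mode)
  arr <- array(vals, target$shape)
  if (is_mask) structure_mask(arr != 0, target, vol$label)
  else scalar_volume(arr, target, kind = vol$kind)
}
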