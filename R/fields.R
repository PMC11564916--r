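# Displacement-field machinery: warping, composition, inversion, Jacobians,
# signed distance transforms, Gaussian smoothing. Fields use the pull-back
# convention throughout: the warped value at fixed-grid voxel centre x is
# the moving volume sampled at x + u(x) (world mm).

#' Warp a volume along a displacement field
#'
#' Pull-back warping: output voxel value = input sampled at
#' `voxel centre + displacement`. This is also the direct dose mapping
#' (DDM) primitive used by [warp_dose()].
#'
#' @param vol A `scalar_volume` on a grid compatible with `dvf` (resampled
#'   to the field grid if not identical).
#' @param dvf A `vector_field` on the output (fixed) grid.
#' @param mode Interpolation mode, `"trilinear"` or `"nearest"`.
#' @param fill Out-of-field fill value.
#' @return A `scalar_volume` on the field's grid.
#' @export
warp_volume <- function(vol, dvf, mode = "trilinear", fill = 0) {
  g <- dvf$grid
  vx <- warp_sample_coords(as_grid_of(vol), dvf)
  vals <- interp_at_voxel(vol$values, vx, fill, mode)
  scalar_volume(array(pmax(vals, if (vol$kind == "dose") 0 else -Inf),
                      g$shape), g, kind = vol$kind)
}

# Continuous 0-based voxel coordinates (in the source grid) of the warp
# sample points `x + u(x)` for every voxel of the field grid. Fast path
# when source and field share one axis-aligned grid.
warp_sample_coords <- function(src_grid, dvf) {
  g <- dvf$grid
  if (grid_equal(src_grid, g) &&
      max(abs(g$direction - diag(3))) < 1e-12) {
    sh <- g$shape
    i <- rep.int(seq_len(sh[1]) - 1, sh[2] * sh[3])
    j <- rep.int(rep(seq_len(sh[2]) - 1, each = sh[1]), sh[3])
    k <- rep(seq_len(sh[3]) - 1, each = sh[1] * sh[2])
    u <- matrix(dvf$values, ncol = 3)
    return(cbind(i + u[, 1] / g$spacing[1],
                 j + u[, 2] / g$spacing[2],
                 k + u[, 3] / g$spacing[3]))
  }
  pts <- grid_points_world(g) + matrix(dvf$values, ncol = 3)
  world_to_voxel(src_grid, pts)
}

#' Warp a structure mask along a displacement field
#'
#' Nearest-neighbour sampling of the mask at displaced coordinates;
#' out-of-field samples become background (FALSE). Output is binary.
#'
#' @param mask A `structure_mask`.
#' @param dvf A `vector_field` on the output grid.
#' @return A `structure_mask` on the field's grid.
#' @export
apply_field_to_mask <- function(mask, dvf) {
  g <- dvf$grid
  vx <- warp_sample_coords(mask$grid, dvf)
  vals <- interp_at_voxel(mask$values, vx, 0, "nearest")
  structure_mask(array(vals != 0, g$shape), g, mask$label)
}

# Sample a vector field at world points; returns n x 3 displacements (mm).
sample_field_at <- function(dvf, pts) {
  vx <- world_to_voxel(dvf$grid, pts)
  sample_field_at_vox(dvf, vx)
}

sample_field_at_vox <- function(dvf, vx) {
  cbind(interp_at_voxel(dvf$values[, , , 1], vx, 0, "trilinear"),
        interp_at_voxel(dvf$values[, , , 2], vx, 0, "trilinear"),
        interp_at_voxel(dvf$values[, , , 3], vx, 0, "trilinear"))
}

field_base_voxels <- function(grid) {
  sh <- grid$shape
  cbind(rep.int(seq_len(sh[1]) - 1, sh[2] * sh[3]),
        rep.int(rep(seq_len(sh[2]) - 1, each = sh[1]), sh[3]),
        rep(seq_len(sh[3]) - 1, each = sh[1] * sh[2]))
}

#' Compose two displacement fields
#'
#' Returns the field `w` whose map `I + w` equals `(I + a) o (I + b)`:
#' `w(x) = b(x) + a(x + b(x))`. Warping by `w` is equivalent to warping by
#' `a` first and then by `b` in pull-back order.
#'
#' @param a,b `vector_field` objects; the result lives on `b`'s grid.
#' @return A `vector_field`.
#' @export
compose_fields <- function(a, b) {
  g <- b$grid
  bb <- matrix(b$values, ncol = 3)
  if (grid_equal(a$grid, g) && max(abs(g$direction - diag(3))) < 1e-12) {
    base <- field_base_voxels(g)
    vx <- cbind(base[, 1] + bb[, 1] / g$spacing[1],
                base[, 2] + bb[, 2] / g$spacing[2],
                base[, 3] + bb[, 3] / g$spacing[3])
    w <- bb + sample_field_at_vox(a, vx)
  } else {
    w <- bb + sample_field_at(a, grid_points_world(g) + bb)
  }
  vector_field(array(w, c(g$shape, 3)), g)
}

#' Invert a displacement field
#'
#' Fixed-point iteration for the field `v` with
#' `(I + v) o (I + u) = I` (and vice versa for small smooth fields):
#' `v_{k+1}(x) = -u(x + v_k(x))`.
#'
#' @param u A `vector_field`.
#' @param iterations Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the mean update, mm.
#' @return A `vector_field` approximating the inverse of `u`.
#' @export
invert_field <- function(u, iterations = 20, tol = 0.02) {
  g <- u$grid
  fast <- max(abs(g$direction - diag(3))) < 1e-12
  base <- if (fast) field_base_voxels(g) else grid_points_world(g)
  v <- -matrix(u$values, ncol = 3)
  for (it in seq_len(iterations)) {
    vx <- if (fast)
      cbind(base[, 1] + v[, 1] / g$spacing[1],
            base[, 2] + v[, 2] / g$spacing[2],
            base[, 3] + v[, 3] / g$spacing[3])
    else world_to_voxel(g, base + v)
    vn <- -sample_field_at_vox(u, vx)
    delta <- mean(abs(vn - v))
    v <- vn
    if (delta < tol) break
  }
  vector_field(array(v, c(g$shape, 3)), g)
}

#' Jacobian determinant of the deformation `I + u`
#'
#' Central finite differences of the displacement in world mm. Values near
#' 1 indicate volume preservation; nonpositive values indicate folding.
#'
#' @param dvf A `vector_field`.
#' @return A `scalar_volume` of determinant values.
#' @export
jacobian_determinant <- function(dvf) {
  g <- dvf$grid
  J <- array(0, c(g$shape, 3, 3))
  for (a in 1:3)
    J[, , , a, ] <- c_grad3(as.double(dvf$values[, , , a]), g$shape,
                            g$spacing)
  d11 <- 1 + J[, , , 1, 1]; d12 <- J[, , , 1, 2]; d13 <- J[, , , 1, 3]
  d21 <- J[, , , 2, 1]; d22 <- 1 + J[, , , 2, 2]; d23 <- J[, , , 2, 3]
  d31 <- J[, , , 3, 1]; d32 <- J[, , , 3, 2]; d33 <- 1 + J[, , , 3, 3]
  det <- d11 * (d22 * d33 - d23 * d32) - d12 * (d21 * d33 - d23 * d31) +
    d13 * (d21 * d32 - d22 * d31)
  scalar_volume(det, g)
}

#' Gaussian smoothing of a scalar array or volume
#'
#' Separable Gaussian with sigma given in mm (converted to voxels per
#' axis); kernels truncated at 3 sigma and renormalised at the borders.
#'
#' @param x A `scalar_volume` or plain 3-D array.
#' @param sigma_mm Smoothing sigma in mm (scalar or length 3).
#' @param grid Required when `x` is a plain array.
#' @return Same type as `x`.
#' @export
gaussian_smooth <- function(x, sigma_mm, grid = NULL) {
  if (inherits(x, "scalar_volume")) {
    grid <- x$grid
    arr <- x$values
  } else arr <- x
  sig <- rep(sigma_mm, length.out = 3) / grid$spacing
  out <- array(c_gauss3(as.double(arr), dim(arr), sig), dim(arr))
  if (inherits(x, "scalar_volume")) scalar_volume(out, grid, kind = x$kind)
  else out
}

# Smooth each component of a displacement field.
smooth_field <- function(dvf, sigma_mm) {
  if (all(sigma_mm <= 0)) return(dvf)
  vals <- dvf$values
  for (a in 1:3)
    vals[, , , a] <- gaussian_smooth(vals[, , , a], sigma_mm, dvf$grid)
  vector_field(vals, dvf$grid)
}

#' Signed Euclidean distance to a mask surface
#'
#' Negative inside the structure, positive outside, in mm (exact
#' centre-to-centre Euclidean distance transform, computed separably).
#'
#' @param mask A `structure_mask` (must be nonempty and not fill the grid).
#' @return A `scalar_volume` of signed distances in mm.
#' @export
signed_distance <- function(mask) {
  m <- mask$values
  if (!any(m)) stop("signed distance of an empty mask")
  g <- mask$grid
  dout <- sqrt(c_edt3_sq(as.logical(m), g$shape, g$spacing))
  if (all(m)) {
    sd <- -dout  # degenerate: structure fills the grid
  } else {
    din <- sqrt(c_edt3_sq(!m, g$shape, g$spacing))
    sd <- ifelse(m, -din, dout)
  }
  scalar_volume(array(sd, g$shape), g)
}

#' Dilate a mask by a (possibly anisotropic) margin
#'
#' Morphological dilation with an ellipsoidal structuring element. A
#' direction-dependent margin is supported through `margin_dorsal`, which
#' replaces the margin for offsets with a positive y-component (the
#' posterior direction in the package's synthetic frame); this is how a
#' CTV-to-PTV margin of 5 mm with 3 mm dorsally is built.
#'
#' @param mask A `structure_mask`.
#' @param margin_mm Isotropic margin in mm.
#' @param margin_dorsal_mm Margin used in the +y (dorsal) direction;
#'   defaults to `margin_mm`.
#' @param label Label for the dilated mask.
#' @return A `structure_mask`.
#' @export
dilate_mask <- function(mask, margin_mm, margin_dorsal_mm = margin_mm,
                        label = mask$label) {
  g <- mask$grid
  steps <- lapply(1:3, function(a)
    seq(-ceiling(margin_mm / g$spacing[a]), ceiling(margin_mm / g$spacing[a])))
  offs <- as.matrix(expand.grid(steps))
  w <- sweep(offs, 2, g$spacing, "*")
  my <- ifelse(w[, 2] > 0, margin_dorsal_mm, margin_mm)
  keep <- (w[, 1] / margin_mm)^2 + (w[, 2] / my)^2 +
    (w[, 3] / margin_mm)^2 <= 1 + 1e-9
  # c_dilate3 sets out[x] when mask[x + o] is set, so pass the negated
  # offsets: voxel x is covered when some mask point lies at x - o.
  offs <- -offs[keep, , drop = FALSE]
  storage.mode(offs) <- "integer"
  d <- dim(mask$values)
  out <- array(c_dilate3(as.logical(mask$values), d, offs), d)
  structure_mask(out, g, label)
}
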