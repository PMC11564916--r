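#' Spatial grid specification
#'
#' Describes the geometry of a 3-D voxel grid: its shape in voxels, voxel
#' spacing in mm, the world position (mm) of the centre of voxel
#' `(0, 0, 0)`, and an orthonormal direction matrix mapping voxel axes to
#' world axes. All package coordinates are world coordinates in mm with a
#' voxel-centre convention and 0-based voxel indices.
#'
#' @param shape Integer vector of length 3, voxels per axis (all positive).
#' @param spacing Numeric vector of length 3, voxel spacing in mm (all
#'   positive).
#' @param origin Numeric vector of length 3, world coordinates (mm) of the
#'   centre of voxel `(0, 0, 0)`.
#' @param direction 3x3 orthonormal direction matrix (|det| = 1 within
#'   1e-6). Defaults to the axial identity.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0),
                      direction = diag(3)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("grid shape must be positive on all axes")
  if (any(spacing <= 0)) stop("grid spacing must be positive on all axes")
  if (abs(abs(det(direction)) - 1) > 1e-6 ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = direction),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm%s\n",
              x$origin[1], x$origin[2], x$origin[3],
              if (identical(unname(x$direction), diag(3))) "" else
                ", non-identity orientation"))
  invisible(x)
}

#' Test two grids for geometric equality
#'
#' @param a,b `grid_spec` objects.
#' @param tol Tolerance in mm for spacing/origin and absolute tolerance for
#'   the direction matrix.
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Voxel volume of a grid in mm^3
#' @param grid A `grid_spec`.
#' @return Numeric scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

as_grid_of <- function(x) {
  if (inherits(x, "grid_spec")) x else x$grid
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param grid A `grid_spec`.
#' @param idx Numeric matrix (n x 3) of 0-based (possibly fractional) voxel
#'   indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx %*% (t(grid$direction) * grid$spacing), 2, grid$origin, "+")
}

#' Convert world coordinates (mm) to 0-based voxel indices
#'
#' @param grid A `grid_spec`.
#' @param pts Numeric matrix (n x 3) of world coordinates in mm.
#' @return n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, grid$origin, "-") %*% grid$direction, 2,
        grid$spacing, "/")
}

# World coordinates of all voxel centres, as three arrays (one per axis)
# to avoid materialising an n x 3 matrix when only per-axis values are
# needed. With an identity direction matrix the axes separate.
grid_axis_world <- function(grid, axis) {
  grid$origin[axis] + grid$spacing[axis] * (seq_len(grid$shape[axis]) - 1)
}

# n x 3 matrix of world coordinates of all voxel centres, voxel index
# varying fastest along axis 1 (column-major, matching array storage).
grid_points_world <- function(grid) {
  i <- rep.int(seq_len(grid$shape[1]) - 1, grid$shape[2] * grid$shape[3])
  j <- rep.int(rep(seq_len(grid$shape[2]) - 1, each = grid$shape[1]),
               grid$shape[3])
  k <- rep(seq_len(grid$shape[3]) - 1,
           each = grid$shape[1] * grid$shape[2])
  voxel_to_world(grid, cbind(i, j, k))
}

#' Scalar volume on a grid
#'
#' A 3-D scalar field (image intensity in arbitrary units, or dose in Gy)
#' with its grid geometry.
#'
#' @param values Numeric 3-D array whose dimensions match `grid$shape`.
#' @param grid A `grid_spec`.
#' @param kind Optional label, e.g. `"dose"` or `"image"`; dose volumes must
#'   be nonnegative and finite everywhere.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, kind = "image") {
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("values must be a 3-D array matching the grid shape")
  storage.mode(values) <- "double"
  if (identical(kind, "dose")) {
    if (any(!is.finite(values)) || any(values < 0))
      stop("dose volumes must be nonnegative and finite everywhere")
  }
  structure(list(values = values, grid = grid, kind = kind),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume:%s> range [%.4g, %.4g]\n", x$kind,
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Binary structure mask on a grid
#'
#' @param values Logical 3-D array matching `grid$shape`.
#' @param grid A `grid_spec`.
#' @param label Structure label, one of `"CTV"`, `"PTV"`, `"bladder"`,
#'   `"rectum"`, `"urethra"` (other labels are allowed but the planning
#'   objective checker only knows these).
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, grid, label) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("values must be a 3-D array matching the grid shape")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask must not contain NA")
  structure(list(values = values, grid = grid, label = label),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask:%s> %d voxels, %.2f cm^3\n", x$label,
              sum(x$values), mask_volume_cm3(x)))
  invisible(x)
}

#' Volume of a structure mask in cm^3
#' @param mask A `structure_mask`.
#' @return Numeric scalar, cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$values) * voxel_volume_mm3(mask$grid) / 1000
}

#' Displacement vector field on a grid
#'
#' Per-voxel 3-D displacement in mm, world coordinates, pull-back
#' convention: a volume in the moving frame is resampled at
#' `voxel centre + displacement` to produce its warped version on this
#' (fixed) grid.
#'
#' @param values Numeric 4-D array of dimension `c(grid$shape, 3)`.
#' @param grid A `grid_spec`.
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(values, grid) {
  values <- as.array(values)
  if (length(dim(values)) != 4L || !all(dim(values)[1:3] == grid$shape) ||
      dim(values)[4] != 3L)
    stop("values must be a 4-D array of dimension c(shape, 3)")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("displacement field must be finite everywhere")
  structure(list(values = values, grid = grid), class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(x$values[, , , 1]^2 + x$values[, , , 2]^2 + x$values[, , , 3]^2)
  cat(sprintf("<vector_field> max |u| = %.3f mm, mean |u| = %.3f mm\n",
              max(mag), mean(mag)))
  invisible(x)
}

#' Identity (all-zero) displacement field
#' @param grid A `grid_spec`.
#' @return A `vector_field` with zero displacement everywhere.
#' @export
identity_field <- function(grid) {
  vector_field(array(0, c(grid$shape, 3)), grid)
}

#' Maximum displacement magnitude of a field, in mm
#' @param dvf A `vector_field`.
#' @return Numeric scalar, mm.
#' @export
field_max_mm <- function(dvf) {
  sqrt(max(dvf$values[, , , 1]^2 + dvf$values[, , , 2]^2 +
             dvf$values[, , , 3]^2))
}
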