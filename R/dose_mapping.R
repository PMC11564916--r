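# Direct dose mapping (DDM) along displacement fields and accumulation of
# fraction doses into the fraction-1 frame. DDM interpolates the dose at
# the displaced point and applies no energy rescaling; it preserves
# pointwise dose values but not integral dose under deformation.

#' Warp a dose distribution along a displacement field (DDM)
#'
#' Output voxel value = trilinear sample of the input dose at
#' `voxel centre + displacement`; out-of-field samples are 0 Gy and values
#' are clamped at 0. No energy or mass rescaling is applied (direct dose
#' mapping, not energy/mass transfer).
#'
#' @param dose A `scalar_volume` in Gy.
#' @param dvf A `vector_field` on the output grid.
#' @return A `scalar_volume` (kind `"dose"`) on the field's grid.
#' @export
warp_dose <- function(dose, dvf) {
  if (any(!is.finite(dvf$values))) stop("non-finite displacement field")
  out <- warp_volume(scalar_volume(dose$values, dose$grid, kind = "dose"),
                     dvf, mode = "trilinear", fill = 0)
  out
}

#' Sum fraction doses voxelwise
#'
#' @param fraction_doses Nonempty list of `scalar_volume`s on one grid.
#' @return A `scalar_volume` of the voxelwise sum.
#' @export
accumulate <- function(fraction_doses) {
  if (length(fraction_doses) == 0) stop("empty dose list")
  g <- fraction_doses[[1]]$grid
  total <- fraction_doses[[1]]$values
  for (k in seq_along(fraction_doses)[-1]) {
    if (!grid_equal(fraction_doses[[k]]$grid, g))
      stop("grid mismatch at fraction ", k)
    total <- total + fraction_doses[[k]]$values
  }
  scalar_volume(total, g, kind = "dose")
}

#' Accumulate one treatment arm into the fraction-1 frame
#'
#' For each fraction k, the fraction dose of the requested arm is warped
#' by `dvfs[[k]]` (the pull-back field from the fraction-1 frame to the
#' fraction-k frame; `dvfs[[1]]` is the identity) and the warped doses are
#' summed.
#'
#' @param case A `patient_case` with complete fraction records.
#' @param arm `"conv-IGRT"` or `"OA-MRgRT"`.
#' @param dvfs List of `vector_field`s, one per fraction, fraction-1 frame
#'   to fraction-k frame.
#' @return An object of class `accumulated_dose` with fields `arm`, `dose`
#'   (total Gy) and `frame = "fraction1"`.
#' @export
accumulate_arm <- function(case, arm = c("conv-IGRT", "OA-MRgRT"), dvfs) {
  arm <- match.arg(arm)
  n <- length(case$fractions)
  if (length(dvfs) != n)
    stop("need one DVF per fraction (", n, ")")
  slot <- if (arm == "conv-IGRT") "dose_conv" else "dose_oa"
  warped <- lapply(seq_len(n), function(k) {
    d <- case$fractions[[k]][[slot]]
    if (is.null(d)) stop("fraction ", k, " has no ", slot)
    warp_dose(d, dvfs[[k]])
  })
  structure(list(arm = arm, dose = accumulate(warped), frame = "fraction1"),
            class = "accumulated_dose")
}

#' @export
print.accumulated_dose <- function(x, ...) {
  cat(sprintf("<accumulated_dose:%s> frame %s, max %.2f Gy\n", x$arm,
              x$frame, max(x$dose$values)))
  invisible(x)
}

#' Ground-truth fraction-1 to fraction-k displacement fields
#'
#' The phantom stores pull-back fields u_k warping the reference into each
#' fraction. The pull-back field from the fraction-1 frame to the
#' fraction-k frame is the composition `(I + u_k)^{-1} o ... ` expressed
#' as `compose_fields(invert_field(u_k), u_1)`; fraction 1 maps to itself
#' through the identity.
#'
#' @param case A `patient_case` with ground-truth fields.
#' @return List of `vector_field`s, one per fraction.
#' @export
gt_dvfs_to_fraction1 <- function(case) {
  u1 <- case$fractions[[1]]$gt_dvf_ref_to_fx
  lapply(seq_along(case$fractions), function(k) {
    if (k == 1) return(identity_field(u1$grid))
    uk <- case$fractions[[k]]$gt_dvf_ref_to_fx
    compose_fields(invert_field(uk), u1)
  })
}

#' Registered fraction-1 to fraction-k displacement fields
#'
#' Runs the deformable registration surrogate for each fraction k > 1 with
#' the fraction image as moving and the fraction-1 image as fixed, using
#' the fraction-1 structures as guidance (the DDA workflow definition).
#'
#' @param case A `patient_case`.
#' @param cfg A [dir_config()].
#' @return List of `vector_field`s, one per fraction.
#' @export
registered_dvfs_to_fraction1 <- function(case, cfg = dir_config()) {
  fx1 <- case$fractions[[1]]
  lapply(seq_along(case$fractions), function(k) {
    if (k == 1) return(identity_field(fx1$image$grid))
    fxk <- case$fractions[[k]]
    deformable_register(fxk$image, fx1$image, fxk$structures,
                        fx1$structures, cfg)
  })
}

#' Accumulate both adaptive arms of a case
#'
#' Convenience driver: computes the fraction-to-fraction-1 fields either
#' from the phantom ground truth (`method = "gt"`, the oracle path) or by
#' deformable registration (`method = "dir"`), then accumulates each arm.
#'
#' @param case A `patient_case`.
#' @param method `"gt"` or `"dir"`.
#' @param cfg A [dir_config()] (used for `method = "dir"`).
#' @return Named list with `conv` and `oa` `accumulated_dose` objects and
#'   the `dvfs` used.
#' @export
accumulate_case <- function(case, method = c("gt", "dir"),
                            cfg = dir_config()) {
  method <- match.arg(method)
  dvfs <- if (method == "gt") gt_dvfs_to_fraction1(case)
  else registered_dvfs_to_fraction1(case, cfg)
  list(conv = accumulate_arm(case, "conv-IGRT", dvfs),
       oa = accumulate_arm(case, "OA-MRgRT", dvfs),
       dvfs = dvfs)
}
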