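# Synthetic pelvis cohort with ground-truth deformations.
#
# World frame: x = left-right, y = anterior(-)/posterior(+), z =
# inferior(-)/superior(+), mm, identity orientation. The anatomy is a set
# of smooth parametric shapes: an ellipsoidal prostate (CTV) at the origin
# with a thin urethra along its axis, a tubular rectum directly dorsal to
# it, and an ellipsoidal bladder anterior-superior. The reference plan is
# an analytic conformal dose: prescription-level plateau inside the PTV
# with a sigmoid penumbra, two dorso-lateral hotspot lobes (realistic plan
# heterogeneity), and hard max-dose carving inside OARs standing in for
# optimizer constraints.

#' Parameters of the synthetic cohort generator
#'
#' Defaults are the study conditions: 10 patients, 20 x 3 Gy, PTV = CTV +
#' 5 mm (3 mm dorsally), and per-fraction anatomical variation consisting
#' of a per-patient systematic posterior prostate drift, random residual
#' shifts, and bladder/rectum volume changes. Variation magnitudes are
#' generator configuration chosen so that, qualitatively, conventional
#' IGRT (translation-only couch correction) violates organ-at-risk
#' objectives in some patients while daily re-planning does not.
#'
#' @param n_patients Number of patients (default 10).
#' @param n_fractions Fractions per patient (default 20).
#' @param dose_per_fraction Gy per fraction (default 3.0).
#' @param prescription Total prescription in Gy (default 60.0); must equal
#'   `n_fractions * dose_per_fraction`.
#' @param ctv_margin_mm CTV-to-PTV margin (default 5).
#' @param ctv_margin_dorsal_mm Dorsal (towards rectum) margin (default 3).
#' @param bladder_volume_range Daily bladder volume range, cm^3.
#' @param rectum_volume_range Daily rectum volume range, cm^3.
#' @param prostate_shift_sd SD of the random per-fraction prostate shift,
#'   mm, per axis.
#' @param prostate_drift_range Range of the per-patient systematic
#'   posterior drift amplitude, mm.
#' @param rectal_wall_coupling Fraction of the prostate shift transmitted
#'   to deep rectal tissue (the anterior wall follows more, the lumen
#'   less).
#' @param deformation_smoothness Decay length (mm) of the organ deformation
#'   fields.
#' @param image_noise_sd SD of daily image noise, intensity units.
#' @param grid_spacing Isotropic voxel size in mm (default 2).
#' @param grid_shape Grid shape in voxels (default 80^3, a 160 mm cube).
#' @param seed Master seed.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(n_patients = 10L, n_fractions = 20L,
                           dose_per_fraction = 3.0, prescription = 60.0,
                           ctv_margin_mm = 5.0, ctv_margin_dorsal_mm = 3.0,
                           bladder_volume_range = c(90, 180),
                           rectum_volume_range = c(45, 75),
                           prostate_shift_sd = 1.5,
                           prostate_drift_range = c(2, 9),
                           rectal_wall_coupling = 0.3,
                           deformation_smoothness = 12,
                           image_noise_sd = 1.5,
                           grid_spacing = 2, grid_shape = c(80, 80, 80),
                           seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            n_fractions = as.integer(n_fractions),
            dose_per_fraction = dose_per_fraction,
            prescription = prescription,
            ctv_margin_mm = ctv_margin_mm,
            ctv_margin_dorsal_mm = ctv_margin_dorsal_mm,
            bladder_volume_range = sort(bladder_volume_range),
            rectum_volume_range = sort(rectum_volume_range),
            prostate_shift_sd = prostate_shift_sd,
            prostate_drift_range = sort(prostate_drift_range),
            rectal_wall_coupling = rectal_wall_coupling,
            deformation_smoothness = deformation_smoothness,
            image_noise_sd = image_noise_sd,
            grid_spacing = grid_spacing,
            grid_shape = as.integer(grid_shape),
            seed = as.integer(seed))
  if (abs(p$n_fractions * p$dose_per_fraction - p$prescription) > 1e-9)
    stop("n_fractions * dose_per_fraction must equal the prescription")
  if (any(c(p$bladder_volume_range, p$rectum_volume_range) <= 0) ||
      p$prostate_shift_sd < 0 || any(p$prostate_drift_range < 0))
    stop("variation magnitudes must be nonnegative and volumes positive")
  class(p) <- "phantom_params"
  p
}

phantom_grid <- function(params) {
  sp <- rep(params$grid_spacing, 3)
  grid_spec(params$grid_shape, sp,
            origin = -(params$grid_shape - 1) / 2 * sp)
}

# Fixed anatomical layout (mm, world). Organ shapes are scaled/displaced
# per fraction; these are the reference positions.
phantom_layout <- function() {
  list(ctv_c = c(0, 0, 0), ctv_r = c(23, 20, 22),
       ure_r = 3, ure_z = c(-21, 11),
       rec_c = c(0, 33), rec_r = 13.5, rec_z = c(-55, 45),
       bla_c = c(0, -18, 44), bla_r = c(36, 31, 28),
       bla_base = c(0, -18, 17))
}

# smooth ramp: 1 for x <= x0, cosine taper to 0 at x1
ramp01 <- function(x, x0, x1) {
  t <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  0.5 * (1 + cos(pi * t))
}

phantom_masks <- function(grid) {
  L <- phantom_layout()
  x <- grid_axis_world(grid, 1); y <- grid_axis_world(grid, 2)
  z <- grid_axis_world(grid, 3)
  X <- array(x, grid$shape)
  Y <- array(rep(y, each = grid$shape[1]), grid$shape)
  Z <- array(rep(z, each = grid$shape[1] * grid$shape[2]), grid$shape)
  ell <- function(c3, r3)
    ((X - c3[1]) / r3[1])^2 + ((Y - c3[2]) / r3[2])^2 +
    ((Z - c3[3]) / r3[3])^2 <= 1
  ctv <- ell(L$ctv_c, L$ctv_r)
  ure <- (X^2 + (Y - 0)^2 <= L$ure_r^2) & Z >= L$ure_z[1] &
    Z <= L$ure_z[2] & ctv
  rec <- ((X - L$rec_c[1])^2 + (Y - L$rec_c[2])^2 <= L$rec_r^2) &
    Z >= L$rec_z[1] & Z <= L$rec_z[2] & !ctv
  bla <- ell(L$bla_c, L$bla_r) & !ctv & !rec
  list(CTV = structure_mask(ctv, grid, "CTV"),
       urethra = structure_mask(ure, grid, "urethra"),
       rectum = structure_mask(rec, grid, "rectum"),
       bladder = structure_mask(bla, grid, "bladder"))
}

# Priority rule applied to warped masks: CTV wins over OARs, urethra stays
# inside the CTV. Mirrors contour-resolution practice when organs abut.
resolve_mask_overlap <- function(structs) {
  structs$urethra$values <- structs$urethra$values & structs$CTV$values
  structs$rectum$values <- structs$rectum$values & !structs$CTV$values
  structs$bladder$values <- structs$bladder$values & !structs$CTV$values &
    !structs$rectum$values
  structs
}

phantom_image <- function(grid, masks, seed) {
  set.seed(seed)
  tex <- gaussian_smooth(array(stats::rnorm(prod(grid$shape)), grid$shape),
                         5, grid)
  tex <- tex / stats::sd(tex) * 12
  img <- array(30, grid$shape) + tex
  img[masks$CTV$values] <- img[masks$CTV$values] + 90
  img[masks$bladder$values] <- img[masks$bladder$values] + 140
  img[masks$rectum$values] <- img[masks$rectum$values] + 20
  img[masks$urethra$values] <- img[masks$urethra$values] + 20
  img <- gaussian_smooth(array(img, grid$shape), 1, grid)
  scalar_volume(img, grid, kind = "image")
}

# --- analytic plan model -----------------------------------------------

default_plan_model <- function(params) {
  list(bath = 8, plateau = 61.8, penumbra = 2, edge_offset = 4,
       hotspot_amp = 1.5, hotspot_sigma = 6,
       hotspot_offsets = rbind(c(6, 14, 0), c(-6, 14, 0)),
       dmax_trigger = 58, dmax_level = 60.5, carve_margin = 3,
       v56_level = 55.5, v56_margin_frac = 0.9,
       prescription = params$prescription)
}

mask_centroid <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE) - 1
  colMeans(voxel_to_world(mask$grid, idx))
}

#' Evaluate the analytic plan model on an anatomy
#'
#' Produces a total-course dose distribution conformal to the given PTV:
#' `bath + (plateau - bath) * plogis((edge_offset - sdist_PTV) / penumbra)`
#' plus two hotspot lobes anchored to the CTV centroid, followed by hard
#' enforcement of the organ-at-risk planning constraints (max-dose carving
#' and, when triggered, V56Gy carving), emulating constrained
#' re-optimization on the given anatomy.
#'
#' @param structures Named list of `structure_mask`s with CTV, PTV,
#'   rectum, bladder, urethra.
#' @param model Plan-model parameter list (see the methods vignette).
#' @return A `scalar_volume` (kind `"dose"`), total course dose in Gy.
#' @export
plan_dose_on_anatomy <- function(structures, model) {
  grid <- structures$PTV$grid
  sdist <- signed_distance(structures$PTV)$values
  prof <- stats::plogis((model$edge_offset - sdist) / model$penumbra)
  dose <- model$bath + (model$plateau - model$bath) * prof
  cen <- mask_centroid(structures$CTV)
  x <- grid_axis_world(grid, 1); y <- grid_axis_world(grid, 2)
  z <- grid_axis_world(grid, 3)
  X <- array(x, grid$shape)
  Y <- array(rep(y, each = grid$shape[1]), grid$shape)
  Z <- array(rep(z, each = grid$shape[1] * grid$shape[2]), grid$shape)
  for (r in seq_len(nrow(model$hotspot_offsets))) {
    b <- cen + model$hotspot_offsets[r, ]
    d2 <- (X - b[1])^2 + (Y - b[2])^2 + (Z - b[3])^2
    dose <- dose + model$hotspot_amp *
      exp(-d2 / (2 * model$hotspot_sigma^2)) * prof
  }
  vol <- scalar_volume(dose, grid, kind = "dose")
  carve_constraints(vol, structures, model)
}

# Hard constraint enforcement inside the OARs, standing in for the
# optimizer's max-dose and dose-volume constraints.
carve_constraints <- function(dose, structures, model) {
  vals <- dose$values
  for (lab in c("rectum", "bladder", "urethra")) {
    msk <- structures[[lab]]
    if (!any(msk$values)) next
    if (max(vals[msk$values]) > model$dmax_trigger) {
      # carve with a safety margin so the daily plan tolerates small
      # residual setup/mapping offsets (a planning-risk-volume margin)
      m <- if (model$carve_margin > 0)
        dilate_mask(msk, model$carve_margin)$values else msk$values
      sel <- m & vals > model$dmax_level
      vals[sel] <- model$dmax_level
    }
  }
  obj <- planning_objectives()
  for (lab in c("rectum", "bladder")) {
    m <- structures[[lab]]
    if (!any(m$values)) next
    lim <- obj$limit[obj$objective == paste0(lab, "_V56")]
    v56 <- volume_at_dose(compute_dvh(scalar_volume(vals, dose$grid,
                                                    kind = "dose"),
                                      m), 56)
    if (v56 >= model$v56_margin_frac * lim) {
      sel <- m$values & vals >= model$v56_level + 0.4
      vals[sel] <- model$v56_level
    }
  }
  scalar_volume(vals, dose$grid, kind = "dose")
}

#' Generate a reference case (anatomy + reference plan, no fractions)
#'
#' Builds the parametric pelvis anatomy, the PTV (CTV dilated by the
#' configured margins), a reference image with seeded smooth texture, and
#' an analytic reference dose tuned until [check_objectives()] passes on
#' all printed planning objectives.
#'
#' @param params A `phantom_params`.
#' @param patient_seed Integer seed for this patient.
#' @return An object of class `patient_case` with empty `fractions`.
#' @export
generate_reference_case <- function(params, patient_seed) {
  grid <- phantom_grid(params)
  structs <- phantom_masks(grid)
  structs$PTV <- dilate_mask(structs$CTV, params$ctv_margin_mm,
                             params$ctv_margin_dorsal_mm, label = "PTV")
  img <- phantom_image(grid, structs, seed = patient_seed)
  model <- default_plan_model(params)
  dose <- NULL
  for (it in 1:12) {
    dose <- plan_dose_on_anatomy(structs, model)
    chk <- check_objectives(extract_dvps(dose, structs))
    if (all(chk$pass)) break
    bad <- chk[!chk$pass, ]
    if ("CTV_D50" %in% bad$objective)
      model$plateau <- model$plateau +
        (60 - bad$value[bad$objective == "CTV_D50"]) + 0.1
    if ("CTV_D98" %in% bad$objective)
      model$edge_offset <- model$edge_offset + 0.4
    if (any(grepl("Dmax", bad$objective)))
      model$dmax_trigger <- model$dmax_trigger - 0.2
    if (it == 12)
      stop("reference plan tuner failed; violated: ",
           paste(bad$objective, collapse = ", "))
  }
  set.seed(patient_seed + 7L)
  drift <- stats::runif(1, params$prostate_drift_range[1],
                        params$prostate_drift_range[2])
  structure(list(ref_image = img, ref_structures = structs,
                 ref_dose = dose, fractions = list(),
                 plan_model = model, params = params,
                 drift_mm = c(0, drift, 0),
                 patient_seed = as.integer(patient_seed)),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %d fractions, ref dose max %.2f Gy\n",
              length(x$fractions), max(x$ref_dose$values)))
  invisible(x)
}

# Cached weight/component fields used by the fraction deformation sampler.
# The pull-back field of a fraction is a linear combination of these:
#   u_a = -shift_a * g_shift + (1/lam_bla - 1) * B_bla_a
#                            + (1/lam_rec - 1) * B_rec_a
anatomy_fields <- function(case) {
  if (!is.null(case$cache)) return(case$cache)
  grid <- case$ref_image$grid
  s <- case$params$deformation_smoothness
  sh <- grid$shape
  L <- phantom_layout()
  d_ctv <- pmax(signed_distance(case$ref_structures$CTV)$values, 0)
  d_rec <- signed_distance(case$ref_structures$rectum)$values
  d_bla <- signed_distance(case$ref_structures$bladder)$values
  # prostate motion weight: rigid inside the CTV and its vicinity
  g_shift <- ramp01(d_ctv, 6, 6 + 1.5 * s)
  # partial transmission into rectal tissue (the prostate slides along the
  # anterior rectal wall; the lumen follows only partially)
  cw <- case$params$rectal_wall_coupling
  depth <- pmax(-d_rec, 0)
  att <- 1 - (1 - cw) * pmin(depth / 4, 1)
  att <- gaussian_smooth(array(att, sh), 2, grid)
  g_shift <- g_shift * att
  # protection of the target region from organ scaling fields
  g_protect <- ramp01(d_ctv, 4, 4 + 0.7 * s)
  h_bla <- ramp01(d_bla, 2, 2 + s) * (1 - g_protect)
  h_rec <- ramp01(d_rec, 2, 2 + s) * (1 - g_protect)
  x <- grid_axis_world(grid, 1); y <- grid_axis_world(grid, 2)
  z <- grid_axis_world(grid, 3)
  X <- array(x, sh)
  Y <- array(rep(y, each = sh[1]), sh)
  Z <- array(rep(z, each = sh[1] * sh[2]), sh)
  B_bla <- array(0, c(sh, 3))
  B_bla[, , , 1] <- (X - L$bla_base[1]) * h_bla
  B_bla[, , , 2] <- (Y - L$bla_base[2]) * h_bla
  B_bla[, , , 3] <- (Z - L$bla_base[3]) * h_bla
  B_rec <- array(0, c(sh, 3))
  B_rec[, , , 1] <- (X - L$rec_c[1]) * h_rec
  B_rec[, , , 2] <- (Y - L$rec_c[2]) * h_rec
  # cropped evaluation subsets for organ-volume calibration
  sub_of <- function(mask) {
    bb <- mask_world_bbox(mask)
    inside <- X >= bb[1, 1] - 22 & X <= bb[2, 1] + 22 &
      Y >= bb[1, 2] - 22 & Y <= bb[2, 2] + 22 &
      Z >= bb[1, 3] - 22 & Z <= bb[2, 3] + 22
    which(inside)
  }
  base <- field_base_voxels(grid)
  mk_sub <- function(organ) {
    idx <- sub_of(case$ref_structures[[organ]])
    list(idx = idx, base = base[idx, , drop = FALSE],
         g = g_shift[idx],
         Bb = cbind(B_bla[, , , 1][idx], B_bla[, , , 2][idx],
                    B_bla[, , , 3][idx]),
         Br = cbind(B_rec[, , , 1][idx], B_rec[, , , 2][idx], 0))
  }
  list(g_shift = g_shift, B_bla = B_bla, B_rec = B_rec,
       sub = list(bladder = mk_sub("bladder"), rectum = mk_sub("rectum")),
       ref_vol_bla = mask_volume_cm3(case$ref_structures$bladder),
       ref_vol_rec = mask_volume_cm3(case$ref_structures$rectum))
}

# Build the pull-back displacement field for a fraction: the fraction
# volume at x equals the reference sampled at x + u(x).
build_fraction_field <- function(case, shift, lam_bla, lam_rec, cache) {
  grid <- case$ref_image$grid
  sh <- grid$shape
  u <- array(0, c(sh, 3))
  fb <- 1 / lam_bla - 1
  fr <- 1 / lam_rec - 1
  for (a in 1:3) {
    ua <- -shift[a] * cache$g_shift
    if (fb != 0) ua <- ua + fb * cache$B_bla[, , , a]
    if (fr != 0 && a < 3) ua <- ua + fr * cache$B_rec[, , , a]
    u[, , , a] <- ua
  }
  vector_field(u, grid)
}

# Voxelised volume (cm^3) of a warped organ, evaluated only on the cached
# cropped subset around the organ.
measure_warped_volume <- function(case, organ, shift, lam_bla, lam_rec,
                                  cache) {
  s <- cache$sub[[organ]]
  g <- case$ref_image$grid
  fb <- 1 / lam_bla - 1
  fr <- 1 / lam_rec - 1
  vox <- s$base
  for (a in 1:3) {
    ua <- -shift[a] * s$g + fb * s$Bb[, a] + fr * s$Br[, a]
    vox[, a] <- vox[, a] + ua / g$spacing[a]
  }
  m <- case$ref_structures[[organ]]$values
  hit <- c_interp3(as.double(m), dim(m), vox[, 1], vox[, 2], vox[, 3],
                   0, 1L)
  sum(hit != 0) * voxel_volume_mm3(g) / 1000
}

#' Sample the anatomy of one treatment fraction
#'
#' Draws a prostate shift (per-patient systematic posterior drift plus an
#' isotropic Gaussian residual), daily bladder and rectum volumes (uniform
#' in the configured ranges, achieved by calibrated radial scaling about
#' the bladder base / rectal axis), composes them into one smooth
#' displacement field, verifies invertibility via the Jacobian determinant,
#' and warps the reference image and structures into the fraction frame.
#' The ground-truth field is stored on the record.
#'
#' @param case A `patient_case` from [generate_reference_case()].
#' @param index Fraction index in `1..n_fractions`.
#' @param params A `phantom_params`.
#' @param seed Integer seed for this fraction.
#' @return A `fraction_record` with anatomy and `gt_dvf_ref_to_fx` (doses
#'   not yet filled).
#' @export
sample_fraction_anatomy <- function(case, index, params, seed) {
  if (index < 1 || index > params$n_fractions)
    stop("fraction index out of range")
  cache <- anatomy_fields(case)
  grid <- case$ref_image$grid
  for (attempt in 0:4) {
    set.seed(seed + attempt * 99991L)
    shift <- case$drift_mm + stats::rnorm(3, 0, params$prostate_shift_sd)
    vb <- stats::runif(1, params$bladder_volume_range[1],
                       params$bladder_volume_range[2])
    vr <- stats::runif(1, params$rectum_volume_range[1],
                       params$rectum_volume_range[2])
    lam_bla <- calibrate_scale(case, shift, vb, cache, organ = "bladder")
    lam_rec <- calibrate_scale(case, shift, vr, cache, organ = "rectum",
                               lam_bla = lam_bla)
    dvf <- build_fraction_field(case, shift, lam_bla, lam_rec, cache)
    jmin <- min(jacobian_determinant(dvf)$values)
    if (jmin > 0.05) break
    if (attempt == 4)
      stop("could not sample an invertible fraction deformation")
  }
  structs <- lapply(case$ref_structures[c("CTV", "rectum", "bladder",
                                          "urethra")],
                    apply_field_to_mask, dvf = dvf)
  structs <- resolve_mask_overlap(structs)
  structs$PTV <- dilate_mask(structs$CTV, params$ctv_margin_mm,
                             params$ctv_margin_dorsal_mm, label = "PTV")
  img <- warp_volume(case$ref_image, dvf, fill = 30)
  if (params$image_noise_sd > 0)
    img$values <- img$values +
      stats::rnorm(length(img$values), 0, params$image_noise_sd)
  structure(list(index = as.integer(index), image = img,
                 structures = structs, gt_dvf_ref_to_fx = dvf,
                 applied_shift = shift,
                 bladder_volume_cm3 = vb, rectum_volume_cm3 = vr),
            class = "fraction_record")
}

#' @export
print.fraction_record <- function(x, ...) {
  cat(sprintf("<fraction_record #%d> shift (%.1f, %.1f, %.1f) mm%s\n",
              x$index, x$applied_shift[1], x$applied_shift[2],
              x$applied_shift[3],
              if (is.null(x$dose_oa)) "" else ", doses filled"))
  invisible(x)
}

# Calibrate the radial scale factor so the voxelised warped organ volume
# matches the drawn target (secant refinement; voxelisation would
# otherwise bias the endpoint draws out of the configured range).
calibrate_scale <- function(case, shift, target_cm3, cache,
                            organ = c("bladder", "rectum"), lam_bla = 1) {
  organ <- match.arg(organ)
  ref_v <- if (organ == "bladder") cache$ref_vol_bla else cache$ref_vol_rec
  if (abs(target_cm3 - ref_v) / ref_v < 0.015) return(1)
  guess <- function(lam, v) lam * if (organ == "bladder")
    (target_cm3 / v)^(1 / 3) else sqrt(target_cm3 / v)
  measure <- function(lam) {
    if (organ == "bladder")
      measure_warped_volume(case, organ, shift, lam, 1, cache)
    else measure_warped_volume(case, organ, shift, lam_bla, lam, cache)
  }
  lam1 <- guess(1, ref_v)
  v1 <- measure(lam1)
  lam2 <- guess(lam1, v1)
  for (i in 1:3) {
    v2 <- measure(lam2)
    if (abs(v2 - target_cm3) / target_cm3 < 0.008) return(lam2)
    if (abs(v2 - v1) < 1e-6) break
    lam3 <- lam2 + (target_cm3 - v2) * (lam2 - lam1) / (v2 - v1)
    lam1 <- lam2; v1 <- v2
    lam2 <- max(0.5, min(2, lam3))
  }
  lam2
}

#' Generate the two arms' fraction doses for a sampled fraction
#'
#' The online-adaptive (OA) arm re-evaluates the analytic plan model on the
#' fraction's own anatomy (daily PTV, daily OAR constraints) — the daily
#' re-planning surrogate. The conventional-IGRT arm translates the
#' reference plan dose by the translation found by
#' [rigid_translate_register()] between the reference and fraction images
#' (the couch-correction simulation). Both are scaled to one fraction.
#'
#' @param case A `patient_case`.
#' @param fx A `fraction_record` from [sample_fraction_anatomy()].
#' @param params A `phantom_params`.
#' @return The `fraction_record` with `dose_oa`, `dose_conv` and
#'   `found_shift` filled.
#' @export
generate_fraction_doses <- function(case, fx, params) {
  total_oa <- plan_dose_on_anatomy(fx$structures, case$plan_model)
  fx$dose_oa <- scalar_volume(total_oa$values / params$n_fractions,
                              total_oa$grid, kind = "dose")
  tr <- rigid_translate_register(case$ref_image, fx$image,
                                 case$ref_structures$CTV)
  fx$found_shift <- tr
  conv <- translate_volume(case$ref_dose, tr)
  fx$dose_conv <- scalar_volume(conv$values / params$n_fractions,
                                conv$grid, kind = "dose")
  fx
}

#' Generate one complete patient case
#'
#' @param params A `phantom_params`.
#' @param patient_seed Integer seed for this patient.
#' @return A `patient_case` with `n_fractions` complete fraction records.
#' @export
generate_patient_case <- function(params, patient_seed) {
  case <- generate_reference_case(params, patient_seed)
  case$cache <- anatomy_fields(case)
  set.seed(patient_seed)
  fx_seeds <- sample.int(.Machine$integer.max %/% 2, params$n_fractions)
  case$fractions <- lapply(seq_len(params$n_fractions), function(i) {
    fx <- sample_fraction_anatomy(case, i, params, fx_seeds[i])
    generate_fraction_doses(case, fx, params)
  })
  case
}

#' Generate the full synthetic cohort
#'
#' Per-patient seeds are derived deterministically from the master seed,
#' so the cohort is a pure function of its parameters. Note that a full
#' default cohort holds 200 fraction records in memory; for cohort-level
#' analyses prefer the streaming driver [run_cohort_analysis()].
#'
#' @param params A `phantom_params`.
#' @return List of `patient_case` objects.
#' @export
generate_cohort <- function(params) {
  lapply(patient_seeds(params), function(s)
    generate_patient_case(params, s))
}

patient_seeds <- function(params) {
  set.seed(params$seed)
  sample.int(.Machine$integer.max %/% 2, params$n_patients)
}
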