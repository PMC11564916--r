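# Registration: translation-only rigid registration (the conventional-IGRT
# couch-correction simulation) and a structure-guided multi-resolution
# demons deformable registration producing the pull-back displacement
# field used for dose mapping.

#' Translate a volume rigidly
#'
#' Returns the volume resampled so that the content appears shifted by
#' `t_mm` (world mm): output(x) = input(x - t_mm). An exactly zero
#' translation returns the input values unchanged.
#'
#' @param vol A `scalar_volume`.
#' @param t_mm Numeric length-3 translation in mm.
#' @param fill Out-of-field fill value.
#' @return A `scalar_volume` on the same grid.
#' @export
translate_volume <- function(vol, t_mm, fill = 0) {
  if (all(t_mm == 0)) return(vol)
  g <- vol$grid
  pts <- sweep(grid_points_world(g), 2, as.numeric(t_mm), "-")
  vals <- interp_at_voxel(vol$values, world_to_voxel(g, pts), fill,
                          "trilinear")
  if (vol$kind == "dose") vals <- pmax(vals, 0)
  scalar_volume(array(vals, g$shape), g, kind = vol$kind)
}

#' Translation-only rigid registration
#'
#' Finds the world translation `T` (mm, moving-frame to fixed-frame, i.e.
#' `fixed(x) ~ moving(x - T)`) minimising the mean squared intensity
#' difference inside the axis-aligned bounding box of `bbox_mask` dilated
#' by `margin_mm`, evaluated on the fixed grid. Exhaustive coarse search
#' on a `step_mm` lattice within `search_mm`, then per-axis golden-section
#' refinement. Rotations are excluded by contract. Ties are broken towards
#' the smallest-magnitude translation, so identical images return exactly
#' zero.
#'
#' @param moving,fixed `scalar_volume`s (intensity images).
#' @param bbox_mask A nonempty `structure_mask` defining the evaluation
#'   region (e.g. the CTV).
#' @param search_mm Half-width of the coarse search per axis, mm.
#' @param step_mm Coarse lattice step, mm.
#' @param margin_mm Dilation of the bounding box, mm.
#' @param refine_tol Golden-section tolerance, mm.
#' @return Numeric length-3 translation in mm (class `translation3`).
#' @export
rigid_translate_register <- function(moving, fixed, bbox_mask,
                                     search_mm = 15, step_mm = 3,
                                     margin_mm = 10, refine_tol = 0.02) {
  if (!any(bbox_mask$values)) stop("empty bounding-box mask")
  gf <- fixed$grid
  ext <- mask_world_bbox(bbox_mask)
  lo <- ext[1, ] - margin_mm
  hi <- ext[2, ] + margin_mm
  vlo <- pmax(floor(world_to_voxel(gf, rbind(lo))[1, ]), 0)
  vhi <- pmin(ceiling(world_to_voxel(gf, rbind(hi))[1, ]), gf$shape - 1)
  ii <- seq(vlo[1], vhi[1]); jj <- seq(vlo[2], vhi[2])
  kk <- seq(vlo[3], vhi[3])
  fvals <- fixed$values[ii + 1, jj + 1, kk + 1]
  if (stats::sd(fvals) == 0)
    stop("degenerate input: zero-variance image region")
  idx <- as.matrix(expand.grid(ii, jj, kk))
  pts <- voxel_to_world(gf, idx)
  f <- as.vector(fvals)
  gm <- moving$grid
  # moving-frame voxel coordinates of the evaluation points at T = 0; a
  # world translation then only shifts these by R' T / spacing
  vx0 <- world_to_voxel(gm, pts)
  # coarse stage uses a strided subset of the points for speed
  sub <- seq(1, nrow(vx0), by = 3)
  vx0_sub <- vx0[sub, , drop = FALSE]
  f_sub <- f[sub]
  mvals <- as.double(moving$values)
  mdim <- dim(moving$values)
  msd_at <- function(t3, vx, fv) {
    tv <- (t3 %*% gm$direction)[1, ] / gm$spacing
    m <- c_interp3(mvals, mdim, vx[, 1] - tv[1], vx[, 2] - tv[2],
                   vx[, 3] - tv[3], NA_real_, 0L)
    ok <- !is.na(m)
    if (!any(ok)) return(Inf)
    mean((m[ok] - fv[ok])^2)
  }
  metric_core <- function(t3, coarse) {
    if (coarse) msd_at(t3, vx0_sub, f_sub) else msd_at(t3, vx0, f)
  }
  metric <- function(t3) metric_core(t3, FALSE)
  offs <- seq(-search_mm, search_mm, by = step_mm)
  best <- c(0, 0, 0); bestv <- metric_core(best, TRUE)
  for (dz in offs) for (dy in offs) for (dx in offs) {
    t3 <- c(dx, dy, dz)
    v <- metric_core(t3, TRUE)
    if (v < bestv * (1 - 1e-9) ||
        (abs(v - bestv) <= 1e-9 * max(bestv, 1e-12) &&
         sum(t3^2) < sum(best^2))) {
      best <- t3; bestv <- v
    }
  }
  bestv <- metric(best)
  refined <- best
  for (sweep_i in 1:2) for (a in 1:3) {
    lo_a <- refined[a] - step_mm; hi_a <- refined[a] + step_mm
    fa <- function(t) {
      tt <- refined; tt[a] <- t; metric(tt)
    }
    opt <- stats::optimize(fa, c(lo_a, hi_a), tol = refine_tol)
    refined[a] <- opt$minimum
  }
  vref <- metric(refined)
  cands <- list(c(0, 0, 0), best, refined)
  cvals <- c(metric(c(0, 0, 0)), bestv, vref)
  ord <- order(cvals + 1e-12 * sqrt(vapply(cands, function(t) sum(t^2), 0)))
  pick <- cands[[ord[1]]]
  # prefer strictly smaller translations on numerically equal metric
  for (i in seq_along(cands)) {
    if (cvals[i] <= cvals[ord[1]] * (1 + 1e-9) &&
        sum(cands[[i]]^2) < sum(pick^2))
      pick <- cands[[i]]
  }
  structure(pick, class = "translation3")
}

mask_world_bbox <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE) - 1
  w <- voxel_to_world(mask$grid, idx)
  rbind(apply(w, 2, min), apply(w, 2, max))
}

#' Configuration of the deformable registration surrogate
#'
#' @param pyramid_levels Number of multi-resolution levels (coarsest level
#'   downsampled by `2^(levels-1)`).
#' @param smoothing_sigma Field (diffusion) regularisation sigma, mm.
#' @param update_sigma Update (fluid) smoothing sigma, mm.
#' @param structure_weight Weight of each structure signed-distance channel
#'   relative to the intensity channel; 0 disables guidance.
#' @param max_iterations Iterations per level (scalar or per-level vector,
#'   coarsest first).
#' @param convergence_tol Stop when the mean update falls below this, mm.
#' @param step_max Maximum update magnitude per iteration, mm.
#' @return An object of class `dir_config`.
#' @export
dir_config <- function(pyramid_levels = 3, smoothing_sigma = 1.5,
                       update_sigma = 1.0, structure_weight = 2,
                       max_iterations = c(100, 60, 30),
                       convergence_tol = 0.02, step_max = 2.0) {
  stopifnot(pyramid_levels >= 1, smoothing_sigma > 0, update_sigma >= 0,
            structure_weight >= 0, all(max_iterations >= 1),
            convergence_tol > 0, step_max > 0)
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 smoothing_sigma = smoothing_sigma,
                 update_sigma = update_sigma,
                 structure_weight = structure_weight,
                 max_iterations = rep(as.integer(max_iterations),
                                      length.out = pyramid_levels),
                 convergence_tol = convergence_tol,
                 step_max = step_max),
            class = "dir_config")
}

downsample_grid <- function(grid, factor) {
  if (factor == 1) return(grid)
  shape <- pmax(as.integer(ceiling(grid$shape / factor)), 2L)
  grid_spec(shape, grid$spacing * factor, grid$origin, grid$direction)
}

resample_smooth <- function(vol, target, presigma) {
  v <- if (presigma > 0) gaussian_smooth(vol, presigma) else vol
  resample_to_grid(v, target, mode = "trilinear",
                   fill = v$values[1, 1, 1])
}

#' Structure-guided deformable registration (demons surrogate)
#'
#' Multi-resolution demons with an intensity channel plus one channel per
#' guidance structure: the mean-squared difference of (clamped, scaled)
#' signed distance transforms of corresponding masks, weighted by
#' `structure_weight`. Gaussian fluid/diffusion regularisation per
#' iteration. Returns the pull-back field on the fixed grid: the moving
#' volume sampled at `x + u(x)` aligns with the fixed volume.
#'
#' @param moving_img,fixed_img `scalar_volume` intensity images.
#' @param moving_structs,fixed_structs Named lists of `structure_mask`s
#'   sharing the guidance labels (CTV, bladder, rectum).
#' @param cfg A [dir_config()].
#' @param guidance_labels Structure labels used for guidance.
#' @return A `vector_field` on the fixed grid.
#' @export
deformable_register <- function(moving_img, fixed_img,
                                moving_structs = list(),
                                fixed_structs = list(),
                                cfg = dir_config(),
                                guidance_labels = c("CTV", "bladder",
                                                    "rectum")) {
  use_structs <- cfg$structure_weight > 0 && length(guidance_labels) > 0
  if (use_structs) {
    miss <- setdiff(guidance_labels,
                    intersect(names(moving_structs), names(fixed_structs)))
    if (length(miss))
      stop("missing guidance structure(s): ", paste(miss, collapse = ", "))
  }
  norm_img <- function(v) {
    s <- stats::sd(v$values)
    scalar_volume((v$values - mean(v$values)) / max(s, 1e-12), v$grid)
  }
  sdt_chan <- function(m) {
    sd <- signed_distance(m)$values
    scalar_volume(pmax(pmin(sd, 20), -20) / 10, m$grid)
  }
  fix_ch <- list(norm_img(fixed_img))
  mov_ch <- list(norm_img(moving_img))
  wts <- 1
  if (use_structs) {
    for (lab in guidance_labels) {
      fix_ch <- c(fix_ch, list(sdt_chan(fixed_structs[[lab]])))
      mov_ch <- c(mov_ch, list(sdt_chan(moving_structs[[lab]])))
      wts <- c(wts, cfg$structure_weight)
    }
  }
  gf_full <- fixed_img$grid
  u <- NULL
  converged <- FALSE
  for (lev in seq_len(cfg$pyramid_levels)) {
    factor <- 2^(cfg$pyramid_levels - lev)
    g <- downsample_grid(gf_full, factor)
    presig <- if (factor > 1) 0.5 * factor * mean(gf_full$spacing) else 0
    F_l <- lapply(fix_ch, resample_smooth, target = g, presigma = presig)
    M_l <- lapply(mov_ch, resample_smooth, target = g, presigma = presig)
    u <- if (is.null(u)) identity_field(g) else {
      vals <- array(0, c(g$shape, 3))
      for (a in 1:3)
        vals[, , , a] <- resample_to_grid(
          scalar_volume(u$values[, , , a], u$grid), g,
          mode = "trilinear")$values
      vector_field(vals, g)
    }
    base_pts <- grid_points_world(g)
    delta2 <- mean(g$spacing)^2
    for (it in seq_len(cfg$max_iterations[lev])) {
      pts <- base_pts + matrix(u$values, ncol = 3)
      upd <- matrix(0, nrow(pts), 3)
      for (ci in seq_along(F_l)) {
        vxm <- world_to_voxel(M_l[[ci]]$grid, pts)
        mw <- interp_at_voxel(M_l[[ci]]$values, vxm, 0, "trilinear")
        mw_arr <- array(mw, g$shape)
        gr <- c_grad3(as.double(mw_arr), g$shape, g$spacing)
        diffv <- mw - as.vector(F_l[[ci]]$values)
        den <- gr[, 1]^2 + gr[, 2]^2 + gr[, 3]^2 + diffv^2 / delta2
        fac <- ifelse(den > 1e-12, -diffv / den, 0)
        upd <- upd + wts[ci] * (gr * fac)
      }
      upd <- upd / sum(wts)
      mag <- sqrt(rowSums(upd^2))
      over <- mag > cfg$step_max
      if (any(over))
        upd[over, ] <- upd[over, ] * (cfg$step_max / mag[over])
      uf <- vector_field(array(upd, c(g$shape, 3)), g)
      if (cfg$update_sigma > 0) uf <- smooth_field(uf, cfg$update_sigma)
      u <- vector_field(u$values + uf$values, g)
      u <- smooth_field(u, cfg$smoothing_sigma)
      if (mean(mag) < cfg$convergence_tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    message("deformable_register: iteration budget reached at the finest ",
            "level without meeting the convergence tolerance")
  u
}

#' Dice overlap of two masks
#' @param a,b `structure_mask`s on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}
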