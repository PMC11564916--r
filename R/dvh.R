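# Cumulative dose-volume histograms, dose-volume parameters and the
# planning-objective checker. DVHs use a fixed 0.01 Gy bin width by
# default; Dmax is always the single hottest voxel, computed voxelwise and
# never read off the histogram.

#' Compute a cumulative dose-volume histogram
#'
#' Bins run from 0 to `ceiling(max dose)` with uniform `bin_width`.
#' `cumulative_volume[i]` is the percentage of the structure volume
#' receiving at least `bin_edges[i]`.
#'
#' @param dose A `scalar_volume` in Gy.
#' @param mask A nonempty `structure_mask` on the same grid.
#' @param bin_width Bin width in Gy (default 0.01).
#' @return An object of class `dvh` with fields `bin_edges`,
#'   `cumulative_volume`, `structure_label`, `voxel_volume_mm3`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01) {
  if (!grid_equal(dose$grid, mask$grid, tol = 1e-6))
    stop("dose and mask grids do not match")
  d <- dose$values[mask$values]
  if (length(d) == 0) stop("empty structure mask: ", mask$label)
  top <- max(ceiling(max(d)), bin_width)
  edges <- seq(0, top, by = bin_width)
  # voxels with dose >= edge; doses exactly on an edge count as receiving it
  counts <- length(d) -
    findInterval(edges, sort(d), left.open = TRUE)
  structure(list(bin_edges = edges,
                 cumulative_volume = 100 * counts / length(d),
                 structure_label = mask$label,
                 voxel_volume_mm3 = voxel_volume_mm3(dose$grid)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh:%s> %d bins of %.3g Gy, D50%%=%.2f Gy\n",
              x$structure_label, length(x$bin_edges),
              x$bin_edges[2] - x$bin_edges[1], dose_at_volume(x, 50)))
  invisible(x)
}

#' Dose received by at least q% of the structure (Dq%)
#'
#' The largest dose whose cumulative volume is still >= `q`, linearly
#' interpolated between histogram bins.
#'
#' @param dvh A `dvh`.
#' @param q Volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, q) {
  if (!is.finite(q) || q <= 0 || q > 100)
    stop("q must be in (0, 100]")
  v <- dvh$cumulative_volume
  e <- dvh$bin_edges
  idx <- which(v >= q)
  i <- idx[length(idx)]  # last bin still covering q% (v is non-increasing)
  if (i == length(e)) return(e[i])
  # interpolate within [e[i], e[i+1]] where volume drops from v[i] to v[i+1]
  if (v[i] == v[i + 1]) return(e[i])
  e[i] + (e[i + 1] - e[i]) * (v[i] - q) / (v[i] - v[i + 1])
}

#' Volume percentage receiving at least d Gy (VdGy)
#'
#' @param dvh A `dvh`.
#' @param d Dose in Gy (>= 0).
#' @return Volume percentage in [0, 100].
#' @export
volume_at_dose <- function(dvh, d) {
  if (!is.finite(d) || d < 0) stop("d must be a nonnegative dose")
  e <- dvh$bin_edges
  v <- dvh$cumulative_volume
  if (d >= e[length(e)]) return(v[length(v)] * (d == e[length(e)]))
  stats::approx(e, v, xout = d, rule = 2)$y
}

#' Maximum voxel dose inside a structure
#'
#' Computed voxelwise (single hottest voxel), independent of any histogram
#' binning.
#'
#' @param dose A `scalar_volume` in Gy.
#' @param mask A nonempty `structure_mask` on the same grid.
#' @return Dose in Gy.
#' @export
dmax <- function(dose, mask) {
  if (!grid_equal(dose$grid, mask$grid, tol = 1e-6))
    stop("dose and mask grids do not match")
  if (!any(mask$values)) stop("empty structure mask: ", mask$label)
  max(dose$values[mask$values])
}

#' The study's planning objectives
#'
#' CTV D50% >= 60 Gy and D98% >= 57 Gy; rectum, bladder and urethra
#' Dmax <= 61.0 Gy; rectum V56Gy < 13.5%; bladder V56Gy < 18.0%.
#'
#' @return A data frame with columns `objective`, `structure`, `metric`,
#'   `limit`, `direction` (`">="`, `"<="` or `"<"`).
#' @export
planning_objectives <- function() {
  data.frame(
    objective = c("CTV_D50", "CTV_D98", "rectum_Dmax", "bladder_Dmax",
                  "urethra_Dmax", "rectum_V56", "bladder_V56"),
    structure = c("CTV", "CTV", "rectum", "bladder", "urethra", "rectum",
                  "bladder"),
    metric = c("D50", "D98", "Dmax", "Dmax", "Dmax", "V56", "V56"),
    limit = c(60, 57, 61, 61, 61, 13.5, 18),
    direction = c(">=", ">=", "<=", "<=", "<=", "<", "<"),
    stringsAsFactors = FALSE)
}

#' Extract the study's dose-volume parameters for one dose distribution
#'
#' Computes CTV D50%/D98%, OAR Dmax, and rectum/bladder V56Gy from DVHs at
#' the given bin width (Dmax voxelwise).
#'
#' @param dose A `scalar_volume` in Gy (total course dose).
#' @param structures Named list of `structure_mask`s including CTV,
#'   rectum, bladder and urethra.
#' @param bin_width DVH bin width in Gy.
#' @return A data frame with columns `structure`, `metric`, `value`.
#' @export
extract_dvps <- function(dose, structures, bin_width = 0.01) {
  need <- c("CTV", "rectum", "bladder", "urethra")
  miss <- setdiff(need, names(structures))
  if (length(miss)) stop("missing structures: ", paste(miss, collapse = ", "))
  dv <- function(lab) compute_dvh(dose, structures[[lab]], bin_width)
  ctv <- dv("CTV"); rec <- dv("rectum"); bla <- dv("bladder")
  rows <- rbind(
    data.frame(structure = "CTV", metric = "D50",
               value = dose_at_volume(ctv, 50)),
    data.frame(structure = "CTV", metric = "D98",
               value = dose_at_volume(ctv, 98)),
    data.frame(structure = "CTV", metric = "Dmax",
               value = dmax(dose, structures$CTV)),
    data.frame(structure = "rectum", metric = "Dmax",
               value = dmax(dose, structures$rectum)),
    data.frame(structure = "bladder", metric = "Dmax",
               value = dmax(dose, structures$bladder)),
    data.frame(structure = "urethra", metric = "Dmax",
               value = dmax(dose, structures$urethra)),
    data.frame(structure = "rectum", metric = "V56",
               value = volume_at_dose(rec, 56)),
    data.frame(structure = "bladder", metric = "V56",
               value = volume_at_dose(bla, 56)))
  rows
}

#' Check a set of dose-volume parameters against the planning objectives
#'
#' @param dvps Data frame as returned by [extract_dvps()] (columns
#'   `structure`, `metric`, `value`).
#' @return The [planning_objectives()] table with added columns `value` and
#'   `pass`. Boundary values pass inclusive objectives (`>=`, `<=`) and
#'   fail strict ones (`<`).
#' @export
check_objectives <- function(dvps) {
  obj <- planning_objectives()
  obj$value <- NA_real_
  obj$pass <- NA
  for (r in seq_len(nrow(obj))) {
    hit <- dvps$structure == obj$structure[r] & dvps$metric == obj$metric[r]
    if (!any(hit))
      stop("missing DVP for objective ", obj$objective[r])
    v <- dvps$value[hit][1]
    obj$value[r] <- v
    obj$pass[r] <- switch(obj$direction[r],
                          ">=" = v >= obj$limit[r],
                          "<=" = v <= obj$limit[r],
                          "<" = v < obj$limit[r])
  }
  obj
}
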