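# EQD2 / gEUD / LKB NTCP radiobiology. The LKB pipeline used throughout:
# voxelwise EQD2 first, then the gEUD power-mean with volume parameter n,
# then the logistic dose-response. TD50 is the dose at which 50% of the
# population is expected to experience the complication and m the slope of
# the dose-response curve.

#' Radiobiological parameter set for an LKB endpoint
#'
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0).
#' @param TD50 50% complication dose in Gy (> 0).
#' @param m Slope parameter, in (0, 1].
#' @param n Volume parameter of the gEUD reduction, in (0, 1].
#' @param endpoint Free-text endpoint description.
#' @return An object of class `radiobio_params`.
#' @export
radiobio_params <- function(alpha_beta, TD50, m, n, endpoint = "") {
  stopifnot(alpha_beta > 0, TD50 > 0, m > 0, m <= 1, n > 0, n <= 1)
  structure(list(alpha_beta = alpha_beta, TD50 = TD50, m = m, n = n,
                 endpoint = endpoint),
            class = "radiobio_params")
}

#' Published LKB parameter sets used by the analysis
#'
#' Bladder incontinence G2+ (alpha/beta = 1.5 Gy, TD50 = 108.9 Gy,
#' m = 0.24, n = 0.02) and rectum late toxicity G2+ (alpha/beta = 3.0 Gy,
#' TD50 = 80.8 Gy, m = 0.15, n = 0.12).
#'
#' @param organ `"bladder"` or `"rectum"`.
#' @return A `radiobio_params` object.
#' @export
lkb_presets <- function(organ = c("bladder", "rectum")) {
  organ <- match.arg(organ)
  switch(organ,
         bladder = radiobio_params(1.5, 108.9, 0.24, 0.02,
                                   "bladder incontinence G2+"),
         rectum = radiobio_params(3.0, 80.8, 0.15, 0.12,
                                  "rectum late toxicity G2+"))
}

#' Voxelwise EQD2 transform
#'
#' Linear-quadratic equivalent dose in 2 Gy fractions for a uniformly
#' fractionated course: `EQD2 = D * (d + ab) / (2 + ab)` with per-voxel
#' fraction dose `d = D / n_fractions`.
#'
#' @param total_dose A `scalar_volume` (total course dose, Gy) or numeric
#'   vector/array.
#' @param n_fractions Number of fractions (>= 1).
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0).
#' @return Same type as `total_dose`, in Gy EQD2.
#' @export
eqd2_transform <- function(total_dose, n_fractions, alpha_beta) {
  if (!is.finite(alpha_beta) || alpha_beta <= 0)
    stop("alpha_beta must be positive")
  stopifnot(n_fractions >= 1)
  f <- function(D) D * (D / n_fractions + alpha_beta) / (2 + alpha_beta)
  if (inherits(total_dose, "scalar_volume"))
    scalar_volume(f(total_dose$values), total_dose$grid, kind = "dose")
  else f(total_dose)
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' Power mean over in-mask voxels: `(mean(EQD2^(1/n)))^n`. `n = 1` gives
#' the mean dose; as `n -> 0` the gEUD approaches the maximum voxel dose.
#'
#' @param eqd2_dose A `scalar_volume` of voxelwise EQD2 (Gy), or a numeric
#'   vector of in-mask EQD2 values (then `mask` may be omitted).
#' @param mask A nonempty `structure_mask` (required for volumes).
#' @param n Volume parameter in (0, 1].
#' @return gEUD in Gy.
#' @export
geud <- function(eqd2_dose, mask = NULL, n) {
  if (!is.finite(n) || n <= 0 || n > 1) stop("n must be in (0, 1]")
  d <- if (inherits(eqd2_dose, "scalar_volume")) {
    if (is.null(mask)) stop("mask required")
    if (!any(mask$values)) stop("empty structure mask")
    eqd2_dose$values[mask$values]
  } else as.numeric(eqd2_dose)
  if (length(d) == 0) stop("no voxels to reduce")
  # compute on a log scale relative to the max to avoid overflow at small n
  dm <- max(d)
  if (dm == 0) return(0)
  dm * mean((d / dm)^(1 / n))^n
}

#' LKB NTCP from a gEUD-reduced EQD2
#'
#' Logistic Lyman-Kutcher-Burman form:
#' `NTCP = 1 / (1 + exp(-(EQD2 - TD50) / (m * TD50)))`, so that the NTCP at
#' `EQD2 = TD50` is exactly 0.5.
#'
#' @param geud_eqd2 gEUD-reduced EQD2 in Gy.
#' @param params A `radiobio_params` object.
#' @return An object of class `ntcp_result` with fields `ntcp`,
#'   `geud_eqd2`, `params`.
#' @export
lkb_ntcp <- function(geud_eqd2, params) {
  stopifnot(inherits(params, "radiobio_params"))
  t <- (geud_eqd2 - params$TD50) / (params$m * params$TD50)
  structure(list(ntcp = stats::plogis(t), geud_eqd2 = geud_eqd2,
                 params = params),
            class = "ntcp_result")
}

#' @export
print.ntcp_result <- function(x, ...) {
  cat(sprintf("<ntcp> %s: gEUD-EQD2 = %.2f Gy, NTCP = %.4f\n",
              x$params$endpoint, x$geud_eqd2, x$ntcp))
  invisible(x)
}

#' Full LKB pipeline from a total dose distribution
#'
#' Voxelwise EQD2, gEUD reduction over the structure, then the logistic
#' dose-response.
#'
#' @param total_dose A `scalar_volume`, total course dose in Gy.
#' @param mask A nonempty `structure_mask`.
#' @param n_fractions Number of fractions delivered.
#' @param params A `radiobio_params` object.
#' @return An `ntcp_result`.
#' @export
ntcp_from_dose <- function(total_dose, mask, n_fractions, params) {
  eq <- eqd2_transform(total_dose, n_fractions, params$alpha_beta)
  lkb_ntcp(geud(eq, mask, params$n), params)
}
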