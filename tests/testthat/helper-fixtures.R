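# Shared fixtures. Most unit tests run on a coarse 4 mm phantom grid to
# keep the suite fast; the acceptance tests use the default 2 mm study
# grid. Expensive fixtures are memoised per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

small_params <- function(...) {
  phantom_params(grid_spacing = 4, grid_shape = c(40, 40, 40), ...)
}

# params with all anatomical variation switched off; organ volume ranges
# collapse onto the measured reference volumes of `case`
zero_variation_params <- function(params, case) {
  vb <- mask_volume_cm3(case$ref_structures$bladder)
  vr <- mask_volume_cm3(case$ref_structures$rectum)
  params$bladder_volume_range <- c(vb, vb)
  params$rectum_volume_range <- c(vr, vr)
  params$prostate_shift_sd <- 0
  params$prostate_drift_range <- c(0, 0)
  params$image_noise_sd <- 0
  params
}

# study-condition fixtures (2 mm default grid), memoised
acceptance_case <- function() {
  memo("acceptance_case", {
    case <- generate_reference_case(phantom_params(), 101L)
    case$cache <- ddacc:::anatomy_fields(case)
    case
  })
}

acceptance_cohort <- function() {
  memo("acceptance_cohort",
       run_cohort_analysis(phantom_params(), method = "gt"))
}

small_case <- function() {
  memo("small_case", {
    case <- generate_reference_case(small_params(), 7L)
    case$cache <- ddacc:::anatomy_fields(case)
    case
  })
}

# a simple smooth test image on an arbitrary grid (sum of gaussian blobs)
blob_image <- function(grid, centres = rbind(c(0, 0, 0)), amp = 100,
                       sigma = 15, base = 10) {
  pts <- ddacc:::grid_points_world(grid)
  v <- rep(base, nrow(pts))
  for (r in seq_len(nrow(centres))) {
    d2 <- rowSums(sweep(pts, 2, centres[r, ], "-")^2)
    v <- v + amp * exp(-d2 / (2 * sigma^2))
  }
  scalar_volume(array(v, grid$shape), grid, kind = "image")
}

# brute-force Dq% from raw in-mask doses: the largest dose received by at
# least q% of the voxels
brute_dq <- function(doses, q) {
  n <- length(doses)
  cand <- sort(unique(doses))
  ok <- vapply(cand, function(d) mean(doses >= d) >= q / 100, TRUE)
  if (!any(ok)) return(min(doses))
  max(cand[ok])
}

brute_vd <- function(doses, d) 100 * mean(doses >= d)

# independent enumeration oracle: two-sided exact signed-rank p value
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  wall <- as.matrix(signs) %*% r
  min(1, 2 * min(mean(wall <= w + 1e-9), mean(wall >= w - 1e-9)))
}
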