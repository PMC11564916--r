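# Spatial containers, NIfTI round-trips, and grid resampling.

test_that("grid_spec validates its geometry", {
  expect_error(grid_spec(c(10, 10, 10), c(0, 1, 1)), "spacing")
  expect_error(grid_spec(c(0, 10, 10), c(1, 1, 1)), "shape")
  expect_error(grid_spec(c(5, 5, 5), c(1, 1, 1),
                         direction = matrix(2 * diag(3), 3)),
               "orthonormal")
  g <- grid_spec(c(5, 6, 7), c(1, 2, 3), origin = c(-1, 0, 4))
  expect_equal(voxel_volume_mm3(g), 6)
  w <- voxel_to_world(g, rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(w[1, ], c(-1, 0, 4))
  expect_equal(w[2, ], c(0, 2, 7))
  expect_equal(world_to_voxel(g, w), rbind(c(0, 0, 0), c(1, 1, 1)))
})

test_that("volumes round-trip through NIfTI with exact values and geometry", {
  dir <- withr::local_tempdir()
  g <- grid_spec(c(10, 10, 10), c(3, 3, 3), origin = c(-13.5, -13.5, -13.5))
  vol <- scalar_volume(array(0, c(10, 10, 10)), g)
  p <- file.path(dir, "zeros.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_identical(back$values, vol$values)
  expect_equal(back$grid$spacing, c(3, 3, 3), tolerance = 1e-6)
  expect_equal(back$grid$origin, g$origin, tolerance = 1e-6)

  set.seed(1)
  vol2 <- scalar_volume(array(rnorm(1000), c(10, 10, 10)), g)
  write_volume(vol2, p)  # overwrite succeeds
  expect_equal(read_volume(p)$values, vol2$values)

  expect_error(write_volume(vol, file.path(dir, "nope", "x.nii.gz")),
               "directory")
  expect_error(read_volume(file.path(dir, "missing.nii.gz")), "no such")
})

test_that("reading a 4-D NIfTI is rejected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "fourd.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p)
  expect_error(read_volume(p), "expected 3-D")
})

test_that("a non-identity orientation survives the round-trip", {
  dir <- withr::local_tempdir()
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  g <- grid_spec(c(6, 6, 6), c(2, 2, 2), origin = c(1, 2, 3), direction = R)
  vol <- scalar_volume(array(seq_len(216), c(6, 6, 6)), g)
  p <- file.path(dir, "rot.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_equal(back$grid$direction, R, tolerance = 1e-6)
  expect_equal(back$grid$origin, c(1, 2, 3), tolerance = 1e-5)
  expect_identical(back$values, vol$values)
})

test_that("masks and vector fields round-trip through NIfTI", {
  dir <- withr::local_tempdir()
  g <- grid_spec(c(8, 8, 8), c(2, 2, 2), origin = rep(-7, 3))
  set.seed(2)
  m <- structure_mask(array(runif(512) < 0.3, c(8, 8, 8)), g, "rectum")
  pm <- file.path(dir, "m.nii.gz")
  write_structure_mask(m, pm)
  back <- read_structure_mask(pm, "rectum")
  expect_identical(back$values, m$values)
  expect_identical(back$label, "rectum")

  f <- vector_field(array(rnorm(512 * 3), c(8, 8, 8, 3)), g)
  write_vector_field(f, file.path(dir, "field"))
  fb <- read_vector_field(file.path(dir, "field"))
  expect_equal(fb$values, f$values, tolerance = 1e-12)
})

test_that("resampling is exact for identity, constants and linear ramps", {
  g <- grid_spec(c(12, 12, 12), c(2, 2, 2), origin = rep(-11, 3))
  set.seed(3)
  vol <- scalar_volume(array(rnorm(12^3), c(12, 12, 12)), g)
  same <- resample_to_grid(vol, g)
  expect_lt(max(abs(same$values - vol$values)), 1e-9)

  const <- scalar_volume(array(7, c(12, 12, 12)), g)
  g2 <- grid_spec(c(10, 10, 10), c(2.3, 2.3, 2.3), origin = rep(-9, 3))
  r <- resample_to_grid(const, g2)
  pts <- ddacc:::grid_points_world(g2)
  infield <- apply(abs(pts) <= 11, 1, all)
  expect_true(all(abs(r$values[array(infield, g2$shape)] - 7) < 1e-12))

  # affine scalar field reproduced exactly at half spacing
  pts1 <- ddacc:::grid_points_world(g)
  ramp <- scalar_volume(array(2 * pts1[, 1] - pts1[, 2] + 0.5 * pts1[, 3],
                              g$shape), g)
  gh <- grid_spec(c(16, 16, 16), c(1, 1, 1), origin = rep(-8, 3))
  rh <- resample_to_grid(ramp, gh)
  ptsh <- ddacc:::grid_points_world(gh)
  expect_lt(max(abs(rh$values -
                      array(2 * ptsh[, 1] - ptsh[, 2] + 0.5 * ptsh[, 3],
                            gh$shape))), 1e-6)

  far <- grid_spec(c(4, 4, 4), c(1, 1, 1), origin = c(500, 500, 500))
  expect_error(resample_to_grid(vol, far), "overlap")
})

test_that("mask resampling stays binary under nearest-neighbour", {
  g <- grid_spec(c(10, 10, 10), c(3, 3, 3), origin = rep(-13.5, 3))
  set.seed(4)
  m <- structure_mask(array(runif(1000) < 0.4, c(10, 10, 10)), g, "CTV")
  g2 <- grid_spec(c(14, 14, 14), c(2.1, 2.1, 2.1), origin = rep(-13, 3))
  r <- resample_to_grid(m, g2)
  expect_true(is.logical(r$values))
  expect_s3_class(r, "structure_mask")
})

test_that("a patient case survives the on-disk layout round-trip", {
  dir <- withr::local_tempdir()
  p <- small_params(n_fractions = 2L, dose_per_fraction = 30)
  case <- generate_reference_case(p, 3L)
  case$cache <- ddacc:::anatomy_fields(case)
  fx <- sample_fraction_anatomy(case, 1, p, 99L)
  fx <- generate_fraction_doses(case, fx, p)
  case$fractions <- list(fx)
  write_patient_case(case, file.path(dir, "pat01"))
  back <- read_patient_case(file.path(dir, "pat01"))
  expect_equal(back$ref_dose$values, case$ref_dose$values,
               tolerance = 1e-12)
  expect_identical(back$ref_structures$CTV$values,
                   case$ref_structures$CTV$values)
  expect_equal(back$fractions[[1]]$gt_dvf_ref_to_fx$values,
               fx$gt_dvf_ref_to_fx$values, tolerance = 1e-12)
  expect_equal(back$fractions[[1]]$dose_oa$values, fx$dose_oa$values,
               tolerance = 1e-12)
  expect_equal(back$fractions[[1]]$applied_shift, fx$applied_shift,
               tolerance = 1e-9)
})
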