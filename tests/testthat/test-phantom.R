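# Synthetic cohort generator: reference plan feasibility, determinism,
# per-fraction anatomical variation and the two arms' fraction doses.
# Unit tests run on the coarse 4 mm grid.

test_that("the seeded reference plan satisfies every planning objective", {
  case <- small_case()
  chk <- check_objectives(extract_dvps(case$ref_dose, case$ref_structures))
  expect_true(all(chk$pass))
  s <- case$ref_structures
  expect_gt(sum(s$CTV$values), 0)
  expect_true(all(!s$CTV$values | s$PTV$values))  # CTV inside PTV
  # pairwise disjoint except CTV-in-PTV and urethra-in-CTV
  expect_false(any(s$CTV$values & s$rectum$values))
  expect_false(any(s$CTV$values & s$bladder$values))
  expect_false(any(s$rectum$values & s$bladder$values))
  expect_true(all(!s$urethra$values | s$CTV$values))
  for (lab in names(s)) expect_gt(sum(s[[lab]]$values), 0)
})

test_that("reference-case generation is deterministic in its seed", {
  p <- small_params()
  a <- generate_reference_case(p, 13L)
  b <- generate_reference_case(p, 13L)
  expect_identical(a$ref_dose$values, b$ref_dose$values)
  expect_identical(a$ref_image$values, b$ref_image$values)
  expect_identical(a$ref_structures$bladder$values,
                   b$ref_structures$bladder$values)
  expect_identical(a$drift_mm, b$drift_mm)
})

test_that("zero-variance configuration degenerates to the identity", {
  case <- small_case()
  p0 <- zero_variation_params(small_params(), case)
  case0 <- case
  case0$params <- p0
  case0$drift_mm <- c(0, 0, 0)
  fx <- sample_fraction_anatomy(case0, 3, p0, 123L)
  expect_lt(field_max_mm(fx$gt_dvf_ref_to_fx), 1e-6)
  expect_identical(fx$structures$CTV$values,
                   case$ref_structures$CTV$values)
  fx <- generate_fraction_doses(case0, fx, p0)
  ref_fx <- case$ref_dose$values / p0$n_fractions
  expect_lt(max(abs(fx$dose_oa$values - ref_fx)), 1e-6)
  expect_lt(max(abs(fx$dose_conv$values - ref_fx)), 1e-6)
})

test_that("sampled fraction anatomy honours the configured variation", {
  case <- small_case()
  p <- small_params()
  for (seed in c(21L, 22L)) {
    fx <- sample_fraction_anatomy(case, 1, p, seed)
    vb <- mask_volume_cm3(fx$structures$bladder)
    # configured range, with a voxelisation allowance (the generator
    # calibrates the continuous scale to < 1%)
    expect_gte(vb, p$bladder_volume_range[1] * 0.97)
    expect_lte(vb, p$bladder_volume_range[2] * 1.03)
    # invertible ground-truth deformation
    jmin <- min(jacobian_determinant(fx$gt_dvf_ref_to_fx)$values)
    expect_gt(jmin, 0)
  }
})

test_that("CTV volume is preserved when only the organs at risk vary", {
  case <- small_case()
  p <- small_params()
  p$prostate_shift_sd <- 0
  p$prostate_drift_range <- c(0, 0)
  case0 <- case
  case0$params <- p
  case0$drift_mm <- c(0, 0, 0)
  fx <- sample_fraction_anatomy(case0, 1, p, 77L)
  v_ref <- mask_volume_cm3(case$ref_structures$CTV)
  v_fx <- mask_volume_cm3(fx$structures$CTV)
  expect_lt(abs(v_fx - v_ref) / v_ref, 0.05)
})

test_that("fraction doses satisfy the daily coverage objective and energy sanity", {
  case <- small_case()
  p <- small_params()
  fx <- sample_fraction_anatomy(case, 2, p, 31L)
  fx <- generate_fraction_doses(case, fx, p)
  total_oa <- scalar_volume(fx$dose_oa$values * p$n_fractions,
                            fx$dose_oa$grid, kind = "dose")
  dvh <- compute_dvh(total_oa, fx$structures$CTV)
  expect_gte(dose_at_volume(dvh, 98), 57)
  # gross output comparable between arms (re-planning changes shape only)
  expect_lt(abs(sum(fx$dose_oa$values) - sum(fx$dose_conv$values)) /
              sum(fx$dose_conv$values), 0.2)
  expect_true(all(fx$dose_oa$values >= 0) && all(fx$dose_conv$values >= 0))
})

test_that("ground-truth fields reproduce the fraction structures exactly", {
  case <- small_case()
  p <- small_params()
  fx <- sample_fraction_anatomy(case, 1, p, 55L)
  for (lab in c("CTV", "bladder", "rectum")) {
    rewarped <- apply_field_to_mask(case$ref_structures[[lab]],
                                    fx$gt_dvf_ref_to_fx)
    # identical up to the overlap-priority resolution step
    resolved <- ddacc:::resolve_mask_overlap(
      list(CTV = apply_field_to_mask(case$ref_structures$CTV,
                                     fx$gt_dvf_ref_to_fx),
           rectum = apply_field_to_mask(case$ref_structures$rectum,
                                        fx$gt_dvf_ref_to_fx),
           bladder = apply_field_to_mask(case$ref_structures$bladder,
                                         fx$gt_dvf_ref_to_fx),
           urethra = apply_field_to_mask(case$ref_structures$urethra,
                                         fx$gt_dvf_ref_to_fx)))
    expect_identical(fx$structures[[lab]]$values, resolved[[lab]]$values)
    expect_gt(dice_coefficient(rewarped, fx$structures[[lab]]), 0.95)
  }
})

test_that("cohort generation is deterministic and correctly sized", {
  p <- small_params(n_patients = 1L, n_fractions = 2L,
                    dose_per_fraction = 30)
  coh1 <- generate_cohort(p)
  coh2 <- generate_cohort(p)
  expect_length(coh1, 1)
  expect_length(coh1[[1]]$fractions, 2)
  expect_identical(coh1[[1]]$fractions[[2]]$dose_oa$values,
                   coh2[[1]]$fractions[[2]]$dose_oa$values)
  expect_identical(coh1[[1]]$fractions[[1]]$applied_shift,
                   coh2[[1]]$fractions[[1]]$applied_shift)
  p2 <- p; p2$seed <- 999L
  coh3 <- generate_cohort(p2)
  expect_false(identical(coh1[[1]]$fractions[[1]]$applied_shift,
                         coh3[[1]]$fractions[[1]]$applied_shift))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(n_fractions = 19),
               "prescription")
  expect_error(phantom_params(bladder_volume_range = c(-1, 5)), "positive")
  expect_error(sample_fraction_anatomy(small_case(), 0, small_params(), 1L),
               "index")
})
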