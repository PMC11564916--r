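# DVH computation, dose-volume parameters, planning objectives, and the
# EQD2 / gEUD / LKB NTCP radiobiology chain.

two_voxel_fixture <- function(d1 = 50, d2 = 60) {
  g <- grid_spec(c(2, 1, 1), c(10, 10, 10))
  list(dose = scalar_volume(array(c(d1, d2), c(2, 1, 1)), g, kind = "dose"),
       mask = structure_mask(array(TRUE, c(2, 1, 1)), g, "rectum"))
}

test_that("cumulative DVHs and DVPs match voxel enumeration on toy cases", {
  g <- grid_spec(c(4, 4, 4), c(5, 5, 5))
  uni <- scalar_volume(array(60, c(4, 4, 4)), g, kind = "dose")
  m <- structure_mask(array(TRUE, c(4, 4, 4)), g, "CTV")
  dvh <- compute_dvh(uni, m)
  expect_equal(dose_at_volume(dvh, 50), 60)
  expect_equal(dose_at_volume(dvh, 98), 60)
  expect_equal(volume_at_dose(dvh, 56), 100)
  expect_equal(volume_at_dose(dvh, 60.5), 0)

  tv <- two_voxel_fixture()
  dvh2 <- compute_dvh(tv$dose, tv$mask)
  expect_equal(volume_at_dose(dvh2, 55), 50)
  expect_equal(dose_at_volume(dvh2, 50), 60)
  expect_equal(dose_at_volume(dvh2, 98), 50, tolerance = 0.011)
  expect_equal(dose_at_volume(dvh2, 100), 50)
  expect_equal(dmax(tv$dose, tv$mask), 60)

  empty <- structure_mask(array(FALSE, c(2, 1, 1)), tv$dose$grid, "CTV")
  expect_error(compute_dvh(tv$dose, empty), "empty")
  expect_error(dmax(tv$dose, empty), "empty")
  expect_error(dose_at_volume(dvh2, 0), "q must be")
  expect_error(dose_at_volume(dvh2, 101), "q must be")
})

test_that("DVPs agree with brute-force voxel enumeration on random masks", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    g <- grid_spec(c(n, 1, 1), c(2, 2, 2))
    doses <- round(runif(n, 0, 70), 2)
    dose <- scalar_volume(array(doses, c(n, 1, 1)), g, kind = "dose")
    mask <- structure_mask(array(TRUE, c(n, 1, 1)), g, "rectum")
    dvh <- compute_dvh(dose, mask)
    for (q in c(2, 50, 98)) {
      expect_lt(abs(dose_at_volume(dvh, q) - brute_dq(doses, q)), 0.0101)
    }
    d <- round(runif(1, 0, 70), 2)  # on the bin lattice: exact agreement
    expect_equal(volume_at_dose(dvh, d), brute_vd(doses, d),
                 tolerance = 1e-9)
    expect_equal(dmax(dose, mask), max(doses))
  }
})

test_that("DVH self-consistency and DVP ordering hold", {
  # dose values dense on the bin lattice so the DVH decreases every bin
  doses <- seq(20, 65, by = 0.01)
  n <- length(doses)
  g <- grid_spec(c(n, 1, 1), c(2, 2, 2))
  dose <- scalar_volume(array(doses, c(n, 1, 1)), g, kind = "dose")
  mask <- structure_mask(array(TRUE, c(n, 1, 1)), g, "CTV")
  dvh <- compute_dvh(dose, mask)
  for (d in c(30, 45, 60)) {
    v <- volume_at_dose(dvh, d)
    expect_lt(abs(dose_at_volume(dvh, v) - d), 0.011)
  }
  d100 <- dose_at_volume(dvh, 100)
  d98 <- dose_at_volume(dvh, 98)
  d50 <- dose_at_volume(dvh, 50)
  expect_true(dmax(dose, mask) >= d50 && d50 >= d98 && d98 >= d100)
})

test_that("the objective checker applies the printed limits inclusively", {
  mk <- function(d98) data.frame(
    structure = c("CTV", "CTV", "CTV", "rectum", "bladder", "urethra",
                  "rectum", "bladder"),
    metric = c("D50", "D98", "Dmax", "Dmax", "Dmax", "Dmax", "V56", "V56"),
    value = c(60.5, d98, 61, 59, 60, 60.2, 5, 10))
  chk <- check_objectives(mk(57.00))
  expect_true(all(chk$pass))  # boundary D98 = 57.00 passes (inclusive)
  chk2 <- check_objectives(mk(56.9))
  expect_identical(chk2$objective[!chk2$pass], "CTV_D98")
  expect_error(check_objectives(mk(57)[-(4:8), ]), "missing DVP")
  # strict < for the volume objectives
  d <- mk(58); d$value[d$metric == "V56" & d$structure == "rectum"] <- 13.5
  expect_false(check_objectives(d)$pass[6])
})

test_that("EQD2 matches hand-evaluated LQ values", {
  expect_equal(eqd2_transform(40, 20, 3), 40)  # 2 Gy/fx fixed point
  expect_equal(eqd2_transform(60, 20, 3), 72.0)
  expect_equal(eqd2_transform(60, 20, 1.5), 60 * 4.5 / 3.5)
  expect_error(eqd2_transform(60, 20, -1), "positive")
  g <- grid_spec(c(2, 1, 1), c(1, 1, 1))
  vol <- scalar_volume(array(c(60, 40), c(2, 1, 1)), g, kind = "dose")
  out <- eqd2_transform(vol, 20, 3)
  expect_equal(as.vector(out$values), c(72, 40))
})

test_that("gEUD reduces correctly in its closed-form limits", {
  g <- grid_spec(c(2, 1, 1), c(10, 10, 10))
  mask <- structure_mask(array(TRUE, c(2, 1, 1)), g, "bladder")
  two <- scalar_volume(array(c(50, 60), c(2, 1, 1)), g, kind = "dose")
  expect_equal(geud(two, mask, n = 1), 55)  # n = 1 is the mean dose
  uni <- scalar_volume(array(42, c(2, 1, 1)), g, kind = "dose")
  for (n in c(1, 0.5, 0.12, 0.02)) expect_equal(geud(uni, mask, n), 42)
  hand <- 60 * (0.5 * (50 / 60)^50 + 0.5)^0.02
  expect_equal(geud(two, mask, n = 0.02), hand, tolerance = 1e-12)
  expect_equal(hand, 59.17, tolerance = 1e-3)
  # n -> 0 approaches the maximum dose
  expect_gt(geud(two, mask, n = 0.001), geud(two, mask, n = 0.02))
  expect_lt(abs(geud(two, mask, n = 1e-4) - 60), 0.01)
  expect_error(geud(two, mask, n = 0), "n must be")
})

test_that("the LKB logistic hits its defining anchor points", {
  for (organ in c("bladder", "rectum")) {
    par <- lkb_presets(organ)
    expect_equal(lkb_ntcp(par$TD50, par)$ntcp, 0.5)
    # logistic symmetry about TD50
    for (x in c(5, 20, 60))
      expect_equal(lkb_ntcp(par$TD50 + x, par)$ntcp +
                     lkb_ntcp(par$TD50 - x, par)$ntcp, 1, tolerance = 1e-12)
  }
  bla <- lkb_presets("bladder")
  expect_equal(bla$alpha_beta, 1.5)
  expect_equal(bla$TD50, 108.9)
  expect_equal(bla$m, 0.24)
  expect_equal(bla$n, 0.02)
  rec <- lkb_presets("rectum")
  expect_equal(c(rec$alpha_beta, rec$TD50, rec$m, rec$n),
               c(3.0, 80.8, 0.15, 0.12))
  expect_equal(lkb_ntcp(0, bla)$ntcp, 1 / (1 + exp(1 / 0.24)))
  expect_lt(abs(lkb_ntcp(0, bla)$ntcp - 0.01527), 1e-5)
  expect_gt(lkb_ntcp(1000, bla)$ntcp, 0.999)
  # strictly increasing
  doses <- seq(0, 200, by = 10)
  ntcps <- vapply(doses, function(d) lkb_ntcp(d, bla)$ntcp, 0)
  expect_true(all(diff(ntcps) > 0))
})

test_that("the full LKB pipeline composes EQD2, gEUD and the logistic", {
  g <- grid_spec(c(2, 1, 1), c(10, 10, 10))
  mask <- structure_mask(array(TRUE, c(2, 1, 1)), g, "bladder")
  dose <- scalar_volume(array(c(50, 60), c(2, 1, 1)), g, kind = "dose")
  par <- lkb_presets("bladder")
  res <- ntcp_from_dose(dose, mask, 20, par)
  eq <- eqd2_transform(c(50, 60), 20, par$alpha_beta)
  expect_equal(res$geud_eqd2, geud(eq, n = par$n))
  expect_equal(res$ntcp, lkb_ntcp(res$geud_eqd2, par)$ntcp)
})
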