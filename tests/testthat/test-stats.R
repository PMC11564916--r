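# Paired statistics: exact Wilcoxon signed-rank, Bonferroni, Cohen's d,
# population DVHs, and report assembly.

test_that("exact Wilcoxon matches its defining enumeration", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p, 2 / 64)  # all-positive ranks, two-sided tail
  expect_equal(res$statistic, 21)

  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d[d == 0] <- 0.1
    res <- wilcoxon_signed_rank(d, mode = "exact")
    expect_equal(res$p, enum_wilcoxon_p(d), tolerance = 1e-12)
    # cross-check against the reference implementation (tie-free data)
    if (!any(duplicated(abs(d)))) {
      ref <- stats::wilcox.test(d, exact = TRUE)$p.value
      expect_equal(res$p, ref, tolerance = 1e-12)
    }
  }
  # ties are handled by mid-ranks and remain exact under enumeration
  d <- c(1, 1, -1, 2, 2, 3)
  expect_equal(wilcoxon_signed_rank(d)$p, enum_wilcoxon_p(d),
               tolerance = 1e-12)
})

test_that("degenerate and approximate Wilcoxon branches behave", {
  expect_warning(res <- wilcoxon_signed_rank(rep(0, 5)), "zero")
  expect_equal(res$p, 1.0)
  set.seed(11)
  d <- rnorm(40, 0.2)
  approx <- wilcoxon_signed_rank(d, mode = "normal-approx")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_equal(approx$p, ref, tolerance = 1e-9)
  auto <- wilcoxon_signed_rank(d)  # n > 15 falls back to the approximation
  expect_identical(auto$mode, "normal-approx")
})

test_that("Bonferroni adjustment is min(1, k p) and dominates the raw p", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_equal(bonferroni(0.01, 3), stats::p.adjust(0.01, "bonferroni", 3))
  set.seed(12)
  p <- runif(20)
  expect_true(all(bonferroni(p, 3) >= p))
})

test_that("paired Cohen's d matches hand computation and is antisymmetric", {
  expect_equal(cohens_d(c(1, 3)), 2 / sqrt(2))
  a <- c(1, 2, 3, 4); b <- c(2, 2, 5, 3)
  sa <- paired_sample(a, b); sb <- paired_sample(b, a)
  expect_equal(cohens_d(sa), -cohens_d(sb))
  expect_warning(dz <- cohens_d(paired_sample(a, a)), "undefined")
  expect_true(is.na(dz))
})

test_that("population DVH curves average and spread correctly", {
  g <- grid_spec(c(4, 1, 1), c(5, 5, 5))
  m <- structure_mask(array(TRUE, c(4, 1, 1)), g, "CTV")
  mk <- function(vals) compute_dvh(
    scalar_volume(array(vals, c(4, 1, 1)), g, kind = "dose"), m)
  d1 <- mk(c(10, 20, 30, 40))
  pop1 <- population_dvh(list(d1))
  expect_equal(pop1$mean, d1$cumulative_volume)
  expect_true(all(pop1$sd == 0))
  pop2 <- population_dvh(list(d1, d1))
  expect_true(all(pop2$sd == 0))
  d2 <- mk(c(10, 20, 30, 50))  # longer curve: rebinned to the union range
  pop3 <- population_dvh(list(d1, d2))
  v1 <- c(d1$cumulative_volume,
          rep(0, length(pop3$bin_edges) - length(d1$cumulative_volume)))
  expect_equal(pop3$mean, (v1 + d2$cumulative_volume) / 2)
  expect_equal(pop3$sd, abs(v1 - d2$cumulative_volume) / sqrt(2))
  expect_error(population_dvh(list()), "empty")
})

fake_cohort_dvps <- function(n = 5, jitter = 0) {
  arms <- c("refPlan", "conv-IGRT", "OA-MRgRT")
  grid <- expand.grid(patient = seq_len(n), arm = arms,
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    base <- data.frame(
      structure = c("CTV", "CTV", "CTV", "rectum", "bladder", "urethra",
                    "rectum", "bladder"),
      metric = c("D50", "D98", "Dmax", "Dmax", "Dmax", "Dmax", "V56",
                 "V56"),
      value = c(60.3, 58.5, 61.5, 59.5, 60.1, 60.4, 5, 6))
    base$value <- base$value + jitter * (grid$arm[i] != "refPlan") *
      stats::rnorm(nrow(base), 0, 0.2)
    base$patient <- grid$patient[i]
    base$arm <- grid$arm[i]
    base
  }))
  rows
}

fake_cohort_ntcp <- function(n = 5) {
  arms <- c("refPlan", "conv-IGRT", "OA-MRgRT")
  do.call(rbind, lapply(arms, function(a)
    data.frame(patient = seq_len(n), arm = a,
               organ = rep(c("bladder", "rectum"), each = n),
               ntcp = 0.02, geud_eqd2 = 70)))
}

test_that("the report on an identical-arms cohort is fully degenerate", {
  dvps <- fake_cohort_dvps(5, jitter = 0)
  rep <- suppressWarnings(build_report(dvps, fake_cohort_ntcp(5)))
  expect_true(all(rep$comparisons$p_raw == 1))
  expect_true(all(rep$comparisons$p_adjusted == 1))
  expect_true(all(is.na(rep$comparisons$cohens_d)))
  # three pairwise comparisons per DVP
  expect_equal(nrow(rep$comparisons), 3 * 8)
  expect_equal(unname(table(rep$comparisons$key)["CTV_D50"]), 3L)
  # medians identical across arms
  expect_true(all(rep$summary$refPlan == rep$summary$conv_IGRT))
})

test_that("objective attainment is a patient count per arm", {
  dvps <- fake_cohort_dvps(10, jitter = 0)
  # push one conv-IGRT patient over the rectum Dmax limit
  sel <- dvps$arm == "conv-IGRT" & dvps$patient == 3 &
    dvps$structure == "rectum" & dvps$metric == "Dmax"
  dvps$value[sel] <- 61.6
  dvps$value[dvps$metric == "Dmax" & dvps$structure == "CTV"] <- 60.9
  rep <- suppressWarnings(build_report(dvps, fake_cohort_ntcp(10)))
  att <- rep$attainment
  got <- att$attained_pct[att$arm == "conv-IGRT" &
                            att$objective == "rectum_Dmax"]
  expect_equal(got, 90)
  expect_equal(att$attained_pct[att$arm == "refPlan" &
                                  att$objective == "rectum_Dmax"], 100)
  expect_error(build_report(dvps[dvps$arm != "refPlan", ],
                            fake_cohort_ntcp(10)), "missing arm")
  # medians invariant to patient ordering
  shuf <- dvps[sample(nrow(dvps)), ]
  rep2 <- suppressWarnings(build_report(shuf, fake_cohort_ntcp(10)))
  expect_identical(rep$summary, rep2$summary)
})
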