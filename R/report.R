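# Cohort-level analysis driver and report assembly: per-patient DVPs and
# NTCP per treatment arm, median (range) summaries, pairwise Wilcoxon /
# Bonferroni / Cohen's d comparisons, and objective-attainment rates.

arm_levels <- c("refPlan", "conv-IGRT", "OA-MRgRT")

#' Dose-volume parameters and NTCP for one case and arm
#'
#' The refPlan arm is evaluated in the reference frame on the reference
#' structures (no mapping); the accumulated arms are evaluated in the
#' fraction-1 frame on the fraction-1 structures.
#'
#' @param case A `patient_case`.
#' @param arm One of `"refPlan"`, `"conv-IGRT"`, `"OA-MRgRT"`.
#' @param accumulated Optional `accumulated_dose` for the adaptive arms
#'   (computed with ground-truth fields if omitted).
#' @return List with `dvps` (data frame) and `ntcp` (data frame with
#'   bladder and rectum LKB results).
#' @export
case_arm_results <- function(case, arm, accumulated = NULL) {
  arm <- match.arg(arm, arm_levels)
  if (arm == "refPlan") {
    dose <- case$ref_dose
    structs <- case$ref_structures
  } else {
    if (is.null(accumulated)) {
      dvfs <- gt_dvfs_to_fraction1(case)
      accumulated <- accumulate_arm(case, arm, dvfs)
    }
    dose <- accumulated$dose
    structs <- case$fractions[[1]]$structures
  }
  dvps <- extract_dvps(dose, structs)
  nfx <- case$params$n_fractions
  ntcp <- do.call(rbind, lapply(c("bladder", "rectum"), function(org) {
    res <- ntcp_from_dose(dose, structs[[org]], nfx, lkb_presets(org))
    data.frame(organ = org, ntcp = res$ntcp, geud_eqd2 = res$geud_eqd2)
  }))
  dvps$arm <- arm
  ntcp$arm <- arm
  list(dvps = dvps, ntcp = ntcp)
}

#' Run the full cohort analysis
#'
#' Streams over patients: generates each case from its derived seed,
#' accumulates both adaptive arms (ground-truth fields by default),
#' extracts DVPs and NTCP for the three arms, and discards the case before
#' the next one to bound memory.
#'
#' @param params A `phantom_params`.
#' @param method `"gt"` (phantom ground-truth fields) or `"dir"` (run the
#'   deformable registration surrogate per fraction; much slower).
#' @param progress Print one line per patient.
#' @return List with data frames `dvps` (patient, arm, structure, metric,
#'   value) and `ntcp` (patient, arm, organ, ntcp, geud_eqd2).
#' @export
run_cohort_analysis <- function(params, method = c("gt", "dir"),
                                progress = FALSE) {
  method <- match.arg(method)
  seeds <- patient_seeds(params)
  all_dvps <- list(); all_ntcp <- list()
  for (p in seq_len(params$n_patients)) {
    case <- generate_patient_case(params, seeds[p])
    acc <- accumulate_case(case, method = method)
    for (arm in arm_levels) {
      accd <- switch(arm, "conv-IGRT" = acc$conv, "OA-MRgRT" = acc$oa,
                     NULL)
      res <- case_arm_results(case, arm, accd)
      res$dvps$patient <- p
      res$ntcp$patient <- p
      all_dvps[[length(all_dvps) + 1]] <- res$dvps
      all_ntcp[[length(all_ntcp) + 1]] <- res$ntcp
    }
    if (progress)
      cat(sprintf("patient %d/%d done\n", p, params$n_patients))
    rm(case, acc)
  }
  list(dvps = do.call(rbind, all_dvps), ntcp = do.call(rbind, all_ntcp))
}

median_range <- function(x) {
  sprintf("%.1f (%.1f-%.1f)", stats::median(x), min(x), max(x))
}

#' Assemble the cohort report
#'
#' Per-DVP median (range) per arm, the three pairwise arm comparisons per
#' DVP and per NTCP endpoint (exact Wilcoxon signed-rank, Bonferroni
#' k = 3, paired Cohen's d), the NTCP summary, and per-arm
#' objective-attainment percentages.
#'
#' @param dvps Data frame from [run_cohort_analysis()] (`$dvps`).
#' @param ntcps Data frame from [run_cohort_analysis()] (`$ntcp`).
#' @return An object of class `cohort_report`: list of data frames
#'   `summary`, `comparisons`, `ntcp_summary`, `ntcp_comparisons`,
#'   `attainment`.
#' @export
build_report <- function(dvps, ntcps) {
  miss <- setdiff(arm_levels, unique(dvps$arm))
  if (length(miss)) stop("missing arm(s): ", paste(miss, collapse = ", "))
  dvps$key <- paste(dvps$structure, dvps$metric, sep = "_")
  canonical <- c("CTV_D50", "CTV_D98", "CTV_Dmax", "rectum_Dmax",
                 "bladder_Dmax", "urethra_Dmax", "rectum_V56",
                 "bladder_V56")
  keys <- unique(dvps$key)
  keys <- c(intersect(canonical, keys), sort(setdiff(keys, canonical)))
  summary_df <- do.call(rbind, lapply(keys, function(k) {
    d <- dvps[dvps$key == k, ]
    data.frame(dvp = k,
               refPlan = median_range(d$value[d$arm == "refPlan"]),
               conv_IGRT = median_range(d$value[d$arm == "conv-IGRT"]),
               OA_MRgRT = median_range(d$value[d$arm == "OA-MRgRT"]))
  }))
  pairs <- list(c("refPlan", "conv-IGRT"), c("refPlan", "OA-MRgRT"),
                c("conv-IGRT", "OA-MRgRT"))
  compare_tab <- function(df, valcol, keycol) {
    do.call(rbind, lapply(unique(df[[keycol]]), function(k) {
      d <- df[df[[keycol]] == k, ]
      do.call(rbind, lapply(pairs, function(pr) {
        a <- d[d$arm == pr[1], ]
        b <- d[d$arm == pr[2], ]
        a <- a[order(a$patient), ]; b <- b[order(b$patient), ]
        smp <- paired_sample(a[[valcol]], b[[valcol]], labels = pr)
        w <- suppressWarnings(wilcoxon_signed_rank(smp))
        dz <- suppressWarnings(cohens_d(smp))
        data.frame(key = k, arm_a = pr[1], arm_b = pr[2],
                   n = length(a[[valcol]]), p_raw = w$p,
                   p_adjusted = bonferroni(w$p, 3), cohens_d = dz)
      }))
    }))
  }
  comparisons <- compare_tab(dvps, "value", "key")
  ntcp_summary <- do.call(rbind, lapply(unique(ntcps$organ), function(o) {
    d <- ntcps[ntcps$organ == o, ]
    data.frame(organ = o,
               refPlan = stats::median(100 * d$ntcp[d$arm == "refPlan"]),
               conv_IGRT = stats::median(100 * d$ntcp[d$arm == "conv-IGRT"]),
               OA_MRgRT = stats::median(100 * d$ntcp[d$arm == "OA-MRgRT"]))
  }))
  ntcp_comparisons <- compare_tab(ntcps, "ntcp", "organ")
  obj <- planning_objectives()
  attainment <- do.call(rbind, lapply(arm_levels, function(arm) {
    d <- dvps[dvps$arm == arm, ]
    do.call(rbind, lapply(seq_len(nrow(obj)), function(r) {
      v <- d$value[d$structure == obj$structure[r] &
                     d$metric == obj$metric[r]]
      pass <- switch(obj$direction[r],
                     ">=" = v >= obj$limit[r],
                     "<=" = v <= obj$limit[r],
                     "<" = v < obj$limit[r])
      data.frame(arm = arm, objective = obj$objective[r],
                 attained_pct = 100 * mean(pass), n = length(v))
    }))
  }))
  structure(list(summary = summary_df, comparisons = comparisons,
                 ntcp_summary = ntcp_summary,
                 ntcp_comparisons = ntcp_comparisons,
                 attainment = attainment),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Dose-volume parameters, median (range) per arm:\n")
  print(x$summary, row.names = FALSE)
  cat("\nObjective attainment (% of patients):\n")
  print(x$attainment, row.names = FALSE)
  cat("\nNTCP medians (%):\n")
  print(x$ntcp_summary, row.names = FALSE)
  invisible(x)
}

#' Write a cohort report to CSV files plus a text summary
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("summary", "comparisons", "ntcp_summary",
               "ntcp_comparisons", "attainment"))
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}
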