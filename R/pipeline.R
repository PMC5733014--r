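## Orchestration of the full study: QC -> phenotype -> cell imputation
## (only when counts are missing) -> five association scans
## (paired-cognition, paired-cognition-discordant50, paired-change,
## unpaired-cognition, unpaired-change) -> annotation, threshold report,
## cross-analysis overlap and optional enrichment. A single QC pass
## defines one probe set shared by all five scans; individuals with an
## unavailable composite are dropped per analysis, not globally.

ANALYSIS_LABELS <- c("paired-cognition", "paired-cognition-discordant50",
                     "paired-change", "unpaired-cognition",
                     "unpaired-change")

#' Run the full twin-EWAS study
#'
#' @param cohort a \code{twin_cohort} (from [simulate_cohort()] or
#'   [read_cohort()]) or a directory path readable by [read_cohort()].
#' @param output_dir optional directory; when given, all result tables,
#'   the QC report and a run log are written there.
#' @param thresholds [qc_thresholds()] for probe QC.
#' @param report_thresholds [threshold_config()] for reporting.
#' @param gmt optional gene-set collection (from [read_gmt()]); when
#'   supplied, over-representation analysis is run per scan on hits at
#'   the overlap threshold.
#' @param n_components PLS components for cell-count imputation.
#' @param discordant_fraction fraction kept in the discordant subset
#'   analysis (default 0.5).
#' @param epsilon clipping fraction of the M-value transform.
#' @return list of class \code{study_bundle}: \code{results} (named list
#'   of annotated \code{ewas_result} tables), \code{reports} (per-scan
#'   suggestive/significant tables), \code{overlap}, \code{enrichment}
#'   (or NULL), \code{qc_report}, \code{composites}, \code{change},
#'   \code{decline}, \code{cell_counts}, \code{manhattan}, \code{log}
#'   (character vector of stage messages with row counts).
#' @export
run_full_study <- function(cohort, output_dir = NULL,
                           thresholds = qc_thresholds(),
                           report_thresholds = threshold_config(),
                           gmt = NULL, n_components = 10,
                           discordant_fraction = 0.5, epsilon = 1e-6) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "twin_cohort"))
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }

  ## QC ------------------------------------------------------------------
  say("qc: %d probes x %d samples in", nrow(cohort$beta), ncol(cohort$beta))
  masked <- mask_failed_measurements(cohort$beta, cohort$qc, thresholds)
  qcres <- filter_probes(masked, cohort$cross_reactive, thresholds)
  say("qc: %d probes kept (%d dropped: %s)", qcres$report$n_kept,
      qcres$report$n_dropped,
      paste(sprintf("%s=%d", names(qcres$report$dropped_by_reason),
                    qcres$report$dropped_by_reason), collapse = ", "))
  mvals <- logit_transform(qcres$beta, epsilon)

  ## Phenotype ------------------------------------------------------------
  params <- estimate_standardization(cohort$components, wave = "intake")
  comp_intake <- compute_composite(cohort$components, params, "intake")
  comp_follow <- compute_composite(cohort$components, params, "followup")
  change <- compute_change(comp_intake, comp_follow)
  say("phenotype: composite available for %d (intake) / %d (followup), change for %d",
      sum(comp_intake$available), sum(comp_follow$available),
      sum(change$available))
  decline <- test_cohort_decline(change, cohort$sample_sheet)
  say("phenotype: mean 10-year change %.3f (p = %.3g)",
      decline$mean_change, decline$p_value)

  ## Cell counts ----------------------------------------------------------
  counts <- cohort$cell_counts
  n_missing <- sum(!stats::complete.cases(counts[, CELL_TYPES]))
  if (n_missing > 0) {
    say("cells: imputing %d sample(s) by PLS (%d components)", n_missing,
        n_components)
    imputer <- fit_cell_imputer(cohort$beta, cohort$sample_sheet, counts,
                                n_components)
    counts <- impute_missing_counts(imputer, cohort$beta,
                                    cohort$sample_sheet, counts)
  } else {
    say("cells: counts complete, imputation skipped")
  }

  ## Scans ----------------------------------------------------------------
  followup_phen <- comp_follow[, c("sample_id", "value", "available")]
  design_cog <- build_pair_differences(mvals, cohort$sample_sheet,
                                       followup_phen, counts)
  say("paired: %d complete pairs (cognition), %d excluded",
      nrow(design_cog$pairs), nrow(design_cog$excluded))
  design_chg <- build_pair_differences(mvals, cohort$sample_sheet, change,
                                       counts)
  results <- list()
  results[["paired-cognition"]] <-
    run_paired_ewas(design_cog, analysis = "paired-cognition")
  results[["paired-cognition-discordant50"]] <-
    run_paired_ewas(select_most_discordant(design_cog, discordant_fraction),
                    analysis = "paired-cognition-discordant50")
  results[["paired-change"]] <-
    run_paired_ewas(design_chg, analysis = "paired-change")
  results[["unpaired-cognition"]] <-
    run_unpaired_ewas(mvals, cohort$sample_sheet, followup_phen, counts,
                      analysis = "unpaired-cognition")
  results[["unpaired-change"]] <-
    run_unpaired_ewas(mvals, cohort$sample_sheet, change, counts,
                      analysis = "unpaired-change")
  for (nm in names(results))
    say("scan %s: %d probes, %s units", nm, nrow(results[[nm]]),
        paste(unique(stats::na.omit(results[[nm]]$n_units)),
              collapse = "/"))

  ## Reporting ------------------------------------------------------------
  results <- lapply(results, annotate_probes, annotation = cohort$annotation)
  reports <- lapply(results, threshold_report, thresholds = report_thresholds)
  for (nm in names(reports))
    say("report %s: %d suggestive, %d significant", nm,
        nrow(reports[[nm]]$suggestive), nrow(reports[[nm]]$significant))
  overlap <- overlap_analysis(results, cohort$annotation,
                              report_thresholds$overlap_p)
  manhattan <- lapply(results, manhattan_table,
                      significant_p = report_thresholds$significant_p)

  enrichment <- NULL
  if (!is.null(gmt)) {
    ann_kept <- cohort$annotation[
      cohort$annotation$probe_id %in% rownames(mvals), , drop = FALSE]
    enrichment <- lapply(results, function(r) {
      hits <- hits_to_genes(r, ann_kept, report_thresholds$overlap_p)
      enrich_all(hits, gmt, ann_kept)
    })
    for (nm in names(enrichment))
      say("enrichment %s: %d hit-driven sets with raw p < 0.05", nm,
          sum(enrichment[[nm]]$raw_p < 0.05))
  }

  bundle <- structure(list(
    results = results, reports = reports, overlap = overlap,
    enrichment = enrichment, qc_report = qcres$report,
    composites = list(intake = comp_intake, followup = comp_follow),
    change = change, decline = decline, cell_counts = counts,
    manhattan = manhattan, standardization = params, log = log),
    class = "study_bundle")

  if (!is.null(output_dir)) write_study_bundle(bundle, output_dir)
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Twin-EWAS study bundle\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

#' Write a study bundle's tables to a directory
#'
#' @param bundle [run_full_study()] output.
#' @param dir output directory (created if needed).
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(dir, paste0(...))
  for (nm in names(bundle$results)) {
    write_ewas_result(bundle$results[[nm]], f(nm, "_results.tsv"))
    write_ewas_result(bundle$reports[[nm]]$suggestive,
                      f(nm, "_suggestive.tsv"))
    write_ewas_result(bundle$reports[[nm]]$significant,
                      f(nm, "_significant.tsv"))
    utils::write.table(bundle$manhattan[[nm]], f(nm, "_manhattan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    if (!is.null(bundle$enrichment))
      write_enrichment(bundle$enrichment[[nm]], f(nm, "_enrichment.tsv"))
  }
  write_qc_report(bundle$qc_report, f("qc_report.tsv"), f("qc_summary.json"))
  utils::write.table(bundle$overlap$pairs, f("overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  write_cell_counts(bundle$cell_counts, f("cell_counts_completed.tsv"))
  comp <- rbind(bundle$composites$intake, bundle$composites$followup)
  utils::write.table(comp, f("composites.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(bundle$change, f("change_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  writeLines(c(sprintf("twinewas %s", as.character(utils::packageVersion("twinewas"))),
               bundle$log), f("run_log.txt"))
  invisible(dir)
}
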