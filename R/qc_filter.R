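## Probe-level quality control and beta -> M-value transform.
##
## Filtering is staged: bead count / detection p / zero signal act at the
## measurement level (mask the single probe x sample value to NA); the
## ">5% of samples missing" rule then acts at the probe level on the
## masked matrix; cross-reactive probes are removed last. The missingness
## criterion is only meaningful after measurement-level masking.

#' Probe QC thresholds
#'
#' @param min_bead_count minimum beads per measurement; values measured
#'   with fewer beads are masked (default 3, i.e. "<3 beads" fails).
#' @param max_detection_p maximum detection p-value; strictly larger
#'   values are masked (default 0.01).
#' @param max_probe_missing_fraction probes missing in strictly more than
#'   this fraction of samples are dropped (default 0.05).
#' @return object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(min_bead_count = 3, max_detection_p = 0.01,
                          max_probe_missing_fraction = 0.05) {
  if (min_bead_count < 1) stop2("min_bead_count must be >= 1")
  if (max_detection_p <= 0 || max_detection_p >= 1)
    stop2("max_detection_p must be in (0, 1)")
  if (max_probe_missing_fraction <= 0 || max_probe_missing_fraction >= 1)
    stop2("max_probe_missing_fraction must be in (0, 1)")
  structure(list(min_bead_count = min_bead_count,
                 max_detection_p = max_detection_p,
                 max_probe_missing_fraction = max_probe_missing_fraction),
            class = "qc_thresholds")
}

#' Bundle per-measurement QC metrics
#'
#' @param bead_count integer matrix (probes x samples) of bead counts.
#' @param detection_p matrix of detection p-values in [0, 1].
#' @param signal_zero logical matrix flagging zero-signal measurements;
#'   defaults to all-FALSE.
#' @return object of class \code{probe_qc} (a list of the three
#'   matrices), dimension-checked against each other.
#' @export
probe_qc_metrics <- function(bead_count, detection_p, signal_zero = NULL) {
  if (is.null(signal_zero))
    signal_zero <- array(FALSE, dim(bead_count), dimnames(bead_count))
  if (!identical(dim(bead_count), dim(detection_p)) ||
      !identical(dim(bead_count), dim(signal_zero)))
    stop2("QC metric matrices must share dimensions")
  if (any(!is.na(bead_count) & bead_count < 0))
    stop2("bead counts must be >= 0")
  if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1)))
    stop2("detection p-values must be in [0, 1]")
  structure(list(bead_count = bead_count, detection_p = detection_p,
                 signal_zero = signal_zero), class = "probe_qc")
}

#' Mask failed measurements
#'
#' Sets a probe x sample beta value to \code{NA} when its bead count is
#' below \code{min_bead_count}, its detection p-value is strictly above
#' \code{max_detection_p}, or the measurement had zero signal. A
#' detection p-value exactly at the threshold is retained. All other
#' values are unchanged.
#'
#' @param beta beta matrix.
#' @param qc [probe_qc_metrics()] object congruent with \code{beta}.
#' @param thresholds [qc_thresholds()].
#' @return masked beta matrix with attribute \code{mask_counts}, a named
#'   integer vector tallying newly masked cells by cause (precedence
#'   bead > detection > zero-signal for cells failing several).
#' @export
mask_failed_measurements <- function(beta, qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(qc, "probe_qc"), inherits(thresholds, "qc_thresholds"))
  if (!identical(dim(beta), dim(qc$bead_count)))
    stop2("beta and QC metric dimensions differ")
  observed <- !is.na(beta)
  fail_bead <- observed & !is.na(qc$bead_count) &
    qc$bead_count < thresholds$min_bead_count
  fail_det <- observed & !is.na(qc$detection_p) &
    qc$detection_p > thresholds$max_detection_p
  fail_zero <- observed & qc$signal_zero
  out <- beta
  out[fail_bead | fail_det | fail_zero] <- NA_real_
  attr(out, "mask_counts") <- c(
    bead = sum(fail_bead),
    detection = sum(fail_det & !fail_bead),
    zero_signal = sum(fail_zero & !fail_bead & !fail_det))
  out
}

#' Drop probes by missingness and cross-reactivity
#'
#' Applied after [mask_failed_measurements()]: first drops probes whose
#' missing fraction exceeds \code{max_probe_missing_fraction}, then drops
#' any remaining probe on the cross-reactive list. Surviving values are
#' never altered, and the operation is idempotent.
#'
#' @param beta measurement-masked beta matrix.
#' @param cross_reactive character vector of cross-reactive probe ids.
#' @param thresholds [qc_thresholds()].
#' @return list with elements \code{beta} (filtered matrix) and
#'   \code{report} (class \code{qc_report}).
#' @export
filter_probes <- function(beta, cross_reactive = character(),
                          thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  miss_frac <- rowMeans(is.na(beta))
  drop_miss <- miss_frac > thresholds$max_probe_missing_fraction
  drop_xr <- !drop_miss & rownames(beta) %in% cross_reactive
  fate <- ifelse(drop_miss, "dropped",
                 ifelse(drop_xr, "dropped", "kept"))
  reason <- rep(NA_character_, nrow(beta))
  reason[drop_miss] <- "missingness"
  reason[drop_xr] <- "cross-reactive"
  kept <- beta[!(drop_miss | drop_xr), , drop = FALSE]
  if (nrow(kept) == 0) warning("no probes survive QC filtering")
  report <- structure(list(
    probe_fates = data.frame(probe_id = rownames(beta), fate = fate,
                             reason = reason, stringsAsFactors = FALSE),
    n_input = nrow(beta),
    n_kept = nrow(kept),
    n_dropped = sum(drop_miss | drop_xr),
    dropped_by_reason = c(missingness = sum(drop_miss),
                          `cross-reactive` = sum(drop_xr)),
    masked_cells = attr(beta, "mask_counts"),
    thresholds = thresholds), class = "qc_report")
  attr(kept, "mask_counts") <- NULL
  list(beta = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Probe QC report\n")
  cat(sprintf("  probes in: %d, kept: %d, dropped: %d\n",
              x$n_input, x$n_kept, x$n_dropped))
  for (r in names(x$dropped_by_reason))
    cat(sprintf("    dropped (%s): %d\n", r, x$dropped_by_reason[[r]]))
  if (!is.null(x$masked_cells)) {
    cat("  measurements masked:",
        paste(sprintf("%s=%d", names(x$masked_cells), x$masked_cells),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a QC report
#'
#' Emits a per-probe TSV (probe_id, fate, reason) and a JSON summary of
#' the tallies and thresholds.
#'
#' @param report \code{qc_report} from [filter_probes()].
#' @param tsv_path,json_path output paths.
#' @export
write_qc_report <- function(report, tsv_path, json_path) {
  stopifnot(inherits(report, "qc_report"))
  utils::write.table(report$probe_fates, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  summary <- list(n_input = report$n_input, n_kept = report$n_kept,
                  n_dropped = report$n_dropped,
                  dropped_by_reason = as.list(report$dropped_by_reason),
                  masked_cells = as.list(report$masked_cells),
                  thresholds = unclass(report$thresholds))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Beta to M-value (base-2 logit) transform
#'
#' \code{M = log2(beta / (1 - beta))} after clipping beta into
#' \code{[epsilon, 1 - epsilon]} so that boundary values 0 and 1 map to
#' finite M-values. Missing values propagate.
#'
#' @param beta beta matrix (or numeric vector).
#' @param epsilon clipping fraction in (0, 0.5); default \code{1e-6}.
#' @return M-value matrix of the same shape.
#' @export
logit_transform <- function(beta, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 0.5)
    stop2("epsilon must be in (0, 0.5)")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  attributes(m) <- attributes(beta)
  attr(m, "mask_counts") <- NULL
  m
}

#' Inverse of the M-value transform
#'
#' Maps M-values back to beta fractions: \code{beta = 2^M / (1 + 2^M)}.
#' Exact inverse of [logit_transform()] on clipped betas.
#'
#' @param m M-value matrix (or numeric vector).
#' @return beta matrix of the same shape.
#' @export
inverse_logit_transform <- function(m) {
  b <- 1 / (1 + 2^(-m))
  attributes(b) <- attributes(m)
  b
}
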