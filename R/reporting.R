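## Multiple-testing utilities, threshold reporting, annotation joins,
## cross-analysis overlap and Manhattan-plot table preparation.

#' Reporting thresholds
#'
#' Fixed unadjusted p-value cutoffs used for 450K-style EWAS reporting:
#' suggestive reporting at p < 1e-5, genome-wide significance at
#' p < 1e-6, and a looser 1e-4 cutoff for cross-analysis overlap and
#' enrichment input. All comparisons are strict.
#'
#' @param suggestive_p,significant_p,overlap_p cutoffs with
#'   \code{significant_p <= suggestive_p <= overlap_p}.
#' @return object of class \code{threshold_config}.
#' @export
threshold_config <- function(suggestive_p = 1e-5, significant_p = 1e-6,
                             overlap_p = 1e-4) {
  if (!(significant_p <= suggestive_p && suggestive_p <= overlap_p))
    stop2("thresholds must satisfy significant <= suggestive <= overlap")
  structure(list(suggestive_p = suggestive_p, significant_p = significant_p,
                 overlap_p = overlap_p), class = "threshold_config")
}

#' Benjamini-Hochberg adjustment with an explicit family size
#'
#' Step-up FDR adjustment \code{adj_i = min_{j >= i} p_(j) * m_total / j}
#' (capped at 1), returned in input order. The family size is explicit
#' because displayed p-value lists are often truncated to the sets
#' passing a display threshold; inferring \code{m} from the list length
#' would silently mis-correct.
#'
#' @param p p-values in (0, 1].
#' @param m_total family size; must be at least \code{length(p)}.
#'   Unlisted tests are implicitly assumed to have larger p-values than
#'   every listed one.
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p, m_total = length(p)) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop2("p-values must be in (0, 1]")
  if (m_total < length(p))
    stop2("m_total must be at least the number of p-values")
  stats::p.adjust(p, method = "BH", n = m_total)
}

#' Join probe annotation onto EWAS results
#'
#' Adds \code{chromosome}, \code{position}, \code{gene_symbol},
#' \code{distance_bp} and \code{cgi_feature} columns by probe id.
#' Estimates, standard errors and p-values are never altered; probes
#' absent from the annotation are kept with missing annotation and a
#' warning.
#'
#' @param results \code{ewas_result} data frame.
#' @param annotation validated annotation table.
#' @return annotated result table (Table-style column order: probe,
#'   estimate, SE, p, chromosome, position, gene, distance, CGI
#'   feature, then bookkeeping columns).
#' @export
annotate_probes <- function(results, annotation) {
  idx <- match(results$probe_id, annotation$probe_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " probe(s) missing from annotation")
  out <- data.frame(
    results[, c("probe_id", "estimate", "std_error", "p_value")],
    chromosome = annotation$chromosome[idx],
    position = annotation$position[idx],
    gene_symbol = annotation$gene_symbol[idx],
    distance_bp = annotation$distance_bp[idx],
    cgi_feature = annotation$cgi_feature[idx],
    results[, setdiff(names(results),
                      c("probe_id", "estimate", "std_error", "p_value")),
            drop = FALSE],
    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Partition results by reporting thresholds
#'
#' @param results \code{ewas_result} data frame.
#' @param thresholds [threshold_config()].
#' @return list with \code{suggestive} (p < suggestive_p) and
#'   \code{significant} (p < significant_p) tables, each sorted by
#'   ascending p (ties broken by probe id). The significant table is
#'   always a subset of the suggestive one.
#' @export
threshold_report <- function(results, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  ok <- !is.na(results$p_value)
  sug <- results[ok & results$p_value < thresholds$suggestive_p, ,
                 drop = FALSE]
  sig <- results[ok & results$p_value < thresholds$significant_p, ,
                 drop = FALSE]
  sug <- sug[order(sug$p_value, sug$probe_id), , drop = FALSE]
  sig <- sig[order(sig$p_value, sig$probe_id), , drop = FALSE]
  rownames(sug) <- rownames(sig) <- NULL
  list(suggestive = sug, significant = sig)
}

#' Cross-analysis overlap of associated probes and genes
#'
#' For every pair of result tables, intersects the probe ids and the
#' annotated gene symbols of hits with p strictly below
#' \code{overlap_p} in both analyses. Probe-level and gene-level
#' overlaps are reported separately: two analyses can share a gene
#' through different probes.
#'
#' @param result_list named list of \code{ewas_result} tables.
#' @param annotation annotation table (for gene symbols).
#' @param overlap_p cutoff, default 1e-4.
#' @return object of class \code{overlap_result}: list with
#'   \code{pairs} (data frame: analysis_1, analysis_2, n_probes,
#'   n_genes) and \code{detail} (per analysis-pair list of shared probe
#'   ids and gene symbols).
#' @export
overlap_analysis <- function(result_list, annotation, overlap_p = 1e-4) {
  if (length(result_list) < 2)
    stop2("overlap needs at least two result tables")
  if (is.null(names(result_list)))
    names(result_list) <- paste0("analysis_", seq_along(result_list))
  hit_probes <- lapply(result_list, function(r)
    r$probe_id[!is.na(r$p_value) & r$p_value < overlap_p])
  hit_genes <- lapply(hit_probes, function(pr) {
    g <- annotation$gene_symbol[match(pr, annotation$probe_id)]
    sort(unique(g[!is.na(g)]))
  })
  combos <- utils::combn(names(result_list), 2)
  detail <- list()
  rows <- list()
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    key <- paste(a, b, sep = " vs ")
    shared_p <- sort(intersect(hit_probes[[a]], hit_probes[[b]]))
    shared_g <- sort(intersect(hit_genes[[a]], hit_genes[[b]]))
    detail[[key]] <- list(probes = shared_p, genes = shared_g)
    rows[[key]] <- data.frame(analysis_1 = a, analysis_2 = b,
                              n_probes = length(shared_p),
                              n_genes = length(shared_g),
                              stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, c(rows, make.row.names = FALSE)),
                 detail = detail, overlap_p = overlap_p,
                 hit_probes = hit_probes, hit_genes = hit_genes),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Cross-analysis overlap at p < %g\n", x$overlap_p))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Manhattan-plot table
#'
#' Orders annotated results by chromosome (1..22, X, Y, then others)
#' and position, assigns a cumulative genomic coordinate, and computes
#' \code{-log10(p)} with a label flag for genome-wide-significant probes
#' (p strictly below \code{significant_p}).
#'
#' @param results annotated \code{ewas_result} (see [annotate_probes()]).
#' @param significant_p labelling cutoff, default 1e-6.
#' @return data frame: probe_id, chromosome, position,
#'   cumulative_position, neg_log10_p, label.
#' @export
manhattan_table <- function(results, significant_p = 1e-6) {
  if (is.null(results$chromosome))
    stop2("results must be annotated (see annotate_probes)")
  chr_levels <- c(as.character(1:22), "X", "Y")
  chr <- as.character(results$chromosome)
  chr_rank <- match(chr, chr_levels)
  chr_rank[is.na(chr_rank)] <- length(chr_levels) + rank(chr[is.na(chr_rank)])
  ord <- order(chr_rank, results$position)
  r <- results[ord, , drop = FALSE]
  chr_r <- as.character(r$chromosome)
  offset <- 0
  cum <- numeric(nrow(r))
  for (cc in unique(chr_r)) {
    i <- which(chr_r == cc)
    cum[i] <- offset + r$position[i]
    offset <- max(cum[i])
  }
  data.frame(probe_id = r$probe_id, chromosome = chr_r,
             position = r$position, cumulative_position = cum,
             neg_log10_p = -log10(r$p_value),
             label = !is.na(r$p_value) & r$p_value < significant_p,
             stringsAsFactors = FALSE)
}
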