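## Gene-set over-representation analysis (ORA).
##
## The reference universe is the set of unique gene symbols on the
## filtered array annotation; hit lists come from EWAS results below a
## p cutoff. Per set, a one-sided hypergeometric upper tail tests
## whether the observed overlap O exceeds the expectation
## E = C * n / N (C = set genes on the array, n = hit genes, N =
## universe size); R = O / E is the enrichment ratio. BH adjustment uses
## the number of sets actually tested as the family size.

#' Build the ORA reference universe
#'
#' @param annotation validated annotation table (typically restricted to
#'   QC-surviving probes).
#' @param collection gene-set collection from [read_gmt()] (or a named
#'   list of symbol vectors).
#' @param min_set_size drop sets with fewer genes than this after
#'   intersection with the universe (default 1, i.e. only empty sets are
#'   dropped).
#' @return list with \code{universe} (character vector of N gene
#'   symbols) and \code{sets} (collection intersected with the
#'   universe).
#' @export
build_reference <- function(annotation, collection, min_set_size = 1) {
  genes <- unique(annotation$gene_symbol)
  genes <- sort(genes[!is.na(genes) & nzchar(genes)])
  if (!length(genes)) stop2("annotation yields an empty gene universe")
  sets <- lapply(collection, function(s) intersect(unique(s), genes))
  empty <- lengths(sets) < min_set_size
  if (any(empty)) {
    warning(sum(empty), " gene set(s) dropped (fewer than ", min_set_size,
            " genes on the array)")
    sets <- sets[!empty]
  }
  list(universe = genes, sets = sets)
}

#' Map EWAS hits to a gene list
#'
#' Unique gene symbols of probes with p strictly below the cutoff,
#' intersected with the annotation's gene universe.
#'
#' @param results \code{ewas_result} table.
#' @param annotation validated annotation table.
#' @param p_cutoff strict cutoff, default 1e-4.
#' @return character vector of hit gene symbols (possibly empty).
#' @export
hits_to_genes <- function(results, annotation, p_cutoff = 1e-4) {
  hit <- results$probe_id[!is.na(results$p_value) &
                            results$p_value < p_cutoff]
  g <- annotation$gene_symbol[match(hit, annotation$probe_id)]
  sort(unique(g[!is.na(g) & nzchar(g)]))
}

#' Hypergeometric over-representation test for one gene set
#'
#' @param hit_genes hit gene list (assumed within the universe).
#' @param set_genes one gene set (intersected with the universe).
#' @param universe reference gene universe.
#' @return list with \code{C}, \code{O}, \code{E}, \code{R},
#'   \code{raw_p} (upper-tail P(X >= O) for X ~ hypergeometric) and the
#'   overlapping \code{genes}.
#' @export
hypergeometric_ora <- function(hit_genes, set_genes, universe) {
  N <- length(universe)
  hits <- intersect(hit_genes, universe)
  set <- intersect(set_genes, universe)
  n <- length(hits); C <- length(set)
  if (n > N || C > N) stop2("hit list / set larger than universe")
  overlap <- intersect(hits, set)
  O <- length(overlap)
  E <- C * n / N
  if (E == 0 && O > 0) stop2("inconsistent inputs: zero expectation with overlap")
  R <- if (E > 0) O / E else NA_real_
  raw_p <- if (O == 0) 1 else
    stats::phyper(O - 1, C, N - C, n, lower.tail = FALSE)
  list(C = C, O = O, E = E, R = R, raw_p = raw_p, genes = sort(overlap))
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [hypergeometric_ora()] for every set surviving
#' [build_reference()], BH-adjusts the raw p-values with family size
#' equal to the number of sets tested (before any display filtering),
#' and sorts by raw p (ties by set name).
#'
#' @param hit_genes hit gene list from [hits_to_genes()].
#' @param collection gene-set collection.
#' @param annotation annotation table defining the universe.
#' @param min_set_size passed to [build_reference()].
#' @return data frame of class \code{enrichment_table}: \code{pathway},
#'   \code{n_genes} (= O), \code{gene_symbols} (space-separated
#'   overlap), \code{C}, \code{O}, \code{E}, \code{R}, \code{raw_p},
#'   \code{adj_p}. Empty (with a message) when the hit list is empty.
#' @export
enrich_all <- function(hit_genes, collection, annotation,
                       min_set_size = 1) {
  ref <- build_reference(annotation, collection, min_set_size)
  empty <- data.frame(pathway = character(), n_genes = integer(),
                      gene_symbols = character(), C = integer(),
                      O = integer(), E = numeric(), R = numeric(),
                      raw_p = numeric(), adj_p = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_table", "data.frame")
  if (!length(hit_genes)) {
    message("empty hit gene list; enrichment skipped")
    return(empty)
  }
  if (!length(ref$sets)) return(empty)
  hits <- intersect(hit_genes, ref$universe)
  recs <- lapply(names(ref$sets), function(nm) {
    r <- hypergeometric_ora(hits, ref$sets[[nm]], ref$universe)
    data.frame(pathway = nm, n_genes = r$O,
               gene_symbols = paste(r$genes, collapse = " "),
               C = r$C, O = r$O, E = r$E, R = r$R, raw_p = r$raw_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$adj_p <- benjamini_hochberg(out$raw_p, m_total = nrow(out))
  out <- out[order(out$raw_p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, n = 10, ...) {
  cat(sprintf("Over-representation analysis: %d sets tested\n", nrow(x)))
  if (nrow(x))
    print.data.frame(utils::head(
      x[, c("pathway", "C", "O", "E", "R", "raw_p", "adj_p")], n),
      row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an enrichment table to TSV
#' @param x \code{enrichment_table}.
#' @param path output file path.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
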