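#' twinewas: twin-cohort EWAS pipeline
#'
#' Paired (within-pair difference) and unpaired (pair random-intercept)
#' epigenome-wide association scans for monozygotic twin cohorts, with
#' probe QC, cognitive-composite phenotype construction, PLS imputation of
#' blood cell counts, reporting utilities, gene-set over-representation
#' analysis, and a synthetic cohort generator.
#'
#' @keywords internal
"_PACKAGE"

## Controlled vocabularies shared across modules -----------------------------

#' Leukocyte subtypes tracked by the pipeline
#' @export
CELL_TYPES <- c("monocytes", "lymphocytes", "basophils", "neutrophils",
                "eosinophils")

#' Cognitive test battery feeding the composite score
#' @export
COGNITIVE_TESTS <- c("verbal_fluency", "immediate_recall", "delayed_recall",
                     "processing_speed", "attention", "working_memory")

#' Assessment waves
#' @export
WAVES <- c("intake", "followup")

# Gene-region x CpG-island-context vocabulary of 450K-style annotation.
CGI_REGIONS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR",
                 "IGR")
CGI_CONTEXTS <- c("island", "shore", "shelf", "open sea")

#' Valid CpG-island feature labels
#'
#' Cross product of gene region (TSS200, TSS1500, 5'UTR, 1stExon, Body,
#' 3'UTR, IGR) and island context (island, shore, shelf, open sea), joined
#' with a hyphen, e.g. \code{"Body-island"} or \code{"IGR-open sea"}.
#' @export
CGI_FEATURES <- as.vector(outer(CGI_REGIONS, CGI_CONTEXTS, paste, sep = "-"))

stop2 <- function(...) stop(..., call. = FALSE)

## Beta matrix ----------------------------------------------------------------

#' Validate a methylation beta-value matrix
#'
#' A beta matrix is a numeric probes x samples matrix of methylation
#' fractions with unique probe row names and sample column names. Missing
#' measurements are \code{NA}; all non-missing values must lie in [0, 1].
#'
#' @param x numeric matrix, probes in rows, samples in columns.
#' @return \code{x}, invisibly, after validation.
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop2("beta matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop2("beta matrix must carry probe row names and sample column names")
  if (anyDuplicated(rownames(x)))
    stop2("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(x)))
    stop2("duplicate sample ids in beta matrix")
  bad <- which(!is.na(x) & (x < 0 | x > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop2(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(x)[i[1]], colnames(x)[i[2]], x[bad[1]]))
  }
  invisible(x)
}

# Read a numeric TSV matrix with a header and first id column; errors name
# the offending row/column. "NA" is the only missing code.
read_numeric_matrix <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) < 2)
    stop2(sprintf("'%s': expected an id column plus data columns", path))
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop2(sprintf("'%s': duplicate row ids (e.g. '%s')", path,
                  ids[anyDuplicated(ids)]))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(vals)))
    stop2(sprintf("'%s': duplicate column ids", path))
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals == "NA" | is.na(vals)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(vals))
    stop2(sprintf("'%s': malformed numeric cell '%s' at row '%s', column '%s'",
                  path, vals[bad[1]], ids[i[1]], colnames(vals)[i[2]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

write_tsv_matrix <- function(x, path, id_col) {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a beta-value matrix from TSV
#'
#' Expects probes in rows and samples in columns, a header line of sample
#' ids, a leading probe-id column, tab delimiters and literal \code{NA} for
#' missing values.
#'
#' @param path file path.
#' @return validated beta matrix (see [validate_beta_matrix()]).
#' @export
read_beta_matrix <- function(path) {
  x <- read_numeric_matrix(path)
  validate_beta_matrix(x)
  x
}

#' Write a beta-value matrix to TSV
#' @param x beta matrix.
#' @param path output file path.
#' @export
write_beta_matrix <- function(x, path) {
  validate_beta_matrix(x)
  write_tsv_matrix(x, path, "probe_id")
}

#' Read / write an M-value matrix (TSV)
#'
#' Same dialect as [read_beta_matrix()] but values are unbounded
#' log2-ratios.
#' @param path file path.
#' @return numeric matrix, probes x samples.
#' @export
read_m_matrix <- function(path) read_numeric_matrix(path)

#' @rdname read_m_matrix
#' @param x M-value matrix.
#' @export
write_m_matrix <- function(x, path) write_tsv_matrix(x, path, "probe_id")

## Sample sheet ---------------------------------------------------------------

#' Validate a twin-cohort sample sheet
#'
#' Columns: \code{sample_id}, \code{pair_id}, \code{sex} (female/male),
#' \code{age_followup} (years), \code{chip_side} (Left/Right),
#' \code{chip_row} (1..6). Monozygotic design constraints are enforced:
#' members of a pair share sex and follow-up age, and a pair has one or
#' two members. Adds a logical \code{pair_complete} column (both members
#' present).
#'
#' @param sheet data frame.
#' @return the sheet with a \code{pair_complete} column.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "pair_id", "sex", "age_followup", "chip_side",
            "chip_row")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop2("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop2("duplicate sample ids in sample sheet")
  if (!all(sheet$sex %in% c("female", "male")))
    stop2("sex must be 'female' or 'male'")
  if (!all(sheet$chip_side %in% c("Left", "Right")))
    stop2("chip_side must be 'Left' or 'Right'")
  if (!all(as.integer(sheet$chip_row) %in% 1:6))
    stop2("chip_row must be in 1..6")
  if (anyNA(sheet$chip_side) || anyNA(sheet$chip_row))
    stop2("chip position fields must be non-missing")
  sizes <- table(sheet$pair_id)
  if (any(sizes > 2))
    stop2("pair with more than two members: ",
          names(sizes)[which(sizes > 2)[1]])
  for (p in unique(sheet$pair_id)) {
    rows <- sheet[sheet$pair_id == p, ]
    if (length(unique(rows$sex)) > 1)
      stop2(sprintf("pair '%s' has discordant sex (monozygotic pairs are same-sex)", p))
    if (length(unique(rows$age_followup)) > 1)
      stop2(sprintf("pair '%s' has discordant follow-up age", p))
  }
  sheet$pair_complete <- as.vector(sizes[sheet$pair_id] == 2)
  sheet
}

#' Read a sample sheet from TSV
#' @param path file path.
#' @return validated sample sheet data frame (see
#'   [validate_sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             colClasses = c(sample_id = "character",
                                            pair_id = "character"))
  validate_sample_sheet(sheet)
}

#' Write a sample sheet to TSV
#' @param sheet sample sheet data frame.
#' @param path output file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  keep <- setdiff(names(sheet), "pair_complete")
  utils::write.table(sheet[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

## Cell counts ----------------------------------------------------------------

#' Validate a leukocyte count table
#'
#' Columns: \code{sample_id} plus the five subtypes in [CELL_TYPES]
#' (cells per volume; missing allowed) and an optional logical
#' \code{imputed} flag (defaulting to \code{FALSE}).
#'
#' @param counts data frame.
#' @return validated data frame with an \code{imputed} column.
#' @export
validate_cell_counts <- function(counts) {
  need <- c("sample_id", CELL_TYPES)
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop2("cell count table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(counts$sample_id))
    stop2("duplicate sample ids in cell count table")
  for (ct in CELL_TYPES) {
    v <- counts[[ct]]
    if (!is.numeric(v)) stop2("cell counts must be numeric: ", ct)
    if (any(!is.na(v) & v < 0)) stop2("negative cell count in column ", ct)
  }
  if (is.null(counts$imputed)) counts$imputed <- FALSE
  counts
}

#' Read a leukocyte count table from TSV
#' @param path file path.
#' @return validated cell count data frame.
#' @export
read_cell_counts <- function(path) {
  counts <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "",
                              colClasses = c(sample_id = "character"))
  validate_cell_counts(counts)
}

#' Write a leukocyte count table to TSV
#' @param counts cell count data frame.
#' @param path output file path.
#' @export
write_cell_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

## Probe annotation -----------------------------------------------------------

#' Validate a probe annotation table
#'
#' Columns: \code{probe_id}, \code{chromosome}, \code{position} (1-based
#' bp), \code{gene_symbol} (most proximal gene), \code{distance_bp}
#' (signed; negative = probe upstream of the gene; \code{NA} when the
#' probe lies within the gene) and \code{cgi_feature} (one of
#' [CGI_FEATURES]).
#'
#' @param ann data frame.
#' @return validated annotation data frame.
#' @export
validate_annotation <- function(ann) {
  need <- c("probe_id", "chromosome", "position", "gene_symbol",
            "distance_bp", "cgi_feature")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop2("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id))
    stop2("duplicate probe ids in annotation")
  if (any(!is.na(ann$position) & ann$position < 1))
    stop2("annotation positions must be >= 1 (1-based coordinates)")
  bad <- !is.na(ann$cgi_feature) & !(ann$cgi_feature %in% CGI_FEATURES)
  if (any(bad))
    stop2("invalid cgi_feature value: ", ann$cgi_feature[which(bad)[1]])
  ann
}

#' Read a probe annotation table from TSV
#' @param path file path.
#' @return validated annotation data frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c(probe_id = "character",
                                          chromosome = "character",
                                          gene_symbol = "character"))
  validate_annotation(ann)
}

#' Write a probe annotation table to TSV
#' @param ann annotation data frame.
#' @param path output file path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

## Cognitive components -------------------------------------------------------

#' Validate a cognitive component table
#'
#' Columns: \code{sample_id}, \code{wave} (intake/followup) and the six
#' test scores in [COGNITIVE_TESTS], each possibly missing.
#'
#' @param comp data frame.
#' @return validated data frame.
#' @export
validate_components <- function(comp) {
  need <- c("sample_id", "wave", COGNITIVE_TESTS)
  miss <- setdiff(need, names(comp))
  if (length(miss))
    stop2("component table missing columns: ", paste(miss, collapse = ", "))
  if (!all(comp$wave %in% WAVES))
    stop2("wave must be one of: ", paste(WAVES, collapse = ", "))
  if (anyDuplicated(comp[, c("sample_id", "wave")]))
    stop2("duplicate sample/wave rows in component table")
  comp
}

#' Read a cognitive component table from TSV
#' @param path file path.
#' @return validated component data frame.
#' @export
read_components <- function(path) {
  comp <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            colClasses = c(sample_id = "character",
                                           wave = "character"))
  validate_components(comp)
}

#' Write a cognitive component table to TSV
#' @param comp component data frame.
#' @param path output file path.
#' @export
write_components <- function(comp, path) {
  utils::write.table(comp, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

## Gene sets (GMT) ------------------------------------------------------------

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate symbols
#' within a set are deduplicated; set names must be unique.
#'
#' @param path file path.
#' @param source_label optional label naming the collection (e.g. the
#'   pathway database); defaults to the file name.
#' @return object of class \code{gene_set_collection}: a named list of
#'   character vectors with attribute \code{source}.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    sets <- structure(list(), names = character())
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3)
    if (length(short))
      stop2(sprintf("GMT parse error at line %d: fewer than 3 fields",
                    short[1]))
    names(fields) <- vapply(fields, `[[`, "", 1)
    if (anyDuplicated(names(fields)))
      stop2("duplicate gene-set names in GMT file")
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  }
  structure(sets, class = "gene_set_collection", source = source_label)
}

#' Write a gene-set collection to GMT
#' @param collection named list of gene symbol vectors.
#' @param path output file path.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets\n",
              attr(x, "source"), length(x)))
  if (length(x)) {
    sizes <- lengths(x)
    cat(sprintf("  set sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}
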