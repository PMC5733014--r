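## Within-pair difference association scan.
##
## For each complete monozygotic pair the minuend twin is the member with
## the lexicographically smaller sample id; the within-pair differences
## of M-values, phenotype and cell counts are all taken with that
## orientation, so the design is invariant to input row order. Per probe,
## the M-value difference is regressed by OLS on the phenotype difference
## with an intercept and the pair-level covariates sex (female = 1) and
## follow-up age plus the five cell-count differences. Differencing
## removes all pair-shared (genetic and shared-environment) effects; the
## intercept absorbs any orientation-dependent mean shift.

PAIRED_COVARIATES <- c("sex_female", "age_followup",
                       paste0("d_", CELL_TYPES))

#' Build the within-pair difference design
#'
#' @param mvalues M-value matrix (probes x samples).
#' @param sample_sheet validated sample sheet.
#' @param phenotype data frame with \code{sample_id}, \code{value} and
#'   logical \code{available} (a composite or change-score table).
#' @param cell_counts completed cell count table (no missing subtypes).
#' @return object of class \code{paired_design}: list with \code{pairs}
#'   (one row per complete pair: pair_id, minuend, subtrahend,
#'   d_phenotype, sex_female, age_followup, d_<cell> columns),
#'   \code{delta_m} (probes x pairs matrix of M-value differences) and
#'   \code{excluded} (pair_id, reason).
#' @export
build_pair_differences <- function(mvalues, sample_sheet, phenotype,
                                   cell_counts) {
  cell_counts <- validate_cell_counts(cell_counts)
  sheet <- sample_sheet[sample_sheet$sample_id %in% colnames(mvalues), ]
  phen <- phenotype$value[match(sheet$sample_id, phenotype$sample_id)]
  avail <- phenotype$available[match(sheet$sample_id, phenotype$sample_id)]
  phen[is.na(avail) | !avail] <- NA_real_
  counts <- as.matrix(
    cell_counts[match(sheet$sample_id, cell_counts$sample_id), CELL_TYPES])

  pair_ids <- sort(unique(sheet$pair_id))
  rows <- list(); excluded <- list(); minuends <- subtrahends <- character()
  for (p in pair_ids) {
    idx <- which(sheet$pair_id == p)
    if (length(idx) < 2) {
      excluded[[p]] <- "incomplete pair"
      next
    }
    idx <- idx[order(sheet$sample_id[idx])]  # minuend = smaller sample id
    a <- idx[1]; b <- idx[2]
    if (is.na(phen[a]) || is.na(phen[b])) {
      excluded[[p]] <- "phenotype unavailable"
      next
    }
    if (anyNA(counts[a, ]) || anyNA(counts[b, ])) {
      excluded[[p]] <- "cell counts unavailable"
      next
    }
    rows[[p]] <- data.frame(
      pair_id = p,
      minuend = sheet$sample_id[a], subtrahend = sheet$sample_id[b],
      d_phenotype = phen[a] - phen[b],
      sex_female = as.numeric(sheet$sex[a] == "female"),
      age_followup = sheet$age_followup[a],
      stringsAsFactors = FALSE)
    dcell <- counts[a, ] - counts[b, ]
    for (k in seq_along(CELL_TYPES))
      rows[[p]][[paste0("d_", CELL_TYPES[k])]] <- dcell[k]
    minuends <- c(minuends, sheet$sample_id[a])
    subtrahends <- c(subtrahends, sheet$sample_id[b])
  }
  if (!length(rows)) stop2("no complete pairs with phenotype available")
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  delta_m <- mvalues[, minuends, drop = FALSE] -
    mvalues[, subtrahends, drop = FALSE]
  colnames(delta_m) <- pairs$pair_id
  excluded_df <- data.frame(pair_id = names(excluded),
                            reason = unlist(excluded, use.names = FALSE),
                            stringsAsFactors = FALSE)
  if (!nrow(excluded_df))
    excluded_df <- data.frame(pair_id = character(), reason = character(),
                              stringsAsFactors = FALSE)
  structure(list(pairs = pairs, delta_m = delta_m, excluded = excluded_df),
            class = "paired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("Paired design: %d complete pairs, %d probes, %d excluded\n",
              nrow(x$pairs), nrow(x$delta_m), nrow(x$excluded)))
  invisible(x)
}

#' Keep the most phenotype-discordant pairs
#'
#' Ranks pairs by |phenotype difference| in decreasing order (ties broken
#' by pair id) and keeps the top \code{ceiling(fraction * n)}.
#'
#' @param design [build_pair_differences()] output.
#' @param fraction fraction of pairs to keep, in (0, 1]; default 0.5 (the
#'   "50\% most discordant" subset).
#' @return subsetted \code{paired_design}.
#' @export
select_most_discordant <- function(design, fraction = 0.5) {
  stopifnot(inherits(design, "paired_design"))
  if (fraction <= 0 || fraction > 1) stop2("fraction must be in (0, 1]")
  ord <- order(-abs(design$pairs$d_phenotype), design$pairs$pair_id)
  keep <- sort(ord[seq_len(ceiling(fraction * nrow(design$pairs)))])
  structure(list(pairs = design$pairs[keep, , drop = FALSE],
                 delta_m = design$delta_m[, keep, drop = FALSE],
                 excluded = design$excluded),
            class = "paired_design")
}

# Vectorized per-probe OLS scan: regress each row of Y (probes x units)
# on X, report the coefficient in column `which_coef` with its t-based
# two-sided p. Rows with missing values are refitted on complete cases.
ols_scan <- function(Y, X, which_coef) {
  n <- ncol(Y); p <- ncol(X)
  est <- se <- pv <- rep(NA_real_, nrow(Y))
  nunit <- rep(NA_integer_, nrow(Y))
  fit_block <- function(Yb, Xb, k) {
    qrX <- qr(Xb)
    if (qrX$rank < ncol(Xb)) {
      # drop aliased columns (pivoted out); results unavailable when the
      # reported coefficient itself is aliased
      keep <- sort(qrX$pivot[seq_len(qrX$rank)])
      if (!(k %in% keep)) return(NULL)
      return(fit_block(Yb, Xb[, keep, drop = FALSE], match(k, keep)))
    }
    coefs <- qr.coef(qrX, t(Yb))
    coefs <- matrix(coefs, ncol = nrow(Yb))
    res <- t(Yb) - Xb %*% coefs
    dfres <- nrow(Xb) - ncol(Xb)
    sigma2 <- colSums(res^2) / dfres
    XtXinv_kk <- chol2inv(qr.R(qrX))[k, k]
    list(est = coefs[k, ], se = sqrt(sigma2 * XtXinv_kk), df = dfres)
  }
  complete <- !apply(is.na(Y), 1, any)
  if (any(complete)) {
    blk <- fit_block(Y[complete, , drop = FALSE], X, which_coef)
    if (!is.null(blk)) {
      est[complete] <- blk$est
      se[complete] <- blk$se
      pv[complete] <- 2 * stats::pt(-abs(blk$est / blk$se), df = blk$df)
      nunit[complete] <- n
    }
  }
  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    if (sum(ok) <= p) next
    blk <- fit_block(Y[i, ok, drop = FALSE], X[ok, , drop = FALSE], which_coef)
    if (is.null(blk)) next
    est[i] <- blk$est
    se[i] <- blk$se
    pv[i] <- 2 * stats::pt(-abs(blk$est / blk$se), df = blk$df)
    nunit[i] <- sum(ok)
  }
  list(estimate = est, std_error = se, p_value = pv, n_units = nunit)
}

#' Run the paired (within-pair difference) EWAS
#'
#' Per probe: OLS of the M-value difference on {intercept, phenotype
#' difference, sex, follow-up age, five cell-count differences}; reports
#' the phenotype-difference coefficient, its standard error and a
#' two-sided t test with \code{n_pairs - 8} degrees of freedom.
#'
#' @param design [build_pair_differences()] output (possibly subsetted by
#'   [select_most_discordant()]).
#' @param probes optional probe id subset; default all probes.
#' @param analysis label recorded in the result table, e.g.
#'   \code{"paired-cognition"}.
#' @return data frame of class \code{ewas_result}: \code{probe_id},
#'   \code{estimate} (M-value units per phenotype unit),
#'   \code{std_error}, \code{p_value}, \code{n_units}, \code{analysis}.
#'   Probes that cannot be fitted (e.g. constant phenotype difference)
#'   carry \code{NA} statistics.
#' @export
run_paired_ewas <- function(design, probes = NULL,
                            analysis = "paired-cognition") {
  stopifnot(inherits(design, "paired_design"))
  Y <- design$delta_m
  if (!is.null(probes)) Y <- Y[probes, , drop = FALSE]
  pr <- design$pairs
  if (nrow(pr) < 9)
    stop2("paired scan needs at least 9 pairs (8 model parameters)")
  X <- cbind(intercept = 1, d_phenotype = pr$d_phenotype,
             as.matrix(pr[, PAIRED_COVARIATES]))
  scan <- ols_scan(Y, X, which_coef = 2L)
  out <- data.frame(probe_id = rownames(Y), estimate = scan$estimate,
                    std_error = scan$std_error, p_value = scan$p_value,
                    n_units = scan$n_units, analysis = analysis,
                    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' @export
print.ewas_result <- function(x, n = 6, ...) {
  cat(sprintf("EWAS results (%s): %d probes, %s units\n",
              paste(unique(x$analysis), collapse = ", "), nrow(x),
              paste(unique(stats::na.omit(x$n_units)), collapse = "/")))
  ord <- order(x$p_value)
  print.data.frame(utils::head(x[ord, ], n), row.names = FALSE, ...)
  if (nrow(x) > n) cat("  ... (showing the", n, "smallest p-values)\n")
  invisible(x)
}

#' Write an EWAS result table to TSV
#' @param results \code{ewas_result} data frame (annotated or not).
#' @param path output file path.
#' @export
write_ewas_result <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
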