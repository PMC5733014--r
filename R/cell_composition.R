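## Imputation of missing leukocyte counts.
##
## A multivariate partial-least-squares regression is trained on samples
## with measured counts: response = log(count + 1) for the five subtypes,
## predictors = every probe observed in all samples plus sex, follow-up
## age and chip-position dummies (side and row). Predictors are centered
## and unit-scaled with training statistics. Predictions are
## back-transformed with exp(.) - 1 and floored at zero.

# Assemble the predictor matrix: fully observed probes + covariates.
# Zero-variance predictors (e.g. a constant covariate in a fixture) are
# dropped and recorded -- they carry no information and break unit
# scaling.
cell_predictor_matrix <- function(beta, sample_sheet) {
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  if (anyNA(sheet$sample_id))
    stop2("sample sheet does not cover all beta-matrix samples")
  complete <- !apply(is.na(beta), 1, any)
  X <- t(beta[complete, , drop = FALSE])
  cov <- cbind(sex_female = as.numeric(sheet$sex == "female"),
               age_followup = sheet$age_followup,
               chip_right = as.numeric(sheet$chip_side == "Right"))
  rows <- as.integer(sheet$chip_row)
  for (r in 2:6)
    cov <- cbind(cov, as.numeric(rows == r))
  colnames(cov)[4:8] <- paste0("chip_row_", 2:6)
  X <- cbind(X, cov)
  rownames(X) <- colnames(beta)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  list(X = X[, keep, drop = FALSE],
       dropped_constant = colnames(X)[!keep],
       complete_probes = rownames(beta)[complete])
}

#' Fit the cell-count imputation model
#'
#' @param beta beta matrix covering all samples (training and to-impute);
#'   only probes observed in every sample enter the predictor set.
#' @param sample_sheet validated sample sheet.
#' @param cell_counts cell count table; samples with all five subtypes
#'   observed form the training set.
#' @param n_components number of PLS latent components (default 10,
#'   capped nowhere -- an infeasible value errors).
#' @return object of class \code{cell_imputer} holding the fitted PLS
#'   model, the predictor list and training metadata.
#' @export
fit_cell_imputer <- function(beta, sample_sheet, cell_counts,
                             n_components = 10) {
  if (n_components < 1) stop2("n_components must be >= 1")
  cell_counts <- validate_cell_counts(cell_counts)
  pred <- cell_predictor_matrix(beta, sample_sheet)
  counts <- cell_counts[match(rownames(pred$X), cell_counts$sample_id), ]
  complete_counts <- stats::complete.cases(counts[, CELL_TYPES])
  train <- which(complete_counts)
  if (length(train) < n_components + 1)
    stop2("need at least n_components + 1 samples with complete counts")
  if (n_components > ncol(pred$X))
    stop2("n_components exceeds the number of predictors")
  Y <- log(as.matrix(counts[train, CELL_TYPES]) + 1)
  rownames(Y) <- counts$sample_id[train]
  fit <- mixOmics::pls(pred$X[train, , drop = FALSE], Y,
                       ncomp = n_components, mode = "regression",
                       scale = TRUE)
  structure(list(fit = fit, n_components = n_components,
                 predictors = colnames(pred$X),
                 complete_probes = pred$complete_probes,
                 dropped_constant = pred$dropped_constant,
                 training_samples = rownames(Y)),
            class = "cell_imputer")
}

#' @export
print.cell_imputer <- function(x, ...) {
  cat(sprintf(
    "Cell-count imputer: %d PLS components, %d predictors (%d probes), %d training samples\n",
    x$n_components, length(x$predictors), length(x$complete_probes),
    length(x$training_samples)))
  invisible(x)
}

#' Predict counts for samples (log scale handled internally)
#'
#' Internal helper: assembles exactly the model's predictor columns for
#' the target samples (no re-derivation of the predictor list, so the
#' training predictor set is binding) and returns back-transformed
#' counts.
#' @noRd
predict_cell_counts <- function(model, beta, sample_sheet, samples) {
  sheet <- sample_sheet[match(samples, sample_sheet$sample_id), ]
  if (anyNA(sheet$sample_id))
    stop2("sample sheet does not cover all prediction samples")
  probe_preds <- intersect(model$predictors, rownames(beta))
  cov <- cbind(sex_female = as.numeric(sheet$sex == "female"),
               age_followup = sheet$age_followup,
               chip_right = as.numeric(sheet$chip_side == "Right"))
  rows <- as.integer(sheet$chip_row)
  for (r in 2:6) cov <- cbind(cov, as.numeric(rows == r))
  colnames(cov)[4:8] <- paste0("chip_row_", 2:6)
  X <- cbind(t(beta[probe_preds, samples, drop = FALSE]),
             cov[, intersect(model$predictors, colnames(cov)), drop = FALSE])
  missing_pred <- setdiff(model$predictors, colnames(X))
  if (length(missing_pred))
    stop2("sample set lacks model predictor(s): ",
          paste(utils::head(missing_pred, 3), collapse = ", "))
  X <- X[, model$predictors, drop = FALSE]
  rownames(X) <- samples
  if (anyNA(X)) {
    bad <- which(colSums(is.na(X)) > 0)[1]
    stop2("missing value in predictor '", colnames(X)[bad], "'")
  }
  pr <- stats::predict(model$fit, X)$predict[, , model$n_components,
                                             drop = FALSE]
  pr <- matrix(pr, nrow = nrow(X),
               dimnames = list(samples, CELL_TYPES))
  pmax(exp(pr) - 1, 0)
}

#' Impute missing leukocyte counts
#'
#' Samples with observed counts are returned unchanged
#' (\code{imputed = FALSE}); samples with any missing subtype get all
#' five subtypes replaced by model predictions, back-transformed with
#' \code{exp(.) - 1} and floored at 0, and are flagged
#' \code{imputed = TRUE}.
#'
#' @param model [fit_cell_imputer()] output.
#' @param beta beta matrix covering the samples to impute.
#' @param sample_sheet validated sample sheet.
#' @param cell_counts cell count table for all samples.
#' @return completed cell count table.
#' @export
impute_missing_counts <- function(model, beta, sample_sheet, cell_counts) {
  stopifnot(inherits(model, "cell_imputer"))
  cell_counts <- validate_cell_counts(cell_counts)
  incomplete <- !stats::complete.cases(cell_counts[, CELL_TYPES])
  cell_counts$imputed <- FALSE
  if (!any(incomplete)) return(cell_counts)
  targets <- cell_counts$sample_id[incomplete]
  preds <- predict_cell_counts(model, beta, sample_sheet, targets)
  cell_counts[incomplete, CELL_TYPES] <- preds[targets, , drop = FALSE]
  cell_counts$imputed[incomplete] <- TRUE
  cell_counts
}

#' Choose the number of PLS components by cross-validation
#'
#' Simple grid search minimizing k-fold cross-validated prediction error
#' (mean squared error on the log-count scale, summed over subtypes).
#'
#' @param beta,sample_sheet,cell_counts as in [fit_cell_imputer()].
#' @param grid candidate component counts.
#' @param folds number of CV folds; \code{folds = n} gives leave-one-out.
#' @param seed fold-assignment seed.
#' @return list with \code{best} (chosen component count) and \code{cv}
#'   (data frame of per-candidate mean squared errors).
#' @export
choose_n_components <- function(beta, sample_sheet, cell_counts,
                                grid = c(2, 5, 10, 15), folds = 10,
                                seed = 1) {
  cell_counts <- validate_cell_counts(cell_counts)
  pred <- cell_predictor_matrix(beta, sample_sheet)
  counts <- cell_counts[match(rownames(pred$X), cell_counts$sample_id), ]
  train <- which(stats::complete.cases(counts[, CELL_TYPES]))
  Y <- log(as.matrix(counts[train, CELL_TYPES]) + 1)
  X <- pred$X[train, , drop = FALSE]
  n <- nrow(X)
  folds <- min(folds, n)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  grid <- grid[grid <= min(ncol(X), n - ceiling(n / folds) - 1)]
  if (!length(grid)) stop2("no feasible component counts in grid")
  mse <- sapply(grid, function(k) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- mixOmics::pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                           ncomp = k, mode = "regression", scale = TRUE)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE])$predict[, , k]
      mean((pr - Y[!tr, , drop = FALSE])^2)
    }, 0)
    mean(errs)
  })
  list(best = grid[which.min(mse)],
       cv = data.frame(n_components = grid, mse = mse))
}
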