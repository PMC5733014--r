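## Individual-level association scan with a twin-pair random intercept.
##
## Model: y = X beta + u_pair + e, u ~ N(0, sigma2_pair),
## e ~ N(0, sigma2_resid). With clusters of size <= 2 the marginal
## covariance is block diagonal with 2x2 compound-symmetric blocks, so
## for a candidate variance ratio lambda = sigma2_pair / sigma2_resid the
## model reduces to weighted least squares in a rotated basis:
##   pair (y1, y2)  ->  (y1+y2)/sqrt(2) with variance sigma2_resid(1+2l),
##                      (y1-y2)/sqrt(2) with variance sigma2_resid,
##   singleton y    ->  y with variance sigma2_resid(1+l).
## The restricted likelihood is profiled over beta and sigma2_resid,
## leaving a one-dimensional REML criterion in lambda that is maximized
## by Brent search on the log scale over [0, 1e6], with the boundary
## lambda = 0 (plain OLS) always considered.

# Rotate y (vector or matrix with units in rows) and X into the
# decorrelated basis. `pair_ids` defines clusters; any cluster size > 2
# is an error. Returns the rotated pieces plus a variance-type code per
# rotated row: 1 = pair sum, 2 = pair difference, 3 = singleton.
rotate_pairs <- function(X, pair_ids) {
  sizes <- table(pair_ids)
  if (any(sizes > 2)) stop2("clusters larger than 2 are not supported")
  idx1 <- idx2 <- integer(0)
  singles <- integer(0)
  for (p in names(sizes)) {
    i <- which(pair_ids == p)
    if (length(i) == 2) {
      idx1 <- c(idx1, i[1]); idx2 <- c(idx2, i[2])
    } else singles <- c(singles, i)
  }
  s <- 1 / sqrt(2)
  Xr <- rbind((X[idx1, , drop = FALSE] + X[idx2, , drop = FALSE]) * s,
              (X[idx1, , drop = FALSE] - X[idx2, , drop = FALSE]) * s,
              X[singles, , drop = FALSE])
  vtype <- rep(c(1L, 2L, 3L),
               c(length(idx1), length(idx1), length(singles)))
  list(X = Xr, vtype = vtype, idx1 = idx1, idx2 = idx2, singles = singles)
}

rotate_response <- function(y, rot) {
  s <- 1 / sqrt(2)
  c((y[rot$idx1] + y[rot$idx2]) * s,
    (y[rot$idx1] - y[rot$idx2]) * s,
    y[rot$singles])
}

# Restricted log-likelihood profiled over beta and sigma2_resid, as a
# function of lambda, in the rotated basis.
reml_criterion_rotated <- function(lambda, yr, Xr, vtype) {
  v <- c(1 + 2 * lambda, 1, 1 + lambda)[vtype]
  w <- 1 / sqrt(v)
  fit <- stats::lm.fit(Xr * w, yr * w)
  p <- fit$rank
  n <- length(yr)
  if (p < ncol(Xr)) return(-Inf)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(fit$qr)
  logdet_xwx <- 2 * sum(log(abs(diag(R))))
  logdet_w <- sum(log(v))
  -0.5 * ((n - p) * (1 + log(2 * pi * sigma2)) + logdet_w + logdet_xwx)
}

# GLS fit at a fixed lambda; returns coefficients, covariance, sigma2.
gls_at_lambda <- function(lambda, yr, Xr, vtype) {
  v <- c(1 + 2 * lambda, 1, 1 + lambda)[vtype]
  w <- 1 / sqrt(v)
  Xw <- Xr * w
  qrX <- qr(Xw)
  coefs <- qr.coef(qrX, yr * w)
  res <- yr * w - Xw %*% coefs
  dfres <- length(yr) - ncol(Xr)
  sigma2 <- sum(res^2) / dfres
  XtXinv <- chol2inv(qr.R(qrX))
  list(coef = coefs, vcov = XtXinv * sigma2, sigma2_resid = sigma2,
       df = dfres)
}

#' Restricted log-likelihood of the pair random-intercept model
#'
#' Profiled over the fixed effects and the residual variance; a function
#' of the variance ratio \code{lambda = sigma2_pair / sigma2_resid}
#' alone. Exposed so the REML optimum can be certified against a grid
#' search.
#'
#' @param y response vector.
#' @param X fixed-effects design matrix.
#' @param pair_ids cluster identifiers (clusters of size 1 or 2).
#' @param lambda non-negative variance ratio (vectorized).
#' @return restricted log-likelihood value(s).
#' @export
reml_loglik <- function(y, X, pair_ids, lambda) {
  ok <- !is.na(y)
  rot <- rotate_pairs(X[ok, , drop = FALSE], pair_ids[ok])
  yr <- rotate_response(y[ok], rot)
  vapply(lambda, reml_criterion_rotated, 0, yr = yr, Xr = rot$X,
         vtype = rot$vtype)
}

# Core fit in the rotated basis (shared by the single-probe entry point
# and the scan). lambda_max bounds the variance-ratio search.
fit_lmm_rotated <- function(yr, Xr, vtype, lambda_max = 1e6) {
  crit <- function(loglam) reml_criterion_rotated(exp(loglam), yr, Xr, vtype)
  opt <- stats::optimize(crit, interval = c(log(1e-8), log(lambda_max)),
                         maximum = TRUE, tol = 1e-9)
  ll0 <- reml_criterion_rotated(0, yr, Xr, vtype)
  if (!is.finite(opt$objective) && !is.finite(ll0))
    return(NULL)
  if (ll0 >= opt$objective) {
    lambda <- 0; ll <- ll0
  } else {
    lambda <- exp(opt$maximum); ll <- opt$objective
  }
  fit <- gls_at_lambda(lambda, yr, Xr, vtype)
  list(lambda = lambda, logreml = ll, fit = fit)
}

#' Fit the pair random-intercept model for one probe
#'
#' REML fit of \code{y = X beta + u_pair + e} by scalar profiling of the
#' variance ratio (see the module header). Wald t inference with
#' \code{n - ncol(X)} degrees of freedom. Missing responses are dropped;
#' a twin whose co-twin is dropped is treated as a singleton.
#'
#' @param y response vector (one probe's M-values across individuals).
#' @param X fixed-effects design matrix (with intercept).
#' @param pair_ids pair identifiers aligned with \code{y}.
#' @param lambda_max upper bound of the variance-ratio search.
#' @return object of class \code{lmm_fit}: coefficients, standard
#'   errors, t and p values, \code{sigma2_pair}, \code{sigma2_resid},
#'   intraclass correlation \code{icc}, \code{logreml}, \code{lambda},
#'   \code{df}, \code{n}, \code{converged}.
#' @export
fit_probe_lmm <- function(y, X, pair_ids, lambda_max = 1e6) {
  ok <- !is.na(y) & !apply(is.na(X), 1, any)
  if (sum(ok) < ncol(X) + 2) stop2("too few observations for the LMM")
  rot <- rotate_pairs(X[ok, , drop = FALSE], pair_ids[ok])
  yr <- rotate_response(y[ok], rot)
  res <- fit_lmm_rotated(yr, rot$X, rot$vtype, lambda_max)
  if (is.null(res))
    return(structure(list(converged = FALSE, n = sum(ok)),
                     class = "lmm_fit"))
  fit <- res$fit
  se <- sqrt(diag(fit$vcov))
  tval <- fit$coef / se
  structure(list(
    coef = fit$coef, se = se, t = tval,
    p = 2 * stats::pt(-abs(tval), df = fit$df),
    sigma2_resid = fit$sigma2_resid,
    sigma2_pair = res$lambda * fit$sigma2_resid,
    icc = res$lambda / (1 + res$lambda),
    logreml = res$logreml, lambda = res$lambda,
    df = fit$df, n = sum(ok), converged = TRUE), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Pair random-intercept fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Pair random-intercept fit (REML): n = %d, sigma2_pair = %.4g, sigma2_resid = %.4g, ICC = %.3f\n",
    x$n, x$sigma2_pair, x$sigma2_resid, x$icc))
  tab <- data.frame(estimate = x$coef, se = x$se, t = x$t, p = x$p)
  print(round(tab, 5))
  invisible(x)
}

# Individual-level fixed-effects design shared by the unpaired scans.
unpaired_design_matrix <- function(sheet, phen, counts) {
  cbind(intercept = 1, phenotype = phen,
        sex_female = as.numeric(sheet$sex == "female"),
        age_followup = sheet$age_followup,
        counts)
}

#' Run the unpaired (pair random-intercept) EWAS
#'
#' Per probe, fits the individual-level model with fixed effects
#' {intercept, phenotype, sex, follow-up age, five cell counts} and a
#' twin-pair random intercept by profiled REML; reports the phenotype
#' coefficient with a Wald t test (\code{n - 8} degrees of freedom).
#' Members of incomplete pairs are included (their random effect
#' integrates out). Probes whose fit fails are flagged unconverged and
#' carry \code{NA} statistics.
#'
#' @param mvalues M-value matrix.
#' @param sample_sheet validated sample sheet.
#' @param phenotype data frame with \code{sample_id}, \code{value},
#'   \code{available}.
#' @param cell_counts completed cell count table.
#' @param probes optional probe subset.
#' @param analysis result label, e.g. \code{"unpaired-cognition"}.
#' @return \code{ewas_result} data frame (see [run_paired_ewas()]) with
#'   an attribute \code{n_not_converged}.
#' @export
run_unpaired_ewas <- function(mvalues, sample_sheet, phenotype, cell_counts,
                              probes = NULL, analysis = "unpaired-cognition") {
  cell_counts <- validate_cell_counts(cell_counts)
  sheet <- sample_sheet[sample_sheet$sample_id %in% colnames(mvalues), ]
  phen <- phenotype$value[match(sheet$sample_id, phenotype$sample_id)]
  avail <- phenotype$available[match(sheet$sample_id, phenotype$sample_id)]
  phen[is.na(avail) | !avail] <- NA_real_
  counts <- as.matrix(
    cell_counts[match(sheet$sample_id, cell_counts$sample_id), CELL_TYPES])
  keep <- !is.na(phen) & !apply(is.na(counts), 1, any)
  if (sum(keep) < 10) stop2("unpaired scan needs at least 10 individuals")
  sheet <- sheet[keep, ]; phen <- phen[keep]; counts <- counts[keep, ]
  if (stats::sd(phen) == 0) stop2("phenotype is constant")
  X <- unpaired_design_matrix(sheet, phen, counts)
  Y <- mvalues[, sheet$sample_id, drop = FALSE]
  if (!is.null(probes)) Y <- Y[probes, , drop = FALSE]

  rot <- rotate_pairs(X, sheet$pair_id)
  est <- se <- pv <- rep(NA_real_, nrow(Y))
  nunit <- rep(NA_integer_, nrow(Y))
  conv <- rep(TRUE, nrow(Y))
  for (i in seq_len(nrow(Y))) {
    yi <- Y[i, ]
    if (anyNA(yi)) {
      f <- tryCatch(fit_probe_lmm(yi, X, sheet$pair_id),
                    error = function(e) NULL)
      if (is.null(f) || !isTRUE(f$converged)) { conv[i] <- FALSE; next }
      est[i] <- f$coef[2]; se[i] <- f$se[2]; pv[i] <- f$p[2]
      nunit[i] <- f$n
      next
    }
    yr <- rotate_response(yi, rot)
    res <- fit_lmm_rotated(yr, rot$X, rot$vtype)
    if (is.null(res)) { conv[i] <- FALSE; next }
    fit <- res$fit
    est[i] <- fit$coef[2]
    se[i] <- sqrt(fit$vcov[2, 2])
    pv[i] <- 2 * stats::pt(-abs(est[i] / se[i]), df = fit$df)
    nunit[i] <- nrow(X)
  }
  if (any(!conv))
    message(sum(!conv), " probe fit(s) did not converge and carry NA results")
  out <- data.frame(probe_id = rownames(Y), estimate = est, std_error = se,
                    p_value = pv, n_units = nunit, analysis = analysis,
                    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  attr(out, "n_not_converged") <- sum(!conv)
  out
}
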