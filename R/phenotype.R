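## Cognitive composite construction.
##
## Six test scores per individual per wave are z-standardized with
## parameters estimated once on a reference wave (default: intake) and
## summed. Using one set of standardization parameters for both waves
## keeps the two composites commeasurable, so the follow-up minus intake
## difference is a meaningful 10-year change score. At most one missing
## component is tolerated; the sum of the remaining five is prorated by
## 6/5. With two or more missing components the composite is unavailable.

#' Estimate per-component standardization parameters
#'
#' Sample mean and SD of each of the six cognitive tests over the
#' individuals observed at the reference wave. The same parameters are
#' subsequently applied to both waves.
#'
#' @param components component table (see [validate_components()]).
#' @param wave reference wave, \code{"intake"} (default) or
#'   \code{"followup"}.
#' @return object of class \code{standardization_params}: list with named
#'   numeric vectors \code{mean} and \code{sd} and the reference
#'   \code{wave}.
#' @export
estimate_standardization <- function(components, wave = "intake") {
  components <- validate_components(components)
  wave <- match.arg(wave, WAVES)
  ref <- components[components$wave == wave, , drop = FALSE]
  mu <- sd_ <- stats::setNames(numeric(length(COGNITIVE_TESTS)),
                               COGNITIVE_TESTS)
  for (tst in COGNITIVE_TESTS) {
    v <- ref[[tst]][!is.na(ref[[tst]])]
    if (length(v) < 2)
      stop2("component '", tst, "' has fewer than 2 observed values at the ",
            wave, " wave")
    mu[tst] <- mean(v)
    sd_[tst] <- stats::sd(v)
    if (sd_[tst] == 0)
      stop2("component '", tst, "' is constant at the ", wave,
            " wave (SD = 0)")
  }
  structure(list(mean = mu, sd = sd_, wave = wave),
            class = "standardization_params")
}

#' Compute composite cognitive scores for one wave
#'
#' Z-scores each available component with the supplied parameters and
#' sums. With exactly one missing component the five-score sum is
#' prorated by 6/5; with two or more missing the score is unavailable.
#'
#' @param components component table.
#' @param params [estimate_standardization()] output.
#' @param wave wave to score.
#' @return data frame \code{sample_id}, \code{wave}, \code{value},
#'   \code{n_components_used}, \code{available}.
#' @export
compute_composite <- function(components, params, wave) {
  stopifnot(inherits(params, "standardization_params"))
  components <- validate_components(components)
  wave <- match.arg(wave, WAVES)
  sub <- components[components$wave == wave, , drop = FALSE]
  z <- sapply(COGNITIVE_TESTS, function(tst)
    (sub[[tst]] - params$mean[tst]) / params$sd[tst])
  z <- matrix(z, nrow = nrow(sub),
              dimnames = list(NULL, COGNITIVE_TESTS))
  n_miss <- rowSums(is.na(z))
  n_used <- 6L - n_miss
  value <- rowSums(z, na.rm = TRUE)
  value[n_miss == 1] <- value[n_miss == 1] * 6 / 5
  available <- n_miss <= 1
  value[!available] <- NA_real_
  data.frame(sample_id = sub$sample_id, wave = wave, value = value,
             n_components_used = as.integer(n_used), available = available,
             stringsAsFactors = FALSE)
}

#' 10-year cognitive change score
#'
#' Follow-up composite minus intake composite per individual; unavailable
#' when either wave's composite is unavailable.
#'
#' @param intake,followup composite tables from [compute_composite()] for
#'   the two waves, covering the same individuals.
#' @return data frame \code{sample_id}, \code{value}, \code{available}.
#' @export
compute_change <- function(intake, followup) {
  if (!setequal(intake$sample_id, followup$sample_id))
    stop2("intake and follow-up composites cover different individuals")
  followup <- followup[match(intake$sample_id, followup$sample_id), ]
  available <- intake$available & followup$available
  value <- ifelse(available, followup$value - intake$value, NA_real_)
  data.frame(sample_id = intake$sample_id, value = value,
             available = available, stringsAsFactors = FALSE)
}

#' Cohort-level test of cognitive change
#'
#' Tests whether mean change differs from zero with an intercept-only
#' linear mixed model carrying a twin-pair random intercept (REML, via
#' lme4), i.e. respecting the non-independence of co-twins. Inference is
#' a Wald t test of the intercept with \code{n_individuals - 1} degrees
#' of freedom (approximate; documented in the methods vignette).
#'
#' @param change change-score table from [compute_change()].
#' @param sample_sheet validated sample sheet providing \code{pair_id}.
#' @return list with \code{mean_change}, \code{se}, \code{t}, \code{df},
#'   \code{p_value}, \code{n_individuals}, \code{n_pairs} and the lme4
#'   \code{fit}.
#' @export
test_cohort_decline <- function(change, sample_sheet) {
  d <- merge(change[change$available, c("sample_id", "value")],
             sample_sheet[, c("sample_id", "pair_id")], by = "sample_id")
  if (nrow(d) == 0) stop2("no available change scores")
  if (length(unique(d$pair_id)) < 2) stop2("need at least 2 pairs")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | pair_id), data = d, REML = TRUE)))
  est <- unname(lme4::fixef(fit)[1])
  se <- sqrt(as.matrix(stats::vcov(fit))[1, 1])
  df <- nrow(d) - 1
  tval <- est / se
  list(mean_change = est, se = se, t = tval, df = df,
       p_value = 2 * stats::pt(-abs(tval), df = df),
       n_individuals = nrow(d), n_pairs = length(unique(d$pair_id)),
       fit = fit)
}
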