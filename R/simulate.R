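## Synthetic monozygotic-twin cohort generator.
##
## Methylation model, per probe p, individual i in pair j:
##   M_pij = mu_p + u_pj + e_pij + cell effects + sex/age effects
## with u ~ N(0, sigma2_pair) shared within pair and e ~ N(0,
## sigma2_indiv) individual (causal probes use causal_sigma2_indiv).
## Betas are the inverse M-value transform of M, giving the bimodal
## marginal distribution typical of array data.
##
## Cognition is generated downstream of methylation: a latent general
## ability with pair-shared and individual parts, plus a coupling
## kappa * sum over causal probes of (M - mu). Cross-sectional causal
## probes feed the ability level (present at both waves, so they do not
## contaminate the change score); longitudinal causal probes feed the
## 10-year change. Six test scores per wave are affine images of the
## latent composite plus sum-to-zero component noise, so the pipeline's
## standardize-and-sum composite recovers the latent scale up to a known
## factor sqrt(v_z).
##
## The couplings are calibrated numerically so that the population
## within-pair regression slope of delta-M on the standardized composite
## difference equals `effect_size_m_per_unit` exactly -- the association
## the paired scan estimates. The calibration accounts for the
## standardization rescaling; infeasible targets (beyond the asymptote
## of the achievable slope) raise an error.

#' Simulation configuration
#'
#' Defaults define the "demo" study conditions (20 pairs x 500 probes);
#' see [simulation_presets()] for the full-scale cohort layout
#' (243 pairs = 111 female + 132 male, 486 individuals).
#'
#' @param seed root RNG seed (single stream, documented draw order).
#' @param n_pairs number of twin pairs.
#' @param n_probes number of CpG probes.
#' @param n_causal_cross_sectional,n_causal_longitudinal planted causal
#'   probe counts per phenotype.
#' @param effect_size_m_per_unit planted association, M-value units per
#'   composite unit (the paired-scan estimand).
#' @param sigma2_pair,sigma2_indiv pair-shared and individual M-value
#'   variance at null probes (defaults give within-pair ICC 0.5).
#' @param causal_sigma2_indiv individual M-value variance at causal
#'   probes (the per-probe residual scale; governs detection power).
#' @param cognition_pair_icc within-pair correlation of the latent
#'   intake ability.
#' @param cognition_sd,intake_mean latent intake composite SD and mean.
#' @param decline_mean,decline_sd latent 10-year change mean and
#'   individual SD.
#' @param component_noise_var variance of per-test noise around the
#'   latent composite (sum-to-zero within individual).
#' @param cell_effect_scale,n_cell_probes SD (M-units per count SD) and
#'   number of probes with leukocyte-composition effects.
#' @param sexage_effect_scale,n_sexage_probes SD and number of probes
#'   with sex/age effects.
#' @param missing_cell_samples samples whose measured counts are masked
#'   (to be imputed downstream).
#' @param qc_bead_rate,qc_detection_rate,qc_zero_rate per-measurement QC
#'   failure rates.
#' @param n_high_missing_probes probes planted with >5\% failed
#'   measurements (dropped by the missingness rule).
#' @param n_cross_reactive probes placed on the cross-reactive list.
#' @param age_mean,age_sd,age_range follow-up age distribution
#'   (truncated normal).
#' @param female_pair_fraction fraction of female pairs.
#' @param incomplete_pair_fraction fraction of pairs with one member
#'   removed.
#' @param component_missing_rate per-cell missingness of raw test
#'   scores.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1,
                              n_pairs = 20,
                              n_probes = 500,
                              n_causal_cross_sectional = 5,
                              n_causal_longitudinal = 5,
                              effect_size_m_per_unit = 0.03,
                              sigma2_pair = 0.1,
                              sigma2_indiv = 0.1,
                              causal_sigma2_indiv = 0.1,
                              cognition_pair_icc = 0.6,
                              cognition_sd = 3.71,
                              intake_mean = -0.53,
                              decline_mean = -1.64,
                              decline_sd = 3,
                              component_noise_var = 0.74,
                              cell_effect_scale = 0.05,
                              n_cell_probes = 25,
                              sexage_effect_scale = 0.05,
                              n_sexage_probes = 25,
                              missing_cell_samples = 0,
                              qc_bead_rate = 0.002,
                              qc_detection_rate = 0.002,
                              qc_zero_rate = 5e-4,
                              n_high_missing_probes = 5,
                              n_cross_reactive = 10,
                              age_mean = 65.9,
                              age_sd = 6.1,
                              age_range = c(55, 79),
                              female_pair_fraction = 111 / 243,
                              incomplete_pair_fraction = 0,
                              component_missing_rate = 0.01) {
  cfg <- as.list(environment())
  if (cfg$n_pairs < 2) stop2("need at least 2 pairs")
  if (any(c(cfg$sigma2_pair, cfg$sigma2_indiv, cfg$causal_sigma2_indiv) < 0))
    stop2("variances must be >= 0")
  if (cfg$cognition_pair_icc < 0 || cfg$cognition_pair_icc >= 1)
    stop2("cognition_pair_icc must be in [0, 1)")
  rates <- c(cfg$qc_bead_rate, cfg$qc_detection_rate, cfg$qc_zero_rate,
             cfg$female_pair_fraction, cfg$incomplete_pair_fraction,
             cfg$component_missing_rate)
  if (any(rates < 0 | rates > 1)) stop2("rates/fractions must be in [0, 1]")
  n_special <- cfg$n_causal_cross_sectional + cfg$n_causal_longitudinal +
    cfg$n_cell_probes + cfg$n_sexage_probes + cfg$n_cross_reactive +
    cfg$n_high_missing_probes
  if (n_special > cfg$n_probes)
    stop2("special probe counts exceed n_probes")
  if (cfg$missing_cell_samples > 2 * cfg$n_pairs)
    stop2("missing_cell_samples exceeds cohort size")
  structure(cfg, class = "simulation_config")
}

#' Bundled simulation presets
#'
#' \code{"demo"}: 20 pairs x 500 probes, runs in seconds.
#' \code{"full_scale"}: 243 pairs (111 female + 132 male, 486
#' individuals) x 20,000 probes with 9 samples missing cell counts,
#' runs in minutes.
#'
#' @param name preset name.
#' @param ... overrides passed to [simulation_config()].
#' @return \code{simulation_config}.
#' @export
simulation_presets <- function(name = c("demo", "full_scale"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    demo = list(),
    full_scale = list(n_pairs = 243, n_probes = 20000,
                       missing_cell_samples = 9, n_cross_reactive = 400,
                       n_high_missing_probes = 200, n_cell_probes = 500,
                       n_sexage_probes = 500))
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

## Effect-size calibration ----------------------------------------------------

# Achievable paired-scan slope (standardized-composite scale) as a
# function of the couplings; see module header for the variance algebra.
calibration_terms <- function(cfg) {
  list(
    s2c = cfg$causal_sigma2_indiv,
    s2p = cfg$sigma2_pair,
    Kcs = cfg$n_causal_cross_sectional,
    Klg = cfg$n_causal_longitudinal,
    a_base = 2 * (1 - cfg$cognition_pair_icc) * cfg$cognition_sd^2 +
      2 * cfg$decline_sd^2,
    a_chg = 2 * cfg$decline_sd^2,
    v0 = cfg$cognition_sd^2 / 36 + (5 / 6) * cfg$component_noise_var)
}

# v_z: variance of one test's latent z-score at intake (the composite
# standardization scale factor is sqrt(v_z)).
calib_vz <- function(tm, kcs) {
  tm$v0 + kcs^2 * tm$Kcs * (tm$s2p + tm$s2c) / 36
}

calib_slope_cs <- function(tm, kcs, klg) {
  denom <- tm$a_base + kcs^2 * tm$Kcs * 2 * tm$s2c +
    klg^2 * tm$Klg * 2 * tm$s2c
  kcs * 2 * tm$s2c * sqrt(calib_vz(tm, kcs)) / denom
}

calib_slope_lg <- function(tm, kcs, klg) {
  denom <- tm$a_chg + klg^2 * tm$Klg * 2 * tm$s2c
  klg * 2 * tm$s2c * sqrt(calib_vz(tm, kcs)) / denom
}

# Smallest kappa achieving `target` for a monotone-then-saturating slope
# curve; errors when the target exceeds the achievable maximum.
solve_one_kappa <- function(slope_fun, target, upper = 1e4) {
  if (target == 0) return(0)
  opt <- stats::optimize(slope_fun, c(0, upper), maximum = TRUE)
  peak <- max(opt$objective, slope_fun(upper))
  if (peak < target)
    stop2(sprintf(
      paste0("planted effect size %.4g is not achievable (maximum %.4g); ",
             "increase causal_sigma2_indiv or sigma2_pair, or reduce the ",
             "effect size"), target, peak))
  hi <- if (opt$objective >= target) opt$maximum else upper
  stats::uniroot(function(k) slope_fun(k) - target, c(0, hi),
                 tol = 1e-12)$root
}

# Joint calibration of the two couplings by alternating 1-D solves.
solve_kappas <- function(cfg) {
  tm <- calibration_terms(cfg)
  target <- cfg$effect_size_m_per_unit
  kcs <- klg <- 0
  t_cs <- if (tm$Kcs > 0) target else 0
  t_lg <- if (tm$Klg > 0) target else 0
  for (it in 1:100) {
    kcs_new <- if (t_cs > 0)
      solve_one_kappa(function(k) calib_slope_cs(tm, k, klg), t_cs) else 0
    klg_new <- if (t_lg > 0)
      solve_one_kappa(function(k) calib_slope_lg(tm, kcs_new, k), t_lg) else 0
    done <- abs(kcs_new - kcs) < 1e-10 && abs(klg_new - klg) < 1e-10
    kcs <- kcs_new; klg <- klg_new
    if (done) break
  }
  list(kappa_cs = kcs, kappa_lg = klg, v_z = calib_vz(tm, kcs))
}

#' Expected paired-scan operating characteristics for a configuration
#'
#' Analytic per-causal-probe correlation with the standardized phenotype
#' difference, the implied t noncentrality at the configured pair count,
#' and the expected two-sided p-value scale, for the cross-sectional
#' analysis. Useful for choosing a configuration whose planted effects
#' are expected to clear a reporting threshold.
#'
#' @param config [simulation_config()].
#' @return list with \code{rho} (within-pair correlation),
#'   \code{ncp} (t noncentrality at \code{n_pairs}), \code{power_p}
#'   function giving power at a two-sided alpha.
#' @export
expected_paired_power <- function(config) {
  tm <- calibration_terms(config)
  kk <- solve_kappas(config)
  q <- kk$kappa_cs^2 * 2 * tm$s2c
  denom <- tm$a_base + tm$Kcs * q + kk$kappa_lg^2 * tm$Klg * 2 * tm$s2c
  rho <- sqrt(q / denom)
  df <- config$n_pairs - 8
  ncp <- rho / sqrt(1 - rho^2) * sqrt(df)
  power_p <- function(alpha) {
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
  }
  list(rho = rho, ncp = ncp, power_p = power_p)
}

## Cohort generation ----------------------------------------------------------

# Raw-score scales of the six tests (arbitrary affine frames; the
# composite is invariant to them by construction).
COMPONENT_MEANS <- c(25, 8, 6, 40, 45, 6)
COMPONENT_SDS <- c(6, 2, 2, 10, 12, 2)

#' Simulate a monozygotic twin cohort
#'
#' Generates every input the pipeline consumes -- beta matrix,
#' measurement QC metrics, sample sheet, cell counts, two-wave cognitive
#' components, cross-reactive list and probe annotation -- plus a
#' ground-truth table and the effect calibration. Deterministic given
#' \code{config$seed}.
#'
#' @param config [simulation_config()].
#' @return list of class \code{twin_cohort} with elements \code{beta},
#'   \code{qc}, \code{sample_sheet}, \code{cell_counts},
#'   \code{components}, \code{cross_reactive}, \code{annotation},
#'   \code{truth}, \code{calibration}, \code{config}.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  kk <- solve_kappas(cfg)

  ## -- pairs and individuals (draws: age) -----------------------------------
  n_pairs <- cfg$n_pairs
  pair_ids <- sprintf("p%04d", seq_len(n_pairs))
  n_female <- round(cfg$female_pair_fraction * n_pairs)
  pair_sex <- rep(c("female", "male"), c(n_female, n_pairs - n_female))
  pair_age <- pmin(pmax(stats::rnorm(n_pairs, cfg$age_mean, cfg$age_sd),
                        cfg$age_range[1]), cfg$age_range[2])
  sample_ids <- as.vector(t(outer(pair_ids, c("a", "b"), paste0)))
  sample_pair <- rep(pair_ids, each = 2)
  n_ind <- length(sample_ids)
  ind_sex <- rep(pair_sex, each = 2)
  ind_age <- rep(pair_age, each = 2)

  ## -- probe roles (draw: one sample of special probes) ---------------------
  probe_ids <- sprintf("cg%06d", seq_len(cfg$n_probes))
  n_special <- cfg$n_causal_cross_sectional + cfg$n_causal_longitudinal +
    cfg$n_cell_probes + cfg$n_sexage_probes + cfg$n_cross_reactive +
    cfg$n_high_missing_probes
  special <- sample.int(cfg$n_probes, n_special)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- special[seq_len(k)]
    special <<- special[-seq_len(k)]
    out
  }
  causal_cs <- take(cfg$n_causal_cross_sectional)
  causal_lg <- take(cfg$n_causal_longitudinal)
  cell_probes <- take(cfg$n_cell_probes)
  sexage_probes <- take(cfg$n_sexage_probes)
  cross_reactive <- take(cfg$n_cross_reactive)
  high_missing <- take(cfg$n_high_missing_probes)

  ## -- methylation (draws: mode, mu, u, e) ----------------------------------
  hyper <- stats::rbinom(cfg$n_probes, 1, 0.5)
  mu <- stats::rnorm(cfg$n_probes, ifelse(hyper == 1, 3.2, -3.2), 0.6)
  sd_e <- rep(sqrt(cfg$sigma2_indiv), cfg$n_probes)
  sd_e[c(causal_cs, causal_lg)] <- sqrt(cfg$causal_sigma2_indiv)
  u <- matrix(stats::rnorm(cfg$n_probes * n_pairs,
                           sd = sqrt(cfg$sigma2_pair)),
              cfg$n_probes, n_pairs)
  e <- matrix(stats::rnorm(cfg$n_probes * n_ind), cfg$n_probes, n_ind) * sd_e
  M <- mu + u[, rep(seq_len(n_pairs), each = 2), drop = FALSE] + e

  ## -- cell counts and their methylation effects (draws: counts, gamma) -----
  cell_means <- c(monocytes = 0.5, lymphocytes = 2.1, basophils = 0.05,
                  neutrophils = 3.9, eosinophils = 0.2)
  counts_true <- sapply(CELL_TYPES, function(ct)
    stats::rlnorm(n_ind, log(cell_means[ct]), 0.3))
  rownames(counts_true) <- sample_ids
  if (cfg$n_cell_probes > 0) {
    gamma <- matrix(stats::rnorm(cfg$n_cell_probes * 5,
                                 sd = cfg$cell_effect_scale),
                    cfg$n_cell_probes, 5)
    counts_scaled <- scale(counts_true)
    M[cell_probes, ] <- M[cell_probes, ] + gamma %*% t(counts_scaled)
  }

  ## -- sex/age effects (draws: coefficients) --------------------------------
  if (cfg$n_sexage_probes > 0) {
    sex_coef <- stats::rnorm(cfg$n_sexage_probes,
                             sd = cfg$sexage_effect_scale)
    age_coef <- stats::rnorm(cfg$n_sexage_probes,
                             sd = cfg$sexage_effect_scale)
    M[sexage_probes, ] <- M[sexage_probes, ] +
      outer(sex_coef, as.numeric(ind_sex == "female")) +
      outer(age_coef, (ind_age - cfg$age_mean) / 10)
  }

  ## -- cognition (draws: A, b, d, component noise x2, missingness) ----------
  icc <- cfg$cognition_pair_icc
  A <- stats::rnorm(n_pairs, sd = sqrt(icc) * cfg$cognition_sd)
  b <- stats::rnorm(n_ind, sd = sqrt(1 - icc) * cfg$cognition_sd)
  d <- stats::rnorm(n_ind, sd = cfg$decline_sd)
  dev <- M - mu  # u + e (+ cell/sexage terms, absent at causal probes)
  S_cs <- if (length(causal_cs))
    colSums(dev[causal_cs, , drop = FALSE]) else numeric(n_ind)
  S_lg <- if (length(causal_lg))
    colSums(dev[causal_lg, , drop = FALSE]) else numeric(n_ind)
  phi1 <- cfg$intake_mean + A[rep(seq_len(n_pairs), each = 2)] + b +
    kk$kappa_cs * S_cs
  change <- cfg$decline_mean + d + kk$kappa_lg * S_lg
  phi2 <- phi1 + change

  sum_zero_noise <- function() {
    eta <- matrix(stats::rnorm(n_ind * 6,
                               sd = sqrt(cfg$component_noise_var)),
                  n_ind, 6)
    eta - rowMeans(eta)
  }
  z1 <- (phi1 - cfg$intake_mean) / 6 + sum_zero_noise()
  z2 <- z1 + change / 6 + sum_zero_noise()
  raw <- function(z) sweep(sweep(z, 2, COMPONENT_SDS, "*"), 2,
                           COMPONENT_MEANS, "+")
  comp1 <- raw(z1); comp2 <- raw(z2)
  if (cfg$component_missing_rate > 0) {
    comp1[stats::runif(length(comp1)) < cfg$component_missing_rate] <- NA
    comp2[stats::runif(length(comp2)) < cfg$component_missing_rate] <- NA
  }
  components <- rbind(
    data.frame(sample_id = sample_ids, wave = "intake", comp1,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sample_ids, wave = "followup", comp2,
               stringsAsFactors = FALSE))
  names(components)[3:8] <- COGNITIVE_TESTS

  ## -- QC metrics (draws: bead base/failures, detection, zero signal) -------
  nm <- cfg$n_probes * n_ind
  bead <- matrix(3L + stats::rpois(nm, 11), cfg$n_probes, n_ind)
  bead_fail <- stats::runif(nm) < cfg$qc_bead_rate
  bead[bead_fail] <- sample(0:2, sum(bead_fail), replace = TRUE)
  detp <- matrix(stats::runif(nm) * 0.009, cfg$n_probes, n_ind)
  det_fail <- stats::runif(nm) < cfg$qc_detection_rate
  detp[det_fail] <- 0.0101 + stats::runif(sum(det_fail)) * 0.98
  zero <- matrix(stats::runif(nm) < cfg$qc_zero_rate, cfg$n_probes, n_ind)
  if (length(high_missing)) {
    n_bad <- ceiling(0.08 * n_ind)
    for (p in high_missing) {
      cells <- sample.int(n_ind, n_bad)
      detp[p, cells] <- 0.0101 + stats::runif(n_bad) * 0.98
    }
  }

  ## -- incomplete pairs / missing cell counts (draws: selections) -----------
  keep <- rep(TRUE, n_ind)
  if (cfg$incomplete_pair_fraction > 0) {
    n_inc <- floor(cfg$incomplete_pair_fraction * n_pairs)
    if (n_inc > 0) {
      inc_pairs <- sample.int(n_pairs, n_inc)
      drop_member <- sample(1:2, n_inc, replace = TRUE)
      keep[2 * (inc_pairs - 1) + drop_member] <- FALSE
    }
  }
  counts_obs <- counts_true
  if (cfg$missing_cell_samples > 0) {
    miss <- sample(which(keep), cfg$missing_cell_samples)
    counts_obs[miss, ] <- NA
  }

  ## -- annotation (draws: gaps, within-gene flag, distances, features) ------
  chr <- sort(rep_len(as.character(1:22), cfg$n_probes))
  pos <- unlist(lapply(split(seq_len(cfg$n_probes), chr), function(i)
    cumsum(sample.int(100000, length(i), replace = TRUE))),
    use.names = FALSE)
  n_genes <- ceiling(cfg$n_probes / 1.5)
  gene <- sprintf("GENE%05d",
                  ceiling(seq_len(cfg$n_probes) * n_genes / cfg$n_probes))
  within_gene <- stats::runif(cfg$n_probes) < 0.6
  dist <- ifelse(within_gene, NA_integer_,
                 sample(c(-1L, 1L), cfg$n_probes, replace = TRUE) *
                   sample.int(200000, cfg$n_probes, replace = TRUE))
  annotation <- data.frame(
    probe_id = probe_ids, chromosome = chr, position = pos,
    gene_symbol = gene, distance_bp = dist,
    cgi_feature = sample(CGI_FEATURES, cfg$n_probes, replace = TRUE),
    stringsAsFactors = FALSE)

  ## -- assemble --------------------------------------------------------------
  dimnames(M) <- list(probe_ids, sample_ids)
  beta <- inverse_logit_transform(M)
  dimnames(bead) <- dimnames(detp) <- dimnames(zero) <- dimnames(M)

  target <- rep("none", cfg$n_probes)
  target[causal_cs] <- "cross-sectional"
  target[causal_lg] <- "longitudinal"
  truth <- data.frame(
    probe_id = probe_ids, target = target,
    true_effect = ifelse(target == "none", 0, cfg$effect_size_m_per_unit),
    cell_associated = seq_len(cfg$n_probes) %in% cell_probes,
    sexage_associated = seq_len(cfg$n_probes) %in% sexage_probes,
    high_missing = seq_len(cfg$n_probes) %in% high_missing,
    stringsAsFactors = FALSE)

  sheet <- data.frame(
    sample_id = sample_ids, pair_id = sample_pair, sex = ind_sex,
    age_followup = round(ind_age, 1),
    chip_side = rep_len(c("Left", "Right"), n_ind),
    chip_row = rep_len(1:6, n_ind), stringsAsFactors = FALSE)

  cell_counts <- data.frame(sample_id = sample_ids,
                            as.data.frame(counts_obs),
                            stringsAsFactors = FALSE)
  rownames(cell_counts) <- NULL

  sel <- function(df) df[df$sample_id %in% sample_ids[keep], , drop = FALSE]
  structure(list(
    beta = beta[, keep, drop = FALSE],
    qc = probe_qc_metrics(bead[, keep, drop = FALSE],
                          detp[, keep, drop = FALSE],
                          zero[, keep, drop = FALSE]),
    sample_sheet = validate_sample_sheet(sel(sheet)),
    cell_counts = validate_cell_counts(sel(cell_counts)),
    components = sel(components),
    cross_reactive = probe_ids[cross_reactive],
    annotation = annotation,
    truth = truth,
    calibration = kk,
    config = cfg), class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic MZ twin cohort: %d individuals (%d pairs), %d probes (seed %d)\n",
    ncol(x$beta), x$config$n_pairs, nrow(x$beta), x$config$seed))
  cat(sprintf(
    "  causal probes: %d cross-sectional, %d longitudinal (effect %.3g M/unit)\n",
    x$config$n_causal_cross_sectional, x$config$n_causal_longitudinal,
    x$config$effect_size_m_per_unit))
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' All files use the package's TSV dialects; a \code{manifest.json}
#' records the file list, the full configuration and the seed, so the
#' cohort can be regenerated bit-identically.
#'
#' @param cohort [simulate_cohort()] output.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, name)
  write_beta_matrix(cohort$beta, f("beta.tsv"))
  write_tsv_matrix(cohort$qc$bead_count, f("bead_count.tsv"), "probe_id")
  write_tsv_matrix(cohort$qc$detection_p, f("detection_p.tsv"), "probe_id")
  write_tsv_matrix(cohort$qc$signal_zero * 1L, f("signal_zero.tsv"),
                   "probe_id")
  write_sample_sheet(cohort$sample_sheet, f("sample_sheet.tsv"))
  write_cell_counts(cohort$cell_counts[, c("sample_id", CELL_TYPES)],
                    f("cell_counts.tsv"))
  write_components(cohort$components, f("components.tsv"))
  write_annotation(cohort$annotation, f("annotation.tsv"))
  writeLines(cohort$cross_reactive, f("cross_reactive.txt"))
  utils::write.table(cohort$truth, f("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  files <- c("beta.tsv", "bead_count.tsv", "detection_p.tsv",
             "signal_zero.tsv", "sample_sheet.tsv", "cell_counts.tsv",
             "components.tsv", "annotation.tsv", "cross_reactive.txt",
             "truth.tsv")
  jsonlite::write_json(
    list(files = files, seed = cohort$config$seed,
         config = unclass(cohort$config)),
    f("manifest.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(f("manifest.json"))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing a \code{manifest.json}.
#' @return \code{twin_cohort}-shaped list (without truth/calibration if
#'   absent).
#' @export
read_cohort <- function(dir) {
  f <- function(name) file.path(dir, name)
  manifest <- jsonlite::read_json(f("manifest.json"), simplifyVector = TRUE)
  bead <- read_numeric_matrix(f("bead_count.tsv"))
  truth <- if (file.exists(f("truth.tsv")))
    utils::read.table(f("truth.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  structure(list(
    beta = read_beta_matrix(f("beta.tsv")),
    qc = probe_qc_metrics(bead, read_numeric_matrix(f("detection_p.tsv")),
                          read_numeric_matrix(f("signal_zero.tsv")) > 0),
    sample_sheet = read_sample_sheet(f("sample_sheet.tsv")),
    cell_counts = read_cell_counts(f("cell_counts.tsv")),
    components = read_components(f("components.tsv")),
    cross_reactive = readLines(f("cross_reactive.txt")),
    annotation = read_annotation(f("annotation.tsv")),
    truth = truth,
    manifest = manifest), class = "twin_cohort")
}
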