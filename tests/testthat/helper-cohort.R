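# Shared fixtures: small simulated cohorts and derived pipeline objects.

# A compact cohort with clean measurements (no QC failures) unless
# overridden; defaults chosen for speed.
tiny_cohort <- function(seed = 42, n_pairs = 30, n_probes = 40,
                        n_cell_probes = 5, n_sexage_probes = 5, ...) {
  simulate_cohort(simulation_config(
    seed = seed, n_pairs = n_pairs, n_probes = n_probes,
    n_causal_cross_sectional = 0, n_causal_longitudinal = 0,
    n_cell_probes = n_cell_probes, n_sexage_probes = n_sexage_probes,
    qc_bead_rate = 0, qc_detection_rate = 0, qc_zero_rate = 0,
    n_high_missing_probes = 0, n_cross_reactive = 0,
    component_missing_rate = 0, ...))
}

# Follow-up composite phenotype for a cohort.
followup_phenotype <- function(co) {
  params <- estimate_standardization(co$components, wave = "intake")
  compute_composite(co$components, params, "followup")
}

change_phenotype <- function(co) {
  params <- estimate_standardization(co$components, wave = "intake")
  compute_change(compute_composite(co$components, params, "intake"),
                 compute_composite(co$components, params, "followup"))
}

# Individual-level fixed-effects design matrix matching the unpaired scan.
unpaired_X <- function(co, phen) {
  sheet <- co$sample_sheet
  counts <- as.matrix(co$cell_counts[match(sheet$sample_id,
                                           co$cell_counts$sample_id),
                                     CELL_TYPES])
  cbind(intercept = 1,
        phenotype = phen$value[match(sheet$sample_id, phen$sample_id)],
        sex_female = as.numeric(sheet$sex == "female"),
        age_followup = sheet$age_followup, counts)
}

# A small beta matrix with labelled dims.
toy_beta <- function(values, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("cg%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  values
}
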