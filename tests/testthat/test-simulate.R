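# Synthetic cohort generator: determinism, planted structure, calibration.

test_that("generation is deterministic and matches the configured layout", {
  cfg <- simulation_config(seed = 123, n_pairs = 15, n_probes = 120)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$components, b$components)
  expect_identical(a$qc$bead_count, b$qc$bead_count)
  expect_identical(a$truth, b$truth)

  # a 243-pair cohort with the 111 female / 132 male split has 486 samples
  cfg2 <- simulation_config(seed = 1, n_pairs = 243, n_probes = 5,
                            n_causal_cross_sectional = 0,
                            n_causal_longitudinal = 0, n_cell_probes = 0,
                            n_sexage_probes = 0, n_cross_reactive = 0,
                            n_high_missing_probes = 0)
  co2 <- simulate_cohort(cfg2)
  expect_equal(ncol(co2$beta), 486)
  sex_by_pair <- tapply(co2$sample_sheet$sex, co2$sample_sheet$pair_id,
                        unique)
  expect_equal(sum(sex_by_pair == "female"), 111)
  expect_equal(sum(sex_by_pair == "male"), 132)
  expect_true(all(co2$sample_sheet$age_followup >= 55 &
                    co2$sample_sheet$age_followup <= 79))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_probes = 10, n_causal_cross_sectional = 20),
               "exceed")
  expect_error(simulation_config(sigma2_pair = -1), "variances")
  expect_error(
    simulate_cohort(simulation_config(effect_size_m_per_unit = 10)),
    "not achievable")
})

test_that("within-pair M-value correlation at null probes matches the ICC", {
  co <- tiny_cohort(seed = 88, n_pairs = 150, n_probes = 60,
                    n_cell_probes = 0, n_sexage_probes = 0)
  m <- logit_transform(co$beta)
  sheet <- co$sample_sheet
  first <- sheet$sample_id[seq(1, nrow(sheet), 2)]
  second <- sheet$sample_id[seq(2, nrow(sheet), 2)]
  cors <- vapply(seq_len(nrow(m)), function(i)
    cor(m[i, first], m[i, second]), 0)
  # sigma2_pair = sigma2_indiv = 0.1 -> ICC 0.5
  expect_lt(abs(mean(cors) - 0.5), 0.05)
})

test_that("within-pair intake composite correlation matches the configured ICC", {
  co <- tiny_cohort(seed = 99, n_pairs = 250, n_probes = 12,
                    cognition_pair_icc = 0.6)
  params <- estimate_standardization(co$components)
  comp <- compute_composite(co$components, params, "intake")
  sheet <- co$sample_sheet
  v <- comp$value[match(sheet$sample_id, comp$sample_id)]
  icc <- cor(v[seq(1, length(v), 2)], v[seq(2, length(v), 2)])
  expect_lt(abs(icc - 0.6), 0.08)
})

test_that("planted QC failures are exactly recovered by the filter", {
  co <- simulate_cohort(simulation_config(
    seed = 31, n_pairs = 20, n_probes = 120, n_causal_cross_sectional = 0,
    n_causal_longitudinal = 0, n_cell_probes = 0, n_sexage_probes = 0,
    qc_bead_rate = 0, qc_detection_rate = 0, qc_zero_rate = 0,
    n_high_missing_probes = 7, n_cross_reactive = 9))
  masked <- mask_failed_measurements(co$beta, co$qc)
  res <- filter_probes(masked, co$cross_reactive)
  planted_miss <- co$truth$probe_id[co$truth$high_missing]
  fates <- res$report$probe_fates
  expect_setequal(fates$probe_id[fates$reason %in% "missingness"],
                  planted_miss)
  expect_setequal(fates$probe_id[fates$reason %in% "cross-reactive"],
                  setdiff(co$cross_reactive, planted_miss))
  expect_equal(res$report$n_kept, 120 - 7 - 9)
})

test_that("null cohorts produce uniform paired-scan p-values", {
  co <- tiny_cohort(seed = 41, n_pairs = 80, n_probes = 600,
                    n_cell_probes = 0, n_sexage_probes = 0)
  m <- logit_transform(co$beta)
  des <- build_pair_differences(m, co$sample_sheet, followup_phenotype(co),
                                co$cell_counts)
  res <- run_paired_ewas(des)
  expect_gt(stats::ks.test(res$p_value, "punif")$p.value, 0.01)
})

test_that("cohorts round-trip through a directory with a faithful manifest", {
  co <- tiny_cohort(seed = 55, n_pairs = 6, n_probes = 15,
                    missing_cell_samples = 2)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$beta, co$beta, tolerance = 1e-12)
  expect_equal(back$sample_sheet$pair_id, co$sample_sheet$pair_id)
  expect_equal(back$cell_counts[, CELL_TYPES], co$cell_counts[, CELL_TYPES],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$cross_reactive, co$cross_reactive)

  manifest <- jsonlite::read_json(file.path(d, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$seed, 55)
  expect_equal(manifest$config$n_pairs, 6)
  # regenerating from the manifest config yields identical files
  cfg <- do.call(simulation_config, manifest$config[names(manifest$config) !=
                                                      ""])
  co2 <- simulate_cohort(cfg)
  expect_identical(co2$beta, co$beta)
  expect_identical(co2$components, co$components)
})
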