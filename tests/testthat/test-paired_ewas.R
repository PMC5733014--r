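# Within-pair difference design and OLS scan.

test_that("pair differencing is deterministic and zero for identical twins", {
  co <- tiny_cohort(n_pairs = 12, n_probes = 10)
  m <- logit_transform(co$beta)
  phen <- followup_phenotype(co)
  des <- build_pair_differences(m, co$sample_sheet, phen, co$cell_counts)
  expect_s3_class(des, "paired_design")
  expect_equal(nrow(des$pairs), 12)
  # orientation: minuend is the lexicographically smaller sample id
  expect_true(all(des$pairs$minuend < des$pairs$subtrahend))

  # permuting input row order leaves the design identical
  perm <- sample(ncol(m))
  des2 <- build_pair_differences(
    m[, perm], co$sample_sheet[rev(seq_len(nrow(co$sample_sheet))), ],
    phen[sample(nrow(phen)), ], co$cell_counts)
  expect_equal(des$pairs, des2$pairs)
  expect_equal(des$delta_m, des2$delta_m)

  # identical twins -> all deltas zero
  m_same <- m
  for (p in unique(co$sample_sheet$pair_id)) {
    ids <- sort(co$sample_sheet$sample_id[co$sample_sheet$pair_id == p])
    m_same[, ids[2]] <- m_same[, ids[1]]
  }
  phen_same <- phen
  phen_same$value <- 1
  counts_same <- co$cell_counts
  for (p in unique(co$sample_sheet$pair_id)) {
    ids <- sort(co$sample_sheet$sample_id[co$sample_sheet$pair_id == p])
    counts_same[counts_same$sample_id == ids[2], CELL_TYPES] <-
      counts_same[counts_same$sample_id == ids[1], CELL_TYPES]
  }
  des3 <- build_pair_differences(m_same, co$sample_sheet, phen_same,
                                 counts_same)
  expect_true(all(des3$delta_m == 0))
  expect_true(all(des3$pairs$d_phenotype == 0))
})

test_that("incomplete pairs and unavailable phenotypes are excluded with reasons", {
  co <- tiny_cohort(n_pairs = 10, n_probes = 12,
                    incomplete_pair_fraction = 0.2)
  m <- logit_transform(co$beta)
  phen <- followup_phenotype(co)
  phen$available[1] <- FALSE
  des <- build_pair_differences(m, co$sample_sheet, phen, co$cell_counts)
  expect_equal(nrow(des$pairs) + nrow(des$excluded), 10)
  expect_true("incomplete pair" %in% des$excluded$reason)
  expect_true("phenotype unavailable" %in% des$excluded$reason)
})

test_that("perfect linear relation is fitted exactly", {
  n <- 12
  pairs <- data.frame(
    pair_id = sprintf("p%02d", 1:n),
    minuend = sprintf("s%02da", 1:n), subtrahend = sprintf("s%02db", 1:n),
    d_phenotype = seq(-2, 2, length.out = n),
    sex_female = 0, age_followup = 65,
    stringsAsFactors = FALSE)
  for (ct in CELL_TYPES) pairs[[paste0("d_", ct)]] <- 0
  delta_m <- matrix(0.5 * pairs$d_phenotype, 1, n,
                    dimnames = list("cg01", pairs$pair_id))
  des <- structure(list(pairs = pairs, delta_m = delta_m,
                        excluded = data.frame()), class = "paired_design")
  res <- run_paired_ewas(des)
  expect_equal(res$estimate, 0.5, tolerance = 1e-12)
  expect_lt(res$std_error, 1e-8)
})

test_that("scan matches the closed-form normal-equation solution", {
  co <- tiny_cohort(seed = 77, n_pairs = 12, n_probes = 20)
  m <- logit_transform(co$beta)
  phen <- followup_phenotype(co)
  des <- build_pair_differences(m, co$sample_sheet, phen, co$cell_counts)
  res <- run_paired_ewas(des)
  X <- cbind(1, des$pairs$d_phenotype, des$pairs$sex_female,
             des$pairs$age_followup,
             as.matrix(des$pairs[, paste0("d_", CELL_TYPES)]))
  XtXinv <- solve(t(X) %*% X)
  for (i in seq_len(nrow(m))) {
    y <- des$delta_m[i, ]
    bhat <- XtXinv %*% t(X) %*% y
    expect_equal(res$estimate[i], bhat[2], tolerance = 1e-10)
    s2 <- sum((y - X %*% bhat)^2) / (nrow(X) - ncol(X))
    expect_equal(res$std_error[i], sqrt(s2 * XtXinv[2, 2]),
                 tolerance = 1e-10)
  }
  expect_true(all(res$n_units == 12))
})

test_that("pair-constant shifts in M-values leave paired results unchanged", {
  co <- tiny_cohort(seed = 13, n_pairs = 15, n_probes = 12)
  m <- logit_transform(co$beta)
  phen <- followup_phenotype(co)
  res1 <- run_paired_ewas(
    build_pair_differences(m, co$sample_sheet, phen, co$cell_counts))
  shift <- matrix(rnorm(nrow(m) * 15), nrow(m), 15)
  m_shift <- m + shift[, rep(1:15, each = 2)]
  res2 <- run_paired_ewas(
    build_pair_differences(m_shift, co$sample_sheet, phen, co$cell_counts))
  expect_equal(res1$estimate, res2$estimate, tolerance = 1e-9)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-9)
})

test_that("paired estimate equals the pair fixed-effects estimator", {
  # individual-level regression with pair dummies plus orientation
  # interactions reproduces the difference regression coefficient
  co <- tiny_cohort(seed = 31, n_pairs = 30, n_probes = 10)
  m <- logit_transform(co$beta)
  phen <- followup_phenotype(co)
  des <- build_pair_differences(m, co$sample_sheet, phen, co$cell_counts)
  res <- run_paired_ewas(des)
  sheet <- co$sample_sheet
  ord <- order(sheet$pair_id, sheet$sample_id)
  sheet <- sheet[ord, ]
  orient <- ifelse(sheet$sample_id %in% des$pairs$minuend, 0.5, -0.5)
  phe <- phen$value[match(sheet$sample_id, phen$sample_id)]
  counts <- as.matrix(co$cell_counts[match(sheet$sample_id,
                                           co$cell_counts$sample_id),
                                     CELL_TYPES])
  for (i in 1:5) {
    y <- m[i, sheet$sample_id]
    fe <- stats::lm(y ~ 0 + factor(sheet$pair_id) + orient +
                      I(orient * (sheet$sex == "female")) +
                      I(orient * sheet$age_followup) + phe + counts)
    expect_equal(res$estimate[i], unname(coef(fe)["phe"]),
                 tolerance = 1e-8)
  }
})

test_that("null scans are calibrated and planted effects recovered unbiasedly", {
  # no planted effect: p-values approximately uniform
  co <- tiny_cohort(seed = 50, n_pairs = 60, n_probes = 400)
  m <- logit_transform(co$beta)
  des <- build_pair_differences(m, co$sample_sheet, followup_phenotype(co),
                                co$cell_counts)
  res <- run_paired_ewas(des)
  ks <- stats::ks.test(res$p_value, "punif")
  expect_gt(ks$p.value, 0.01)

  # planted cross-sectional effects: estimates center on the truth
  ests <- unlist(lapply(1:10, function(r) {
    cs <- simulate_cohort(simulation_config(
      seed = 500 + r, n_pairs = 60, n_probes = 60,
      n_causal_cross_sectional = 3, n_causal_longitudinal = 0,
      qc_bead_rate = 0, qc_detection_rate = 0, qc_zero_rate = 0,
      n_high_missing_probes = 0, n_cross_reactive = 0,
      component_missing_rate = 0))
    mm <- logit_transform(cs$beta)
    dd <- build_pair_differences(mm, cs$sample_sheet,
                                 followup_phenotype(cs), cs$cell_counts)
    rr <- run_paired_ewas(dd)
    causal <- cs$truth$probe_id[cs$truth$target == "cross-sectional"]
    rr$estimate[match(causal, rr$probe_id)]
  }))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.03), 2 * mc_se + 1e-12)
})

test_that("discordant subsetting ranks by |delta| with ceiling and ties", {
  pairs <- data.frame(
    pair_id = c("p1", "p2", "p3", "p4"),
    minuend = paste0("m", 1:4), subtrahend = paste0("s", 1:4),
    d_phenotype = c(3, -2, 1, 0), sex_female = 0, age_followup = 65,
    stringsAsFactors = FALSE)
  for (ct in CELL_TYPES) pairs[[paste0("d_", ct)]] <- 0
  des <- structure(list(
    pairs = pairs,
    delta_m = matrix(1:4, 1, 4, dimnames = list("cg01", pairs$pair_id)),
    excluded = data.frame()), class = "paired_design")
  top <- select_most_discordant(des, 0.5)
  expect_setequal(top$pairs$pair_id, c("p1", "p2"))
  expect_identical(colnames(top$delta_m), top$pairs$pair_id)

  # 5 pairs at fraction 0.5 keeps ceiling(2.5) = 3
  pairs5 <- rbind(pairs, pairs[1, ])
  pairs5$pair_id[5] <- "p5"; pairs5$d_phenotype[5] <- -1
  des5 <- structure(list(
    pairs = pairs5,
    delta_m = matrix(1:5, 1, 5, dimnames = list("cg01", pairs5$pair_id)),
    excluded = data.frame()), class = "paired_design")
  expect_equal(nrow(select_most_discordant(des5, 0.5)$pairs), 3)
  # tie between p3 (|1|) and p5 (|-1|): pair id breaks the tie
  expect_setequal(select_most_discordant(des5, 0.5)$pairs$pair_id,
                  c("p1", "p2", "p3"))

  # fraction 1 is the identity
  expect_equal(select_most_discordant(des, 1)$pairs, des$pairs)
  expect_error(select_most_discordant(des, 0), "fraction")
})

test_that("constant phenotype difference yields unavailable results", {
  co <- tiny_cohort(n_pairs = 12, n_probes = 12)
  m <- logit_transform(co$beta)
  phen <- followup_phenotype(co)
  phen$value <- 7
  des <- build_pair_differences(m, co$sample_sheet, phen, co$cell_counts)
  res <- run_paired_ewas(des)
  expect_true(all(is.na(res$estimate)))
})
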