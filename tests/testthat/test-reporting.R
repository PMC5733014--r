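# BH adjustment, annotation joins, threshold reports, overlap, Manhattan.

test_that("BH with explicit family size reproduces the published worked case", {
  # four displayed raw p-values from a six-test family
  p <- c(0.0098, 0.0302, 0.0494, 0.0606)
  expect_equal(round(benjamini_hochberg(p, m_total = 6), 4),
               c(0.0588, 0.0906, 0.0909, 0.0909))
  expect_equal(benjamini_hochberg(0.03, m_total = 1), 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(p, m_total = 3), "m_total")
  expect_error(benjamini_hochberg(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("BH matches a brute-force step-up and is permutation invariant", {
  step_up <- function(p, m) {
    o <- order(p)
    ps <- p[o]
    adj <- sapply(seq_along(ps), function(i)
      min(1, min(ps[i:length(ps)] * m / (i:length(ps)))))
    out <- numeric(length(p)); out[o] <- adj; out
  }
  set.seed(4)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))
    m <- length(p) + sample(0:10, 1)
    expect_equal(benjamini_hochberg(p, m), step_up(p, m),
                 tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p, m)[perm],
                 benjamini_hochberg(p[perm], m), tolerance = 1e-12)
    # monotone nondecreasing in sorted-p order
    expect_true(all(diff(benjamini_hochberg(p, m)[order(p)]) >= -1e-15))
  }
})

fake_results <- function(p, probes = sprintf("cg%03d", seq_along(p))) {
  out <- data.frame(probe_id = probes,
                    estimate = rep(0.01, length(p)),
                    std_error = rep(0.002, length(p)),
                    p_value = p, n_units = rep(50L, length(p)),
                    analysis = rep("test", length(p)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  out
}

test_that("annotation join carries gene context and never alters statistics", {
  ann <- data.frame(
    probe_id = c("cg001", "cg002", "cg003"),
    chromosome = c("20", "1", "3"),
    position = c(62402415L, 247553836L, 100L),
    gene_symbol = c("ZBTB46", "NLRP3", "OTHER"),
    distance_bp = c(NA, -25622L, 500L),
    cgi_feature = c("Body-island", "IGR-open sea", "TSS200-shore"),
    stringsAsFactors = FALSE)
  res <- fake_results(c(5.84e-7, 2.62e-6, 0.2))
  out <- annotate_probes(res, ann)
  # a probe inside a gene body in an island: no distance, Body-island
  expect_true(is.na(out$distance_bp[1]))
  expect_equal(out$cgi_feature[1], "Body-island")
  # a probe 25,622 bp upstream carries a negative distance
  expect_equal(out$distance_bp[2], -25622L)
  expect_equal(out$p_value, res$p_value)
  expect_equal(out$estimate, res$estimate)

  # unannotated probe kept with missing fields and a warning
  res2 <- fake_results(c(0.1, 0.2), probes = c("cg001", "cgXXX"))
  expect_warning(out2 <- annotate_probes(res2, ann), "missing from annotation")
  expect_true(is.na(out2$gene_symbol[2]))
  expect_equal(nrow(out2), 2)
})

test_that("threshold report partitions strictly and sorts by p", {
  res <- fake_results(c(5e-6, 5e-7, 2e-5, 1e-6, 1e-5))
  rep <- threshold_report(res)
  expect_identical(rep$suggestive$p_value, c(5e-7, 1e-6, 5e-6))
  expect_identical(rep$significant$p_value, 5e-7)  # 1e-6 excluded (strict)
  expect_true(all(rep$significant$probe_id %in% rep$suggestive$probe_id))
  empty <- threshold_report(fake_results(numeric(0)))
  expect_equal(nrow(empty$suggestive), 0)
  expect_error(threshold_config(suggestive_p = 1e-7), "thresholds")
})

test_that("overlap distinguishes probe-level from gene-level sharing", {
  ann <- data.frame(
    probe_id = c("cg001", "cg002", "cg003"),
    chromosome = "1", position = c(10L, 20L, 30L),
    gene_symbol = c("GENEA", "GENEA", "GENEB"),
    distance_bp = NA_integer_,
    cgi_feature = "Body-island", stringsAsFactors = FALSE)
  r1 <- fake_results(c(1e-6, 0.5, 0.5))
  r2 <- fake_results(c(0.5, 1e-6, 0.5))
  r3 <- fake_results(c(1e-6, 0.5, 1e-6))
  ov <- overlap_analysis(list(a = r1, b = r2, c = r3), ann)
  # a and c share probe cg001
  expect_equal(ov$detail[["a vs c"]]$probes, "cg001")
  # a and b share no probe but share GENEA through different probes
  expect_equal(ov$detail[["a vs b"]]$probes, character(0))
  expect_equal(ov$detail[["a vs b"]]$genes, "GENEA")
  # identical tables: intersection equals own hit set
  ov2 <- overlap_analysis(list(x = r3, y = r3), ann)
  expect_setequal(ov2$detail[["x vs y"]]$probes, c("cg001", "cg003"))
  # shared sets are subsets of each contributing hit set
  expect_true(all(ov$detail[["a vs c"]]$probes %in% ov$hit_probes$a))
})

test_that("Manhattan table orders genome-wide and labels strictly", {
  ann <- data.frame(
    probe_id = sprintf("cg%03d", 1:6),
    chromosome = c("2", "1", "1", "10", "2", "X"),
    position = c(50L, 100L, 20L, 5L, 10L, 7L),
    gene_symbol = "G", distance_bp = NA_integer_,
    cgi_feature = "Body-shore", stringsAsFactors = FALSE)
  res <- annotate_probes(fake_results(c(1e-6, 1e-7, 0.5, 0.1, 0.2, 0.9)),
                         ann)
  mt <- manhattan_table(res)
  expect_true(all(diff(mt$cumulative_position) > 0))
  expect_identical(mt$chromosome,
                   c("1", "1", "2", "2", "10", "X"))
  # p = 1e-6 exactly is not labelled; p = 1e-7 is; labels match report
  expect_identical(mt$label[match(c("cg001", "cg002"), mt$probe_id)],
                   c(FALSE, TRUE))
  expect_equal(mt$neg_log10_p[mt$probe_id == "cg001"], 6)
  rep <- threshold_report(res)
  expect_setequal(mt$probe_id[mt$label], rep$significant$probe_id)
})
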