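# Hypergeometric over-representation analysis.

small_ann <- function(genes) {
  data.frame(probe_id = sprintf("cg%03d", seq_along(genes)),
             chromosome = "1", position = seq_along(genes),
             gene_symbol = genes, distance_bp = NA_integer_,
             cgi_feature = "Body-island", stringsAsFactors = FALSE)
}

test_that("reference universe deduplicates genes and intersects sets", {
  ann <- small_ann(c(paste0("G", 1:20), "G1", "G2"))  # duplicate probes/gene
  ref <- build_reference(ann, list(S = paste0("G", 1:5)))
  expect_length(ref$universe, 20)
  expect_length(ref$sets$S, 5)
  # absent symbols excluded from C
  ref2 <- build_reference(ann, list(S = c("G1", "G2", "NOPE")))
  expect_length(ref2$sets$S, 2)
  expect_warning(build_reference(ann, list(S = "NOPE")), "dropped")
  expect_error(build_reference(small_ann(NA_character_), list(S = "G1")),
               "empty gene universe")
})

test_that("hit genes deduplicate probes and apply the cutoff strictly", {
  ann <- small_ann(c("GA", "GA", "GB", "GC"))
  res <- data.frame(probe_id = sprintf("cg%03d", 1:4),
                    p_value = c(1e-5, 2e-5, 1e-4, 0.5))
  hits <- hits_to_genes(res, ann, p_cutoff = 1e-4)
  expect_identical(hits, "GA")  # two probes one gene; 1e-4 itself excluded
  expect_identical(hits_to_genes(res, ann, p_cutoff = 2e-4), c("GA", "GB"))
})

test_that("hypergeometric tail matches exact enumeration on a small universe", {
  # N = 20, C = 5, n = 4, O = 2: enumerate all C(20, 4) draws
  universe <- paste0("G", 1:20)
  set5 <- paste0("G", 1:5)
  draws <- utils::combn(20, 4)
  tail_ge <- function(o) mean(colSums(draws <= 5) >= o)
  r <- hypergeometric_ora(paste0("G", c(1, 2, 6, 7)), set5, universe)
  expect_equal(r$O, 2)
  expect_equal(r$E, 1.0)
  expect_equal(r$R, 2.0)
  expect_equal(r$raw_p, tail_ge(2), tolerance = 1e-12)
  expect_equal(round(r$raw_p, 4), 0.2487)

  # O = 0 gives p = 1; fully saturated draw gives p = 1 and R = 1
  r0 <- hypergeometric_ora(paste0("G", 6:9), set5, universe)
  expect_equal(r0$raw_p, 1.0)
  rfull <- hypergeometric_ora(universe, universe, universe)
  expect_equal(rfull$raw_p, 1.0)
  expect_equal(rfull$R, 1.0)

  # tail probabilities are a proper distribution
  probs <- stats::dhyper(0:4, 5, 15, 4)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  # R * E = O exactly
  expect_equal(r$R * r$E, r$O, tolerance = 1e-12)
})

test_that("enrichment table reproduces the published BH family-size-6 fixture", {
  # six sets whose raw p-values mirror a published KEGG analysis of
  # paired-scan hits; the four displayed adjusted values are reproduced
  # when all six tested sets form the BH family
  raw <- c(0.0098, 0.0302, 0.0494, 0.0606, 0.3, 0.7)
  adj <- benjamini_hochberg(raw, m_total = 6)
  expect_equal(round(adj[1:4], 4), c(0.0588, 0.0906, 0.0909, 0.0909))

  # one set tested: adjusted equals raw
  ann <- small_ann(paste0("G", 1:30))
  e1 <- enrich_all(c("G1", "G2"), list(S = paste0("G", 1:6)), ann)
  expect_equal(e1$adj_p, e1$raw_p)
})

test_that("within one analysis E/C is constant across sets (= n/N)", {
  ann <- small_ann(paste0("G", 1:40))
  sets <- list(A = paste0("G", 1:10), B = paste0("G", 5:20),
               C = paste0("G", 30:40))
  hits <- paste0("G", c(1, 2, 8, 31, 35))
  tab <- enrich_all(hits, sets, ann)
  expect_equal(length(unique(round(tab$E / tab$C, 12))), 1)
  expect_equal(tab$E / tab$C, rep(5 / 40, 3), tolerance = 1e-12)
  # sorted by raw p; O and overlap genes consistent
  expect_true(!is.unsorted(tab$raw_p))
  expect_equal(tab$O, vapply(strsplit(tab$gene_symbols, " "), length, 0L))
})

test_that("recorded summary statistics from a cognition EWAS are self-consistent", {
  # six displayed (C, O, E, R) rows; checks R = O/E and E/C constancy
  # within each analysis at the displayed rounding precision
  rows <- data.frame(
    analysis = c("p-cog", "p-cog", "p-cog", "p-cog", "u-cog", "u-chg"),
    C = c(268, 87, 128, 114, 35, 138),
    O = c(4, 2, 2, 2, 2, 2),
    E = c(0.84, 0.27, 0.40, 0.36, 0.05, 0.14),
    R = c(4.78, 7.37, 5.01, 5.62, 36.63, 13.93))
  # |R - O/E| within the rounding tolerance implied by E's two decimals
  tol <- rows$O / rows$E - rows$O / (rows$E + 0.005)
  expect_true(all(abs(rows$R - rows$O / rows$E) <= tol + 0.01))
  # E/C constant within an analysis to 2%
  ec <- rows$E / rows$C
  for (a in unique(rows$analysis)) {
    v <- ec[rows$analysis == a]
    expect_lt(diff(range(v)) / mean(v), 0.02)
  }
})

test_that("empty hit lists skip enrichment with a message", {
  ann <- small_ann(paste0("G", 1:10))
  expect_message(out <- enrich_all(character(), list(S = "G1"), ann),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("exact tail matches Monte-Carlo resampling of hit lists", {
  set.seed(2)
  universe <- paste0("G", 1:18)
  set7 <- paste0("G", 1:7)
  hits_n <- 5
  r <- hypergeometric_ora(paste0("G", c(1, 2, 3, 10, 11)), set7, universe)
  draws <- replicate(20000, {
    s <- sample(universe, hits_n)
    sum(s %in% set7) >= r$O
  })
  mc <- mean(draws)
  mc_se <- sqrt(mc * (1 - mc) / length(draws))
  expect_lt(abs(r$raw_p - mc), 3 * mc_se)
})
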