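FWD <- "GTGYCAGCMGCCGCGGTAA"
REV <- "GGACTACNVGGGTWTCTAAT"
rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

build_16s <- function(v, fwd_real = "GTGCCAGCAGCCGCGGTAA",
                      rev_real = "GGACTACAAGGGTATCTAAT",
                      left = "AAATTTGGG", right = "CCCGGGAAA") {
  paste0(left, fwd_real, v, rc(rev_real), right)
}

test_that("V4 extraction returns exactly the inter-primer region", {
  v <- "ACGTACGTACGTACGTACGT"
  expect_identical(extract_v4(build_16s(v)), v)
  expect_error(extract_v4("ACGT"), "shorter")
  expect_error(extract_v4(paste0("AAAA", strrep("T", 60))), "forward primer")
})

test_that("degenerate primer positions accept only their IUPAC alternatives", {
  v <- "ACGTACGTAC"
  # position 4 of 515F is Y = C or T
  with_c <- sub("Y", "C", FWD); with_t <- sub("Y", "T", FWD)
  with_g <- sub("Y", "G", FWD)
  expect_identical(extract_v4(build_16s(v, fwd_real = with_c)), v)
  expect_identical(extract_v4(build_16s(v, fwd_real = with_t)), v)
  expect_error(extract_v4(build_16s(v, fwd_real = with_g)), "forward primer")
})

test_that("multiple primer hits use leftmost forward and nearest reverse", {
  v <- "ACGTACGTACGTACGTACGT"
  fwd_real <- "GTGCCAGCAGCCGCGGTAA"
  rev_site <- rc("GGACTACAAGGGTATCTAAT")
  seq2 <- paste0("AAA", fwd_real, v, rev_site, "TTTT", rev_site, "GG")
  expect_warning(out <- extract_v4(seq2), "multiple")
  expect_identical(out, v)
})

test_that("pairing applies the 99.5% identity rule over the 273 bp query", {
  asv <- simulate_asv_sequences("asv1", length = 273, seed = 2L)
  mags <- simulate_mag_fixtures(
    rep(asv, 3) |> stats::setNames(c("q0", "q1", "q2")),
    tibble::tibble(asv_id = c("q0", "q1", "q2"), n_mismatches = c(0L, 1L, 2L)),
    seed = 3L)
  # each MAG against its own query sequence
  for (i in 1:3) {
    pr <- pair_asv_mag(stats::setNames(asv, c("q0", "q1", "q2")[i]), mags[i])
    expect_equal(pr$mismatches, i - 1L)
    expect_equal(pr$identity, 1 - (i - 1) / 273, tolerance = 1e-9)
  }
  p0 <- pair_asv_mag(stats::setNames(asv, "q0"), mags[1])
  p1 <- pair_asv_mag(stats::setNames(asv, "q1"), mags[2])
  p2 <- pair_asv_mag(stats::setNames(asv, "q2"), mags[3])
  expect_true(p0$accepted)    # identity 1
  expect_true(p1$accepted)    # 0.99634 > 0.995
  expect_false(p2$accepted)   # 0.99267 < 0.995
})

test_that("pairing is invariant to MAG input order", {
  seqs <- simulate_asv_sequences(c("a1", "a2", "a3"), seed = 4L)
  mags <- simulate_mag_fixtures(
    seqs, tibble::tibble(asv_id = c("a1", "a2", "a3"), n_mismatches = c(0L, 1L, 0L)),
    seed = 5L)
  p_fwd <- pair_asv_mag(seqs, mags)
  p_rev <- pair_asv_mag(seqs, rev(mags))
  expect_equal(dplyr::arrange(p_fwd, asv_id), dplyr::arrange(p_rev, asv_id))
})

test_that("an ASV longer than every MAG region is rejected with a flag", {
  long_asv <- stats::setNames(strrep("ACGT", 200), "long1")
  seqs <- simulate_asv_sequences("a1", seed = 6L)
  mags <- simulate_mag_fixtures(seqs, tibble::tibble(asv_id = "a1",
                                                     n_mismatches = 0L), seed = 7L)
  pr <- pair_asv_mag(long_asv, mags)
  expect_true(is.na(pr$identity))
  expect_false(pr$accepted)
})

test_that("LCA concordance follows the truncate-to-shallower rule", {
  asv <- parse_taxonomy("asv", "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales")
  mag_ok <- parse_taxonomy("mag", "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Tenuifilaceae")
  expect_true(lca_concordant(asv, mag_ok))
  mag_bad <- parse_taxonomy("mag", "d__Bacteria;p__Firmicutes;c__Clostridia;o__Eubacteriales;f__Ruminococcaceae")
  expect_false(lca_concordant(asv, mag_bad))
  a <- parse_taxonomy("a", "d__Archaea")
  b <- parse_taxonomy("b", "d__Archaea")
  expect_true(lca_concordant(a, b))
})

test_that("MAG quality tiers reproduce the community-standard thresholds", {
  full <- c(`5S` = 1L, `16S` = 1L, `23S` = 1L)
  only16 <- c(`5S` = 0L, `16S` = 1L, `23S` = 0L)
  expect_identical(mag_quality_tier(99.0, 0, full), "HQ")
  expect_identical(mag_quality_tier(93.3, 1.4, full), "HQ")
  expect_identical(mag_quality_tier(78.3, 0.4, only16), "MQ")
  expect_identical(mag_quality_tier(95, 6, full), "MQ")    # fails HQ contamination
  expect_identical(mag_quality_tier(95, 2, only16), "MQ")  # fails HQ rRNA operon
  expect_identical(mag_quality_tier(40, 1, full), "fail")
})

test_that("quality tiers are monotone in completeness and contamination", {
  full <- c(`5S` = 1L, `16S` = 1L, `23S` = 1L)
  rank <- c(fail = 0, MQ = 1, HQ = 2)
  for (comp in c(45, 55, 85, 92, 99)) {
    for (cont in c(0, 3, 6, 12)) {
      t0 <- rank[mag_quality_tier(comp, cont, full)]
      expect_gte(rank[mag_quality_tier(min(comp + 10, 100), cont, full)], t0)
      expect_gte(rank[mag_quality_tier(comp, max(cont - 3, 0), full)], t0)
    }
  }
})

test_that("TPM normalizes by length and sums to a million", {
  expect_equal(tpm(c(10, 10), c(100, 100)), c(5e5, 5e5))
  expect_equal(tpm(c(10, 10), c(100, 200)), c(2e6 / 3, 1e6 / 3), tolerance = 1e-6)
  set.seed(20)
  cts <- rpois(30, 50); lens <- sample(200:2000, 30)
  expect_equal(sum(tpm(cts, lens)), 1e6, tolerance = 1e-3)
  expect_equal(tpm(cts * 2, lens), tpm(cts, lens), tolerance = 1e-9)
  expect_warning(z <- tpm(c(0, 0), c(100, 100)), "all counts zero")
  expect_equal(z, c(0, 0))
})

test_that("MAG-level expression aggregates gene TPM and tracks unbinned reads", {
  genes <- tibble::tibble(gene_id = paste0("g", 1:4),
                          mag_id = c("m1", "m1", "m2", NA),
                          length = c(100L, 200L, 100L, 400L))
  counts <- matrix(c(10, 20, 5, 8,
                     0, 10, 10, 0), ncol = 2,
                   dimnames = list(genes$gene_id, c("s1", "s2")))
  expr <- expression_table(genes, counts)
  agg <- aggregate_mag_expression(expr)
  m1_s1 <- sum(expr$tpm[c("g1", "g2"), "s1"])
  expect_equal(agg$tpm$tpm[agg$tpm$mag_id == "m1" & agg$tpm$sample_id == "s1"],
               m1_s1)
  expect_equal(agg$unbinned_fraction$fraction[1],
               expr$tpm["g4", "s1"] / 1e6, tolerance = 1e-12)
  expect_error(
    aggregate_mag_expression(expr, mags = list(mag_record("mX", "d__Bacteria", 90, 1))),
    "unknown MAG")
})

test_that("MG-MT correlation reports rho, t and df over paired observations", {
  tpm_tab <- tidyr::expand_grid(mag_id = paste0("m", 1:6),
                                sample_id = paste0("s", 1:5))
  set.seed(21)
  tpm_tab$tpm <- rlnorm(nrow(tpm_tab))
  same <- mg_mt_correlation(tpm_tab, tpm_tab)
  expect_equal(same$r, 1)
  expect_equal(same$df, nrow(tpm_tab) - 2)
  other <- tpm_tab; other$tpm <- rlnorm(nrow(other))
  res <- mg_mt_correlation(tpm_tab, other, method = "pearson")
  expect_equal(res$df, res$n - 2)
})

test_that("pathway markers separate encoded, expressed, and absent sets", {
  mag <- mag_record(
    "m1",
    "d__Archaea;p__Halobacterota;c__Methanomicrobia;o__Methanomicrobiales;f__Methanoregulaceae",
    99, 0, c(`5S` = 1L, `16S` = 1L, `23S` = 1L),
    genes = tibble::tibble(
      gene_id = paste0("m1_g", 1:13),
      length = rep(900L, 13),
      annotation = c(paste0("mcr", c("A", "B", "C", "D", "G")),
                     paste0("mtr", c("A", "B", "C", "D", "E", "F", "H")),
                     "rpoB")))
  counts <- matrix(5, nrow = 13, ncol = 2,
                   dimnames = list(mag$genes$gene_id, c("s1", "s2")))
  counts[13, ] <- 0   # rpoB encoded but silent
  expr <- expression_table(
    dplyr::mutate(mag$genes[, c("gene_id", "length")], mag_id = "m1"), counts)
  rep <- pathway_markers(mag, expr)
  hydro <- rep[rep$set == "hydrogenotrophic_methanogenesis", ]
  expect_true(all(hydro$encoded))
  expect_true(all(hydro$expressed))
  aceto <- rep[rep$set == "acetoclastic_methanogenesis", ]
  expect_false(any(aceto$encoded))   # no ack, no pta
  # encoded but unexpressed marker
  custom <- pathway_markers(mag, expr, marker_sets = list(house = "rpoB"))
  expect_true(custom$encoded)
  expect_false(custom$expressed)
  expect_error(pathway_markers(mag, expr, marker_sets = list()), "empty")
})
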