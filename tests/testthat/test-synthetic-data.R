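two_member_scenario <- function(rho, seed = 7L, n_samples = 60L) {
  simulation_scenario(
    n_samples = n_samples, n_asvs = 30,
    configuration_blocks = tibble::tibble(label = c("A", "B"),
                                          start = c(1L, n_samples %/% 2 + 1L),
                                          end = c(n_samples %/% 2, n_samples)),
    guild_modules = list(list(members = 1:2,
                              guilds = c("hydrogenotrophic_methanogen", "syntroph"),
                              rho = rho, config = NA, log2_fc = 0)),
    depth = 10000, seed = seed)
}

test_that("a planted 2-member module shows strong CLR correlation", {
  sim <- simulate_timeseries(two_member_scenario(rho = 0.9))
  clr <- clr_transform(sim$table$counts)
  expect_gt(cor(clr[1, ], clr[2, ]), 0.6)
  expect_equal(nrow(sim$truth$edges), 1)
})

test_that("rho = 0 plants no edges", {
  sim <- simulate_timeseries(two_member_scenario(rho = 0))
  expect_equal(nrow(sim$truth$edges), 0)
})

test_that("the generator is deterministic given the scenario seed", {
  s1 <- simulate_timeseries(two_member_scenario(0.9, seed = 3L))
  s2 <- simulate_timeseries(two_member_scenario(0.9, seed = 3L))
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(tibble::as_tibble(s1$params), tibble::as_tibble(s2$params))
  s3 <- simulate_timeseries(two_member_scenario(0.9, seed = 4L))
  expect_false(identical(s1$table$counts, s3$table$counts))
})

test_that("count columns sum exactly to the configured depth", {
  sim <- simulate_timeseries(two_member_scenario(0.5, seed = 9L))
  expect_true(all(colSums(sim$table$counts) == 10000))
})

test_that("planted module members correlate more strongly than non-members", {
  sim <- simulate_timeseries(default_scenario(seed = 21L))
  clr <- clr_transform(sim$table$counts)
  r <- cor(t(clr))
  member_pairs <- purrr::map_dbl(sim$truth$modules, function(m) {
    sub <- r[m$members, m$members]
    mean(sub[upper.tri(sub)])
  })
  off <- r[101:140, 201:240]   # ASVs outside every module
  expect_true(all(member_pairs > mean(off) + 0.3))
})

test_that("insufficient depth warns instead of failing", {
  sc <- simulation_scenario(
    n_samples = 6, n_asvs = 50,
    configuration_blocks = tibble::tibble(label = "A", start = 1L, end = 6L),
    depth = 30, seed = 2L)
  expect_warning(simulate_timeseries(sc), "depth too small")
})

test_that("scenario invariants are enforced", {
  blocks <- tibble::tibble(label = c("A", "B"), start = c(1L, 4L), end = c(2L, 6L))
  expect_error(simulation_scenario(6, 10, blocks, seed = 1L), "partition")
  blocks$end[1] <- 3L
  mods <- list(list(members = 1:2, guilds = c("syntroph", "other"),
                    rho = 0.5, config = NA, log2_fc = 0),
               list(members = 2:3, guilds = c("syntroph", "other"),
                    rho = 0.5, config = NA, log2_fc = 0))
  expect_error(simulation_scenario(6, 10, blocks, mods, seed = 1L), "disjoint")
  expect_error(simulation_scenario(6, 10, blocks, guild_modules = list(
    list(members = 1:2, guilds = c("syntroph", "other"), rho = 1, config = NA,
         log2_fc = 0)), seed = 1L))
  expect_error(simulation_scenario(6, 10, blocks), "mandatory")
})

test_that("MAG fixtures carry the ASV V4 at the requested mismatch distance", {
  seqs <- simulate_asv_sequences(c("a1", "a2"), seed = 5L)
  mags <- simulate_mag_fixtures(
    seqs, tibble::tibble(asv_id = c("a1", "a2"), n_mismatches = c(0L, 2L)),
    seed = 6L)
  v0 <- extract_v4(mags[[1]]$ssu_sequences[1])
  expect_identical(v0, seqs[["a1"]])
  v2 <- extract_v4(mags[[2]]$ssu_sequences[1])
  expect_equal(nchar(v2), nchar(seqs[["a2"]]))
  mm <- sum(strsplit(v2, "")[[1]] != strsplit(seqs[["a2"]], "")[[1]])
  expect_equal(mm, 2)
})

test_that("MAG fixture FASTA output is byte-identical under a fixed seed", {
  seqs <- simulate_asv_sequences(c("a1", "a2"), seed = 5L)
  pairs <- tibble::tibble(asv_id = c("a1", "a2"), n_mismatches = c(1L, 1L))
  write_run <- function() {
    mags <- simulate_mag_fixtures(seqs, pairs, seed = 11L)
    path <- tempfile(fileext = ".fasta")
    write_fasta(stats::setNames(
      vapply(mags, function(m) m$ssu_sequences[1], character(1)),
      vapply(mags, `[[`, character(1), "mag_id")), path)
    on.exit(unlink(path))
    readBin(path, "raw", file.size(path))
  }
  expect_identical(write_run(), write_run())
})

test_that("expression coupling spans identity to independence", {
  tax <- parse_taxonomy(
    c("b1", "b2", "b3", "b4", "m1"),
    c(rep("d__Bacteria;p__Chloroflexota;c__Anaerolineae;o__Anaerolineales;f__Anaerolineaceae", 4),
      "d__Archaea;p__Halobacterota;c__Methanomicrobia;o__Methanomicrobiales;f__Methanoregulaceae"))
  seqs <- simulate_asv_sequences(tax$id, seed = 1L)
  mags <- simulate_mag_fixtures(seqs, tibble::tibble(asv_id = tax$id, n_mismatches = 0L),
                                taxonomy = tax, seed = 2L)
  ex1 <- simulate_expression(mags, n_samples = 8, coupling = 1, seed = 3L,
                             methanogen_ids = character())
  a_mg <- aggregate_mag_expression(ex1$mg)$tpm
  a_mt <- aggregate_mag_expression(ex1$mt)$tpm
  expect_equal(mg_mt_correlation(a_mg, a_mt)$r, 1)

  ex0 <- simulate_expression(mags, n_samples = 50, coupling = 0, seed = 4L,
                             methanogen_ids = character())
  r0 <- mg_mt_correlation(aggregate_mag_expression(ex0$mg)$tpm,
                          aggregate_mag_expression(ex0$mt)$tpm)$r
  expect_lt(abs(r0), 0.3)
})

test_that("methanogen MAGs show inflated transcript:genome TPM ratios", {
  tax <- parse_taxonomy(
    sprintf("t%02d", 1:10),
    c(rep("d__Bacteria;p__Chloroflexota;c__Anaerolineae;o__Anaerolineales;f__Anaerolineaceae", 8),
      rep("d__Archaea;p__Halobacterota;c__Methanomicrobia;o__Methanomicrobiales;f__Methanoregulaceae", 2)))
  seqs <- simulate_asv_sequences(tax$id, seed = 7L)
  mags <- simulate_mag_fixtures(seqs, tibble::tibble(asv_id = tax$id, n_mismatches = 0L),
                                taxonomy = tax, seed = 8L)
  ex <- simulate_expression(mags, n_samples = 10, coupling = 0.6, seed = 9L)
  ratios <- dplyr::inner_join(
    aggregate_mag_expression(ex$mg)$tpm, aggregate_mag_expression(ex$mt)$tpm,
    by = c("mag_id", "sample_id"), suffix = c("_mg", "_mt")) |>
    dplyr::group_by(.data$mag_id) |>
    dplyr::summarise(ratio = mean(tpm_mt) / mean(tpm_mg)) |>
    dplyr::left_join(ex$mag_guilds, by = c(mag_id = "id"))
  meth <- ratios$ratio[grepl("methanogen", ratios$guild)]
  bact <- ratios$ratio[!grepl("methanogen", ratios$guild)]
  expect_true(all(meth > median(bact)))
})
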