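#' Simulation scenario for a digester-like ASV time series
#'
#' Describes the statistical structure the downstream analysis assumes:
#' configuration blocks along the sample axis, correlated guild modules
#' (e.g. a hydrogenotrophic methanogen co-varying with syntrophs) that
#' are up-shifted in one configuration, log-normal latent abundances, and
#' multinomial count realization at a fixed sequencing depth.
#'
#' @param n_samples,n_asvs Dimensions.
#' @param configuration_blocks Tibble (`label`, `start`, `end`) whose
#'   ranges partition `1:n_samples`.
#' @param guild_modules List of modules; each is a list with `members`
#'   (ASV indices, disjoint across modules), `guilds` (label per member),
#'   `rho` (intra-module latent correlation, `0 <= rho < 1`), `config`
#'   (label of the configuration in which the module is up-shifted, or
#'   `NA`), `log2_fc` (effect size of the shift).
#' @param baseline_log_mean,baseline_log_sd Per-ASV latent log-abundance
#'   mean and sd (scalars recycled).
#' @param depth Sequencing depth per sample (column sums of the counts
#'   equal this exactly).
#' @param start_date First sampling date; samples are biweekly.
#' @param seed Mandatory RNG seed (no hidden global randomness).
#' @return List of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_samples, n_asvs, configuration_blocks,
                                guild_modules = list(),
                                baseline_log_mean = 0, baseline_log_sd = 1,
                                depth = 20000,
                                start_date = as.Date("2016-10-13"),
                                seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  blocks <- tibble::as_tibble(configuration_blocks)
  stopifnot(all(c("label", "start", "end") %in% names(blocks)))
  covered <- unlist(purrr::map2(blocks$start, blocks$end, seq))
  if (!identical(sort(covered), seq_len(n_samples))) {
    stop("configuration blocks must partition the sample axis", call. = FALSE)
  }
  members <- unlist(purrr::map(guild_modules, "members"))
  if (anyDuplicated(members)) {
    stop("module members must be disjoint across modules", call. = FALSE)
  }
  for (m in guild_modules) {
    stopifnot(m$rho >= 0, m$rho < 1,
              length(m$guilds) == length(m$members))
  }
  structure(
    list(n_samples = n_samples, n_asvs = n_asvs,
         configuration_blocks = blocks, guild_modules = guild_modules,
         baseline_log_mean = rep_len(baseline_log_mean, n_asvs),
         baseline_log_sd = rep_len(baseline_log_sd, n_asvs),
         depth = depth, start_date = as.Date(start_date),
         seed = as.integer(seed)),
    class = "simulation_scenario")
}

#' Default desk-scale scenario
#'
#' Mirrors the shape of a two-year biweekly digester study at desk scale:
#' 40 samples in four configuration blocks (SOI/CEPT/SOII/SER, sized in
#' the proportions of the study's 16/10/11/6 configuration groups),
#' 300 ASVs at depth 20,000, and five 4-member guild modules (one
#' hydrogenotrophic methanogen, two syntrophs, one fermenter each) with
#' intra-module latent correlation 0.9, each up-shifted 3 log2 units in
#' one configuration.
#'
#' @param seed RNG seed (propagated into the scenario).
#' @return A [simulation_scenario()].
#' @export
default_scenario <- function(seed = 1L) {
  blocks <- tibble::tribble(
    ~label, ~start, ~end,
    "SOI",   1L, 15L,
    "CEPT", 16L, 24L,
    "SOII", 25L, 34L,
    "SER",  35L, 40L)
  configs <- c("SOI", "CEPT", "SOII", "SER", "SER")
  modules <- purrr::map(1:5, function(i) {
    list(members = (i - 1L) * 4L + 1:4,
         guilds = c("hydrogenotrophic_methanogen", "syntroph", "syntroph", "other"),
         rho = 0.9, config = configs[i], log2_fc = 4)
  })
  simulation_scenario(n_samples = 40, n_asvs = 300,
                      configuration_blocks = blocks,
                      guild_modules = modules,
                      baseline_log_mean = 0, baseline_log_sd = 1,
                      depth = 20000, seed = seed)
}

# lineages used to label synthetic taxa; guild lineages rotate through the
# named methanogen / syntroph families, fillers avoid any guild family
sim_lineages <- function() {
  list(
    hydrogenotrophic_methanogen = c(
      "d__Archaea;p__Halobacterota;c__Methanomicrobia;o__Methanomicrobiales;f__Methanoregulaceae;g__Methanolinea",
      "d__Archaea;p__Halobacterota;c__Methanomicrobia;o__Methanomicrobiales;f__Methanospirillaceae;g__Methanospirillum",
      "d__Archaea;p__Euryarchaeota;c__Methanobacteria;o__Methanobacteriales;f__Methanobacteriaceae;g__Methanobacterium",
      "d__Archaea;p__Halobacterota;c__Methanomicrobia;o__Methanomicrobiales;f__Methanomicrobiaceae;g__Methanoculleus"),
    acetoclastic_methanogen = c(
      "d__Archaea;p__Halobacterota;c__Methanosarcinia;o__Methanosarciniales;f__Methanosaetaceae;g__Methanothrix"),
    syntroph = c(
      "d__Bacteria;p__Desulfobacterota;c__Syntrophia;o__Syntrophales;f__Syntrophaceae;g__Smithella",
      "d__Bacteria;p__Desulfobacterota;c__Syntrophorhabdia;o__Syntrophorhabdales;f__Syntrophorhabdaceae;g__Syntrophorhabdus",
      "d__Bacteria;p__Firmicutes;c__Clostridia;o__Eubacteriales;f__Syntrophomonadaceae;g__Syntrophomonas",
      "d__Bacteria;p__Synergistota;c__Synergistia;o__Synergistales;f__Synergistaceae;g__Thermovirga"),
    other = c(
      "d__Bacteria;p__Cloacimonadota;c__Cloacimonadia;o__Cloacimonadales;f__Cloacimonadaceae;g__Cloacimonas",
      "d__Bacteria;p__Chloroflexota;c__Anaerolineae;o__Anaerolineales;f__Anaerolineaceae;g__Anaerolinea",
      "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Rikenellaceae;g__DMER64",
      "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Lentimicrobiaceae;g__Lentimicrobium",
      "d__Bacteria;p__Spirochaetota;c__Spirochaetia;o__Spirochaetales;f__Spirochaetaceae;g__Treponema",
      "d__Bacteria;p__Firmicutes;c__Clostridia;o__Oscillospirales;f__Ruminococcaceae;g__Ruminococcus"))
}

#' Simulate an ASV time series with planted structure
#'
#' Latent log-abundances are multivariate normal with correlation
#' `rho` inside each guild module and 0 elsewhere (realized through a
#' shared per-sample module factor); configuration effects enter as mean
#' shifts of `log(2) * log2_fc` for module members in their up-shifted
#' configuration; counts are drawn multinomially per sample at the
#' configured depth (column sums are exact). A physicochemical series is
#' emitted whose parameters are linear functions of configuration plus
#' noise, with a fraction of interior measurements dropped so that
#' interpolation has work to do.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `table` ([abundance_table()]), `taxonomy`
#'   (`taxonomy_table`), `params` ([parameter_series()]), and `truth`
#'   (list: `edges` tibble of planted intra-module pairs, `indicators`
#'   tibble of configuration-shifted ASVs, `guilds` tibble, `modules`).
#' @export
simulate_timeseries <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  if (sc$depth / sc$n_asvs < 1) {
    warning("depth too small to realize all ASVs (expected count < 1 per ASV)")
  }
  config <- character(sc$n_samples)
  for (i in seq_len(nrow(sc$configuration_blocks))) {
    config[sc$configuration_blocks$start[i]:sc$configuration_blocks$end[i]] <-
      sc$configuration_blocks$label[i]
  }
  dates <- sc$start_date + 14 * (seq_len(sc$n_samples) - 1)
  asv_ids <- sprintf("ASV_%03d", seq_len(sc$n_asvs))

  # latent log abundances: shared module factor induces the block correlation
  eps <- matrix(stats::rnorm(sc$n_asvs * sc$n_samples), sc$n_asvs, sc$n_samples)
  for (m in sc$guild_modules) {
    if (m$rho > 0) {
      f <- stats::rnorm(sc$n_samples)
      eps[m$members, ] <- sqrt(m$rho) * matrix(f, length(m$members), sc$n_samples,
                                               byrow = TRUE) +
        sqrt(1 - m$rho) * eps[m$members, , drop = FALSE]
    }
  }
  z <- sc$baseline_log_mean + sc$baseline_log_sd * eps
  for (m in sc$guild_modules) {
    if (!is.na(m$config)) {
      z[m$members, config == m$config] <-
        z[m$members, config == m$config] + log(2) * m$log2_fc
    }
  }
  counts <- apply(z, 2, function(col) {
    stats::rmultinom(1, sc$depth, exp(col) / sum(exp(col)))
  })
  dimnames(counts) <- list(asv_ids, sprintf("S%02d", seq_len(sc$n_samples)))
  table <- abundance_table(counts, dates, config)

  # taxonomy: guild lineages for module members, filler lineages elsewhere
  pools <- sim_lineages()
  used <- stats::setNames(rep(0L, length(pools)), names(pools))
  lineages <- character(sc$n_asvs)
  for (m in sc$guild_modules) {
    for (i in seq_along(m$members)) {
      g <- m$guilds[i]
      pool <- pools[[g]]
      used[g] <- used[g] %% length(pool) + 1L
      lineages[m$members[i]] <- pool[used[g]]
    }
  }
  filler <- pools$other
  free <- which(lineages == "")
  lineages[free] <- filler[(seq_along(free) - 1) %% length(filler) + 1]
  taxonomy <- parse_taxonomy(asv_ids, lineages)

  # physicochemical series: configuration-level means plus noise, 20% of
  # interior measurements dropped
  param_defs <- tibble::tribble(
    ~parameter,             ~SOI, ~CEPT, ~SOII, ~SER, ~sd,
    "organic_loading_rate",  2.0,   3.5,   2.1,  2.6, 0.25,
    "volatile_fatty_acids",  120,   180,   130,  260, 20,
    "ammonia",               900,  1000,   950, 1400, 80,
    "nitrate",               1.5,   2.5,   1.8,  3.5, 0.3,
    "biogas_total",         4200,  5500,  4300, 3600, 250,
    "ch4_percent",          61.0,  60.0,  61.5, 66.0, 1.0)
  block_labels <- sc$configuration_blocks$label
  params <- purrr::pmap_dfr(param_defs, function(parameter, SOI, CEPT, SOII, SER, sd) {
    # study-configuration means recycled over the scenario's blocks by position
    level <- rep_len(c(SOI, CEPT, SOII, SER), length(block_labels))
    mu <- stats::setNames(level, block_labels)[config]
    value <- mu + stats::rnorm(sc$n_samples, 0, sd)
    interior <- 2:(sc$n_samples - 1)
    drop <- sample(interior, size = floor(0.2 * length(interior)))
    value[drop] <- NA
    tibble::tibble(date = dates, parameter = parameter, value = value)
  })
  params <- parameter_series(params)

  planted_edges <- purrr::map_dfr(sc$guild_modules, function(m) {
    if (m$rho == 0 || length(m$members) < 2) return(NULL)
    pairs <- utils::combn(sort(asv_ids[m$members]), 2)
    tibble::tibble(from = pairs[1, ], to = pairs[2, ])
  })
  indicators <- purrr::map_dfr(sc$guild_modules, function(m) {
    if (is.na(m$config)) return(NULL)
    tibble::tibble(asv_id = asv_ids[m$members], configuration = m$config)
  })
  guilds <- tibble::tibble(id = asv_ids, guild = "other")
  for (m in sc$guild_modules) guilds$guild[m$members] <- m$guilds

  list(table = table, taxonomy = taxonomy, params = params,
       truth = list(edges = planted_edges, indicators = indicators,
                    guilds = guilds, modules = sc$guild_modules))
}

#' Random ASV-like V4 sequences
#'
#' @param ids Sequence names.
#' @param length Sequence length in bp (default 253, a typical V4).
#' @param seed RNG seed.
#' @return Named character vector.
#' @export
simulate_asv_sequences <- function(ids, length = 253, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  seqs <- vapply(seq_along(ids), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
  stats::setNames(seqs, ids)
}

# concrete realization of a degenerate primer (first allowed base per code)
realize_primer <- function(primer) {
  map <- c(A = "A", C = "C", G = "G", T = "T", Y = "C", M = "A", N = "A",
           V = "A", W = "A", R = "A", S = "C", K = "G", B = "C", D = "A",
           H = "A")
  paste(map[strsplit(toupper(primer), "")[[1]]], collapse = "")
}

#' Simulate MAG records paired to ASVs at controlled 16S distance
#'
#' Each requested pair produces a MAG whose (single) full-length 16S
#' contains the ASV's V4 region mutated at exactly `n_mismatches`
#' positions, flanked by concrete realizations of the 515F/806R primer
#' sites (so [extract_v4()] recovers the mutated region) and random
#' flanking sequence. Mutations are placed only inside the V4 region, so
#' they can never collide with the primer sites. Quality metrics are
#' drawn from the configured ranges; gene content follows the ASV's
#' guild (methanogen MAGs carry `mcr`/`mtr` operons and lack `ack`/`pta`;
#' syntroph MAGs carry Wood-Ljungdahl methyl-branch and glycine-cleavage
#' genes; all carry housekeeping genes).
#'
#' @param asv_sequences Named character vector of ASV V4 sequences.
#' @param pairs Tibble (`asv_id`, `n_mismatches`).
#' @param taxonomy Optional `taxonomy_table`; the MAG inherits its ASV's
#'   lineage (making the pair LCA-concordant).
#' @param seed RNG seed (fixed seed gives byte-identical output).
#' @param completeness_range,contamination_range Quality metric ranges.
#' @param flank Flanking sequence length on each side.
#' @return List of [mag_record()]s (mag_id = `MAG_<asv_id>`).
#' @export
simulate_mag_fixtures <- function(asv_sequences, pairs, taxonomy = NULL, seed,
                                  completeness_range = c(91, 100),
                                  contamination_range = c(0, 4.5),
                                  flank = 150) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("asv_id", "n_mismatches") %in% names(pairs)))
  set.seed(seed)
  fwd <- realize_primer("GTGYCAGCMGCCGCGGTAA")
  rev_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(realize_primer("GGACTACNVGGGTWTCTAAT"))))
  purrr::pmap(pairs, function(asv_id, n_mismatches) {
    v <- asv_sequences[[asv_id]]
    if (is.null(v)) stop("unknown ASV id: ", asv_id, call. = FALSE)
    stopifnot(n_mismatches >= 0, n_mismatches <= nchar(v))
    chars <- strsplit(v, "")[[1]]
    if (n_mismatches > 0) {
      pos <- sample(nchar(v), n_mismatches)
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      }
    }
    v_mut <- paste(chars, collapse = "")
    rand_flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")
    ssu <- paste0(rand_flank(flank), fwd, v_mut, rev_rc, rand_flank(flank))
    lineage <- if (!is.null(taxonomy) && asv_id %in% taxonomy$id) {
      taxonomy[taxonomy$id == asv_id, ]
    } else {
      parse_taxonomy(asv_id, "d__Bacteria")
    }
    guild <- assign_guilds(lineage)$guild[1]
    mag_record(
      mag_id = paste0("MAG_", asv_id),
      taxonomy = dplyr::mutate(lineage, id = paste0("MAG_", asv_id)),
      completeness = stats::runif(1, completeness_range[1], completeness_range[2]),
      contamination = stats::runif(1, contamination_range[1], contamination_range[2]),
      rrna_counts = c(`5S` = 1L, `16S` = 1L, `23S` = 1L),
      ssu_sequences = ssu,
      genes = sim_mag_genes(paste0("MAG_", asv_id), guild))
  })
}

sim_mag_genes <- function(mag_id, guild) {
  symbols <- switch(
    guild,
    hydrogenotrophic_methanogen = c(paste0("mcr", c("A", "B", "C", "D", "G")),
                                    paste0("mtr", c("A", "B", "C", "D", "E", "F", "H")),
                                    "rpoB", "gyrA", "fwdA"),
    syntroph = c("fdh", "fhs", "fol", "met", "gcvH", "gcvP", "gcvT",
                 "rpoB", "gyrA", "hydA"),
    acetoclastic_methanogen = c("ack", "pta", "mcrA", "mcrB", "rpoB", "gyrA"),
    c("rpoB", "gyrA", "recA", "dnaK", "ftsZ")
  )
  tibble::tibble(
    gene_id = sprintf("%s_g%03d", mag_id, seq_along(symbols)),
    length = as.integer(600 + 150 * (seq_along(symbols) %% 5)),
    annotation = symbols)
}

#' Simulate matched metagenome / metatranscriptome gene counts
#'
#' Per-MAG latent log-abundances drive the metagenome; metatranscriptome
#' log-abundances are `coupling * metagenome + (1 - coupling) * noise`
#' (noise sd `noise_sd`). For methanogen MAGs (identified from their
#' taxonomy, or passed explicitly) the transcriptome is additionally
#' inflated by `methanogen_inflation` natural-log units independently of
#' the metagenome, emulating the genome/transcript decoupling of
#' methanogens. Counts are a deterministic length-weighted rounding of
#' the latent abundances, so `coupling = 1` without inflation reproduces
#' the metagenome table exactly.
#'
#' @param mags List of [mag_record()]s (each with >= 1 gene).
#' @param n_samples Number of matched libraries.
#' @param coupling Value in `[0, 1]`.
#' @param seed RNG seed.
#' @param methanogen_ids MAG ids to inflate; default: MAGs whose guild
#'   (from taxonomy) is a methanogen guild. Use `character()` to disable.
#' @param methanogen_inflation Transcript inflation (natural-log units).
#' @param noise_sd Sd of the independent transcriptional noise.
#' @return List with `mg` and `mt` [expression_table()]s and
#'   `mag_guilds` (tibble `id`, `guild`).
#' @export
simulate_expression <- function(mags, n_samples, coupling, seed,
                                methanogen_ids = NULL,
                                methanogen_inflation = 3, noise_sd = 2) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(coupling >= 0, coupling <= 1)
  if (any(vapply(mags, function(m) nrow(m$genes) == 0, logical(1)))) {
    stop("every MAG needs at least one gene", call. = FALSE)
  }
  set.seed(seed)
  mag_ids <- vapply(mags, `[[`, character(1), "mag_id")
  guilds <- purrr::map_dfr(mags, function(m) assign_guilds(m$taxonomy))
  if (is.null(methanogen_ids)) {
    methanogen_ids <- guilds$id[grepl("methanogen", guilds$guild)]
  }
  genes <- purrr::map_dfr(mags, function(m) {
    dplyr::mutate(m$genes[, c("gene_id", "length")], mag_id = m$mag_id)
  })
  genes <- genes[, c("gene_id", "mag_id", "length")]
  n_genes <- nrow(genes)
  sample_ids <- sprintf("MTS%02d", seq_len(n_samples))
  mag_ab <- matrix(stats::rnorm(length(mags) * n_samples), length(mags), n_samples,
                   dimnames = list(mag_ids, sample_ids))
  gene_base <- stats::rnorm(n_genes, 0, 0.5)
  l_mg <- mag_ab[genes$mag_id, , drop = FALSE] + gene_base
  # transcriptional noise is an organism-level state: drawn per MAG and
  # sample, shared by the MAG's genes (so it survives MAG-level aggregation)
  eta_mag <- matrix(stats::rnorm(length(mags) * n_samples, 0, noise_sd),
                    length(mags), n_samples, dimnames = list(mag_ids, sample_ids))
  l_mt <- coupling * l_mg + (1 - coupling) * eta_mag[genes$mag_id, , drop = FALSE]
  inflate <- genes$mag_id %in% methanogen_ids
  l_mt[inflate, ] <- l_mt[inflate, ] + methanogen_inflation
  to_counts <- function(l) {
    cts <- round(exp(l) * (genes$length / 1000) * 50)
    dimnames(cts) <- list(genes$gene_id, sample_ids)
    cts
  }
  list(mg = expression_table(genes, to_counts(l_mg)),
       mt = expression_table(genes, to_counts(l_mt)),
       mag_guilds = guilds)
}
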