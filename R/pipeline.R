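#' Read MAG records from flat text inputs
#'
#' @param metadata_path TSV with columns `mag_id`, `lineage`,
#'   `completeness`, `contamination`, `rrna_5s`, `rrna_16s`, `rrna_23s`.
#' @param fasta_path 16S sequences, FASTA ids = mag ids (one per MAG).
#' @param genes_path TSV with columns `gene_id`, `mag_id`, `length`,
#'   `annotation`.
#' @return List of [mag_record()]s.
#' @export
read_mag_records <- function(metadata_path, fasta_path, genes_path) {
  meta <- read_tsv_strict(metadata_path)
  seqs <- read_fasta(fasta_path)
  genes <- read_tsv_strict(genes_path)
  purrr::pmap(meta, function(mag_id, lineage, completeness, contamination,
                             rrna_5s, rrna_16s, rrna_23s, ...) {
    mag_record(
      mag_id = mag_id,
      taxonomy = parse_taxonomy(mag_id, lineage),
      completeness = completeness, contamination = contamination,
      rrna_counts = c(`5S` = rrna_5s, `16S` = rrna_16s, `23S` = rrna_23s),
      ssu_sequences = unname(seqs[names(seqs) == mag_id]),
      genes = genes[genes$mag_id == mag_id, c("gene_id", "length", "annotation")])
  })
}

write_taxonomy <- function(taxonomy, path) {
  tax <- tibble::as_tibble(taxonomy)
  lineage <- apply(as.matrix(tax[tax_ranks()]), 1, function(r) {
    r <- r[!is.na(r)]
    paste(paste0(substr(c("d", "p", "c", "o", "f", "g", "s")[seq_along(r)], 1, 1),
                 "__", r), collapse = ";")
  })
  utils::write.table(data.frame(id = tax$id, lineage = lineage), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

read_taxonomy <- function(path) {
  df <- read_tsv_strict(path)
  parse_taxonomy(df$id, df$lineage)
}

read_gene_counts <- function(path) {
  df <- read_tsv_strict(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Generate a complete, runnable synthetic input bundle
#'
#' Simulates the full input set of the pipeline from a scenario — ASV
#' counts with metadata, taxonomy, physicochemical series, ASV sequences,
#' MAG records at controlled 16S distance, matched metagenome /
#' metatranscriptome gene counts — writes everything as flat text files
#' under `dir`, together with the ground truth and a ready-to-run
#' pipeline config, and returns the config.
#'
#' @param dir Output directory (created if needed).
#' @param scenario A [simulation_scenario()]; default
#'   [default_scenario()] at `seed`.
#' @param seed Seed for the sequence/MAG/expression layers (the count
#'   layer uses the scenario's own seed).
#' @param expression_samples Number of matched MG/MT libraries.
#' @param expression_coupling Transcriptome/genome coupling in `[0, 1]`.
#' @return The pipeline config (list), invisibly written to
#'   `dir/config.yaml`.
#' @export
simulate_inputs <- function(dir, scenario = default_scenario(seed), seed = 1L,
                            expression_samples = 14,
                            expression_coupling = 0.6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  sim <- simulate_timeseries(scenario)
  write_abundance_table(sim$table, p("counts.tsv"), p("sample_metadata.tsv"))
  write_parameter_series(sim$params, p("parameters.tsv"))
  write_taxonomy(sim$taxonomy, p("taxonomy.tsv"))

  asv_ids <- rownames(sim$table$counts)
  seqs <- simulate_asv_sequences(asv_ids, seed = seed + 1L)
  write_fasta(seqs, p("asv_sequences.fasta"))

  module_members <- unique(sim$truth$indicators$asv_id)
  if (length(module_members) == 0) {
    module_members <- unique(unlist(purrr::map(sim$truth$modules, function(m)
      asv_ids[m$members])))
  }
  pairs <- tibble::tibble(asv_id = module_members,
                          n_mismatches = rep_len(c(0L, 1L), length(module_members)))
  mags <- simulate_mag_fixtures(seqs, pairs, taxonomy = sim$taxonomy,
                                seed = seed + 2L)
  mag_meta <- purrr::map_dfr(mags, function(m) {
    tibble::tibble(mag_id = m$mag_id,
                   lineage = lineage_string(m$taxonomy),
                   completeness = m$completeness, contamination = m$contamination,
                   rrna_5s = m$rrna_counts[["5S"]], rrna_16s = m$rrna_counts[["16S"]],
                   rrna_23s = m$rrna_counts[["23S"]])
  })
  utils::write.table(mag_meta, p("mag_metadata.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(stats::setNames(
    vapply(mags, function(m) m$ssu_sequences[1], character(1)),
    vapply(mags, `[[`, character(1), "mag_id")), p("mag_16s.fasta"))
  mag_genes <- purrr::map_dfr(mags, function(m)
    dplyr::mutate(m$genes, mag_id = m$mag_id))
  utils::write.table(mag_genes[, c("gene_id", "mag_id", "length", "annotation")],
                     p("mag_genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  expr <- simulate_expression(mags, n_samples = expression_samples,
                              coupling = expression_coupling, seed = seed + 3L)
  for (nm in c("mg", "mt")) {
    df <- data.frame(gene_id = rownames(expr[[nm]]$counts), expr[[nm]]$counts,
                     check.names = FALSE)
    utils::write.table(df, p(nm, "_counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  utils::write.table(as.data.frame(sim$truth$edges), p("truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$truth$indicators), p("truth_indicators.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$truth$guilds), p("truth_guilds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  config <- pipeline_config(
    inputs = list(counts = p("counts.tsv"),
                  sample_metadata = p("sample_metadata.tsv"),
                  parameters = p("parameters.tsv"),
                  taxonomy = p("taxonomy.tsv"),
                  asv_fasta = p("asv_sequences.fasta"),
                  mag_metadata = p("mag_metadata.tsv"),
                  mag_fasta = p("mag_16s.fasta"),
                  mag_genes = p("mag_genes.tsv"),
                  mg_counts = p("mg_counts.tsv"),
                  mt_counts = p("mt_counts.tsv")),
    output_dir = file.path(dir, "results"),
    seed = seed)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(config)
}

lineage_string <- function(taxonomy) {
  r <- unlist(taxonomy[1, tax_ranks()], use.names = FALSE)
  r <- r[!is.na(r)]
  paste(paste0(c("d", "p", "c", "o", "f", "g", "s")[seq_along(r)], "__", r),
        collapse = ";")
}

#' Pipeline configuration
#'
#' @param inputs Named list of input paths (see [simulate_inputs()] for
#'   the full set).
#' @param output_dir Where stage outputs land.
#' @param stages Named logical toggles: `prep`, `community`, `network`,
#'   `indicators`, `link`, `expression`, `subnetworks`, `enrichment`.
#' @param seed Global seed; every stochastic stage derives its own seed
#'   from it.
#' @param min_mean_count,prevalence_core,n_perm_permanova,n_perm_indicator,n_perm_enrichment
#'   Stage parameters.
#' @param network Network configuration ([network_config()] or its list
#'   of fields).
#' @return Config list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, output_dir,
                            stages = list(prep = TRUE, community = TRUE,
                                          network = TRUE, indicators = TRUE,
                                          link = TRUE, expression = TRUE,
                                          subnetworks = TRUE, enrichment = TRUE),
                            seed = 1L,
                            min_mean_count = 1.0,
                            prevalence_core = 0.8,
                            n_perm_permanova = 999,
                            n_perm_indicator = 999,
                            n_perm_enrichment = 10000,
                            network = list()) {
  structure(list(inputs = inputs, output_dir = output_dir, stages = stages,
                 seed = as.integer(seed), min_mean_count = min_mean_count,
                 prevalence_core = prevalence_core,
                 n_perm_permanova = n_perm_permanova,
                 n_perm_indicator = n_perm_indicator,
                 n_perm_enrichment = n_perm_enrichment,
                 network = network),
            class = c("pipeline_config", "list"))
}

#' Run the analysis pipeline end to end
#'
#' Executes the stages in dependency order — metadata prep, community
#' structure, network inference, indicator analysis, MAG linking,
#' expression overlay, subnetwork extraction, guild enrichment — writing
#' each stage's outputs under the configured output directory together
#' with a machine-readable JSON run report (config hash, seeds, package
#' version, stage status). Disabled stages are skipped; a stage whose
#' dependency was disabled and has no prior output on disk fails with a
#' dependency error. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()], a config list, or the path to a
#'   YAML config file.
#' @return Invisible list of in-memory stage results plus `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  on_stage <- function(name) isTRUE(cfg$stages[[name]])
  need <- function(dep, what) {
    stop("stage '", what, "' requires stage '", dep,
         "' to have run (enable it or provide its outputs)", call. = FALSE)
  }
  res <- list()
  status <- list()

  table <- read_abundance_table(cfg$inputs$counts, cfg$inputs$sample_metadata)
  table <- filter_low_abundance(table, cfg$min_mean_count %||% 1.0)
  taxonomy <- if (!is.null(cfg$inputs$taxonomy)) read_taxonomy(cfg$inputs$taxonomy)

  if (on_stage("prep")) {
    series <- read_parameter_series(cfg$inputs$parameters)
    interp <- interpolate_parameters(series, table$samples$date)
    utils::write.table(as.data.frame(interp), p("interpolated_parameters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$interp <- interp
    status$prep <- "ok"
  }

  if (on_stage("community")) {
    d <- bray_curtis(table)
    utils::write.table(as.data.frame(unclass(d)), p("bray_curtis.tsv"),
                       sep = "\t", quote = FALSE)
    hc <- hierarchical_cluster(d)
    write_dendrogram_newick(hc, p("dendrogram.nwk"))
    ord <- pcoa(d, groups = table$samples$configuration)
    utils::write.table(as.data.frame(ord$scores), p("pcoa_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pmv <- permanova(d, table$samples$configuration,
                     n_perm = cfg$n_perm_permanova %||% 999,
                     seed = cfg$seed + 11L)
    utils::write.table(as.data.frame(pmv), p("permanova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    core <- core_microbiome(table, cfg$prevalence_core %||% 0.8)
    utils::write.table(as.data.frame(core$prevalence), p("core_microbiome.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$distance <- d; res$pcoa <- ord; res$permanova <- pmv; res$core <- core
    status$community <- "ok"
  }

  net <- NULL
  if (on_stage("network")) {
    ncfg <- do.call(network_config, c(cfg$network, list(seed = cfg$seed + 21L)))
    net <- build_network(table, ncfg, taxonomy = taxonomy)
    stats_tab <- attr(net, "edge_stats")
    if (!is.null(stats_tab)) {
      utils::write.table(as.data.frame(stats_tab), p("edge_statistics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    status$network <- "ok"
  }

  if (on_stage("indicators")) {
    ind <- indicator_test(table, n_perm = cfg$n_perm_indicator %||% 999,
                          seed = cfg$seed + 31L)
    utils::write.table(as.data.frame(ind), p("indicators.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(net)) net <- set_node_indicators(net, ind)
    res$indicators <- ind
    status$indicators <- "ok"
  }

  pairs <- NULL
  if (on_stage("link")) {
    asv_seqs <- read_fasta(cfg$inputs$asv_fasta)
    mags <- read_mag_records(cfg$inputs$mag_metadata, cfg$inputs$mag_fasta,
                             cfg$inputs$mag_genes)
    pairs <- pair_asv_mag(asv_seqs, mags, asv_taxonomy = taxonomy)
    utils::write.table(as.data.frame(pairs), p("asv_mag_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(net)) net <- set_node_mags(net, pairs)
    res$pairs <- pairs; res$mags <- mags
    status$link <- "ok"
  }

  if (on_stage("expression")) {
    if (is.null(pairs)) need("link", "expression")
    genes_tab <- read_tsv_strict(cfg$inputs$mag_genes)
    read_expr <- function(path) {
      cts <- read_gene_counts(path)
      genes <- genes_tab[match(rownames(cts), genes_tab$gene_id),
                         c("gene_id", "mag_id", "length")]
      expression_table(genes, cts)
    }
    mg <- read_expr(cfg$inputs$mg_counts)
    mt <- read_expr(cfg$inputs$mt_counts)
    mg_agg <- aggregate_mag_expression(mg, res$mags)
    mt_agg <- aggregate_mag_expression(mt, res$mags)
    mag_guilds <- purrr::map_dfr(res$mags, function(m) assign_guilds(m$taxonomy))
    mgmt <- mg_mt_correlation(mg_agg$tpm, mt_agg$tpm, mag_guilds = mag_guilds)
    utils::write.table(as.data.frame(mt_agg$tpm), p("mag_tpm_mt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(mgmt), p("mg_mt_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(net)) net <- set_node_expression(net, mt_agg$tpm)
    res$mg_tpm <- mg_agg; res$mt_tpm <- mt_agg; res$mg_mt <- mgmt
    status$expression <- "ok"
  }

  if (!is.null(net)) {
    write_network(net, p("network.graphml"), "graphml")
    write_network(net, p("network_edges.tsv"), "edge_tsv")
    res$network <- net
  }

  subs <- NULL
  if (on_stage("subnetworks")) {
    if (is.null(net)) {
      if (file.exists(p("network.graphml"))) {
        net <- read_network(p("network.graphml"), "graphml")
      } else {
        need("network", "subnetworks")
      }
    }
    subs <- extract_subnetworks(net)
    utils::write.table(as.data.frame(tidy(subs)), p("subnetworks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$subnetworks <- subs
    status$subnetworks <- "ok"
  }

  if (on_stage("enrichment")) {
    if (is.null(subs)) need("subnetworks", "enrichment")
    enr <- purrr::map_dfr(subs, function(s) {
      guild_enrichment(net, s, n_perm = cfg$n_perm_enrichment %||% 10000,
                       seed = cfg$seed + 41L + s$id)
    })
    utils::write.table(as.data.frame(enr), p("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$enrichment <- enr
    status$enrichment <- "ok"
  }

  report <- list(
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("digestnet")),
    stages = status,
    timestamp_free = TRUE)
  jsonlite::write_json(report, p("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  res$report <- report
  invisible(res)
}
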