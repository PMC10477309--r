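#' Parse ranked lineage strings
#'
#' Accepts GTDB/SILVA-style lineage strings
#' (`"d__Archaea;p__Halobacteriota;...;s__"`), with or without rank
#' prefixes. Missing ranks are only allowed as a suffix: once a rank is
#' unannotated, all deeper ranks must be too.
#'
#' @param ids Identifier per lineage (ASV or MAG ids).
#' @param lineages Character vector of `;`-separated lineages.
#' @return Tibble of class `taxonomy_table`: one row per id with columns
#'   `id`, `domain`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species` (`NA` for unannotated ranks).
#' @export
parse_taxonomy <- function(ids, lineages) {
  stopifnot(length(ids) == length(lineages))
  ranks <- tax_ranks()
  rows <- lapply(lineages, function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts <- sub("^[dpcofgs]__", "", parts)
    parts[parts == ""] <- NA_character_
    length(parts) <- length(ranks)
    parts
  })
  m <- do.call(rbind, rows)
  colnames(m) <- ranks
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(ids)), out)
  validate_taxonomy(out)
}

tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

validate_taxonomy <- function(x) {
  m <- as.matrix(x[tax_ranks()])
  bad <- apply(m, 1, function(r) {
    miss <- is.na(r)
    any(miss) && any(!miss[seq_along(miss) > which(miss)[1]])
  })
  if (any(bad)) {
    stop("lineage has an annotated rank below a missing one for id(s): ",
         paste(x$id[bad], collapse = ", "), call. = FALSE)
  }
  class(x) <- unique(c("taxonomy_table", class(x)))
  x
}

#' Lowest-common-ancestor taxonomy concordance
#'
#' Two lineages are concordant when, truncated to the shallower of their
#' two deepest annotated ranks, all retained ranks agree. For example an
#' ASV annotated to order and a MAG annotated to family agree iff they
#' share domain through order.
#'
#' @param asv_tax,mag_tax Character vectors of ranked names ordered
#'   domain..species (`NA` for unannotated), or single-row
#'   `taxonomy_table`s.
#' @return `TRUE`/`FALSE`.
#' @export
lca_concordant <- function(asv_tax, mag_tax) {
  asv_tax <- lineage_vector(asv_tax)
  mag_tax <- lineage_vector(mag_tax)
  depth <- min(max(which(!is.na(asv_tax)), 0L), max(which(!is.na(mag_tax)), 0L))
  if (depth == 0) stop("both lineages must have at least one annotated rank",
                       call. = FALSE)
  keep <- seq_len(depth)
  all(norm_taxon(asv_tax[keep]) == norm_taxon(mag_tax[keep]))
}

lineage_vector <- function(x) {
  if (inherits(x, "data.frame")) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[1, tax_ranks()], use.names = FALSE)
  }
  as.character(x)
}

norm_taxon <- function(x) tolower(trimws(sub("^[dpcofgs]__", "", x)))

#' Default taxonomy-to-guild lookup
#'
#' Maps the methanogen and syntroph lineages named in anaerobic-digester
#' studies to functional guilds. Matching is by any rank name (family or
#' genus level entries provided). Editable: pass your own table to
#' [assign_guilds()].
#'
#' @return Tibble with columns `taxon` and `guild`
#'   (`hydrogenotrophic_methanogen`, `acetoclastic_methanogen`,
#'   `syntroph`).
#' @export
default_guild_table <- function() {
  tibble::tribble(
    ~taxon,                ~guild,
    "Methanoregulaceae",   "hydrogenotrophic_methanogen",
    "Methanospirillaceae", "hydrogenotrophic_methanogen",
    "Methanomicrobiaceae", "hydrogenotrophic_methanogen",
    "Methanobacteriaceae", "hydrogenotrophic_methanogen",
    "Methanolinea",        "hydrogenotrophic_methanogen",
    "Methanobacterium",    "hydrogenotrophic_methanogen",
    "Methanospirillum",    "hydrogenotrophic_methanogen",
    "Methanoculleus",      "hydrogenotrophic_methanogen",
    "Methanosaetaceae",    "acetoclastic_methanogen",
    "Methanothrix",        "acetoclastic_methanogen",
    "Methanosaeta",        "acetoclastic_methanogen",
    "Syntrophaceae",       "syntroph",
    "Syntrophorhabdus",    "syntroph",
    "Syntrophomonas",      "syntroph",
    "Syntrophomonadaceae", "syntroph",
    "Smithella",           "syntroph",
    "Synergistaceae",      "syntroph"
  )
}

#' Assign functional guilds from taxonomy
#'
#' @param taxonomy A `taxonomy_table` (see [parse_taxonomy()]).
#' @param guild_table Lookup of taxon name to guild; defaults to
#'   [default_guild_table()].
#' @return Tibble `id`, `guild`; ids with no matching lineage entry get
#'   guild `"other"`. If several ranks match, the deepest matching rank
#'   wins.
#' @export
assign_guilds <- function(taxonomy, guild_table = default_guild_table()) {
  lookup <- stats::setNames(guild_table$guild, norm_taxon(guild_table$taxon))
  m <- as.matrix(taxonomy[tax_ranks()])
  guild <- apply(m, 1, function(r) {
    hits <- lookup[norm_taxon(r[!is.na(r)])]
    hits <- hits[!is.na(hits)]
    if (length(hits) == 0) "other" else unname(hits[length(hits)])
  })
  tibble::tibble(id = taxonomy$id, guild = unname(guild))
}
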