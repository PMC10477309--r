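#' Metagenome-assembled genome record
#'
#' Carries everything downstream stages need about one genome bin:
#' identity, GTDB-style taxonomy, CheckM-style quality metrics, rRNA gene
#' counts, SSU (16S) sequences, and a flat gene table.
#'
#' @param mag_id Identifier.
#' @param taxonomy Single-row `taxonomy_table` (see [parse_taxonomy()]) or
#'   lineage string.
#' @param completeness,contamination Percentages (0-100 and >= 0).
#' @param rrna_counts Named integer vector with elements `5S`, `16S`, `23S`.
#' @param ssu_sequences Character vector of 16S rRNA gene sequences.
#' @param genes Tibble with columns `gene_id`, `length` (bp, > 0),
#'   `annotation` (searchable labels: gene symbols / ortholog ids).
#' @return Object of class `mag_record`.
#' @export
mag_record <- function(mag_id, taxonomy, completeness, contamination,
                       rrna_counts = c(`5S` = 0L, `16S` = 0L, `23S` = 0L),
                       ssu_sequences = character(),
                       genes = tibble::tibble(gene_id = character(),
                                              length = integer(),
                                              annotation = character())) {
  if (is.character(taxonomy)) taxonomy <- parse_taxonomy(mag_id, taxonomy)
  stopifnot(completeness >= 0, completeness <= 100, contamination >= 0)
  if (!all(c("5S", "16S", "23S") %in% names(rrna_counts))) {
    stop("rrna_counts must name 5S, 16S and 23S", call. = FALSE)
  }
  genes <- tibble::as_tibble(genes)
  if (nrow(genes) > 0 && any(genes$length <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  structure(
    list(mag_id = mag_id, taxonomy = taxonomy,
         completeness = completeness, contamination = contamination,
         rrna_counts = rrna_counts[c("5S", "16S", "23S")],
         ssu_sequences = toupper(ssu_sequences), genes = genes,
         quality_tier = mag_quality_tier(completeness, contamination, rrna_counts)),
    class = "mag_record"
  )
}

#' @export
print.mag_record <- function(x, ...) {
  cat(sprintf("<mag_record> %s [%s] %.1f%% complete, %.1f%% contamination, %d genes\n",
              x$mag_id, x$quality_tier, x$completeness, x$contamination,
              nrow(x$genes)))
  invisible(x)
}

#' Tier a MAG by community quality standards
#'
#' High quality: >90% complete, <5% contamination, and at least one copy
#' of each rRNA subunit gene (5S, 16S, 23S). Medium quality: >50%
#' complete, <10% contamination, and at least one rRNA subunit gene of any
#' kind. Anything else fails.
#'
#' @param completeness,contamination Percentages.
#' @param rrna_counts Named integer vector (`5S`, `16S`, `23S`).
#' @return `"HQ"`, `"MQ"`, or `"fail"`.
#' @export
mag_quality_tier <- function(completeness, contamination, rrna_counts) {
  rrna <- rrna_counts[c("5S", "16S", "23S")]
  if (anyNA(rrna)) stop("rrna_counts must name 5S, 16S and 23S", call. = FALSE)
  if (completeness > 90 && contamination < 5 && all(rrna >= 1)) return("HQ")
  if (completeness > 50 && contamination < 10 && any(rrna >= 1)) return("MQ")
  "fail"
}
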