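#' Extract the 16S V4 region delimited by the 515F/806R primers
#'
#' Finds the forward primer site (IUPAC-degenerate matching: Y = C/T,
#' M = A/C, N = any, V = A/C/G, W = A/T) and the reverse primer site
#' (matched as its reverse complement) in a 16S gene sequence and returns
#' the region between the forward primer's 3' end and the reverse site.
#' No mismatches are tolerated in the primer sites. With multiple hits
#' the leftmost forward match and the nearest downstream reverse match
#' are used, with a warning.
#'
#' @param seq 16S nucleotide sequence (character).
#' @param fwd,rev Primer sequences (defaults: 515F / 806R).
#' @return The V4 subsequence (character).
#' @export
extract_v4 <- function(seq, fwd = "GTGYCAGCMGCCGCGGTAA",
                       rev = "GGACTACNVGGGTWTCTAAT") {
  seq <- toupper(seq)
  if (nchar(seq) < nchar(fwd) + nchar(rev)) {
    stop("sequence shorter than the primers", call. = FALSE)
  }
  subject <- Biostrings::DNAString(seq)
  fwd_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subject,
                                       fixed = "subject")
  if (length(fwd_hits) == 0) stop("forward primer site not found", call. = FALSE)
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  rev_hits <- Biostrings::matchPattern(rev_rc, subject, fixed = "subject")
  if (length(rev_hits) == 0) stop("reverse primer site not found", call. = FALSE)
  if (length(fwd_hits) > 1 || length(rev_hits) > 1) {
    warning("multiple primer sites; using leftmost forward and nearest downstream reverse")
  }
  f_end <- Biostrings::end(fwd_hits)[1]
  starts <- Biostrings::start(rev_hits)
  downstream <- starts[starts > f_end]
  if (length(downstream) == 0) {
    stop("no reverse primer site downstream of the forward site", call. = FALSE)
  }
  substr(seq, f_end + 1, min(downstream) - 1)
}

#' Pair ASVs with MAGs by 16S V4 homology
#'
#' Each MAG's 16S sequences are reduced to their V4 regions with
#' [extract_v4()] (sequences without recoverable primer sites are
#' skipped). Every ASV is compared end-to-end and ungapped against every
#' MAG V4 region; identity = matched positions / query (ASV) length,
#' minimized over ungapped offsets when the MAG region is longer. Per ASV
#' the best-identity MAG is kept (exact identity ties broken by MAG
#' quality score `completeness - 5 * contamination`, then lexicographic
#' mag_id, so input order never matters). A pair is accepted when
#' identity exceeds `min_identity` (e.g. 0 or 1 mismatch along a 273 bp
#' query at the default 0.995) and, if taxonomies are supplied, the
#' lineages are lowest-common-ancestor concordant.
#'
#' @param asv_seqs Named character vector of ASV sequences.
#' @param mags List of [mag_record()]s.
#' @param min_identity Acceptance threshold (exclusive; default 0.995).
#' @param asv_taxonomy Optional `taxonomy_table` for the ASVs; when given
#'   (and the MAG carries taxonomy) the LCA concordance flag is computed
#'   and required for acceptance.
#' @return Tibble `asv_id`, `mag_id`, `identity`, `mismatches`,
#'   `alignment_length`, `lca_concordant`, `accepted`. ASVs longer than
#'   every candidate MAG region are reported with `NA` identity and
#'   `accepted = FALSE`.
#' @export
pair_asv_mag <- function(asv_seqs, mags, min_identity = 0.995,
                         asv_taxonomy = NULL) {
  stopifnot(!is.null(names(asv_seqs)))
  regions <- purrr::map(mags, function(m) {
    v4 <- character()
    for (s in m$ssu_sequences) {
      v <- tryCatch(suppressWarnings(extract_v4(s)), error = function(e) NULL)
      if (!is.null(v) && nchar(v) > 0) v4 <- c(v4, v)
    }
    v4
  })
  mag_ids <- vapply(mags, `[[`, character(1), "mag_id")
  quality <- vapply(mags, function(m) m$completeness - 5 * m$contamination,
                    numeric(1))
  names(regions) <- names(quality) <- mag_ids
  rows <- purrr::imap(asv_seqs, function(query, asv_id) {
    best <- NULL
    for (mid in mag_ids) {
      for (region in regions[[mid]]) {
        mm <- ungapped_mismatches(query, region)
        if (is.na(mm)) next
        cand <- list(mag_id = mid, mismatches = mm,
                     identity = 1 - mm / nchar(query), quality = quality[[mid]])
        if (is.null(best) ||
            cand$identity > best$identity + 1e-12 ||
            (abs(cand$identity - best$identity) <= 1e-12 &&
             (cand$quality > best$quality ||
              (cand$quality == best$quality && cand$mag_id < best$mag_id)))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) {
      return(tibble::tibble(asv_id = asv_id, mag_id = NA_character_,
                            identity = NA_real_, mismatches = NA_integer_,
                            alignment_length = nchar(query),
                            lca_concordant = NA, accepted = FALSE))
    }
    conc <- NA
    if (!is.null(asv_taxonomy)) {
      atax <- asv_taxonomy[asv_taxonomy$id == asv_id, ]
      mtax <- mags[[match(best$mag_id, mag_ids)]]$taxonomy
      if (nrow(atax) == 1 && !is.null(mtax)) {
        conc <- lca_concordant(atax, mtax)
      }
    }
    tibble::tibble(asv_id = asv_id, mag_id = best$mag_id,
                   identity = best$identity,
                   mismatches = as.integer(best$mismatches),
                   alignment_length = nchar(query),
                   lca_concordant = conc,
                   accepted = best$identity > min_identity &&
                     (is.na(conc) || conc))
  })
  dplyr::bind_rows(rows)
}

# minimum Hamming distance of query against all ungapped placements inside
# region; NA when the query is longer than the region
ungapped_mismatches <- function(query, region) {
  lq <- nchar(query); lr <- nchar(region)
  if (lq > lr) return(NA_integer_)
  q <- utf8ToInt(toupper(query))
  r <- utf8ToInt(toupper(region))
  best <- lq
  for (off in 0:(lr - lq)) {
    mm <- sum(q != r[(off + 1):(off + lq)])
    if (mm < best) best <- mm
    if (best == 0) break
  }
  as.integer(best)
}

#' Default methanogenesis / syntrophy marker gene sets
#'
#' @return Named list of character vectors of gene symbols:
#'   hydrogenotrophic methanogenesis (`mcrABCDG`, `mtrABCDEFH`),
#'   acetoclastic methanogenesis (`ack`, `pta`), Wood-Ljungdahl methyl
#'   branch (`fdh`, `fhs`, `fol`, `met`), glycine cleavage system
#'   (`gcvH`, `gcvP`, `gcvT`).
#' @export
default_marker_sets <- function() {
  list(
    hydrogenotrophic_methanogenesis = c(paste0("mcr", c("A", "B", "C", "D", "G")),
                                        paste0("mtr", c("A", "B", "C", "D", "E", "F", "H"))),
    acetoclastic_methanogenesis = c("ack", "pta"),
    wood_ljungdahl_methyl_branch = c("fdh", "fhs", "fol", "met"),
    glycine_cleavage_system = c("gcvH", "gcvP", "gcvT")
  )
}

#' Pathway marker presence and expression in a MAG
#'
#' A marker is encoded when any gene annotation label in the MAG matches
#' it (whole-word, case-insensitive), and expressed when it is encoded
#' and the summed TPM of its matching genes is positive.
#'
#' @param mag A [mag_record()].
#' @param expr Optional [expression_table()] holding the MAG's genes;
#'   without it `expressed` is `NA`.
#' @param marker_sets Named list of marker label vectors (default
#'   [default_marker_sets()]).
#' @return Tibble `mag_id`, `set`, `marker`, `encoded`, `expressed`.
#' @export
pathway_markers <- function(mag, expr = NULL, marker_sets = default_marker_sets()) {
  if (length(marker_sets) == 0) stop("empty marker set list", call. = FALSE)
  ann <- mag$genes$annotation
  gene_tpm <- NULL
  if (!is.null(expr)) {
    gene_tpm <- rowSums(expr$tpm)[match(mag$genes$gene_id, rownames(expr$tpm))]
    gene_tpm[is.na(gene_tpm)] <- 0
  }
  rows <- purrr::imap(marker_sets, function(markers, set_name) {
    purrr::map(markers, function(mk) {
      hit <- grepl(paste0("\\b", mk, "\\b"), ann, ignore.case = TRUE)
      encoded <- any(hit)
      expressed <- if (is.null(gene_tpm)) NA else encoded && sum(gene_tpm[hit]) > 0
      tibble::tibble(mag_id = mag$mag_id, set = set_name, marker = mk,
                     encoded = encoded, expressed = expressed)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Metagenome vs metatranscriptome abundance correlation
#'
#' Correlates MAG-level TPM abundance between matched metagenome and
#' metatranscriptome libraries over all MAG-sample observations,
#' optionally excluding guilds whose transcription is decoupled from
#' genome abundance (methanogens, by default). Reports the correlation
#' with its t statistic and df = n - 2.
#'
#' @param mg_tpm,mt_tpm Tibbles (`mag_id`, `sample_id`, `tpm`), e.g. the
#'   `tpm` element of [aggregate_mag_expression()].
#' @param mag_guilds Optional tibble (`id`, `guild`) mapping MAGs to
#'   guilds; required for guild exclusion.
#' @param exclude_guilds Guild labels dropped before correlating.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble from [correlation_test()].
#' @export
mg_mt_correlation <- function(mg_tpm, mt_tpm, mag_guilds = NULL,
                              exclude_guilds = c("hydrogenotrophic_methanogen",
                                                 "acetoclastic_methanogen"),
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  joined <- dplyr::inner_join(mg_tpm, mt_tpm, by = c("mag_id", "sample_id"),
                              suffix = c("_mg", "_mt"))
  if (!is.null(mag_guilds)) {
    drop <- mag_guilds$id[mag_guilds$guild %in% exclude_guilds]
    joined <- joined[!joined$mag_id %in% drop, ]
  }
  n <- nrow(joined)
  if (n < 3) stop("fewer than 3 paired observations", call. = FALSE)
  r <- stats::cor(joined$tpm_mg, joined$tpm_mt, method = method)
  correlation_test(r, n)
}
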