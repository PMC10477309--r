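#' Gene expression table with TPM normalization
#'
#' Holds per-gene read counts across samples together with gene lengths
#' and the MAG each gene was binned to (`NA` = unbinned), and the derived
#' transcripts-per-million matrix. TPM for gene g in a sample is
#' `(c_g / l_g) / sum_h (c_h / l_h) * 1e6`, so each sample with any reads
#' sums to one million.
#'
#' @param genes Tibble with columns `gene_id`, `mag_id` (`NA` allowed),
#'   `length` (bp, > 0).
#' @param counts Non-negative matrix, genes x samples, rownames matching
#'   `gene_id`.
#' @return Object of class `expression_table` with elements `genes`,
#'   `counts`, `tpm`.
#' @export
expression_table <- function(genes, counts) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene_id", "mag_id", "length") %in% names(genes)))
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- genes$gene_id
  if (!identical(rownames(counts), as.character(genes$gene_id))) {
    counts <- counts[match(genes$gene_id, rownames(counts)), , drop = FALSE]
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(genes$length <= 0)) stop("gene lengths must be positive", call. = FALSE)
  tpm_mat <- apply(counts, 2, tpm, lengths = genes$length)
  dimnames(tpm_mat) <- dimnames(counts)
  structure(list(genes = genes, counts = counts, tpm = tpm_mat),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d samples (%d MAGs, %d unbinned genes)\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(stats::na.omit(x$genes$mag_id)),
              sum(is.na(x$genes$mag_id))))
  invisible(x)
}

#' Transcripts-per-million normalization
#'
#' @param counts Non-negative read counts per gene (one sample).
#' @param lengths Gene lengths in bp (> 0).
#' @return TPM vector summing to 1e6 (all-zero input returns all zeros,
#'   with a warning).
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- counts / lengths
  total <- sum(rate)
  if (total == 0) {
    warning("all counts zero; TPM undefined, returning zeros")
    return(rep(0, length(counts)))
  }
  rate / total * 1e6
}

#' Sum gene TPM to the MAG level
#'
#' @param expr An [expression_table()].
#' @param mags Optional list of [mag_record()]s; if given, every non-`NA`
#'   `mag_id` in `expr` must be among them.
#' @return List with `tpm`: tibble (`mag_id`, `sample_id`, `tpm`) of
#'   per-MAG summed TPM, and `unbinned_fraction`: tibble (`sample_id`,
#'   `fraction`) of TPM attributed to unbinned genes.
#' @export
aggregate_mag_expression <- function(expr, mags = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  if (!is.null(mags)) {
    known <- vapply(mags, function(m) m$mag_id, character(1))
    unknown <- setdiff(stats::na.omit(unique(expr$genes$mag_id)), known)
    if (length(unknown) > 0) {
      stop("genes mapped to unknown MAG(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  long <- tibble::as_tibble(expr$tpm, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "tpm") |>
    dplyr::left_join(expr$genes[, c("gene_id", "mag_id")], by = "gene_id")
  binned <- long |>
    dplyr::filter(!is.na(.data$mag_id)) |>
    dplyr::group_by(.data$mag_id, .data$sample_id) |>
    dplyr::summarise(tpm = sum(.data$tpm), .groups = "drop")
  unbinned <- long |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(fraction = sum(.data$tpm[is.na(.data$mag_id)]) / 1e6,
                     .groups = "drop")
  list(tpm = binned, unbinned_fraction = unbinned)
}
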