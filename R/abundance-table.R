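#' ASV abundance table
#'
#' The backbone object of the package: a taxa-by-sample matrix of amplicon
#' sequence variant (ASV) read counts together with per-sample metadata
#' (calendar date and process-configuration label, e.g. SOI / CEPT / SOII /
#' SER for the four digester operating modes).
#'
#' @param counts Non-negative integer matrix, ASVs in rows, samples in
#'   columns. Row and column names are the ASV and sample identifiers.
#' @param sample_dates `Date` vector (or ISO-8601 strings), one per sample.
#' @param configuration Character vector of configuration labels, one per
#'   sample.
#'
#' @return An object of class `abundance_table`: a list with elements
#'   `counts` (integer matrix) and `samples` (tibble with columns
#'   `sample_id`, `date`, `configuration`).
#' @export
abundance_table <- function(counts, sample_dates, configuration) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry ASV row names and sample column names", call. = FALSE)
  }
  sample_dates <- as.Date(sample_dates)
  configuration <- as.character(configuration)
  if (length(sample_dates) != ncol(counts) || length(configuration) != ncol(counts)) {
    stop("`sample_dates` and `configuration` must have one entry per sample",
         call. = FALSE)
  }
  x <- structure(
    list(
      counts = counts,
      samples = tibble::tibble(
        sample_id = colnames(counts),
        date = sample_dates,
        configuration = configuration
      )
    ),
    class = "abundance_table"
  )
  validate_abundance_table(x)
}

validate_abundance_table <- function(x) {
  counts <- x$counts
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate ASV ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or non-numeric count at ASV '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(x$counts) <- "integer"
  if (anyNA(x$samples$date)) stop("every sample needs a date", call. = FALSE)
  if (anyNA(x$samples$configuration)) {
    stop("every sample needs a configuration label", call. = FALSE)
  }
  x
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d ASVs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  configurations:",
      paste(sprintf("%s (%d)", names(table(x$samples$configuration)),
                    table(x$samples$configuration)), collapse = ", "), "\n")
  cat("  dates:", format(min(x$samples$date)), "to", format(max(x$samples$date)), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Tidy an abundance table into long form
#'
#' @param x An [abundance_table()].
#' @param ... Unused.
#' @return Tibble with columns `asv_id`, `sample_id`, `date`,
#'   `configuration`, `count`.
#' @export
tidy.abundance_table <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "asv_id") |>
    tidyr::pivot_longer(-"asv_id", names_to = "sample_id", values_to = "count") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' Read an ASV count table and its sample metadata
#'
#' Both files are tab-separated UTF-8 text; lines starting with `#` are
#' ignored. The count table has ASV ids in the first column and one column
#' per sample; the metadata file has columns `sample_id`, `date`
#' (ISO-8601), and `configuration`. Metadata row order need not match the
#' count table: samples are aligned by id.
#'
#' @param path Count table path.
#' @param metadata_path Sample metadata path.
#' @return An [abundance_table()]. Input ASV and sample order is preserved.
#' @export
read_abundance_table <- function(path, metadata_path) {
  tab <- read_tsv_strict(path)
  meta <- read_tsv_strict(metadata_path)
  need <- c("sample_id", "date", "configuration")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  asv_ids <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    counts <- apply(tab[, -1, drop = FALSE], 2, function(v) suppressWarnings(as.numeric(v)))
  }
  rownames(counts) <- asv_ids
  extra <- setdiff(meta$sample_id, colnames(counts))
  if (length(extra) > 0) {
    stop("metadata names unknown sample(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing) > 0) {
    stop("no metadata for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  abundance_table(counts, meta$date, meta$configuration)
}

#' Write an abundance table and metadata to TSV
#'
#' @param x An [abundance_table()].
#' @param path Count table destination.
#' @param metadata_path Metadata destination.
#' @return `x`, invisibly.
#' @export
write_abundance_table <- function(x, path, metadata_path) {
  df <- data.frame(asv_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = x$samples$sample_id,
                     date = format(x$samples$date),
                     configuration = x$samples$configuration)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

# strict TSV reader shared by all table readers: tab-separated, '#' comments,
# header row, first column is the id column
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "")
  tibble::as_tibble(df)
}
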