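#' Read a nucleotide FASTA file
#'
#' IUPAC degeneracy codes are permitted; sequences are upper-cased.
#' Duplicate ids and empty sequences are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Destination.
#' @return `seqs`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(seqs)
}
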