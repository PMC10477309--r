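#' Physicochemical parameter series
#'
#' A long table of dated measurements for the process parameters recorded at
#' the treatment plant (organic loading rate, volatile fatty acids, ammonia,
#' nitrate, biogas volume and composition, ...). Missing measurements are
#' allowed; dates must be strictly increasing within each parameter.
#'
#' @param data Data frame with columns `date`, `parameter`, `value`
#'   (`value` may contain `NA`).
#' @return A tibble of class `parameter_series`.
#' @export
parameter_series <- function(data) {
  need <- c("date", "parameter", "value")
  if (!all(need %in% names(data))) {
    stop("parameter series needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$date <- as.Date(out$date)
  out$value <- as.numeric(out$value)
  out <- dplyr::arrange(out, .data$parameter, .data$date)
  dup <- out |>
    dplyr::count(.data$parameter, .data$date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate measurement dates for parameter(s): ",
         paste(unique(dup$parameter), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("parameter_series", class(out))
  out
}

#' Read a dated physicochemical parameter table
#'
#' Wide TSV: first column `date` (ISO-8601), one column per parameter.
#' Empty fields or `NA` encode missing measurements.
#'
#' @param path File path.
#' @return A [parameter_series()] tibble in long form.
#' @export
read_parameter_series <- function(path) {
  tab <- read_tsv_strict(path)
  if (names(tab)[1] != "date") {
    stop("first column of a parameter table must be 'date'", call. = FALSE)
  }
  long <- tidyr::pivot_longer(tab, -"date", names_to = "parameter",
                              values_to = "value")
  parameter_series(long)
}

#' Write a parameter series as a wide TSV
#'
#' @param x A [parameter_series()].
#' @param path Destination.
#' @return `x`, invisibly.
#' @export
write_parameter_series <- function(x, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x), names_from = "parameter",
                             values_from = "value")
  wide <- dplyr::arrange(wide, .data$date)
  wide$date <- format(wide$date)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(x)
}
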