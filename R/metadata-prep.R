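#' Interpolate physicochemical series to biological sampling dates
#'
#' Process parameters are not measured on every biological sampling date,
#' so each parameter is interpolated with a natural cubic spline through
#' its measured points. The interpolant passes exactly through every
#' measurement; queries outside the measured date range are refused
#' (no extrapolation). Interpolated values whose magnitude exceeds 1.5x
#' the measured range of the parameter are flagged `out_of_range` for
#' review.
#'
#' @param series A [parameter_series()].
#' @param query_dates Dates (or ISO strings) at which values are needed.
#' @return Tibble of class `interp_series` with columns `parameter`,
#'   `date`, `value`, `flag` (`"measured"` or `"interpolated"`), and
#'   `out_of_range` (logical).
#' @export
interpolate_parameters <- function(series, query_dates) {
  query_dates <- as.Date(query_dates)
  origin <- min(series$date, na.rm = TRUE)
  out <- tibble::as_tibble(series) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(df, key) {
      df <- df[!is.na(df$value), ]
      if (nrow(df) < 2) {
        stop("parameter '", key$parameter,
             "' has fewer than 2 measured values", call. = FALSE)
      }
      x <- as.numeric(df$date - origin)
      lo <- min(df$date); hi <- max(df$date)
      outside <- query_dates < lo | query_dates > hi
      if (any(outside)) {
        stop(sprintf("query date(s) %s outside measured range [%s, %s] for parameter '%s'",
                     paste(format(query_dates[outside]), collapse = ", "),
                     format(lo), format(hi), key$parameter), call. = FALSE)
      }
      f <- stats::splinefun(x, df$value, method = "natural")
      qx <- as.numeric(query_dates - origin)
      measured_at <- match(qx, x)
      value <- ifelse(!is.na(measured_at), df$value[measured_at], f(qx))
      rng <- range(df$value)
      half <- diff(rng) / 2
      centre <- mean(rng)
      oor <- is.na(measured_at) & abs(value - centre) > 1.5 * max(half, .Machine$double.eps)
      tibble::tibble(
        date = query_dates,
        value = value,
        flag = ifelse(is.na(measured_at), "interpolated", "measured"),
        out_of_range = oor
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("interp_series", class(out))
  out
}

#' Plot interpolated parameter series
#'
#' @param object An `interp_series` from [interpolate_parameters()].
#' @param ... Unused.
#' @return A ggplot object (line per parameter, measured points marked).
#' @export
autoplot.interp_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag, shape = .data$out_of_range)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL, shape = "outside range")
}

#' Correlate individual ASV abundances with physicochemical parameters
#'
#' Computes the correlation between each ASV's relative-abundance trace
#' and each interpolated parameter over samples matched by date. ASVs or
#' parameters that are constant over the matched dates yield `NA`
#' (flagged, not silently zeroed).
#'
#' @param table An [abundance_table()]; abundances are converted to
#'   relative abundances internally.
#' @param params An `interp_series` (see [interpolate_parameters()]).
#' @param method `"pearson"` (default, the convention for this analysis)
#'   or `"spearman"`.
#' @return Tibble `asv_id`, `parameter`, `r` (`NA` where undefined).
#' @export
asv_parameter_correlation <- function(table, params,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rel <- relative_abundance(table)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(params)[, c("parameter", "date", "value")],
    names_from = "parameter", values_from = "value")
  keep <- match(wide$date, table$samples$date)
  if (all(is.na(keep))) stop("no overlapping dates between table and parameters",
                             call. = FALSE)
  wide <- wide[!is.na(keep), , drop = FALSE]
  rel <- rel[, keep[!is.na(keep)], drop = FALSE]
  pm <- as.matrix(wide[, setdiff(names(wide), "date"), drop = FALSE])
  r <- suppressWarnings(stats::cor(t(rel), pm, method = method))
  tibble::as_tibble(r, rownames = "asv_id") |>
    tidyr::pivot_longer(-"asv_id", names_to = "parameter", values_to = "r")
}

#' Best environmental-variable subset by maximum rank correlation
#'
#' Exhaustively evaluates every non-empty subset of parameters up to
#' `max_size`: parameters are standardized (zero mean, unit sd), Euclidean
#' distances among samples are computed on each subset, and the Spearman
#' rank correlation between those distances and the community distances
#' (corresponding off-diagonal entries) is recorded. The subset attaining
#' the maximum correlation is returned together with the full ranking.
#'
#' @param community_dist A `dist` or square symmetric matrix of community
#'   dissimilarities.
#' @param params Numeric data frame / matrix, samples x parameters, sample
#'   order matching `community_dist`.
#' @param max_size Largest subset size to consider (default: all
#'   parameters). Refuses searches of more than 2^20 subsets.
#' @return List of class `bioenv_result`: `best` (one-row tibble),
#'   `ranking` (tibble of all evaluated subsets, best first, columns
#'   `subset`, `size`, `rho`).
#' @export
bioenv_best_subset <- function(community_dist, params, max_size = ncol(params)) {
  d <- as.matrix(community_dist)
  stopifnot(isSymmetric(unname(d)))
  params <- as.matrix(params)
  if (max_size > ncol(params)) {
    stop("max_size exceeds the number of parameters", call. = FALSE)
  }
  n_subsets <- sum(choose(ncol(params), seq_len(max_size)))
  if (n_subsets > 2^20) {
    stop("refusing to enumerate ", n_subsets, " subsets (> 2^20)", call. = FALSE)
  }
  z <- scale(params)
  cd <- d[lower.tri(d)]
  degenerate <- stats::sd(cd) == 0
  if (degenerate) {
    warning("community distances are constant; rank correlation undefined for every subset")
  }
  vars <- colnames(params)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(params)))
  rows <- list()
  for (size in seq_len(max_size)) {
    combos <- utils::combn(seq_len(ncol(params)), size, simplify = FALSE)
    for (cb in combos) {
      ed <- stats::dist(z[, cb, drop = FALSE])
      rho <- if (degenerate) NA_real_ else
        suppressWarnings(stats::cor(cd, as.vector(ed), method = "spearman"))
      rows[[length(rows) + 1]] <- tibble::tibble(
        subset = paste(vars[cb], collapse = "+"),
        size = size, rho = rho)
    }
  }
  ranking <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$rho))
  structure(list(best = ranking[1, ], ranking = ranking),
            class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat(sprintf("<bioenv_result> best subset: %s (rho = %.4f, rho^2 = %.4f)\n",
              x$best$subset, x$best$rho, x$best$rho^2))
  cat(sprintf("  %d subsets evaluated\n", nrow(x$ranking)))
  invisible(x)
}

#' @rdname bioenv_best_subset
#' @param x A `bioenv_result`.
#' @param ... Unused.
#' @export
tidy.bioenv_result <- function(x, ...) x$ranking

#' @rdname bioenv_best_subset
#' @export
glance.bioenv_result <- function(x, ...) {
  tibble::tibble(best_subset = x$best$subset, rho = x$best$rho,
                 rho_squared = x$best$rho^2, n_subsets = nrow(x$ranking))
}
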