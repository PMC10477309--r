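#' Group-equalized indicator value components
#'
#' For every ASV and group computes the IndVal.g components: specificity
#' `A_gk = (mean abundance in group k) / (sum over groups of mean
#' abundance)` and fidelity `B_gk = fraction of group-k samples where the
#' ASV is present`, with `stat = sqrt(A * B)`. Group means equalize group
#' sizes, so unbalanced designs do not bias A. Abundances are converted
#' to relative abundances first, making the statistic invariant to
#' per-sample sequencing depth.
#'
#' @param table An [abundance_table()].
#' @param groups Group label per sample; defaults to the table's
#'   configuration labels.
#' @return Tibble `asv_id`, `group`, `A`, `B`, `stat`. ASVs absent from
#'   every sample are excluded (with a warning): their statistic is
#'   undefined.
#' @export
indval <- function(table, groups = NULL) {
  if (is.null(groups)) groups <- table$samples$configuration
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(table$counts))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  rel <- relative_abundance(table)
  absent <- rowSums(rel) == 0
  if (any(absent)) {
    warning(sum(absent), " ASV(s) absent everywhere excluded (undefined statistic)")
    rel <- rel[!absent, , drop = FALSE]
  }
  comp <- indval_components(rel, groups)
  tibble::tibble(
    asv_id = rep(rownames(rel), times = nlevels(groups)),
    group = rep(levels(groups), each = nrow(rel)),
    A = as.vector(comp$A), B = as.vector(comp$B), stat = as.vector(comp$stat))
}

# A, B, stat matrices (taxa x groups) from a relative-abundance matrix
indval_components <- function(rel, groups) {
  gm <- stats::model.matrix(~ groups - 1)
  gm <- sweep(gm, 2, colSums(gm), "/")       # columns average within group
  mean_k <- rel %*% gm                        # taxa x groups group means
  A <- mean_k / rowSums(mean_k)
  B <- (rel > 0) %*% gm
  list(A = A, B = B, stat = sqrt(A * B))
}

#' Permutation-tested indicator species analysis
#'
#' Each ASV's indicator statistic is its best (maximum over groups)
#' IndVal.g value; the null distribution is generated by permuting the
#' sample-to-group labels (group sizes preserved), and
#' `p = (1 + #[permuted stat >= observed]) / (1 + n_perm)`. P-values are
#' BH-adjusted across ASVs; the significant set is `q < alpha`.
#'
#' @param table An [abundance_table()].
#' @param groups Group label per sample; defaults to the table's
#'   configuration labels.
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed.
#' @param alpha FDR level for the significant set.
#' @return Tibble of class `indicator_result`: `asv_id`, `group` (best
#'   group), `A`, `B`, `stat`, `p`, `q`, `significant`, plus attributes
#'   `n_perm` and `seed`.
#' @export
indicator_test <- function(table, groups = NULL, n_perm = 999, seed = 1L,
                           alpha = 0.05) {
  stopifnot(n_perm >= 99)
  if (is.null(groups)) groups <- table$samples$configuration
  groups <- as.factor(groups)
  rel <- relative_abundance(table)
  absent <- rowSums(rel) == 0
  if (any(absent)) {
    warning(sum(absent), " ASV(s) absent everywhere excluded (undefined statistic)")
    rel <- rel[!absent, , drop = FALSE]
  }
  comp <- indval_components(rel, groups)
  best <- max.col(comp$stat, ties.method = "first")
  obs <- comp$stat[cbind(seq_len(nrow(rel)), best)]
  set.seed(seed)
  exceed <- integer(nrow(rel))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(ncol(rel))
    stat_p <- indval_components(rel[, perm, drop = FALSE], groups)$stat
    exceed <- exceed + (apply(stat_p, 1, max) >= obs - 1e-12)
  }
  p <- unname((1 + exceed) / (1 + n_perm))
  out <- tibble::tibble(
    asv_id = rownames(rel),
    group = levels(groups)[best],
    A = comp$A[cbind(seq_len(nrow(rel)), best)],
    B = comp$B[cbind(seq_len(nrow(rel)), best)],
    stat = obs, p = p, q = bh_adjust(p))
  out$significant <- out$q < alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("indicator_result", class(out))
  out
}

#' @rdname indicator_test
#' @param x An `indicator_result`.
#' @param ... Unused.
#' @return `glance()`: one-row summary (ASVs tested, significant count,
#'   permutations).
#' @export
glance.indicator_result <- function(x, ...) {
  tibble::tibble(n_asvs = nrow(x), n_significant = sum(x$significant),
                 n_perm = attr(x, "n_perm"), seed = attr(x, "seed"))
}

#' Indicator statistic overview plot
#'
#' @param object An `indicator_result`.
#' @param ... Unused.
#' @return A ggplot object (stat vs q, faceted by best group).
#' @export
autoplot.indicator_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$stat, y = -log10(.data$q),
                                       colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "indicator statistic", y = expression(-log[10](q)))
}
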