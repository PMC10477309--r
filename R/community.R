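#' Remove ASVs with low mean abundance
#'
#' Drops ASVs with fewer than `min_mean` observations on average across
#' all samples (the standard pre-filter for denoised amplicon tables).
#'
#' @param table An [abundance_table()].
#' @param min_mean Mean-count threshold; ASVs with mean count `>= min_mean`
#'   are retained.
#' @return A filtered [abundance_table()] (sample axis unchanged).
#' @export
filter_low_abundance <- function(table, min_mean = 1.0) {
  keep <- rowMeans(table$counts) >= min_mean
  if (!any(keep)) stop("all ASVs removed by the mean-abundance filter", call. = FALSE)
  abundance_table(table$counts[keep, , drop = FALSE],
                  table$samples$date, table$samples$configuration)
}

#' Per-sample relative abundances
#'
#' @param table An [abundance_table()] or non-negative matrix (taxa x
#'   samples).
#' @return Matrix whose columns sum to 1.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  cs <- colSums(counts)
  if (any(cs == 0)) {
    stop("empty sample(s): ", paste(colnames(counts)[cs == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2, cs, "/")
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa; 0 for
#' identical samples, 1 for disjoint supports. A pair whose combined
#' abundance is all zero has no defined dissimilarity and is flagged `NA`.
#'
#' @param x An [abundance_table()] or a non-negative matrix with taxa in
#'   rows and samples in columns.
#' @return Symmetric matrix of class `dist_matrix` with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative values", call. = FALSE)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- sum(m[, i] + m[, j])
      d[i, j] <- d[j, i] <- if (tot == 0) NA_real_ else sum(abs(m[, i] - m[, j])) / tot
    }
  }
  if (anyNA(d)) warning("sample pair(s) with all-zero combined abundance flagged NA")
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Hierarchical clustering of a distance matrix
#'
#' @param d Square symmetric dissimilarity matrix (e.g. [bray_curtis()]).
#' @param linkage `"complete"` (default), `"average"`, or `"ward"`
#'   (ward.D2).
#' @return An `hclust` object (n-1 merges with heights).
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(d)
  if (nrow(m) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(stats::as.dist(m), method = method)
}

#' Export a dendrogram as a Newick tree
#'
#' @param hc An `hclust` (see [hierarchical_cluster()]).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers the squared dissimilarities and eigendecomposes;
#' coordinates are returned for all axes with positive eigenvalues,
#' ordered by eigenvalue. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported, not dropped; the
#' variance fraction of an axis is its eigenvalue over the sum of positive
#' eigenvalues.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param groups Optional grouping labels carried into the scores tibble
#'   (used by `autoplot`).
#' @return List of class `pcoa_result`: `scores` (tibble: `sample_id`,
#'   `Axis1`..., optional `group`), `eigenvalues` (all, ordered),
#'   `variance_fraction` (per positive axis).
#' @export
pcoa <- function(d, groups = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  # k = n-1 axes requested; cmdscale warns when fewer are positive, which
  # is expected for non-Euclidean dissimilarities
  cmd <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- cmd$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- cmd$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  scores <- tibble::as_tibble(coords)
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m) %||% as.character(seq_len(n))), scores)
  if (!is.null(groups)) scores$group <- groups
  structure(
    list(scores = scores,
         eigenvalues = eig,
         variance_fraction = eig[pos] / sum(eig[pos])),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("<pcoa_result> %d samples, %d positive axes (Axis1 %.1f%%, Axis2 %.1f%%)\n",
              nrow(x$scores), length(vf), 100 * vf[1],
              if (length(vf) > 1) 100 * vf[2] else NA))
  if (any(x$eigenvalues < 0)) {
    cat(sprintf("  %d negative eigenvalues (min %.4g)\n",
                sum(x$eigenvalues < 0), min(x$eigenvalues)))
  }
  invisible(x)
}

#' @rdname pcoa
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @export
tidy.pcoa_result <- function(x, ...) x$scores

#' Ordination plot of the first two principal coordinates
#'
#' @param object A `pcoa_result` from [pcoa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_result <- function(object, ...) {
  vf <- object$variance_fraction
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("Axis 2 (%.1f%%)", 100 * vf[2]))
  if ("group" %in% names(object$scores)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
      ggplot2::stat_ellipse(ggplot2::aes(colour = .data$group), level = 0.95)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities (Gower-centered
#' form: `SS = sum of squared distances / n` within each stratum) into
#' among- and within-group components, forms the pseudo-F statistic, and
#' obtains its p-value by freely permuting sample labels:
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param groups Group label per sample (at least two groups).
#' @param n_perm Number of label permutations (ignored when
#'   `exact = TRUE`).
#' @param seed RNG seed for the permutations.
#' @param exact Enumerate all distinct label arrangements instead of
#'   sampling (feasible only for small n; includes the observed
#'   arrangement).
#' @return One-row tibble of class `permanova_result`: `pseudo_f`, `r2`,
#'   `p_value`, `n_perm`, `seed`, `df_among`, `df_within`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L, exact = FALSE) {
  m <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(m)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == n)) stop("a group equals the whole sample set", call. = FALSE)
  a <- nlevels(groups)
  stat <- function(g) {
    ss_t <- sum(m[lower.tri(m)]^2) / n
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- m[idx, idx]
        ss_w <- ss_w + sum(sub[lower.tri(sub)]^2) / length(idx)
      }
    }
    ss_a <- ss_t - ss_w
    c(f = (ss_a / (a - 1)) / (ss_w / (n - a)), r2 = ss_a / ss_t)
  }
  obs <- stat(groups)
  if (exact) {
    perms <- all_label_arrangements(groups)
    f_perm <- vapply(perms, function(g) stat(g)[["f"]], numeric(1))
    p <- mean(f_perm >= obs[["f"]] - 1e-12)
    n_used <- length(perms)
  } else {
    stopifnot(n_perm >= 1)
    set.seed(seed)
    f_perm <- replicate(n_perm, stat(factor(sample(groups), levels = levels(groups)))[["f"]])
    p <- (1 + sum(f_perm >= obs[["f"]] - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  out <- tibble::tibble(pseudo_f = obs[["f"]], r2 = obs[["r2"]], p_value = p,
                        n_perm = n_used, seed = if (exact) NA_integer_ else seed,
                        df_among = a - 1L, df_within = n - a)
  class(out) <- c("permanova_result", class(out))
  out
}

# all distinct assignments of the multiset of group labels to positions
all_label_arrangements <- function(groups) {
  n <- length(groups)
  perms <- unique_permutations(as.integer(groups))
  lapply(perms, function(p) factor(levels(groups)[p], levels = levels(groups)))
}

unique_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    for (p in unique_permutations(rest)) out[[length(out) + 1]] <- c(u, p)
  }
  out
}

#' @rdname permanova
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @export
glance.permanova_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' Core microbiome screen
#'
#' An ASV is core when present (count > 0) in at least
#' `ceiling(prevalence_threshold * n_samples)` samples.
#'
#' @param table An [abundance_table()].
#' @param prevalence_threshold Fraction of samples required (default 0.80).
#' @return List of class `core_set`: `core_ids`, `threshold`,
#'   `read_fraction` (share of total reads carried by core ASVs),
#'   `prevalence` (tibble per ASV).
#' @export
core_microbiome <- function(table, prevalence_threshold = 0.80) {
  n <- ncol(table$counts)
  needed <- ceiling(prevalence_threshold * n)
  present <- rowSums(table$counts > 0)
  core <- names(present)[present >= needed]
  structure(
    list(core_ids = core,
         threshold = prevalence_threshold,
         read_fraction = sum(table$counts[core, , drop = FALSE]) / sum(table$counts),
         prevalence = tibble::tibble(asv_id = rownames(table$counts),
                                     n_present = unname(present),
                                     prevalence = unname(present) / n,
                                     core = rownames(table$counts) %in% core)),
    class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %d core ASVs at >= %.0f%% prevalence; %.1f%% of reads\n",
              length(x$core_ids), 100 * x$threshold, 100 * x$read_fraction))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
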