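#' Biweight midcorrelation
#'
#' Robust correlation using Tukey biweights: with `u_i = (x_i - med x) /
#' (9 MAD_x)` (MAD unscaled) and weights `w_i = (1 - u_i^2)^2 [|u_i| < 1]`,
#' each vector is transformed to `x~_i = (x_i - med x) w_i`, normalized,
#' and the correlation is the inner product of the two normalized
#' transforms. Observations beyond 9 MADs from the median get zero weight,
#' so single outliers cannot dominate. When a vector's MAD is zero the
#' biweight is undefined and that vector falls back to Pearson
#' standardization (the standard degenerate rule), with a warning.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  tx <- bicor_transform(x)
  ty <- bicor_transform(y)
  sum(tx * ty)
}

bicor_transform <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {
    warning("MAD is zero; falling back to Pearson standardization")
    ctr <- x - mean(x)
  } else {
    u <- (x - med) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    ctr <- (x - med) * w
  }
  nrm <- sqrt(sum(ctr^2))
  if (nrm == 0) stop("vector is constant after biweighting", call. = FALSE)
  ctr / nrm
}

#' All-pairs biweight midcorrelation
#'
#' @param mat Numeric matrix, observations in rows, variables in columns
#'   (same orientation as [stats::cor()]).
#' @return Symmetric correlation matrix.
#' @export
bicor_matrix <- function(mat) {
  mat <- as.matrix(mat)
  tx <- apply(mat, 2, bicor_transform)
  r <- crossprod(tx)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Correlation t-test
#'
#' Two-sided test of a correlation against zero using the Student-t
#' approximation `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `df = n - 2`.
#'
#' @param r Correlation value(s).
#' @param n Number of paired observations (>= 3).
#' @return Tibble `r`, `n`, `t`, `df`, `p`, `exact` (`TRUE` where
#'   `|r| = 1` and p is exactly 0 rather than from the t distribution).
#' @export
correlation_test <- function(r, n) {
  stopifnot(all(n >= 3), all(abs(r) <= 1 + 1e-12))
  r <- pmin(1, pmax(-1, r))
  df <- n - 2
  exact <- abs(r) >= 1
  t <- ifelse(exact, Inf * sign(r), r * sqrt(df) / sqrt(1 - r^2))
  p <- ifelse(exact, 0, 2 * stats::pt(-abs(t), df))
  tibble::tibble(r = r, n = n, t = t, df = df, p = p, exact = exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; monotone in rank, capped at 1.
#'
#' @param pvalues P-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Centered log-ratio transform
#'
#' Per sample (column): `log((x + pc) / g)` where `g` is the geometric
#' mean of `x + pc`. Columns sum to zero; multiplying a sample's counts by
#' a constant leaves its CLR unchanged.
#'
#' @param counts Non-negative matrix, taxa x samples.
#' @param pseudocount Added to every count before the log (default 1).
#' @return Transformed matrix of the same shape.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  m <- as.matrix(counts) + pseudocount
  if (any(m <= 0)) stop("counts must be non-negative", call. = FALSE)
  lg <- log(m)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Network inference configuration
#'
#' @param prevalence_threshold Minimum fraction of samples an ASV must be
#'   observed in to become a node (default 0.25).
#' @param edge_method `"bicor_fdr"` (default: robust correlation edges
#'   kept at FDR `alpha`) or `"clr_glasso"` (sparse inverse covariance on
#'   CLR abundances with stability-based penalty selection).
#' @param fdr_alpha FDR level for `bicor_fdr` edges (default 0.05).
#' @param positive_edges_only Keep only positive associations (default
#'   `TRUE`, the convention for this network type).
#' @param pseudocount CLR pseudocount for `clr_glasso`.
#' @param lambda_min_ratio Smallest penalty as a fraction of the maximal
#'   one (default 0.1).
#' @param n_lambda Penalty path length (default 20).
#' @param stars_threshold Edge-instability threshold for penalty selection
#'   (default 0.05).
#' @param stars_subsamples Number of subsamples (default 20).
#' @param stars_subsample_size Size of each subsample; default
#'   `min(n, floor(10 * sqrt(n)))`.
#' @param seed RNG seed for subsampling.
#' @return List of class `network_config`.
#' @export
network_config <- function(prevalence_threshold = 0.25,
                           edge_method = c("bicor_fdr", "clr_glasso"),
                           fdr_alpha = 0.05,
                           positive_edges_only = TRUE,
                           pseudocount = 1,
                           lambda_min_ratio = 0.1,
                           n_lambda = 20,
                           stars_threshold = 0.05,
                           stars_subsamples = 20,
                           stars_subsample_size = NULL,
                           seed = 1L) {
  edge_method <- match.arg(edge_method)
  stopifnot(prevalence_threshold > 0, prevalence_threshold <= 1,
            fdr_alpha > 0, fdr_alpha <= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(prevalence_threshold = prevalence_threshold,
                 edge_method = edge_method, fdr_alpha = fdr_alpha,
                 positive_edges_only = positive_edges_only,
                 pseudocount = pseudocount,
                 lambda_min_ratio = lambda_min_ratio, n_lambda = n_lambda,
                 stars_threshold = stars_threshold,
                 stars_subsamples = stars_subsamples,
                 stars_subsample_size = stars_subsample_size,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build the time-resolved co-occurrence network
#'
#' Nodes are ASVs observed in at least `prevalence_threshold` of samples,
#' sized by mean relative abundance. With the default `bicor_fdr` method
#' every node pair is scored by biweight midcorrelation on relative
#' abundances, p-values come from the correlation t-test, and edges are
#' the pairs with BH-adjusted `q < fdr_alpha` (positive correlations only
#' by default), weighted by the correlation. With `clr_glasso` the CLR
#' counts go through sparse inverse-covariance estimation
#' (see [sparse_precision_network()]).
#'
#' @param table An [abundance_table()] (>= 4 samples).
#' @param cfg A [network_config()].
#' @param taxonomy Optional `taxonomy_table` used to set node guild labels
#'   via [assign_guilds()].
#' @return A [cooc_network()]; the full per-pair statistics table is
#'   attached as attribute `"edge_stats"` (bicor path only).
#' @export
build_network <- function(table, cfg = network_config(), taxonomy = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (ncol(table$counts) < 4) stop("need at least 4 samples", call. = FALSE)
  prev <- rowMeans(table$counts > 0)
  eligible <- names(prev)[prev >= cfg$prevalence_threshold]
  if (length(eligible) < 2) stop("fewer than 2 eligible nodes", call. = FALSE)
  rel <- relative_abundance(table)
  mean_rel <- rowMeans(rel)[eligible]
  nodes <- tibble::tibble(asv_id = eligible, mean_rel_abund = unname(mean_rel))

  if (cfg$edge_method == "bicor_fdr") {
    r <- bicor_matrix(t(rel[eligible, , drop = FALSE]))
    idx <- which(upper.tri(r), arr.ind = TRUE)
    stats_tab <- correlation_test(r[upper.tri(r)], ncol(rel))
    stats_tab <- dplyr::mutate(stats_tab,
                               from = eligible[idx[, 1]],
                               to = eligible[idx[, 2]],
                               q = bh_adjust(.data$p),
                               .before = 1)
    keep <- stats_tab$q < cfg$fdr_alpha
    if (cfg$positive_edges_only) keep <- keep & stats_tab$r > 0
    edges <- dplyr::transmute(stats_tab[keep, ],
                              from = .data$from, to = .data$to,
                              weight = .data$r, p = .data$p, q = .data$q)
    net <- cooc_network(nodes, edges, positive_only = cfg$positive_edges_only)
    attr(net, "edge_stats") <- stats_tab
  } else {
    clr <- clr_transform(table$counts[eligible, , drop = FALSE], cfg$pseudocount)
    net <- sparse_precision_network(clr, cfg, node_info = nodes)
  }
  if (!is.null(taxonomy)) net <- set_node_guilds(net, taxonomy)
  net
}

#' Average clustering coefficient
#'
#' Mean over nodes of the local coefficient `2 T_i / (k_i (k_i - 1))`
#' (`T_i` = triangles through node i, `k_i` = degree). Nodes with degree
#' < 2 contribute 0 by default (set `exclude_low_degree = TRUE` for the
#' alternative convention that drops them from the mean).
#'
#' @param net A [cooc_network()] or igraph object.
#' @param exclude_low_degree Drop degree-<2 nodes from the mean instead of
#'   counting them as 0.
#' @return Value in `[0, 1]`.
#' @export
avg_clustering_coefficient <- function(net, exclude_low_degree = FALSE) {
  g <- if (inherits(net, "cooc_network")) as_igraph(net) else net
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  if (exclude_low_degree) {
    deg <- igraph::degree(g)
    local <- local[deg >= 2]
    if (length(local) == 0) return(NA_real_)
  }
  mean(local)
}

#' Merge node annotations onto a network
#'
#' `set_node_guilds()` assigns functional guilds from taxonomy,
#' `set_node_indicators()` marks each node's indicator configuration from
#' an [indicator_test()] result, `set_node_mags()` attaches accepted
#' ASV-MAG pairs, and `set_node_expression()` attaches a per-node
#' expression value (mean MAG TPM across samples).
#'
#' @param net A [cooc_network()].
#' @param taxonomy A `taxonomy_table`.
#' @param guild_table Taxon-to-guild lookup (see [default_guild_table()]).
#' @return The network with updated node attributes.
#' @export
set_node_guilds <- function(net, taxonomy, guild_table = default_guild_table()) {
  g <- assign_guilds(taxonomy, guild_table)
  idx <- match(net$nodes$asv_id, g$id)
  net$nodes$guild <- ifelse(is.na(idx), "other", g$guild[idx])
  net
}

#' @rdname set_node_guilds
#' @param indicators Result of [indicator_test()] (uses significant rows).
#' @export
set_node_indicators <- function(net, indicators) {
  sig <- indicators[indicators$significant, ]
  idx <- match(net$nodes$asv_id, sig$asv_id)
  net$nodes$indicator <- ifelse(is.na(idx), NA_character_, sig$group[idx])
  net
}

#' @rdname set_node_guilds
#' @param pairs Accepted pairs from [pair_asv_mag()].
#' @export
set_node_mags <- function(net, pairs) {
  acc <- pairs[pairs$accepted, ]
  idx <- match(net$nodes$asv_id, acc$asv_id)
  net$nodes$mag_id <- ifelse(is.na(idx), NA_character_, acc$mag_id[idx])
  net
}

#' @rdname set_node_guilds
#' @param mag_tpm Per-MAG expression tibble (`mag_id`, `sample_id`,
#'   `tpm`), e.g. from [aggregate_mag_expression()].
#' @export
set_node_expression <- function(net, mag_tpm) {
  mean_tpm <- mag_tpm |>
    dplyr::group_by(.data$mag_id) |>
    dplyr::summarise(expression = mean(.data$tpm), .groups = "drop")
  idx <- match(net$nodes$mag_id, mean_tpm$mag_id)
  net$nodes$expression <- ifelse(is.na(idx), NA_real_, mean_tpm$expression[idx])
  net
}
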