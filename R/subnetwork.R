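#' Extract methanogen-centered subnetworks
#'
#' For every seed node (by default, every hydrogenotrophic methanogen
#' ASV) the breadth-first neighborhood within `max_hops` edges is taken;
#' neighborhoods sharing any node are merged into a single subnetwork.
#' Subnetworks are numbered by descending size, ties broken by smallest
#' member id.
#'
#' @param net A [cooc_network()] with guild labels on its nodes.
#' @param seed_guild Guild defining the seeds (default
#'   `"hydrogenotrophic_methanogen"`).
#' @param max_hops Neighborhood radius in edges (default 2: primary and
#'   secondary co-occurrence).
#' @return List of class `subnetwork_set`; each element is a list with
#'   `id`, `nodes` (sorted ids), `seeds`, `size`, and `guild_counts`
#'   (named: syntrophs `s`, hydrogenotrophic methanogens `m`). Empty (with
#'   a warning) when the network has no seed nodes.
#' @export
extract_subnetworks <- function(net, seed_guild = "hydrogenotrophic_methanogen",
                                max_hops = 2) {
  stopifnot(inherits(net, "cooc_network"))
  seeds <- net$nodes$asv_id[net$nodes$guild == seed_guild]
  if (length(seeds) == 0) {
    warning("no seed nodes with guild '", seed_guild, "'")
    return(structure(list(), class = "subnetwork_set"))
  }
  g <- as_igraph(net)
  hoods <- lapply(seeds, function(s) {
    sort(names(unlist(igraph::ego(g, order = max_hops, nodes = s)[[1]])))
  })
  # merge neighborhoods that intersect (transitively)
  merged <- list()
  assigned <- rep(NA_integer_, length(hoods))
  for (i in seq_along(hoods)) {
    hit <- which(vapply(merged, function(m) length(intersect(m$nodes, hoods[[i]])) > 0,
                        logical(1)))
    if (length(hit) == 0) {
      merged[[length(merged) + 1]] <- list(nodes = hoods[[i]], seeds = seeds[i])
    } else {
      keep <- hit[1]
      for (h in hit) {
        merged[[keep]]$nodes <- union(merged[[keep]]$nodes, merged[[h]]$nodes)
        merged[[keep]]$seeds <- union(merged[[keep]]$seeds, merged[[h]]$seeds)
      }
      merged[[keep]]$nodes <- union(merged[[keep]]$nodes, hoods[[i]])
      merged[[keep]]$seeds <- union(merged[[keep]]$seeds, seeds[i])
      drop <- setdiff(hit, keep)
      if (length(drop) > 0) merged <- merged[-drop]
    }
  }
  guild <- stats::setNames(net$nodes$guild, net$nodes$asv_id)
  subs <- lapply(merged, function(m) {
    nodes <- sort(m$nodes)
    list(nodes = nodes, seeds = sort(m$seeds), size = length(nodes),
         guild_counts = c(s = sum(guild[nodes] == "syntroph"),
                          m = sum(guild[nodes] == "hydrogenotrophic_methanogen")))
  })
  ord <- order(-vapply(subs, `[[`, integer(1), "size"),
               vapply(subs, function(s) s$nodes[1], character(1)))
  subs <- subs[ord]
  for (i in seq_along(subs)) subs[[i]]$id <- i
  structure(subs, class = "subnetwork_set")
}

#' @export
print.subnetwork_set <- function(x, ...) {
  cat(sprintf("<subnetwork_set> %d subnetwork(s)\n", length(x)))
  for (s in x) {
    cat(sprintf("  #%d: %d nodes (%d seed(s), s = %d, m = %d)\n",
                s$id, s$size, length(s$seeds),
                s$guild_counts[["s"]], s$guild_counts[["m"]]))
  }
  invisible(x)
}

#' @rdname extract_subnetworks
#' @param x A `subnetwork_set`.
#' @param ... Unused.
#' @return `tidy()`: tibble with one row per subnetwork member
#'   (`subnetwork`, `asv_id`, `is_seed`).
#' @export
tidy.subnetwork_set <- function(x, ...) {
  purrr::map_dfr(x, function(s) {
    tibble::tibble(subnetwork = s$id, asv_id = s$nodes,
                   is_seed = s$nodes %in% s$seeds)
  })
}

#' Permutation test of subnetwork guild composition
#'
#' Draws `size`-node sets uniformly without replacement from the parent
#' network `n_perm` times and reports the fraction of draws whose
#' syntroph count `s` and hydrogenotrophic-methanogen count `m` meet the
#' criterion against the observed counts: jointly `>=` them
#' (`mode = "at_least"`, the standard enrichment direction) or exactly
#' equal (`mode = "exact_counts"`). The closed-form multivariate
#' hypergeometric probability ([guild_enrichment_exact()]) is reported
#' alongside.
#'
#' @param net The parent [cooc_network()].
#' @param subnet One element of [extract_subnetworks()] (or any list with
#'   `size` and `guild_counts`).
#' @param n_perm Number of random draws (default 10000).
#' @param seed RNG seed.
#' @param mode `"at_least"` or `"exact_counts"`.
#' @param pseudocount Use the `(r + 1) / (B + 1)` convention instead of
#'   the raw fraction (default `FALSE`: raw empirical probability, which
#'   can be 0).
#' @return One-row tibble of class `enrichment_result`: `subnetwork`,
#'   `size`, `s`, `m`, `p_empirical`, `p_exact`, `n_perm`, `seed`,
#'   `mode`.
#' @export
guild_enrichment <- function(net, subnet, n_perm = 10000, seed = 1L,
                             mode = c("at_least", "exact_counts"),
                             pseudocount = FALSE) {
  mode <- match.arg(mode)
  k <- subnet$size
  n_nodes <- nrow(net$nodes)
  if (k > n_nodes) stop("subnetwork larger than the parent network", call. = FALSE)
  s_obs <- subnet$guild_counts[["s"]]
  m_obs <- subnet$guild_counts[["m"]]
  is_syn <- net$nodes$guild == "syntroph"
  is_met <- net$nodes$guild == "hydrogenotrophic_methanogen"
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    draw <- sample.int(n_nodes, k)
    s <- sum(is_syn[draw]); m <- sum(is_met[draw])
    ok <- if (mode == "at_least") s >= s_obs && m >= m_obs
          else s == s_obs && m == m_obs
    hits <- hits + ok
  }
  p_emp <- if (pseudocount) (hits + 1) / (n_perm + 1) else hits / n_perm
  p_ex <- guild_enrichment_exact(N = n_nodes, S = sum(is_syn), M = sum(is_met),
                                 k = k, s = s_obs, m = m_obs, mode = mode)
  out <- tibble::tibble(subnetwork = subnet$id %||% NA_integer_, size = k,
                        s = s_obs, m = m_obs, p_empirical = p_emp,
                        p_exact = p_ex, n_perm = n_perm, seed = seed,
                        mode = mode)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Exact multivariate hypergeometric guild probability
#'
#' Probability that a uniform draw of `k` nodes from a parent of `N`
#' nodes containing `S` syntrophs and `M` hydrogenotrophic methanogens
#' contains `(i, j)` of them meeting the criterion versus `(s, m)`:
#' `P = sum C(S, i) C(M, j) C(N - S - M, k - i - j) / C(N, k)` over
#' qualifying `(i, j)`.
#'
#' @param N,S,M Parent node counts (total, syntroph, methanogen;
#'   `S + M <= N`).
#' @param k Draw size.
#' @param s,m Observed counts (`s <= S` not required for a zero result).
#' @param mode `"at_least"` (jointly >= observed) or `"exact_counts"`.
#' @return Probability in `[0, 1]`.
#' @export
guild_enrichment_exact <- function(N, S, M, k, s, m,
                                   mode = c("at_least", "exact_counts")) {
  mode <- match.arg(mode)
  if (S + M > N || k > N || s < 0 || m < 0) {
    stop("inconsistent counts", call. = FALSE)
  }
  other <- N - S - M
  total <- lchoose(N, k)
  if (mode == "at_least") {
    is_ok <- function(i, j) i >= s && j >= m
  } else {
    is_ok <- function(i, j) i == s && j == m
  }
  p <- 0
  for (i in 0:min(S, k)) {
    for (j in 0:min(M, k - i)) {
      if (k - i - j > other) next
      if (is_ok(i, j)) {
        p <- p + exp(lchoose(S, i) + lchoose(M, j) +
                     lchoose(other, k - i - j) - total)
      }
    }
  }
  min(p, 1)
}
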