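#' Weighted ASV co-occurrence network
#'
#' An undirected graph whose nodes are ASVs and whose edges carry a
#' correlation weight and a multiple-test-adjusted p-value. Node
#' annotations accumulate through the pipeline: mean relative abundance,
#' functional guild, indicator configuration, linked MAG, and MAG
#' expression.
#'
#' @param nodes Tibble with at least `asv_id`; recognised annotation
#'   columns are `mean_rel_abund`, `guild`, `indicator`, `mag_id`,
#'   `expression` (filled with `NA`/`"other"` when absent).
#' @param edges Tibble with columns `from`, `to`, `weight`, and optionally
#'   `p`, `q`.
#' @param positive_only Enforce positive stored weights (the default
#'   convention for this network type).
#' @return Object of class `cooc_network`.
#' @export
cooc_network <- function(nodes, edges, positive_only = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot("asv_id" %in% names(nodes))
  if (anyDuplicated(nodes$asv_id)) stop("duplicate node ids", call. = FALSE)
  defaults <- list(mean_rel_abund = NA_real_, guild = "other",
                   indicator = NA_character_, mag_id = NA_character_,
                   expression = NA_real_)
  for (col in names(defaults)) {
    if (!col %in% names(nodes)) nodes[[col]] <- defaults[[col]]
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = double(), p = double(), q = double())
  }
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (!"p" %in% names(edges)) edges$p <- NA_real_
  if (!"q" %in% names(edges)) edges$q <- NA_real_
  if (any(edges$from == edges$to)) stop("self-edges are not allowed", call. = FALSE)
  unknown <- setdiff(c(edges$from, edges$to), nodes$asv_id)
  if (length(unknown) > 0) {
    stop("edge endpoint(s) not in node set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (positive_only && any(edges$weight <= 0)) {
    stop("stored edges must have positive weight", call. = FALSE)
  }
  # canonical order: endpoints sorted within an edge, edges sorted
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  if (anyDuplicated(edges[, c("from", "to")])) {
    stop("duplicate edges", call. = FALSE)
  }
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges), class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  g <- table(x$nodes$guild)
  cat("  guilds:", paste(sprintf("%s (%d)", names(g), g), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname cooc_network
#' @param x A `cooc_network`.
#' @param ... Unused.
#' @return `tidy()`: the edge tibble with endpoint guilds joined on.
#' @export
tidy.cooc_network <- function(x, ...) {
  guild <- stats::setNames(x$nodes$guild, x$nodes$asv_id)
  dplyr::mutate(x$edges,
                from_guild = unname(guild[.data$from]),
                to_guild = unname(guild[.data$to]))
}

#' @rdname cooc_network
#' @return `glance()`: one-row tibble with node/edge counts, density,
#'   mean weight, and average clustering coefficient.
#' @export
glance.cooc_network <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble::tibble(
    n_nodes = n,
    n_edges = nrow(x$edges),
    density = if (n > 1) nrow(x$edges) / choose(n, 2) else NA_real_,
    mean_weight = if (nrow(x$edges) > 0) mean(x$edges$weight) else NA_real_,
    avg_clustering = if (n > 0) avg_clustering_coefficient(x) else NA_real_
  )
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = as.data.frame(net$nodes))
}

from_igraph <- function(g) {
  nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices"))
  names(nodes)[names(nodes) == "name"] <- "asv_id"
  nodes$id <- NULL   # igraph's internal GraphML vertex id
  # GraphML serializes missing numerics as NaN and missing strings as "NA"
  for (col in names(nodes)) {
    if (is.numeric(nodes[[col]])) nodes[[col]][is.nan(nodes[[col]])] <- NA
    if (is.character(nodes[[col]])) nodes[[col]][nodes[[col]] == "NA"] <- NA
  }
  edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
  for (col in names(edges)) {
    if (is.numeric(edges[[col]])) edges[[col]][is.nan(edges[[col]])] <- NA
  }
  cooc_network(nodes, edges, positive_only = FALSE)
}

#' Write a co-occurrence network to disk
#'
#' `edge_tsv` writes one row per edge with weight and adjusted p;
#' `graphml` writes the full graph with all node attributes (readable
#' back with [read_network()], reproducing the graph and attributes).
#'
#' @param net A [cooc_network()].
#' @param path Destination.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(as.data.frame(net$edges), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(net)
}

#' Read a co-occurrence network written by [write_network()]
#'
#' @param path File path.
#' @param format `"edge_tsv"` (edges only; nodes inferred from endpoints)
#'   or `"graphml"`.
#' @return A [cooc_network()].
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    edges <- read_tsv_strict(path)
    nodes <- tibble::tibble(asv_id = sort(unique(c(edges$from, edges$to))))
    return(cooc_network(nodes, edges, positive_only = FALSE))
  }
  g <- igraph::read_graph(path, format = "graphml")
  from_igraph(g)
}

#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout; node colour = guild, node size = mean
#' relative abundance, edge alpha = weight.
#'
#' @param object A [cooc_network()].
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cooc_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nd <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- stats::setNames(seq_len(nrow(nd)), nd$asv_id)
  ed <- dplyr::mutate(object$edges,
                      x = nd$x[pos[.data$from]], y = nd$y[pos[.data$from]],
                      xend = nd$x[pos[.data$to]], yend = nd$y[pos[.data$to]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$weight),
      colour = "grey50") +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$guild,
                   size = .data$mean_rel_abund)) +
    ggplot2::scale_size_area(max_size = 6, na.value = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "guild", size = "mean rel. abund.",
                  alpha = "|r|")
}
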