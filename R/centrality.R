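#' Min-max normalisation of a score vector
#'
#' Maps scores linearly onto `[0, 1]`; a constant vector maps to all zeros so
#' that degenerate graphs produce a determinate result.
#'
#' @param x numeric vector.
#' @return normalised vector with the same names.
#' @export
minmax_normalize <- function(x) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(stats::setNames(rep(0, length(x)), names(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Shortest-path statistics of a collapsed structure network
#'
#' All-pairs shortest-path lengths (in edge hops) on the simple unweighted
#' undirected graph obtained by [collapse_graph()], and the characteristic
#' path length L: the mean distance over connected unordered node pairs.
#' Disconnected pairs are excluded from the average rather than assigned an
#' infinite distance, which keeps L (and the node-removal scores built on it)
#' finite on fragmented graphs.
#'
#' @param network a `psn` or an `igraph` graph.
#' @return list with `distances` (matrix, `Inf` for disconnected pairs),
#'   `L` (characteristic path length; `NA` if no pair is connected) and
#'   `connected_pairs` (number of connected unordered pairs).
#' @export
path_statistics <- function(network) {
  g <- if (inherits(network, "igraph")) network else collapse_graph(network)
  d <- igraph::distances(g)
  list(distances = d,
       L = characteristic_path_length(d),
       connected_pairs = sum(is.finite(d[upper.tri(d)])))
}

characteristic_path_length <- function(d) {
  ut <- d[upper.tri(d)]
  ut <- ut[is.finite(ut)]
  if (length(ut) == 0L) return(NA_real_)
  mean(ut)
}

#' Betweenness centrality of network nodes
#'
#' For each node, the sum over unordered node pairs (excluding the node
#' itself) of the fraction of shortest paths between the pair that pass
#' through the node, computed on the collapsed simple graph, then min-max
#' normalised across nodes.
#'
#' @param network a `psn` or an `igraph` graph.
#' @param normalize min-max normalise the scores (default `TRUE`, matching
#'   the reporting convention used for allosteric ranking).
#' @return named numeric vector of scores with attribute `method = "BC"`.
#' @export
betweenness_centrality <- function(network, normalize = TRUE) {
  g <- if (inherits(network, "igraph")) network else collapse_graph(network)
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  scores <- if (normalize) minmax_normalize(raw) else raw
  scores <- stats::setNames(as.numeric(scores), igraph::V(g)$name)
  attr(scores, "method") <- "BC"
  scores
}

#' Characteristic path length centrality (CPLC)
#'
#' The effect of removing each node on the characteristic path length:
#' `CPLC_i = L - L_i`, where `L_i` is recomputed on the graph with node `i`
#' deleted. The connected-pairs-only convention for L applies before and
#' after deletion, so deletions that disconnect the graph remain finite;
#' set `drop_disconnecting = TRUE` to score such deletions as `NA` instead
#' (the alternative convention, exposed for comparison). Scores are min-max
#' normalised across nodes.
#'
#' @param network a `psn` or an `igraph` graph.
#' @param normalize min-max normalise the scores (default `TRUE`).
#' @param drop_disconnecting score deletions that change the number of
#'   connected components as `NA` instead of using the connected-pairs
#'   convention.
#' @return named numeric vector of scores with attribute `method = "CPLC"`.
#' @export
cplc <- function(network, normalize = TRUE, drop_disconnecting = FALSE) {
  g <- if (inherits(network, "igraph")) network else collapse_graph(network)
  L <- characteristic_path_length(igraph::distances(g))
  if (is.na(L)) L <- 0   # edgeless graph: no connected pairs anywhere
  n_comp <- igraph::components(g)$no
  names_v <- igraph::V(g)$name
  raw <- vapply(seq_along(names_v), function(i) {
    gi <- igraph::delete_vertices(g, i)
    if (drop_disconnecting &&
        igraph::components(gi)$no > n_comp) return(NA_real_)
    Li <- characteristic_path_length(igraph::distances(gi))
    if (is.na(Li)) Li <- 0
    L - Li
  }, 0)
  scores <- if (normalize) {
    ok <- !is.na(raw)
    out <- raw
    out[ok] <- minmax_normalize(raw[ok])
    out
  } else raw
  scores <- stats::setNames(as.numeric(scores), names_v)
  attr(scores, "method") <- "CPLC"
  scores
}
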