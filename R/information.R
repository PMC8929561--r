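#' Mutual information between two interaction timelines
#'
#' Plug-in (maximum-likelihood) estimate over the joint histogram of
#' per-frame states, in bits (log base 2). States are the raw integer counts;
#' no binning is applied. Terms with zero joint probability contribute
#' nothing. The estimate is non-negative and bounded by the smaller marginal
#' entropy; finite-sample bias is positive and of order
#' `(|X|-1)(|Y|-1) / (2 T ln 2)` bits for independent timelines.
#'
#' @param x,y timelines of equal length.
#' @return mutual information in bits.
#' @examples
#' mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1)) # 1 bit
#' mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)) # 0 bits
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("timeline length mismatch: %d vs %d", length(x), length(y)))
  }
  n <- length(x)
  jt <- table(x, y)
  p <- jt / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log2(p[nz] / (px[nz[, 1L]] * py[nz[, 2L]])))
}

#' Difference of mutual information between a target and a reference pair
#'
#' For a pair of target timelines `(x, y)` and the matching pair from a
#' reference ensemble `(x_ref, y_ref)`, the score is the pointwise
#' mutual-information sum of the target pair minus that of the reference
#' pair, each estimated within its own ensemble (the two ensembles may have
#' different frame counts). Summation formally runs over the union of the
#' state alphabets, but states unobserved in a given ensemble have zero
#' probability there and contribute nothing, so the score equals
#' `I(x; y) - I(x_ref; y_ref)`. An absent reference pair (either member
#' `NULL`) is treated as constant, making the reference term zero.
#'
#' @param x,y target timelines (equal length).
#' @param x_ref,y_ref reference timelines (equal length), or `NULL`.
#' @return difference in bits; may be negative.
#' @export
difference_mutual_information <- function(x, y, x_ref = NULL, y_ref = NULL) {
  target <- mutual_information(x, y)
  if (is.null(x_ref) || is.null(y_ref)) return(target)
  target - mutual_information(x_ref, y_ref)
}

## --- edge neighbourhoods ----------------------------------------------------

edge_key <- function(source, target, type) {
  paste(source, target, type, sep = "\r")
}

#' Neighbouring edges of a focal edge
#'
#' The neighbourhood of edge `(i, j, k)` consists of every other edge sharing
#' at least one endpoint with it: edges touching `i` or `j` through a single
#' common node, and parallel edges (same endpoints, different interaction
#' type), each counted exactly once. The focal edge itself is excluded, which
#' removes its self-information from the correlation sums.
#'
#' @param network a `psn`.
#' @param edge_index row index into `network$edges`.
#' @return integer vector of neighbour row indices.
#' @export
edge_neighbors <- function(network, edge_index) {
  e <- network$edges
  i <- e$source[edge_index]
  j <- e$target[edge_index]
  touching <- which(e$source == i | e$target == i |
                    e$source == j | e$target == j)
  setdiff(touching, edge_index)
}

#' Edge neighbour correlation factor (ECF)
#'
#' Sum of the mutual information between the focal edge's timeline and the
#' timeline of each neighbouring edge (edges separated from the focal edge by
#' at most a single node). When a reference network is supplied, each term is
#' the difference mutual information against the location-matched reference
#' edge pair instead; target edges without a reference partner contribute
#' their full target-pair mutual information, and edges existing solely in
#' the reference network contribute nothing.
#'
#' @param network a `psn`.
#' @param source,target,type edge identity (canonical order not required).
#' @param reference optional reference `psn` at the same grain.
#' @return ECF score in bits; 0 for an edge with no neighbours.
#' @export
ecf <- function(network, source, target, type, reference = NULL) {
  cp <- canonical_pair(source, target)
  idx <- which(network$edges$source == cp$source &
               network$edges$target == cp$target &
               network$edges$type == type)
  if (length(idx) != 1L) {
    stop(sprintf("edge not found: (%s, %s, %s)", source, target, type))
  }
  ref_lookup <- if (!is.null(reference)) match_edges(network, reference)
  ecf_at(network, idx, ref_lookup)
}

## ECF for an edge given by row index, with an optional per-edge reference
## timeline lookup (list parallel to network$edges, NULL where unmatched)
ecf_at <- function(network, idx, ref_timelines = NULL) {
  nb <- edge_neighbors(network, idx)
  if (length(nb) == 0L) return(0)
  x <- network$edges$timeline[[idx]]
  if (is.null(ref_timelines)) {
    return(sum(vapply(nb, function(m)
      mutual_information(x, network$edges$timeline[[m]]), 0)))
  }
  x_ref <- ref_timelines[[idx]]
  sum(vapply(nb, function(m) {
    difference_mutual_information(x, network$edges$timeline[[m]],
                                  x_ref, ref_timelines[[m]])
  }, 0))
}

#' Node correlation factor (NCF) and its difference variant (DNCF)
#'
#' The NCF of a node is the sum of the ECF scores of its adjacent edges,
#' over all interaction types. High NCF marks residues whose interactions
#' carry information about the interaction state of their immediate
#' environment -- candidates for allosteric behaviour. With a reference
#' network supplied (location-matched by residue pair and interaction type),
#' every mutual-information term becomes a target-minus-reference difference
#' and the result is the DNCF score, which highlights residues whose
#' interaction coupling changes between the two ensembles (e.g. ligand-bound
#' versus free). DNCF is not symmetric under swapping target and reference
#' when the two topologies differ.
#'
#' @param network target `psn` (non-empty).
#' @param reference optional reference `psn` at the same grain; triggers
#'   DNCF scoring.
#' @return named numeric vector of per-node scores in bits (isolated nodes
#'   score 0), with attribute `method` set to `"NCF"` or `"DNCF"`.
#' @export
ncf <- function(network, reference = NULL) {
  if (nrow(network$nodes) == 0L) stop("network has no nodes")
  e <- network$edges
  ref_timelines <- if (!is.null(reference)) match_edges(network, reference)
  edge_scores <- vapply(seq_len(nrow(e)), function(i)
    ecf_at(network, i, ref_timelines), 0)
  scores <- stats::setNames(numeric(nrow(network$nodes)), network$nodes$id)
  for (i in seq_len(nrow(e))) {
    scores[e$source[i]] <- scores[e$source[i]] + edge_scores[i]
    scores[e$target[i]] <- scores[e$target[i]] + edge_scores[i]
  }
  attr(scores, "method") <- if (is.null(reference)) "NCF" else "DNCF"
  scores
}

#' @rdname ncf
#' @export
dncf <- function(network, reference) {
  if (missing(reference) || is.null(reference)) {
    stop("DNCF requires a reference network")
  }
  ncf(network, reference)
}

#' Match edges between a target and a reference network by location
#'
#' Two edges are equivalent when they connect the same node identifiers and
#' share the interaction type ("match location"). Returns, for each target
#' edge, the reference timeline, or `NULL` when the reference network has no
#' equivalent edge. Edges existing solely in the reference network are
#' reported in the `reference_only` attribute; they never contribute to
#' difference scores.
#'
#' @param target,reference `psn` objects at the same grain.
#' @return list parallel to `target$edges` rows of reference timelines (or
#'   `NULL`), with attribute `reference_only` naming unmatched reference
#'   edges.
#' @export
match_edges <- function(target, reference) {
  if (!identical(target$grain, reference$grain)) {
    stop(sprintf("grain mismatch: target is %s-grain, reference is %s-grain",
                 target$grain, reference$grain))
  }
  tkey <- edge_key(target$edges$source, target$edges$target, target$edges$type)
  rkey <- edge_key(reference$edges$source, reference$edges$target,
                   reference$edges$type)
  pos <- match(tkey, rkey)
  out <- vector("list", length(tkey))
  hit <- !is.na(pos)
  out[hit] <- reference$edges$timeline[pos[hit]]
  ref_only <- reference$edges[!(rkey %in% tkey),
                              c("source", "target", "type"), drop = FALSE]
  attr(out, "reference_only") <- ref_only
  out
}
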