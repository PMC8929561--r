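#' @title Timeline-carrying protein structure networks
#'
#' @description
#' A structure network maps atoms (or groups of atoms, typically residues) to
#' nodes and physical interactions -- carbon contacts, hydrogen bonds -- to
#' typed edges. Every edge carries a timeline recording the state of the
#' interaction in each frame of the analysed ensemble. A node pair may be
#' connected by several edges of different interaction types. A network built
#' from a single structure is the degenerate case where every timeline has
#' length one.
#'
#' Node identifiers are colon-separated strings: `chain:residue:resname` for
#' group-grain nodes and `chain:residue:resname:atom` for atom-grain nodes,
#' where `residue` is the residue sequence number with any insertion code
#' appended. Edges are stored with endpoints in canonical (lexicographic)
#' order so that storage and iteration order are deterministic.
#'
#' @name psn
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
BACKBONE_HYDROGENS <- c("H", "HN", "H1", "H2", "H3", "HA", "HA2", "HA3",
                        "HT1", "HT2", "HT3")

#' Is an atom part of the peptide backbone?
#'
#' Backbone atoms are N, CA, C, O (plus terminal OXT) and the hydrogens bound
#' to them; everything else, including CB, counts as sidechain. Glycine
#' therefore has no sidechain atoms.
#'
#' @param atom atom name(s), PDB convention.
#' @return logical vector.
#' @export
is_backbone_atom <- function(atom) {
  atom %in% c(BACKBONE_ATOMS, BACKBONE_HYDROGENS)
}

## --- node identifiers -------------------------------------------------------

atom_id <- function(chain, residue, resname, atom) {
  paste(chain, residue, resname, atom, sep = ":")
}

group_id_of <- function(id) {
  sub(":[^:]*$", "", id)
}

parse_node_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 3L | n > 4L)) {
    stop("malformed node identifier: ", id[which(n < 3L | n > 4L)[1L]])
  }
  data.frame(
    id      = id,
    chain   = vapply(parts, `[`, "", 1L),
    residue = vapply(parts, `[`, "", 2L),
    resname = vapply(parts, `[`, "", 3L),
    atom    = vapply(parts, function(p) if (length(p) == 4L) p[4L] else NA_character_, ""),
    grain   = ifelse(n == 4L, "atom", "group"),
    stringsAsFactors = FALSE
  )
}

node_table <- function(ids) {
  tab <- parse_node_id(ids)
  tab$sidechain <- ifelse(tab$grain == "atom", !is_backbone_atom(tab$atom), NA)
  rownames(tab) <- NULL
  tab
}

canonical_pair <- function(a, b) {
  swap <- b < a
  list(source = ifelse(swap, b, a), target = ifelse(swap, a, b))
}

## --- constructor ------------------------------------------------------------

new_psn <- function(nodes, edges, frames, grain,
                    atom_edges = NULL, grouping = NULL) {
  ord <- order(edges$source, edges$target, edges$type)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, frames = as.integer(frames),
         grain = grain, atom_edges = atom_edges, grouping = grouping),
    class = "psn"
  )
}

#' @export
print.psn <- function(x, ...) {
  cat(sprintf("<structure network: %d nodes (%s grain), %d edges, %d frame%s>\n",
              nrow(x$nodes), x$grain, nrow(x$edges), x$frames,
              if (x$frames == 1L) "" else "s"))
  if (nrow(x$edges) > 0L) {
    types <- table(x$edges$type)
    cat("  edge types:",
        paste(sprintf("%s (%d)", names(types), types), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build an atom-grain structure network from timeline records
#'
#' Timeline records are the exchange currency of the package: one row per
#' interaction, holding the two atom identifiers, the interaction type and
#' the per-frame timeline. They are produced by the extraction and parsing
#' functions ([extract_contacts()], [extract_hbonds()], [parse_timeseries()],
#' [read_aif()]) or constructed directly.
#'
#' @param records data.frame with columns `source`, `target` (atom
#'   identifiers, `chain:residue:resname:atom`), `type` (interaction type
#'   label) and `timeline` (list column of per-frame count vectors).
#' @param frames ensemble frame count; every timeline must have this length.
#' @return an atom-grain `psn` object.
#' @examples
#' rec <- timeline_records(
#'   source = "A:1:ALA:CB", target = "A:2:GLY:CA",
#'   type = "contact", timeline = list(c(1, 0, 1)))
#' build_network(rec, frames = 3)
#' @export
build_network <- function(records, frames) {
  records <- as_timeline_records(records)
  if (nrow(records) == 0L) stop("no timeline records supplied")
  frames <- as.integer(frames)
  if (frames < 1L) stop("frame count must be >= 1")
  if (any(records$source == records$target)) {
    bad <- which(records$source == records$target)[1L]
    stop("self-interaction record: ", records$source[bad])
  }
  for (i in seq_len(nrow(records))) {
    tl <- records$timeline[[i]]
    if (length(tl) != frames) {
      stop(sprintf("record %s -- %s (%s): timeline length %d does not match frame count %d",
                   records$source[i], records$target[i], records$type[i],
                   length(tl), frames))
    }
    records$timeline[[i]] <- check_timeline(tl, frames)
  }
  cp <- canonical_pair(records$source, records$target)
  records$source <- cp$source
  records$target <- cp$target
  key <- paste(records$source, records$target, records$type, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate record for pair (%s, %s) type %s",
                 dup$source, dup$target, dup$type))
  }
  ids <- sort(unique(c(records$source, records$target)))
  nodes <- node_table(ids)
  if (any(nodes$grain != "atom")) {
    stop("build_network expects atom-grain identifiers (chain:residue:resname:atom)")
  }
  edges <- records[, c("source", "target", "type", "timeline")]
  sc <- stats::setNames(nodes$sidechain, nodes$id)
  edges$sidechain <- sc[edges$source] & sc[edges$target]
  new_psn(nodes, edges, frames, grain = "atom")
}

#' Construct a timeline-record data.frame
#'
#' @param source,target atom identifiers.
#' @param type interaction type label(s).
#' @param timeline list of per-frame count vectors.
#' @return a data.frame usable by [build_network()] and the AIF writer.
#' @export
timeline_records <- function(source, target, type, timeline) {
  if (!is.list(timeline)) timeline <- list(timeline)
  data.frame(source = source, target = target, type = type,
             timeline = I(timeline), stringsAsFactors = FALSE)
}

as_timeline_records <- function(records) {
  if (!is.data.frame(records)) records <- do.call(rbind, records)
  need <- c("source", "target", "type", "timeline")
  if (!all(need %in% names(records))) {
    stop("timeline records need columns: ", paste(need, collapse = ", "))
  }
  records
}

## --- adjacency --------------------------------------------------------------

#' Adjacency matrix for one interaction type
#'
#' Symmetric binary matrix over the network's nodes with a 1 wherever an edge
#' of the requested type connects two nodes; the diagonal is zero.
#'
#' @param network a `psn` object.
#' @param type interaction type label.
#' @return a symmetric 0/1 matrix with node identifiers as dimnames.
#' @export
adjacency_matrix <- function(network, type) {
  ids <- network$nodes$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  e <- network$edges[network$edges$type == type, , drop = FALSE]
  if (nrow(e) > 0L) {
    A[cbind(e$source, e$target)] <- 1L
    A[cbind(e$target, e$source)] <- 1L
  }
  A
}

## --- grain transformations --------------------------------------------------

#' Default atom-to-residue grouping of an atom-grain network
#'
#' @param network atom-grain `psn`.
#' @return named character vector mapping atom identifiers to residue
#'   (group) identifiers.
#' @export
residue_grouping <- function(network) {
  at <- network$nodes[network$nodes$grain == "atom", ]
  stats::setNames(group_id_of(at$id), at$id)
}

#' Aggregate an atom-grain network to atom groups (residues)
#'
#' The timeline of a group-pair edge is the frame-wise sum of the timelines
#' of all atomic interactions between the two groups, per interaction type.
#' Interactions internal to a group are dropped (no self edges). The atomic
#' records are retained inside the returned object so that [split_node()]
#' can later restore atomic resolution for selected nodes.
#'
#' @param network atom-grain `psn`.
#' @param grouping named character vector atom id -> group id; defaults to
#'   one group per residue.
#' @return a group-grain `psn`.
#' @export
aggregate_to_groups <- function(network, grouping = residue_grouping(network)) {
  if (network$grain != "atom") stop("input must be an atom-grain network")
  atoms <- network$nodes$id
  missing <- setdiff(atoms, names(grouping))
  if (length(missing) > 0L) {
    stop("atom missing from grouping: ", missing[1L])
  }
  e <- network$edges
  gs <- unname(grouping[e$source])
  gt <- unname(grouping[e$target])
  keep <- gs != gt
  e2 <- e[keep, , drop = FALSE]
  gs <- gs[keep]; gt <- gt[keep]
  cp <- canonical_pair(gs, gt)
  key <- paste(cp$source, cp$target, e2$type, sep = "\r")
  groups <- sort(unique(unname(grouping)))
  if (nrow(e2) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        type = character(), sidechain = logical())
    edges$timeline <- list()
  } else {
    idx <- split(seq_len(nrow(e2)), key)
    rows <- lapply(idx, function(ii) {
      tl <- Reduce(`+`, e2$timeline[ii])
      data.frame(source = cp$source[ii[1L]], target = cp$target[ii[1L]],
                 type = e2$type[ii[1L]],
                 sidechain = all(e2$sidechain[ii]),
                 timeline = I(list(tl)),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
  }
  nodes <- node_table(groups)
  new_psn(nodes, edges[, c("source", "target", "type", "timeline", "sidechain")],
          network$frames, grain = "group",
          atom_edges = network$edges, grouping = grouping)
}

#' Split a group node back into its member atoms
#'
#' Replaces one group-grain node by its member atoms, producing a mixed-grain
#' network: interactions between the split atoms and another group become
#' atom-to-group edges (frame-wise sums over the other group's atoms), and
#' interactions internal to the split group become atom-to-atom edges.
#' Re-aggregating the split atoms reproduces the original group edges.
#'
#' @param network group- or mixed-grain `psn` produced by
#'   [aggregate_to_groups()] (or a previous split).
#' @param node identifier of the group node to split.
#' @param records atomistic timeline records covering the node's member
#'   atoms; defaults to the records retained at aggregation time.
#' @return a mixed-grain `psn`.
#' @export
split_node <- function(network, node, records = NULL) {
  if (!(node %in% network$nodes$id)) stop("node not in network: ", node)
  if (network$nodes$grain[network$nodes$id == node] != "group") {
    stop("node is not group-grain: ", node)
  }
  if (is.null(records)) records <- network$atom_edges
  if (is.null(records)) stop("no atomistic records available for node: ", node)
  grouping <- network$grouping
  if (is.null(grouping)) stop("network carries no atom grouping")
  members <- names(grouping)[grouping == node]
  if (length(members) == 0L) stop("no atomistic records for node: ", node)

  touches <- (records$source %in% members) | (records$target %in% members)
  rec <- records[touches, , drop = FALSE]
  ## endpoint mapping: member atoms stay atomic, atoms of previously split
  ## nodes stay atomic too, everything else maps to its group id
  current_atoms <- network$nodes$id[network$nodes$grain == "atom"]
  map_end <- function(a) {
    out <- character(length(a))
    for (i in seq_along(a)) {
      ai <- a[i]
      if (ai %in% members || ai %in% current_atoms) out[i] <- ai
      else out[i] <- unname(grouping[ai])
    }
    out
  }
  ms <- map_end(rec$source)
  mt <- map_end(rec$target)
  keep <- ms != mt
  rec <- rec[keep, , drop = FALSE]; ms <- ms[keep]; mt <- mt[keep]
  cp <- canonical_pair(ms, mt)
  key <- paste(cp$source, cp$target, rec$type, sep = "\r")
  new_rows <- if (nrow(rec) == 0L) NULL else {
    idx <- split(seq_len(nrow(rec)), key)
    do.call(rbind, lapply(idx, function(ii) {
      data.frame(source = cp$source[ii[1L]], target = cp$target[ii[1L]],
                 type = rec$type[ii[1L]],
                 sidechain = all(rec$sidechain[ii]),
                 timeline = I(list(Reduce(`+`, rec$timeline[ii]))),
                 stringsAsFactors = FALSE)
    }))
  }
  old <- network$edges
  untouched <- old[old$source != node & old$target != node, , drop = FALSE]
  edges <- rbind(untouched[, c("source", "target", "type", "timeline", "sidechain")],
                 if (!is.null(new_rows))
                   new_rows[, c("source", "target", "type", "timeline", "sidechain")])
  node_ids <- sort(unique(c(setdiff(network$nodes$id, node), members)))
  nodes <- node_table(node_ids)
  new_psn(nodes, edges, network$frames, grain = "mixed",
          atom_edges = network$atom_edges, grouping = grouping)
}

## --- filtering --------------------------------------------------------------

#' Filter network edges by occupancy, type and sidechain membership
#'
#' Retains edges whose occupancy (fraction of frames with count > 0) is at
#' least `min_occupancy`, whose interaction type is among `types`, and --
#' when `sidechain_only` -- whose contributing atoms are all sidechain atoms.
#' Nodes are kept even when they become isolated. The operation is idempotent
#' at fixed parameters.
#'
#' @param network a `psn`.
#' @param min_occupancy minimum fraction of frames in `[0, 1]` (default 0).
#' @param types interaction types to keep; `NULL` keeps all.
#' @param sidechain_only drop edges with any backbone contribution.
#' @return a filtered `psn` with the same node set.
#' @export
filter_network <- function(network, min_occupancy = 0, types = NULL,
                           sidechain_only = FALSE) {
  if (min_occupancy < 0 || min_occupancy > 1) {
    stop("min_occupancy must lie in [0, 1]")
  }
  e <- network$edges
  occ <- vapply(e$timeline, timeline_occupancy, 0)
  keep <- occ >= min_occupancy
  if (!is.null(types)) keep <- keep & e$type %in% types
  if (sidechain_only) keep <- keep & e$sidechain
  out <- network
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

## --- collapsing to a simple graph -------------------------------------------

#' Collapse a structure network to a simple unweighted igraph graph
#'
#' Shortest-path centralities operate on a simple undirected graph: a single
#' unweighted edge connects two nodes wherever at least one interaction of
#' any retained type is ever present (occupancy > 0). Interaction magnitude
#' and multiplicity are deliberately ignored. Isolated nodes are kept.
#'
#' @param network a `psn`.
#' @return an `igraph` undirected simple graph with vertex names equal to
#'   node identifiers.
#' @export
collapse_graph <- function(network) {
  e <- network$edges
  occ <- vapply(e$timeline, timeline_occupancy, 0)
  e <- e[occ > 0, , drop = FALSE]
  pairs <- unique(e[, c("source", "target")])
  g <- igraph::graph_from_data_frame(
    pairs, directed = FALSE,
    vertices = data.frame(name = network$nodes$id)
  )
  igraph::simplify(g)
}

## --- score table export -----------------------------------------------------

#' Write a node score table as tab-separated text
#'
#' @param scores named numeric vector (node identifier -> score) or a
#'   data.frame with columns `id` and `score`.
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  if (!is.data.frame(scores)) {
    scores <- data.frame(id = names(scores), score = unname(scores))
  }
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a node score table written by [write_scores()]
#'
#' @param path tab-separated file with columns `id` and `score`.
#' @return named numeric vector.
#' @export
read_scores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$score, tab$id)
}
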