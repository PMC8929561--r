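# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph): literal summations for the information
# measures, exhaustive path enumeration for the centralities.

## mutual information by literal double sum over the state alphabets
mi_oracle <- function(x, y) {
  n <- length(x)
  total <- 0
  for (xs in unique(x)) {
    for (ys in unique(y)) {
      pxy <- sum(x == xs & y == ys) / n
      if (pxy == 0) next
      px <- sum(x == xs) / n
      py <- sum(y == ys) / n
      total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

## difference MI by literal summation over the union alphabets
dmi_oracle <- function(x, y, x_ref = NULL, y_ref = NULL) {
  if (is.null(x_ref) || is.null(y_ref)) {
    x_ref <- rep(0L, 2L); y_ref <- rep(0L, 2L)  # constant reference pair
  }
  xs_all <- union(unique(x), unique(x_ref))
  ys_all <- union(unique(y), unique(y_ref))
  term <- function(a, b, xs, ys) {
    n <- length(a)
    pxy <- sum(a == xs & b == ys) / n
    if (pxy == 0) return(0)
    pxy * log2(pxy / ((sum(a == xs) / n) * (sum(b == ys) / n)))
  }
  total <- 0
  for (xs in xs_all) {
    for (ys in ys_all) {
      total <- total + term(x, y, xs, ys) - term(x_ref, y_ref, xs, ys)
    }
  }
  total
}

## ECF by literal evaluation of the neighbour indicator
## chi = d_in + d_jm - d_in*d_jm*(d_kl + 1) over ordered pairs (n, m),
## using the symmetric adjacency (each undirected edge visited in both
## orientations)
ecf_oracle <- function(net, focal, ref_timelines = NULL) {
  e <- net$edges
  i <- e$source[focal]; j <- e$target[focal]; k <- e$type[focal]
  x <- e$timeline[[focal]]
  x_ref <- if (!is.null(ref_timelines)) ref_timelines[[focal]]
  total <- 0
  for (m in seq_len(nrow(e))) {
    l <- e$type[m]
    y <- e$timeline[[m]]
    mi <- if (is.null(ref_timelines)) {
      mi_oracle(x, y)
    } else {
      y_ref <- ref_timelines[[m]]
      if (is.null(x_ref) || is.null(y_ref)) mi_oracle(x, y)
      else mi_oracle(x, y) - mi_oracle(x_ref, y_ref)
    }
    for (orient in list(c(e$source[m], e$target[m]),
                        c(e$target[m], e$source[m]))) {
      n_ <- orient[1L]; m_ <- orient[2L]
      d_in <- as.integer(i == n_); d_jm <- as.integer(j == m_)
      d_kl <- as.integer(k == l)
      chi <- d_in + d_jm - d_in * d_jm * (d_kl + 1L)
      total <- total + chi * mi
    }
  }
  total
}

ncf_oracle <- function(net, ref_timelines = NULL) {
  e <- net$edges
  ecfs <- vapply(seq_len(nrow(e)), function(f)
    ecf_oracle(net, f, ref_timelines), 0)
  scores <- setNames(numeric(nrow(net$nodes)), net$nodes$id)
  for (m in seq_len(nrow(e))) {
    scores[e$source[m]] <- scores[e$source[m]] + ecfs[m]
    scores[e$target[m]] <- scores[e$target[m]] + ecfs[m]
  }
  scores
}

## reference timeline lookup by (endpoints, type), mirroring match-location
## semantics but written directly against the edge tables
ref_lookup_oracle <- function(target, reference) {
  rkey <- paste(reference$edges$source, reference$edges$target,
                reference$edges$type)
  lapply(seq_len(nrow(target$edges)), function(i) {
    key <- paste(target$edges$source[i], target$edges$target[i],
                 target$edges$type[i])
    hit <- match(key, rkey)
    if (is.na(hit)) NULL else reference$edges$timeline[[hit]]
  })
}

## ---- path/centrality oracles on adjacency matrices ------------------------

## all-pairs shortest distances by Floyd-Warshall
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

## enumerate every shortest path between two nodes by recursion on the
## distance matrix
enumerate_shortest_paths <- function(adj, d, from, to) {
  if (!is.finite(d[from, to])) return(list())
  if (from == to) return(list(from))
  nexts <- which(adj[from, ] == 1 & d[, to] == d[from, to] - 1)
  out <- list()
  for (nx in nexts) {
    for (tail in enumerate_shortest_paths(adj, d, nx, to)) {
      out[[length(out) + 1L]] <- c(from, tail)
    }
  }
  out
}

bc_oracle <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  raw <- numeric(n)
  for (j in seq_len(n - 1L)) {
    for (k in seq.int(j + 1L, n)) {
      paths <- enumerate_shortest_paths(adj, d, j, k)
      if (length(paths) == 0L) next
      for (i in seq_len(n)) {
        if (i == j || i == k) next
        through <- sum(vapply(paths, function(p) i %in% p, TRUE))
        raw[i] <- raw[i] + through / length(paths)
      }
    }
  }
  raw
}

cpl_oracle <- function(adj) {
  d <- fw_distances(adj)
  ut <- d[upper.tri(d)]
  ut <- ut[is.finite(ut)]
  if (length(ut) == 0L) return(NA_real_)
  mean(ut)
}

cplc_oracle <- function(adj) {
  n <- nrow(adj)
  L <- cpl_oracle(adj)
  if (is.na(L)) L <- 0
  vapply(seq_len(n), function(i) {
    sub <- adj[-i, -i, drop = FALSE]
    Li <- if (nrow(sub) < 2L) NA_real_ else cpl_oracle(sub)
    if (is.na(Li)) Li <- 0
    L - Li
  }, 0)
}

minmax_oracle <- function(x) {
  if (max(x) == min(x)) return(rep(0, length(x)))
  (x - min(x)) / (max(x) - min(x))
}

## Mann-Whitney rank statistic: P(score_pos > score_neg) for tie-free scores
auc_rank_oracle <- function(scores, labels) {
  s <- scores[names(labels)]
  pos <- s[labels == 1L]
  neg <- s[labels == 0L]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

## ---- random instances ------------------------------------------------------

random_network <- function(seed, max_nodes = 8L, max_types = 3L,
                           max_frames = 50L, count_states = 3L) {
  withr::with_seed(seed, {
    n <- sample(3:max_nodes, 1L)
    frames <- sample(5:max_frames, 1L)
    types <- paste0("t", seq_len(sample(seq_len(max_types), 1L)))
    ids <- sprintf("A:%d:ALA:CB", seq_len(n))
    combos <- expand.grid(a = seq_len(n), b = seq_len(n), type = types,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$a < combos$b, ]
    keep <- combos[runif(nrow(combos)) < 0.5, , drop = FALSE]
    if (nrow(keep) == 0L) keep <- combos[1L, , drop = FALSE]
    rec <- timeline_records(
      source = ids[keep$a], target = ids[keep$b], type = keep$type,
      timeline = lapply(seq_len(nrow(keep)), function(i)
        sample(0:count_states, frames, replace = TRUE)))
    build_network(rec, frames)
  })
}

random_adjacency <- function(seed, max_nodes = 9L, p = 0.4) {
  withr::with_seed(seed, {
    n <- sample(3:max_nodes, 1L)
    adj <- matrix(0L, n, n)
    ut <- which(upper.tri(adj))
    on <- ut[runif(length(ut)) < p]
    adj[on] <- 1L
    adj <- adj + t(adj)
    adj
  })
}

## wrap an adjacency matrix as an igraph graph with stable names
graph_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- as.character(seq_len(nrow(adj)))
  g
}
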