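#' Generate pairs of coupled binary interaction timelines
#'
#' Each pair is drawn as: a master Bernoulli(`occupancy`) series of length
#' `frames`; the partner copies the master frame-by-frame with probability
#' `coupling` and otherwise redraws independently from
#' Bernoulli(`occupancy`). Coupling 1 duplicates the master exactly (so the
#' mutual information equals the master's entropy); coupling 0 gives
#' independent draws (mutual information at the finite-sample bias floor).
#' Fully reproducible for a given seed; the global random state is left
#' untouched.
#'
#' @param n_pairs number of timeline pairs.
#' @param frames frames per timeline.
#' @param coupling per-frame copy probability in `[0, 1]`.
#' @param occupancy Bernoulli rate in (0, 1) (default 0.5, the maximum-
#'   entropy choice that makes coupling easiest to detect).
#' @param seed integer seed.
#' @return list of `n_pairs` lists with elements `x` (master) and `y`.
#' @export
generate_coupled_timelines <- function(n_pairs, frames, coupling,
                                       occupancy = 0.5, seed = 1L) {
  stopifnot(coupling >= 0, coupling <= 1, occupancy > 0, occupancy < 1,
            frames >= 1, n_pairs >= 1)
  withr::with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      x <- stats::rbinom(frames, 1L, occupancy)
      copy <- stats::runif(frames) < coupling
      y <- ifelse(copy, x, stats::rbinom(frames, 1L, occupancy))
      list(x = as.integer(x), y = as.integer(y))
    })
  })
}

#' Generate a ring network with one planted coupled hub node
#'
#' Builds an atom-grain ring of `n_nodes` pseudo-residues (one carbon atom
#' each, so every node has degree 2) whose edges carry independent
#' Bernoulli(`occupancy`) contact timelines -- except the two edges incident
#' to a designated hub node, which are coupled copies of one master timeline
#' (per-frame copy probability `coupling`). The hub is the only node whose
#' adjacent interactions share information, so it should attain the top
#' node-correlation-factor rank when the coupling is detectable.
#'
#' @param n_nodes ring size (>= 4).
#' @param frames timeline length.
#' @param coupling copy probability for the hub's edges.
#' @param occupancy Bernoulli rate for all timelines.
#' @param seed integer seed.
#' @return list with `network` (atom-grain `psn`), `hub` (node id) and
#'   `records`.
#' @export
generate_hub_network <- function(n_nodes = 8L, frames = 2000L,
                                 coupling = 0.8, occupancy = 0.5,
                                 seed = 1L) {
  stopifnot(n_nodes >= 4L)
  ids <- atom_id("A", seq_len(n_nodes), "ALA", "CB")
  hub <- ids[1L]
  withr::with_seed(seed, {
    master <- stats::rbinom(frames, 1L, occupancy)
    couple <- function() {
      copy <- stats::runif(frames) < coupling
      as.integer(ifelse(copy, master, stats::rbinom(frames, 1L, occupancy)))
    }
    timelines <- vector("list", n_nodes)
    for (e in seq_len(n_nodes)) {
      a <- ids[e]
      b <- ids[if (e == n_nodes) 1L else e + 1L]
      coupled <- hub %in% c(a, b)
      timelines[[e]] <- list(
        source = a, target = b,
        timeline = if (coupled) couple()
                   else as.integer(stats::rbinom(frames, 1L, occupancy)))
    }
  })
  records <- timeline_records(
    source = vapply(timelines, `[[`, "", "source"),
    target = vapply(timelines, `[[`, "", "target"),
    type = "contact",
    timeline = lapply(timelines, `[[`, "timeline"))
  list(network = build_network(records, frames), hub = hub, records = records)
}

#' Generate a toy coordinate ensemble with scheduled interactions
#'
#' Builds a small multi-model ensemble of pseudo-residues placed 20 Angstrom
#' apart (far beyond any interaction cutoff) in which two interactions follow
#' a known square-wave schedule with period `switch_period` frames:
#'
#' * a carbon contact between the CB atoms of residues 1 and 2, oscillating
#'   across the 5-Angstrom boundary (4.5 vs 6.5 Angstrom), and
#' * a backbone hydrogen bond from residue 3's N-H to residue 4's O,
#'   oscillating in D-H-A angle (165 vs 120 degrees at fixed 2.9-Angstrom
#'   donor-acceptor distance) across the 135-degree boundary.
#'
#' The true timelines are returned alongside, so extraction can be verified
#' against construction. Geometry is exact, not sampled; `seed` only jitters
#' the uninvolved atoms by a negligible amount to avoid pathological
#' coincidences.
#'
#' @param n_residues number of pseudo-residues (>= 4).
#' @param n_frames ensemble frame count (>= 2).
#' @param switch_period frames per schedule half-period (default 1:
#'   alternate every frame).
#' @param seed integer seed for the coordinate jitter.
#' @return list with `ensemble` (a `structure_ensemble`) and `schedules`
#'   (list with `contact` and `hbond`: each a list of `source`, `target`,
#'   `timeline`).
#' @export
generate_toy_ensemble <- function(n_residues = 4L, n_frames = 6L,
                                  switch_period = 1L, seed = 1L) {
  stopifnot(n_residues >= 4L, n_frames >= 2L, switch_period >= 1L)
  on_phase <- (((seq_len(n_frames) - 1L) %/% switch_period) %% 2L) == 0L

  atoms <- list(); coord0 <- list()
  add_atom <- function(res, name, element, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = "A", residue = as.character(res), resname = "ALA",
      atom = name, element = element, stringsAsFactors = FALSE)
    coord0[[length(coord0) + 1L]] <<- xyz
  }
  for (r in seq_len(n_residues)) {
    x0 <- (r - 1L) * 20
    add_atom(r, "N", "N", c(x0, 1.4, 0))
    add_atom(r, "CA", "C", c(x0, 0, 0))
    add_atom(r, "C", "C", c(x0 + 1.0, -1.0, 0))
    add_atom(r, "O", "O", c(x0 + 1.0, -2.2, 0))
    add_atom(r, "CB", "C", c(x0 + 1.2, 1.1, 0))
    if (r == 3L) add_atom(r, "H", "H", c(x0, 2.4, 0))
  }
  atoms <- do.call(rbind, atoms)
  base <- do.call(rbind, coord0)

  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, n_frames))
  jitter <- withr::with_seed(seed,
    array(stats::runif(length(coords), -0.01, 0.01), dim = dim(coords)))
  for (t in seq_len(n_frames)) coords[, , t] <- base + jitter[, , t]

  arow <- function(res, name) which(atoms$residue == as.character(res) &
                                    atoms$atom == name)
  ## contact pair: CB1 -- CB2 along x
  cb1 <- arow(1L, "CB"); cb2 <- arow(2L, "CB")
  for (t in seq_len(n_frames)) {
    d <- if (on_phase[t]) 4.5 else 6.5
    coords[cb1, , t] <- c(8, 0, 0)
    coords[cb2, , t] <- c(8 + d, 0, 0)
  }
  ## hydrogen bond: N3-H3 ... O4 with controlled D-H-A angle
  n3 <- arow(3L, "N"); h3 <- arow(3L, "H"); o4 <- arow(4L, "O")
  for (t in seq_len(n_frames)) {
    theta <- if (on_phase[t]) 165 else 120
    npos <- c(50, 0, 0)
    hpos <- npos + c(1.0, 0, 0)
    coords[n3, , t] <- npos
    coords[h3, , t] <- hpos
    coords[o4, , t] <- place_acceptor(npos, hpos, angle = theta, dist = 2.9)
  }

  ensemble <- structure(
    list(atoms = transform(atoms, sidechain = !is_backbone_atom(atoms$atom)),
         coords = coords, frames = n_frames, source = "synthetic"),
    class = "structure_ensemble")
  ids <- ensemble_atom_ids(ensemble)
  schedules <- list(
    contact = list(source = ids[cb1], target = ids[cb2],
                   timeline = as.integer(on_phase)),
    hbond = list(source = ids[n3], target = ids[o4],
                 timeline = as.integer(on_phase))
  )
  list(ensemble = ensemble, schedules = schedules)
}

## place an acceptor so that the D-H-A angle is `angle` degrees and the
## donor-acceptor distance is `dist`, in the plane through D and H
place_acceptor <- function(dpos, hpos, angle, dist) {
  u <- hpos - dpos
  blen <- sqrt(sum(u^2))
  u <- u / blen
  ## orthonormal partner of u
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  phi <- (180 - angle) * pi / 180     # direction of H->A relative to +u
  dir <- cos(phi) * u + sin(phi) * v
  ## solve |H + s*dir - D| = dist for s > 0
  ## |b*u + s*dir|^2 = b^2 + 2 b s (u.dir) + s^2
  a <- 1
  b2 <- 2 * blen * sum(u * dir)
  c2 <- blen^2 - dist^2
  s <- (-b2 + sqrt(b2^2 - 4 * a * c2)) / 2
  hpos + s * dir
}
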