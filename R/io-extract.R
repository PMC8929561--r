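#' Extract carbon-contact timelines from a structure ensemble
#'
#' For every pair of selected carbon atoms in different residues, emits a
#' binary timeline with a 1 in each frame where the Euclidean distance is at
#' most `cutoff` Angstrom. Pairs never in contact are omitted. Native and
#' non-native contacts are not distinguished: everything is interaction type
#' `"contact"`. Pairs within the same residue are always excluded; an
#' optional minimum sequence separation can additionally exclude
#' sequence-neighbour residues (off by default).
#'
#' @param ensemble a `structure_ensemble`.
#' @param cutoff contact distance cutoff in Angstrom (default 5).
#' @param selection optional predicate `function(atoms) -> logical` applied
#'   to the atom table to restrict the atom set further (within carbons).
#' @param min_residue_separation minimum |residue index difference| within a
#'   chain for a pair to be considered (default 0 = no exclusion beyond the
#'   same residue).
#' @return timeline-record data.frame (`source`, `target`, `type`,
#'   `timeline`).
#' @export
extract_contacts <- function(ensemble, cutoff = 5, selection = NULL,
                             min_residue_separation = 0L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- ensemble$atoms
  sel <- at$element == "C"
  if (!is.null(selection)) sel <- sel & selection(at)
  if (!any(sel)) stop("empty atom selection: no carbon atoms selected")
  idx <- which(sel)
  ids <- ensemble_atom_ids(ensemble)[idx]
  res_key <- paste(at$chain[idx], at$residue[idx], sep = ":")
  resnum <- suppressWarnings(as.integer(gsub("[^0-9-]", "", at$residue[idx])))

  n <- length(idx)
  if (n < 2L) return(empty_records())
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) seq.int(i + 1L, n)))
  keep <- res_key[pair_i] != res_key[pair_j]
  if (min_residue_separation > 0L) {
    same_chain <- at$chain[idx][pair_i] == at$chain[idx][pair_j]
    sep <- abs(resnum[pair_i] - resnum[pair_j])
    keep <- keep & !(same_chain & !is.na(sep) & sep < min_residue_separation)
  }
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  if (length(pair_i) == 0L) return(empty_records())

  tls <- matrix(0L, nrow = length(pair_i), ncol = ensemble$frames)
  for (t in seq_len(ensemble$frames)) {
    xyz <- ensemble$coords[idx, , t, drop = FALSE]
    dim(xyz) <- c(n, 3L)
    d2 <- (xyz[pair_i, 1L] - xyz[pair_j, 1L])^2 +
          (xyz[pair_i, 2L] - xyz[pair_j, 2L])^2 +
          (xyz[pair_i, 3L] - xyz[pair_j, 3L])^2
    tls[, t] <- as.integer(d2 <= cutoff^2)
  }
  ever <- rowSums(tls) > 0L
  if (!any(ever)) return(empty_records())
  cp <- canonical_pair(ids[pair_i[ever]], ids[pair_j[ever]])
  out <- timeline_records(
    source = cp$source,
    target = cp$target,
    type = "contact",
    timeline = lapply(which(ever), function(r) tls[r, ])
  )
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  out <- data.frame(source = character(), target = character(),
                    type = character(), stringsAsFactors = FALSE)
  out$timeline <- list()
  out
}

## Hydrogen-bond chemistry for the standard amino acids. Donors are N/O/S
## heavy atoms bearing a hydrogen; acceptors are N/O/S with a lone pair.
## Backbone N (except proline) donates; backbone O and terminal OXT accept.
## Unknown residues contribute neither (they still form contacts).
HBOND_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), HIE = "NE2", HID = "ND1",
  SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1", CYS = "SG"
)
HBOND_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  HIE = "ND1", HID = "NE2", MET = "SD", CYS = "SG"
)
STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "HID", "HIE", "HIP", "ILE", "LEU",
                       "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                       "TYR", "VAL")

is_hbond_donor <- function(resname, atom) {
  if (length(resname) == 0L) return(logical(0))
  std <- resname %in% STANDARD_RESIDUES
  backbone_n <- std & atom == "N" & resname != "PRO"
  side <- mapply(function(r, a) a %in% HBOND_DONORS[[r]],
                 resname, atom, USE.NAMES = FALSE)
  backbone_n | (std & as.logical(side))
}

is_hbond_acceptor <- function(resname, atom) {
  if (length(resname) == 0L) return(logical(0))
  std <- resname %in% STANDARD_RESIDUES
  backbone_o <- std & atom %in% c("O", "OXT")
  side <- mapply(function(r, a) a %in% HBOND_ACCEPTORS[[r]],
                 resname, atom, USE.NAMES = FALSE)
  backbone_o | (std & as.logical(side))
}

#' Extract hydrogen-bond timelines from a structure ensemble
#'
#' A hydrogen bond between a donor heavy atom D (N/O/S bearing a hydrogen)
#' and an acceptor heavy atom A (N/O/S with a lone pair, per a built-in
#' chemistry table for the standard amino acids) is present in a frame when
#' the heavy-atom distance d(D, A) is at most `dist_cutoff` and the D-H-A
#' angle of at least one hydrogen bound to D is at least `angle_cutoff`.
#' Pairs within one residue are excluded; pairs never bonded are omitted.
#'
#' When the ensemble contains no hydrogens at all (typical for crystal
#' structures), detection falls back to the distance criterion alone and the
#' returned records carry `approximate = TRUE`; a warning is emitted.
#'
#' @param ensemble a `structure_ensemble`.
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_cutoff donor-hydrogen-acceptor angle cutoff, degrees
#'   (default 135; must lie in (0, 180]).
#' @return timeline-record data.frame with type `"hbond"` and an
#'   `approximate` logical column.
#' @export
extract_hbonds <- function(ensemble, dist_cutoff = 3.5, angle_cutoff = 135) {
  if (dist_cutoff <= 0) stop("dist_cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 180) {
    stop("angle_cutoff must lie in (0, 180] degrees")
  }
  at <- ensemble$atoms
  ids <- ensemble_atom_ids(ensemble)
  res_key <- paste(at$chain, at$residue, sep = ":")

  heavy_ok <- at$element %in% c("N", "O", "S")
  donors <- which(heavy_ok & is_hbond_donor(at$resname, at$atom))
  acceptors <- which(heavy_ok & is_hbond_acceptor(at$resname, at$atom))
  if (length(donors) == 0L || length(acceptors) == 0L) return(empty_records())

  hydrogens <- which(at$element == "H")
  use_angle <- length(hydrogens) > 0L
  if (!use_angle) {
    warning("ensemble contains no hydrogens: falling back to distance-only ",
            "hydrogen-bond detection (records flagged approximate)")
  }

  ## hydrogens attached to each donor: same residue, within 1.25 A in frame 1
  donor_h <- list()
  if (use_angle) {
    xyz1 <- ensemble$coords[, , 1L, drop = FALSE]
    dim(xyz1) <- c(nrow(at), 3L)
    donor_h <- lapply(donors, function(d) {
      hs <- hydrogens[res_key[hydrogens] == res_key[d]]
      if (length(hs) == 0L) return(integer())
      dd <- sqrt(rowSums((xyz1[hs, , drop = FALSE] -
                          matrix(xyz1[d, ], length(hs), 3L, byrow = TRUE))^2))
      hs[dd <= 1.25]
    })
    has_h <- lengths(donor_h) > 0L
    donors <- donors[has_h]
    donor_h <- donor_h[has_h]
    if (length(donors) == 0L) return(empty_records())
  }

  records <- list()
  for (di in seq_along(donors)) {
    d <- donors[di]
    acc <- acceptors[res_key[acceptors] != res_key[d] & acceptors != d]
    if (length(acc) == 0L) next
    tl <- matrix(0L, nrow = length(acc), ncol = ensemble$frames)
    for (t in seq_len(ensemble$frames)) {
      xyz <- ensemble$coords[, , t, drop = FALSE]
      dim(xyz) <- c(nrow(at), 3L)
      dpos <- xyz[d, ]
      dist_da <- sqrt(rowSums((xyz[acc, , drop = FALSE] -
                       matrix(dpos, length(acc), 3L, byrow = TRUE))^2))
      ok <- dist_da <= dist_cutoff
      if (use_angle && any(ok)) {
        for (ai in which(ok)) {
          apos <- xyz[acc[ai], ]
          angles <- vapply(donor_h[[di]], function(h) {
            hpos <- xyz[h, ]
            v1 <- dpos - hpos; v2 <- apos - hpos
            cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          }, 0)
          ok[ai] <- any(angles >= angle_cutoff)
        }
      }
      tl[, t] <- as.integer(ok)
    }
    ever <- rowSums(tl) > 0L
    if (any(ever)) {
      records[[length(records) + 1L]] <- timeline_records(
        source = ids[d], target = ids[acc[ever]], type = "hbond",
        timeline = lapply(which(ever), function(r) tl[r, ]))
    }
  }
  if (length(records) == 0L) return(empty_records())
  out <- do.call(rbind, records)
  ## canonicalise endpoint order; a pair donating in both directions yields
  ## one edge whose timeline is the frame-wise union
  cp <- canonical_pair(out$source, out$target)
  out$source <- cp$source; out$target <- cp$target
  key <- paste(out$source, out$target, sep = "\r")
  if (anyDuplicated(key)) {
    idx <- split(seq_len(nrow(out)), key)
    out <- do.call(rbind, lapply(idx, function(ii) {
      r <- out[ii[1L], , drop = FALSE]
      r$timeline[[1L]] <- as.integer(Reduce(pmax, out$timeline[ii]))
      r
    }))
    rownames(out) <- NULL
  }
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out$approximate <- !use_angle
  out
}
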