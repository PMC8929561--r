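#' Read a (multi-model) PDB file as a structure ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame ensemble. The atom roster (chain, residue,
#' atom name) must be identical across models. Waters are skipped; other
#' `HETATM` records (ligands, peptides) are kept and treated like ordinary
#' residues. Alternate locations other than blank or `A` are skipped.
#'
#' No installed package in this stack reads multi-model PDB, so the parser is
#' local: fixed-column parsing of ATOM/HETATM records per PDB v3, with
#' element inference from the atom-name columns when the element field is
#' blank (common in older files).
#'
#' @param path PDB file.
#' @param first_model_only keep only the first model (the convention used
#'   when a single representative structure is wanted from an NMR-style
#'   multi-model file).
#' @return a `structure_ensemble`: list with `atoms` (data.frame: chain,
#'   residue, resname, atom, element, sidechain), `coords` (array
#'   n_atoms x 3 x frames, Angstrom) and `frames`.
#' @export
read_pdb_ensemble <- function(path, first_model_only = FALSE) {
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(trimws(rec) == "MODEL")
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  if (length(model_starts) == 0L) {
    frames_idx <- list(which(is_atom))
  } else {
    model_ends <- which(trimws(rec) == "ENDMDL")
    if (length(model_ends) < length(model_starts)) {
      model_ends <- c(model_ends, length(lines))
    }
    frames_idx <- lapply(seq_along(model_starts), function(m) {
      span <- seq.int(model_starts[m], model_ends[m])
      span[is_atom[span]]
    })
    frames_idx <- Filter(function(ii) length(ii) > 0L, frames_idx)
  }
  if (first_model_only) frames_idx <- frames_idx[1L]

  parse_frame <- function(ii) {
    ln <- lines[ii]
    atom   <- trimws(substr(ln, 13L, 16L))
    altloc <- substr(ln, 17L, 17L)
    resname <- trimws(substr(ln, 18L, 20L))
    chain  <- trimws(substr(ln, 22L, 22L))
    resnum <- trimws(substr(ln, 23L, 26L))
    icode  <- trimws(substr(ln, 27L, 27L))
    x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
    y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
    z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- ii[which(is.na(x) | is.na(y) | is.na(z))[1L]]
      stop(sprintf("unparseable ATOM record at line %d of %s", bad, path))
    }
    element <- trimws(substr(ln, 77L, 78L))
    keep <- (altloc == " " | altloc == "A") & resname != "HOH"
    data.frame(chain = chain, residue = paste0(resnum, icode),
               resname = resname, atom = atom,
               element = element, x = x, y = y, z = z,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }

  frames <- lapply(frames_idx, parse_frame)
  roster <- function(f) paste(f$chain, f$residue, f$resname, f$atom, sep = ":")
  ref <- roster(frames[[1L]])
  if (anyDuplicated(ref)) {
    stop("duplicate atom in model 1: ", ref[duplicated(ref)][1L])
  }
  for (m in seq_along(frames)[-1L]) {
    r <- roster(frames[[m]])
    if (!identical(r, ref)) {
      mism <- if (length(r) != length(ref)) {
        sprintf("model %d has %d atoms, model 1 has %d", m, length(r), length(ref))
      } else {
        sprintf("model %d atom %s differs from model 1 atom %s",
                m, r[which(r != ref)[1L]], ref[which(r != ref)[1L]])
      }
      stop("inconsistent atom rosters: ", mism)
    }
  }

  atoms <- frames[[1L]][, c("chain", "residue", "resname", "atom", "element")]
  atoms$element <- infer_element(atoms$element, atoms$atom)
  atoms$sidechain <- !is_backbone_atom(atoms$atom)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, length(frames)))
  for (m in seq_along(frames)) {
    coords[, , m] <- as.matrix(frames[[m]][, c("x", "y", "z")])
  }
  structure(list(atoms = atoms, coords = coords, frames = length(frames),
                 source = path),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure ensemble: %d atoms, %d frame%s>\n",
              nrow(x$atoms), x$frames, if (x$frames == 1L) "" else "s"))
  invisible(x)
}

TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "CA",
                         "BR", "SE", "NI", "CO", "CD", "HG")

infer_element <- function(element, atom) {
  blank <- is.na(element) | element == ""
  out <- toupper(element)
  guess <- function(name) {
    stripped <- gsub("[0-9']", "", toupper(name))
    # PDB v3 amino-acid names put the element in the first character once
    # digits are stripped (remote-position letters like G in "CG" follow it)
    if (nchar(stripped) == 0L) return("")
    if (nchar(name) == 4L && substr(name, 1L, 1L) %in% c("H", "1", "2", "3")) {
      return("H")
    }
    two <- substr(stripped, 1L, 2L)
    if (two %in% TWO_LETTER_ELEMENTS && !(substr(stripped, 1L, 1L) %in%
          c("C", "N", "O", "H", "S", "P") && nchar(name) <= 3L)) {
      return(two)
    }
    substr(stripped, 1L, 1L)
  }
  out[blank] <- vapply(atom[blank], guess, "")
  # normalise case: "Fe" style for two-letter symbols
  long <- nchar(out) == 2L
  out[long] <- paste0(substr(out[long], 1L, 1L),
                      tolower(substr(out[long], 2L, 2L)))
  out
}

ensemble_atom_ids <- function(ensemble) {
  with(ensemble$atoms, atom_id(chain, residue, resname, atom))
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' Minimal writer used for generated fixtures; one `MODEL` block per frame.
#'
#' @param ensemble a `structure_ensemble`.
#' @param path output file.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- ensemble$atoms
  for (m in seq_len(ensemble$frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(a))) {
      name <- a$atom[i]
      name_field <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4s    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, name_field, a$resname[i],
        ifelse(a$chain[i] == "", " ", a$chain[i]),
        a$residue[i],
        ensemble$coords[i, 1L, m], ensemble$coords[i, 2L, m],
        ensemble$coords[i, 3L, m], toupper(a$element[i])), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}
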