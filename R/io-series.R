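#' Parse MD-analysis interaction time series into timeline records
#'
#' Reads whitespace-separated per-frame time-series files of the kind written
#' by trajectory analysis tools: a header row beginning with `#Frame` whose
#' remaining tokens name one interaction each, followed by one row per frame
#' (frame index, then one value per interaction column).
#'
#' Two header-token shapes are understood:
#' \describe{
#'   \item{`RES_4@OD1-RES_2@NH1` or `...-HH11`}{underscore/at-sign atom
#'     specs. A third `-`-separated part (the hydrogen of a hydrogen bond)
#'     is accepted and dropped; the record joins the two heavy atoms. The
#'     chain is not encoded in this shape and is taken from `chain`.}
#'   \item{`A:4:ASP:OD1-A:2:ARG:NH1`}{this package's colon identifiers.}
#' }
#'
#' Columns naming the same atom pair (e.g. native and non-native contact
#' series for one pair, or several hydrogens of one donor-acceptor pair) are
#' merged by the frame-wise union (element-wise maximum).
#'
#' @param paths one or more series files; all must have the same frame count.
#' @param dialect `"hbond-series"` (records typed `"hbond"`) or
#'   `"contacts-series"` (records typed `"contact"`).
#' @param chain chain identifier to assume for underscore-style tokens
#'   (default `"A"`).
#' @return timeline-record data.frame.
#' @export
parse_timeseries <- function(paths, dialect = c("contacts-series", "hbond-series"),
                             chain = "A") {
  dialect <- match.arg(dialect)
  type <- if (dialect == "hbond-series") "hbond" else "contact"
  all_records <- lapply(paths, parse_series_file, type = type, chain = chain)
  frames <- vapply(all_records, function(r) attr(r, "frames"), 0L)
  if (length(unique(frames)) > 1L) {
    stop("series files disagree on frame count: ",
         paste(unique(frames), collapse = " vs "))
  }
  out <- do.call(rbind, all_records)
  merge_duplicate_records(out)
}

parse_series_file <- function(path, type, chain) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("series file too short: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (!grepl("^#?Frame$", header[1L], ignore.case = TRUE)) {
    stop("series header must start with '#Frame': ", path)
  }
  tokens <- header[-1L]
  pairs <- lapply(tokens, parse_series_token, chain = chain)

  n_cols <- length(tokens) + 1L
  values <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = length(tokens))
  for (r in seq.int(2L, length(lines))) {
    fields <- strsplit(trimws(lines[r]), "\\s+")[[1L]]
    if (length(fields) != n_cols) {
      stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                   r - 1L, path, length(fields), n_cols))
    }
    values[r - 1L, ] <- as.numeric(fields[-1L])
  }
  frames <- nrow(values)
  rec <- timeline_records(
    source = vapply(pairs, `[[`, "", 1L),
    target = vapply(pairs, `[[`, "", 2L),
    type = type,
    timeline = lapply(seq_along(tokens), function(c) as.integer(values[, c]))
  )
  attr(rec, "frames") <- frames
  rec
}

parse_series_token <- function(token, chain) {
  parts <- strsplit(token, "-", fixed = TRUE)[[1L]]
  if (length(parts) == 3L) parts <- parts[1:2]   # drop the hydrogen part
  if (length(parts) != 2L) stop("unparseable series header token: ", token)
  vapply(parts, function(p) {
    if (grepl("@", p, fixed = TRUE)) {
      ra <- strsplit(p, "@", fixed = TRUE)[[1L]]
      rn <- strsplit(ra[1L], "_", fixed = TRUE)[[1L]]
      if (length(ra) != 2L || length(rn) != 2L) {
        stop("unparseable series header token: ", token)
      }
      atom_id(chain, rn[2L], rn[1L], ra[2L])
    } else if (grepl(":", p, fixed = TRUE)) {
      if (length(strsplit(p, ":", fixed = TRUE)[[1L]]) != 4L) {
        stop("unparseable series header token: ", token)
      }
      p
    } else {
      stop("unparseable series header token: ", token)
    }
  }, "")
}

merge_duplicate_records <- function(records) {
  cp <- canonical_pair(records$source, records$target)
  records$source <- cp$source
  records$target <- cp$target
  key <- paste(records$source, records$target, records$type, sep = "\r")
  if (!anyDuplicated(key)) {
    rownames(records) <- NULL
    return(records)
  }
  idx <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(idx, function(ii) {
    r <- records[ii[1L], , drop = FALSE]
    r$timeline[[1L]] <- as.integer(Reduce(pmax, records$timeline[ii]))
    r
  }))
  rownames(out) <- NULL
  out
}
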