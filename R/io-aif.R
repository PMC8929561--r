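#' Read and write the interaction-timeline text format
#'
#' A line-oriented exchange format for lists of interaction timelines,
#' designed to be created and inspected with a text editor. The grammar:
#'
#' ```
#' #AIF 1
#' #FRAMES <T>
#' <sourceAtom>\t<targetAtom>\t<type>\t<v1,v2,...,vT>
#' ...
#' ```
#'
#' Two header lines declare the format version (currently 1) and the frame
#' count; every following non-comment line is one record with tab-separated
#' fields: the two atom identifiers (`chain:residue:resname:atom`), the
#' interaction type, and the comma-separated per-frame counts, whose number
#' must equal the declared frame count. Round trips are lossless.
#'
#' @param records timeline-record data.frame (non-empty).
#' @param path file path.
#' @param frames frame count; defaults to the length of the first timeline.
#' @return `read_aif` returns a timeline-record data.frame with attribute
#'   `frames`; `write_aif` returns `path` invisibly.
#' @name aif
NULL

#' @rdname aif
#' @export
write_aif <- function(records, path, frames = NULL) {
  records <- as_timeline_records(records)
  if (nrow(records) == 0L) stop("refusing to write an empty record list")
  if (is.null(frames)) frames <- length(records$timeline[[1L]])
  lens <- lengths(records$timeline)
  if (any(lens != frames)) {
    bad <- which(lens != frames)[1L]
    stop(sprintf("record %s -- %s: timeline length %d does not match frame count %d",
                 records$source[bad], records$target[bad], lens[bad], frames))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#AIF\t1", sprintf("#FRAMES\t%d", frames)), con)
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(records$source[i], records$target[i], records$type[i],
          paste(records$timeline[[i]], collapse = ","), sep = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname aif
#' @export
read_aif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("truncated interaction-timeline file: ", path)
  h1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(h1) != 2L || h1[1L] != "#AIF" || h1[2L] != "1") {
    stop("unsupported format version header: ", lines[1L])
  }
  h2 <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (length(h2) != 2L || h2[1L] != "#FRAMES") {
    stop("missing #FRAMES header in ", path)
  }
  frames <- as.integer(h2[2L])
  if (is.na(frames) || frames < 1L) stop("invalid frame count: ", h2[2L])

  body <- lines[-(1:2)]
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed record line %d: %s", bad[1L] + 2L, body[bad[1L]]))
  }
  source <- vapply(fields, `[`, "", 1L)
  target <- vapply(fields, `[`, "", 2L)
  type   <- vapply(fields, `[`, "", 3L)
  timeline <- lapply(seq_along(fields), function(i) {
    v <- as.integer(strsplit(fields[[i]][4L], ",", fixed = TRUE)[[1L]])
    if (anyNA(v)) {
      stop(sprintf("non-integer timeline value in record %s -- %s",
                   source[i], target[i]))
    }
    if (length(v) != frames) {
      stop(sprintf("record %s -- %s: timeline length %d does not match declared frame count %d",
                   source[i], target[i], length(v), frames))
    }
    v
  })
  rec <- timeline_records(source, target, type, timeline)
  attr(rec, "frames") <- frames
  rec
}
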