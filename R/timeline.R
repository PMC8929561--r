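#' Validate an interaction timeline
#'
#' A timeline is a vector of non-negative integer interaction counts, one per
#' frame of a structure ensemble. Atom-level timelines are binary (an
#' interaction is present or absent in a frame); residue-level timelines are
#' small non-negative counts obtained by summing atomic timelines.
#'
#' @param x numeric vector of per-frame counts.
#' @param frames expected length, or `NULL` to accept any length >= 1.
#' @return the timeline as an integer vector, invisibly checked.
#' @keywords internal
check_timeline <- function(x, frames = NULL) {
  if (length(x) < 1L) stop("timeline must contain at least one frame")
  if (anyNA(x)) stop("timeline contains missing values")
  if (any(x < 0)) stop("timeline contains negative counts")
  if (any(x != round(x))) stop("timeline counts must be integers")
  if (!is.null(frames) && length(x) != frames) {
    stop(sprintf("timeline length %d does not match frame count %d",
                 length(x), frames))
  }
  as.integer(x)
}

#' Shannon entropy of a timeline's state histogram
#'
#' Plug-in (maximum-likelihood) estimate over the distinct observed counts,
#' in bits. This is the same marginal entropy that enters the
#' mutual-information scores, computed from the same histogram.
#'
#' @param x timeline (vector of non-negative counts).
#' @return entropy in bits (>= 0).
#' @examples
#' timeline_entropy(c(0, 1, 0, 1)) # 1 bit
#' timeline_entropy(c(0, 0, 0, 0)) # 0 bits
#' @export
timeline_entropy <- function(x) {
  p <- tabulate(match(x, unique(x)))
  p <- p / length(x)
  -sum(p * log2(p))
}

#' Mean lifetime of contiguous interaction runs
#'
#' Mean length, in frames, of maximal runs of consecutive frames in which the
#' interaction is present (count > 0). `NA` when the interaction never occurs.
#'
#' @param x timeline.
#' @return mean run length in frames, or `NA_real_`.
#' @export
timeline_lifetime <- function(x) {
  r <- rle(x > 0)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) return(NA_real_)
  mean(runs)
}

#' Autocorrelation of a timeline at a fixed lag
#'
#' Pearson correlation between the timeline and its copy shifted by `lag`
#' frames, i.e. `cor(x[1:(T-lag)], x[(1+lag):T])`. Undefined (returned as
#' `NA`) when either window is constant.
#'
#' @param x timeline.
#' @param lag lag in frames, `0 <= lag < length(x)`.
#' @return correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
timeline_autocorrelation <- function(x, lag = 1L) {
  n <- length(x)
  if (lag < 0L || lag >= n) stop("lag must satisfy 0 <= lag < length(x)")
  a <- x[seq_len(n - lag)]
  b <- x[seq.int(1L + lag, n)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Summarise a timeline
#'
#' Descriptive statistics for one interaction timeline: mean value (for a
#' binary timeline this is the occupancy, the fraction of frames in which the
#' interaction is present), Shannon entropy of the state histogram, mean
#' lifetime of contiguous runs, and autocorrelation at a given lag.
#'
#' @param x timeline.
#' @param lag lag in frames for the autocorrelation (default 1).
#' @return a one-row data.frame with columns `mean`, `occupancy`, `entropy`,
#'   `lifetime`, `autocorrelation`.
#' @examples
#' summarize_timeline(c(1, 1, 0, 0), lag = 1)
#' @export
summarize_timeline <- function(x, lag = 1L) {
  x <- check_timeline(x)
  data.frame(
    mean            = mean(x),
    occupancy       = mean(x > 0),
    entropy         = timeline_entropy(x),
    lifetime        = timeline_lifetime(x),
    autocorrelation = timeline_autocorrelation(x, lag)
  )
}

#' Occupancy of a timeline
#'
#' Fraction of frames in which the interaction is present (count > 0). This
#' is the quantity used by occupancy-based edge filtering.
#'
#' @param x timeline.
#' @return fraction in `[0, 1]`.
#' @export
timeline_occupancy <- function(x) mean(x > 0)
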