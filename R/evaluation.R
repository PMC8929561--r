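#' Construct a binary reference label set
#'
#' Residue-level binary labels (1 = allosteric, 0 = non-allosteric) keyed by
#' residue identifier (`chain:residue:resname`).
#'
#' @param ids residue identifiers.
#' @param labels 0/1 labels, same length.
#' @return named integer vector.
#' @export
reference_set <- function(ids, labels) {
  if (length(ids) != length(labels)) stop("ids and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (anyDuplicated(ids)) stop("duplicate residue id: ", ids[duplicated(ids)][1L])
  stats::setNames(as.integer(labels), ids)
}

#' Read a tab-separated reference label table
#'
#' Expects columns `id` and `label`.
#'
#' @param path file path.
#' @return named integer vector as from [reference_set()].
#' @export
read_reference_set <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  reference_set(tab$id, tab$label)
}

#' Exclude a residue type from a reference set
#'
#' Produces the label-set variant with all residues of the given type
#' removed (e.g. alanines, which some prediction methods cannot score).
#' Residue types are resolved from the identifier's `resname` field.
#'
#' @param labels named label vector from [reference_set()].
#' @param exclude residue name(s) to drop, e.g. `"ALA"`.
#' @return filtered named label vector.
#' @export
make_variant <- function(labels, exclude) {
  resname <- vapply(strsplit(names(labels), ":", fixed = TRUE),
                    function(p) p[min(3L, length(p))], "")
  labels[!(resname %in% exclude)]
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Evaluate a residue score table against binary reference labels
#'
#' Sweeps the decision threshold over all distinct score values (a residue is
#' predicted allosteric when its score is >= the threshold; tied scores enter
#' together), builds the ROC curve (false positive rate vs true positive
#' rate) and the precision-recall curve, and integrates both areas by the
#' trapezoidal rule. Higher scores are assumed to mean "more likely
#' allosteric". The ROC curve is anchored at (0, 0); the PR curve is anchored
#' at recall 0 with the precision of the highest threshold (no extrapolated
#' precision). Residues scored but not labelled are ignored; labelled
#' residues without a score are an error.
#'
#' @param scores named numeric vector, residue id -> score.
#' @param labels named 0/1 vector from [reference_set()].
#' @return list with `rocAUC`, `prAUC`, `roc` (data.frame: threshold, FPR,
#'   TPR) and `pr` (data.frame: threshold, recall, precision).
#' @examples
#' labels <- reference_set(c("A:1:VAL", "A:2:ALA"), c(1, 0))
#' evaluate_scores(c("A:1:VAL" = 0.9, "A:2:ALA" = 0.1), labels)$rocAUC # 1
#' @export
evaluate_scores <- function(scores, labels) {
  missing <- setdiff(names(labels), names(scores))
  if (length(missing) > 0L) {
    stop("labelled residues without a score: ", paste(missing, collapse = ", "))
  }
  s <- unname(scores[names(labels)])
  y <- unname(labels)
  pos <- sum(y == 1L); neg <- sum(y == 0L)
  if (pos == 0L || neg == 0L) {
    stop("labels must contain at least one positive and one negative")
  }
  thresholds <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thresholds, function(th) sum(y == 1L & s >= th), 0L)
  fp <- vapply(thresholds, function(th) sum(y == 0L & s >= th), 0L)
  tpr <- tp / pos
  fpr <- fp / neg
  precision <- tp / (tp + fp)
  roc <- data.frame(threshold = c(Inf, thresholds),
                    FPR = c(0, fpr), TPR = c(0, tpr))
  pr <- data.frame(threshold = c(Inf, thresholds),
                   recall = c(0, tpr),
                   precision = c(precision[1L], precision))
  list(rocAUC = trapezoid_area(roc$FPR, roc$TPR),
       prAUC = trapezoid_area(pr$recall, pr$precision),
       roc = roc, pr = pr)
}

#' Threshold closest to the top-left ROC corner
#'
#' Returns the score threshold whose ROC point minimises the Euclidean
#' distance to the ideal corner (FPR 0, TPR 1); ties are broken toward the
#' higher (more conservative) threshold.
#'
#' @param roc ROC data.frame from [evaluate_scores()] (columns `threshold`,
#'   `FPR`, `TPR`), with at least two points.
#' @return list with `threshold`, `FPR`, `TPR`, `distance`.
#' @export
optimal_threshold <- function(roc) {
  if (nrow(roc) < 2L) stop("ROC curve needs at least two points")
  d <- sqrt(roc$FPR^2 + (1 - roc$TPR)^2)
  best <- which(d == min(d))
  best <- best[which.max(roc$threshold[best])]
  list(threshold = roc$threshold[best], FPR = roc$FPR[best],
       TPR = roc$TPR[best], distance = d[best])
}

#' Parameter grid for network-construction benchmarking
#'
#' Enumerates the standard benchmark grid: contact distance cutoff, the
#' interaction subset (all interactions or sidechain-exclusive), and the
#' structure source. The default grid has 6 x 2 x 4 = 48 combinations.
#'
#' @param cutoffs contact cutoffs in Angstrom.
#' @param subsets interaction subsets.
#' @param sources structure sources.
#' @return data.frame with one row per configuration.
#' @export
grid_configs <- function(cutoffs = 4:9,
                         subsets = c("all", "sidechain"),
                         sources = c("apo", "pep", "apo-NMR", "pep-NMR")) {
  expand.grid(cutoff = cutoffs, subset = subsets, source = sources,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Evaluate residue scores over a parameter grid
#'
#' Runs [evaluate_scores()] for each configuration's score table and collects
#' rocAUC/prAUC into one table. Configurations whose scores are missing or
#' whose evaluation fails are flagged (`ok = FALSE`) rather than dropped.
#'
#' @param configs data.frame of configurations (e.g. from [grid_configs()]).
#' @param scores_by_config list of named score vectors, parallel to the rows
#'   of `configs`; `NULL` entries mark missing configurations.
#' @param labels reference label vector.
#' @return `configs` with columns `rocAUC`, `prAUC`, `ok` appended.
#' @export
grid_search <- function(configs, scores_by_config, labels) {
  if (length(scores_by_config) != nrow(configs)) {
    stop("need one score table (or NULL) per configuration")
  }
  out <- configs
  out$rocAUC <- NA_real_
  out$prAUC <- NA_real_
  out$ok <- FALSE
  for (i in seq_len(nrow(configs))) {
    sc <- scores_by_config[[i]]
    if (is.null(sc)) next
    ev <- tryCatch(evaluate_scores(sc, labels), error = function(e) NULL)
    if (is.null(ev)) next
    out$rocAUC[i] <- ev$rocAUC
    out$prAUC[i] <- ev$prAUC
    out$ok[i] <- TRUE
  }
  out
}

#' Grouped summary of grid-search results
#'
#' Mean and standard deviation of rocAUC within groups of one grid variable
#' (cutoff, subset or source).
#'
#' @param results output of [grid_search()].
#' @param by name of the grouping column.
#' @return data.frame with columns `by`, `n`, `mean_rocAUC`, `sd_rocAUC`.
#' @export
grid_summary <- function(results, by) {
  groups <- split(results$rocAUC[results$ok], results[[by]][results$ok])
  out <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean_rocAUC = vapply(groups, mean, 0),
    sd_rocAUC = vapply(groups, function(x)
      if (length(x) > 1L) stats::sd(x) else 0, 0)
  )
  names(out)[1L] <- by
  rownames(out) <- NULL
  out
}
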