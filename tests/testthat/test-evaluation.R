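mk_labels <- function(labels, resnames = NULL) {
  n <- length(labels)
  if (is.null(resnames)) resnames <- rep("VAL", n)
  reference_set(sprintf("A:%d:%s", seq_len(n), resnames), labels)
}

test_that("evaluate_scores handles perfect, inverted and tied rankings", {
  lab <- mk_labels(c(1, 0))
  perfect <- setNames(c(0.9, 0.1), names(lab))
  expect_equal(evaluate_scores(perfect, lab)$rocAUC, 1.0)
  inverted <- setNames(c(0.1, 0.9), names(lab))
  expect_equal(evaluate_scores(inverted, lab)$rocAUC, 0.0)

  # ties enter the sweep together
  lab4 <- mk_labels(c(1, 1, 0, 0))
  tied <- setNames(c(2, 1, 1, 0), names(lab4))
  ev <- evaluate_scores(tied, lab4)
  expect_equal(nrow(ev$roc), 4L)   # anchor + three distinct thresholds

  expect_error(evaluate_scores(perfect, mk_labels(c(1, 1))),
               "positive and one negative")
  expect_error(evaluate_scores(perfect[1], lab), "without a score")
})

test_that("trapezoidal rocAUC equals the rank-statistic oracle", {
  for (seed in 1:20) {
    dat <- withr::with_seed(seed, {
      n <- sample(8:20, 1)
      list(labels = mk_labels(c(1, rbinom(n - 2, 1, 0.4), 0)),
           scores = runif(n))
    })
    scores <- setNames(dat$scores, names(dat$labels))  # tie-free
    expect_equal(evaluate_scores(scores, dat$labels)$rocAUC,
                 auc_rank_oracle(scores, dat$labels), tolerance = 1e-12)
  }
})

test_that("rocAUC is invariant under strictly monotone score transforms", {
  lab <- mk_labels(c(1, 0, 1, 0, 1, 0, 0, 1, 0, 0))
  scores <- setNames(withr::with_seed(5, runif(10)), names(lab))
  base <- evaluate_scores(scores, lab)
  for (f in list(function(x) 10 * x - 3, exp, function(x) x^3)) {
    tr <- evaluate_scores(setNames(f(scores), names(scores)), lab)
    expect_equal(tr$rocAUC, base$rocAUC)
    expect_equal(tr$prAUC, base$prAUC)
  }
})

test_that("rocAUC of random rankings centres on 0.5 and negation complements", {
  aucs <- vapply(1:200, function(seed) {
    lab <- mk_labels(rep(c(1, 0), each = 10))
    scores <- setNames(withr::with_seed(seed, runif(20)), names(lab))
    evaluate_scores(scores, lab)$rocAUC
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)

  lab <- mk_labels(c(1, 0, 1, 0, 0, 1, 0, 0))
  scores <- setNames(withr::with_seed(3, runif(8)), names(lab))
  expect_equal(evaluate_scores(scores, lab)$rocAUC +
               evaluate_scores(setNames(-scores, names(scores)), lab)$rocAUC,
               1.0)
})

test_that("optimal_threshold picks the point nearest the top-left corner", {
  roc <- data.frame(threshold = c(Inf, 5, 1),
                    FPR = c(0, 0.11, 1), TPR = c(0, 0.75, 1))
  # distances: 1 vs sqrt(0.11^2 + 0.25^2) = 0.273 vs 1
  best <- optimal_threshold(roc)
  expect_equal(best$threshold, 5)
  expect_equal(best$TPR, 0.75)

  perfect <- data.frame(threshold = c(Inf, 2, 1),
                        FPR = c(0, 0, 1), TPR = c(0, 1, 1))
  expect_equal(optimal_threshold(perfect)$threshold, 2)

  # equidistant points: the higher threshold wins
  ties <- data.frame(threshold = c(Inf, 4, 2),
                     FPR = c(0, 0.3, 0.4), TPR = c(0, 0.6, 0.7))
  d <- sqrt(ties$FPR^2 + (1 - ties$TPR)^2)
  expect_equal(d[2], d[3])
  expect_equal(optimal_threshold(ties)$threshold, 4)
})

test_that("make_variant filters residues by type", {
  lab <- mk_labels(c(1, 0, 1, 0, 1),
                   resnames = c("ALA", "VAL", "ALA", "LEU", "ILE"))
  out <- make_variant(lab, "ALA")
  expect_equal(length(out), 3L)
  expect_false(any(grepl(":ALA$", names(out))))
  expect_identical(make_variant(lab, "TRP"), lab)  # absent type: identity
  # excluding everything leaves a single-class set that evaluate rejects
  only_neg <- make_variant(lab, c("ALA", "ILE"))
  expect_error(evaluate_scores(setNames(seq_along(only_neg), names(only_neg)),
                               only_neg), "positive and one negative")
})

test_that("grid enumeration and search keep every configuration accounted for", {
  grid <- grid_configs()
  expect_equal(nrow(grid), 48L)
  expect_equal(nrow(unique(grid)), 48L)

  lab <- mk_labels(c(1, 0, 1, 0))
  good <- setNames(c(4, 1, 3, 2), names(lab))
  scores <- rep(list(good), nrow(grid))
  scores[7] <- list(NULL)                  # one missing configuration
  res <- grid_search(grid, scores, lab)
  expect_equal(nrow(res), 48L)
  expect_false(res$ok[7])
  expect_true(all(res$ok[-7]))
  expect_true(all(res$rocAUC[res$ok] == 1))

  # grouped mean over identical AUCs: that value with zero spread
  summ <- grid_summary(res, "cutoff")
  expect_true(all(summ$mean_rocAUC == 1))
  expect_true(all(summ$sd_rocAUC == 0))

  single <- grid_search(grid[1, , drop = FALSE], list(good), lab)
  expect_equal(nrow(single), 1L)
})

test_that("reference-set constructors validate and round-trip", {
  expect_error(reference_set(c("a", "a"), c(1, 0)), "duplicate")
  expect_error(reference_set("a", 2), "binary")
  lab <- mk_labels(c(1, 0, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(id = names(lab), label = unname(lab)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_reference_set(path), lab)
})
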