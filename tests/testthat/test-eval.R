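test_that("group tokens separate routine, pig-wise and stall recordings", {
  man <- fixtureManifest()
  tok <- assignGroups(man)
  r <- manifestRecords(man)
  same <- which(!r$close_range)
  a <- same[1]
  b <- same[which(r$pen_id[same] == r$pen_id[a] & r$date[same] == r$date[a] &
                  r$session[same] == r$session[a])]
  expect_true(all(tok[b] == tok[a]))
  cr <- which(r$close_range)
  expect_true(all(startsWith(tok[cr], "pig:")))
  # all close-range coughs from one pig share one token across dates
  onePig <- cr[r$pig_id[cr] == r$pig_id[cr[1]]]
  expect_equal(length(unique(tok[onePig])), 1)
  # routine vs close-range cough from different sources: different tokens
  routineCough <- which(r$label == "cough" & !r$close_range)
  expect_false(any(tok[routineCough] %in% tok[cr]))
})

test_that("degenerate singleton groups split exactly 80/10/10", {
  rec <- data.frame(
    id = sprintf("s%03d", 1:100), label = rep(pigClasses(), each = 20),
    pen_id = sprintf("p%03d", 1:100), date = "d01", session = "morning",
    pig_id = NA_character_, close_range = FALSE, event_seed = 1:100,
    bg_gain_db = 0, stringsAsFactors = FALSE)
  man <- new("BarnManifest", records = rec, seed = 1L, config = list())
  split <- groupedHoldoutSplit(man, seed = 3)
  expect_equal(as.vector(table(split)[c("train", "val", "test")]),
               c(80, 10, 10))
  assertNoLeakage(man, split)
})

test_that("group allocation error is bounded by one group size", {
  # 10 groups of 10 samples, one class: each partition within a group of target
  rec <- data.frame(
    id = sprintf("s%03d", 1:100), label = "cough",
    pen_id = rep(sprintf("p%02d", 1:10), each = 10), date = "d01",
    session = "morning", pig_id = NA_character_, close_range = FALSE,
    event_seed = 1:100, bg_gain_db = 0, stringsAsFactors = FALSE)
  man <- new("BarnManifest", records = rec, seed = 1L, config = list())
  split <- groupedHoldoutSplit(man, seed = 5)
  counts <- table(factor(split, c("train", "val", "test")))
  expect_lte(abs(counts[["train"]] - 80), 10)
  expect_lte(abs(counts[["val"]] - 10), 10)
  expect_lte(abs(counts[["test"]] - 10), 10)
  expect_equal(sum(counts), 100)
})

test_that("too few groups make the holdout split infeasible", {
  rec <- data.frame(
    id = c("a", "b"), label = "cough", pen_id = c("p1", "p2"), date = "d01",
    session = "morning", pig_id = NA_character_, close_range = FALSE,
    event_seed = 1:2, bg_gain_db = 0, stringsAsFactors = FALSE)
  man <- new("BarnManifest", records = rec, seed = 1L, config = list())
  expect_error(groupedHoldoutSplit(man), "infeasible")
})

test_that("grouped k-fold partitions samples exhaustively and disjointly", {
  man <- fixtureManifest()
  folds <- groupedKfold(man, k = 5, seed = 2)
  r <- manifestRecords(man)
  expect_setequal(names(folds), r$id)
  expect_true(all(folds %in% 1:5))
  assertNoLeakage(man, folds)
  tok <- assignGroups(man)
  maxGroup <- max(table(tok))
  expect_lte(diff(range(table(folds))), maxGroup)
})

test_that("five equal singleton-class groups give one group per fold", {
  rec <- data.frame(
    id = sprintf("s%02d", 1:25), label = rep(pigClasses(), 5),
    pen_id = rep(sprintf("p%d", 1:5), each = 5), date = "d01",
    session = "morning", pig_id = NA_character_, close_range = FALSE,
    event_seed = 1:25, bg_gain_db = 0, stringsAsFactors = FALSE)
  man <- new("BarnManifest", records = rec, seed = 1L, config = list())
  folds <- groupedKfold(man, k = 5, seed = 1)
  expect_true(all(table(folds) == 5))
  tok <- assignGroups(man)
  expect_true(all(tapply(folds, tok, function(x) length(unique(x))) == 1))
  expect_error(groupedKfold(man, k = 6), "fewer groups")
})

test_that("LOSO produces three leakage-free session splits", {
  man <- fixtureManifest()
  splits <- losoBySession(man)
  expect_setequal(names(splits), c("morning", "noon", "evening"))
  r <- manifestRecords(man)
  for (s in names(splits)) {
    part <- splits[[s]][r$id]
    expect_true(all(part[r$session == s] == "test"))
    expect_true(all(part[r$session != s] %in% c("train", "val")))
    assertNoLeakage(man, splits[[s]])
    valFrac <- mean(part[r$session != s] == "val")
    # group-level allocation approximates the configured 1/9 ratio
    expect_gt(valFrac, 0.02)
    expect_lt(valFrac, 0.3)
  }
})

test_that("metrics match a brute-force tally on the printed toy confusion", {
  # counts [[5,1,0],[0,4,2],[1,0,7]] over three classes
  cls <- pigClasses()[1:3]
  yTrue <- rep(cls, times = c(6, 6, 8))
  yPred <- c(rep(cls[1], 5), cls[2],
             rep(cls[2], 4), rep(cls[3], 2),
             cls[1], rep(cls[3], 7))
  expect_warning(m <- computeMetrics(yTrue, yPred), "absent")
  bf <- bruteForceMetrics(yTrue, yPred)
  expect_equal(m$accuracy, bf$accuracy)
  expect_equal(m$macro_precision, bf$macro_precision)
  expect_equal(m$macro_recall, bf$macro_recall)
  expect_equal(m$macro_f1, bf$macro_f1)
  expect_equal(unname(m$confusion[1:3, 1:3]),
               rbind(c(5L, 1L, 0L), c(0L, 4L, 2L), c(1L, 0L, 7L)))
})

test_that("perfect predictions score 100 percent everywhere", {
  y <- rep(pigClasses(), each = 4)
  sc <- diag(5)[match(y, pigClasses()), ]
  colnames(sc) <- pigClasses()
  m <- computeMetrics(y, y, sc)
  expect_equal(m$accuracy, 100)
  expect_equal(m$macro_f1, 100)
  expect_equal(m$macro_auroc, 1)
})

test_that("metrics equal the brute-force tally on random label vectors", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(2:50, 1)
    yTrue <- sample(pigClasses(), n, replace = TRUE)
    yPred <- sample(pigClasses(), n, replace = TRUE)
    m <- suppressWarnings(computeMetrics(yTrue, yPred))
    bf <- bruteForceMetrics(yTrue, yPred)
    expect_equal(m$macro_f1, bf$macro_f1, tolerance = 1e-12)
    expect_equal(m$macro_precision, bf$macro_precision, tolerance = 1e-12)
    expect_equal(m$accuracy, bf$accuracy, tolerance = 1e-12)
  }
})

test_that("AUROC is 1 for separated scores, 0.5 for interleaved, and is rank-invariant", {
  pos <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(rankAuroc(c(4, 3.5, 3, 2.9, 2, 1, 0.5, 0), pos), 1)
  # fully interleaved ranks: positives at ranks 8,5,4,1 give 8/16 pairs
  expect_equal(rankAuroc(c(8, 5, 4, 1, 7, 6, 3, 2), pos), 0.5)
  set.seed(21)
  sc <- stats::runif(30)
  lab <- stats::runif(30) > 0.5
  a1 <- rankAuroc(sc, lab)
  expect_equal(rankAuroc(exp(5 * sc), lab), a1)
  expect_equal(rankAuroc(rank(sc), lab), a1)
})

test_that("rank AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  sc <- stats::rnorm(40)
  lab <- stats::rbinom(40, 1, 0.4) == 1
  expect_equal(rankAuroc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              levels = c(FALSE, TRUE),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("out-of-fold confusion is complete, normalized and fold-order invariant", {
  set.seed(23)
  ids <- sprintf("s%03d", 1:100)
  truth <- sample(pigClasses(), 100, replace = TRUE)
  pred <- ifelse(stats::runif(100) < 0.8, truth,
                 sample(pigClasses(), 100, replace = TRUE))
  foldOf <- rep(1:5, each = 20)
  preds <- lapply(1:5, function(f) data.frame(
    id = ids[foldOf == f], y_true = truth[foldOf == f],
    y_pred = pred[foldOf == f], stringsAsFactors = FALSE))
  cm <- oofConfusion(preds)
  expect_equal(sum(cm), 100)
  pc <- confusionPercent(cm)
  expect_true(all(abs(rowSums(pc)[rowSums(cm) > 0] - 100) < 0.5))
  expect_identical(oofConfusion(preds[c(4, 1, 5, 2, 3)]), cm)
  dup <- preds
  dup[[2]] <- rbind(dup[[2]], dup[[1]][1, ])
  expect_error(oofConfusion(dup), "coverage")
})

test_that("noon-degradation and session summaries do exact arithmetic", {
  expect_equal(deltaNoon(c(morning = 96.52, noon = 96.03, evening = 96.79)), 0.62)
  expect_equal(deltaNoon(c(morning = 95.63, noon = 94.58, evening = 95.87)), 1.17)
  expect_equal(deltaNoon(c(morning = 10, noon = 10, evening = 10)), 0)
  rep1 <- sessionSummary(c(morning = 96.52, noon = 96.03, evening = 96.79))
  expect_equal(round(rep1$mean, 2), 96.45)
  expect_equal(round(rep1$sd, 2), 0.39)
  expect_equal(rep1$delta_noon, 0.62)
  # two-pass oracle on arbitrary values
  v <- c(morning = 91.37, noon = 90.63, evening = 91.88)
  rep2 <- sessionSummary(v)
  mu <- sum(v) / 3
  expect_equal(rep2$mean, mu, tolerance = 1e-12)
  expect_equal(rep2$sd, sqrt(sum((v - mu)^2) / 2), tolerance = 1e-12)
  expect_equal(sessionSummary(c(morning = 5, noon = 5, evening = 5))$sd, 0)
  expect_error(deltaNoon(c(morning = 1, evening = 2)), "noon")
})

test_that("the signed-rank fold test is exact, symmetric and tie-safe", {
  # identical inputs raise both the dropped-ties and the all-zero warnings
  expect_warning(expect_warning(p0 <- wilcoxonFoldTest(c(1, 2, 3), c(1, 2, 3)),
                                "zero difference"), "all differences")
  expect_equal(p0$p.value, 1)
  a <- c(97.1, 96.8, 97.5, 97.0, 97.3)
  b <- c(96.2, 96.5, 96.4, 96.1, 96.9)
  res <- wilcoxonFoldTest(a, b)
  expect_equal(res$p.value, 0.0625)
  expect_equal(wilcoxonFoldTest(b, a)$p.value, res$p.value)
  # agrees with the exact reference implementation when there are no ties
  set.seed(24)
  for (i in 1:10) {
    x <- stats::rnorm(7)
    y <- stats::rnorm(7)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxonFoldTest(x, y)$p.value, ref, tolerance = 1e-12)
  }
})
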