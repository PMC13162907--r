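## Macro classification metrics, out-of-fold confusion, the exact signed-rank
## fold test, and the session-shift (noon degradation) statistics.

#' One-vs-rest AUROC by the rank statistic
#'
#' Mann-Whitney formulation with average ranks for ties, invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric scores.
#' @param positive logical vector, TRUE for positives.
#' @return AUROC in `[0, 1]`, or NA if one class is empty.
#' @export
rankAuroc <- function(scores, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' @keywords internal
macroF1Quick <- function(yTrue, yPred, classes = pigClasses()) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    if (tp + fn == 0) return(NA_real_)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  100 * mean(f1, na.rm = TRUE)
}

#' Confusion matrix with the fixed class order
#'
#' @param yTrue,yPred label vectors.
#' @param classes class order (default [pigClasses()]).
#' @return integer C x C matrix, rows = truth, columns = prediction.
#' @export
confusionMatrix <- function(yTrue, yPred, classes = pigClasses()) {
  tab <- table(factor(yTrue, classes), factor(yPred, classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(truth = classes, prediction = classes))
  m
}

#' Row-normalized confusion percentages
#'
#' @param cm a count matrix from [confusionMatrix()] or [oofConfusion()].
#' @param digits decimals to round to (default 1, the reporting convention).
#' @return matrix of row percentages.
#' @export
confusionPercent <- function(cm, digits = 1) {
  rs <- rowSums(cm)
  out <- 100 * cm / ifelse(rs == 0, 1, rs)
  round(out, digits)
}

#' Macro classification metrics
#'
#' Accuracy, per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 and
#' one-vs-rest AUROC, with unweighted macro averages. Classes absent from
#' `yTrue` are flagged and excluded from the macro averages with a warning
#' (their per-class values are NA). Percentages are on the 0-100 scale;
#' AUROC on 0-1.
#'
#' @param yTrue,yPred label vectors.
#' @param yScore optional matrix of class probabilities (columns named or
#'   ordered by `classes`); without it AUROC is NA.
#' @param classes class order (default [pigClasses()]).
#' @return a `MetricsReport` list with elements `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `macro_auroc`,
#'   `per_class` (data.frame) and `confusion`.
#' @export
computeMetrics <- function(yTrue, yPred, yScore = NULL,
                           classes = pigClasses()) {
  stopifnot(length(yTrue) == length(yPred))
  cm <- confusionMatrix(yTrue, yPred, classes)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  present <- rowSums(cm) > 0
  if (!all(present))
    warning("classes absent from truth excluded from macro averages: ",
            paste(classes[!present], collapse = ", "))

  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, NA_real_, tp / (tp + fn))
  f1 <- ifelse(is.na(rec), NA_real_,
               ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec)))
  prec[!present] <- NA_real_

  auroc <- rep(NA_real_, length(classes))
  if (!is.null(yScore)) {
    sc <- as.matrix(yScore)
    if (!is.null(colnames(sc))) sc <- sc[, classes, drop = FALSE]
    for (i in seq_along(classes))
      if (present[i]) auroc[i] <- rankAuroc(sc[, i], yTrue == classes[i])
  }

  perClass <- data.frame(class = classes, precision = 100 * prec,
                         recall = 100 * rec, f1 = 100 * f1, auroc = auroc)
  structure(list(
    accuracy = 100 * mean(yPred == yTrue),
    macro_precision = mean(100 * prec[present]),
    macro_recall = mean(100 * rec[present]),
    macro_f1 = mean(100 * f1[present]),
    macro_auroc = if (all(is.na(auroc))) NA_real_ else mean(auroc[present]),
    per_class = perClass,
    confusion = cm
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("Accuracy %.2f%% | macro P %.2f%% R %.2f%% F1 %.2f%% | AUROC %s\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              ifelse(is.na(x$macro_auroc), "NA", sprintf("%.3f", x$macro_auroc))))
  invisible(x)
}

#' Out-of-fold confusion matrix
#'
#' Concatenates per-fold validation predictions (each sample scored exactly
#' once by the model not trained on its group) into one confusion matrix.
#'
#' @param foldPredictions list of data.frames with columns `id`, `y_true`,
#'   `y_pred`.
#' @param classes class order.
#' @return count matrix as in [confusionMatrix()].
#' @export
oofConfusion <- function(foldPredictions, classes = pigClasses()) {
  all <- do.call(rbind, foldPredictions)
  if (anyDuplicated(all$id))
    stopInvalid("coverage error: samples predicted in more than one fold: ",
                paste(unique(all$id[duplicated(all$id)]), collapse = ", "))
  confusionMatrix(all$y_true, all$y_pred, classes)
}

#' Noon-degradation statistic
#'
#' `(Morning + Evening) / 2 - Noon` on session-wise Macro-F1 (%); smaller
#' values mean lower sensitivity to the midday domain shift.
#'
#' @param x either a named numeric vector with entries `morning`, `noon`,
#'   `evening`, or a report from [sessionSummary()].
#' @param digits decimals to round to (default 2, the reporting convention);
#'   `NA` for no rounding.
#' @return the statistic in Macro-F1 percentage points.
#' @export
deltaNoon <- function(x, digits = 2) {
  v <- if (is.list(x) && !is.null(x$per_session_macro_f1)) x$per_session_macro_f1 else x
  if (!all(c("morning", "noon", "evening") %in% names(v)))
    stopInvalid("need morning, noon and evening values")
  d <- (v[["morning"]] + v[["evening"]]) / 2 - v[["noon"]]
  if (is.na(digits)) d else round(d, digits)
}

#' Cross-session generalization summary
#'
#' Mean and sample standard deviation (divisor n-1) of the three session-wise
#' Macro-F1 values, plus the noon-degradation statistic.
#'
#' @param perSessionMacroF1 named numeric vector (`morning`, `noon`,
#'   `evening`) of Macro-F1 in %.
#' @return a `SessionGeneralizationReport` list with
#'   `per_session_macro_f1`, `mean`, `sd`, `delta_noon`.
#' @export
sessionSummary <- function(perSessionMacroF1) {
  v <- perSessionMacroF1
  if (!all(c("morning", "noon", "evening") %in% names(v)))
    stopInvalid("need morning, noon and evening values")
  v <- v[c("morning", "noon", "evening")]
  structure(list(per_session_macro_f1 = v, mean = mean(v), sd = stats::sd(v),
                 delta_noon = deltaNoon(v)),
            class = "SessionGeneralizationReport")
}

#' @export
print.SessionGeneralizationReport <- function(x, ...) {
  cat(sprintf("Macro-F1 morning %.2f / noon %.2f / evening %.2f | mean %.2f +/- %.2f | dNoon %.2f\n",
              x$per_session_macro_f1[["morning"]], x$per_session_macro_f1[["noon"]],
              x$per_session_macro_f1[["evening"]], x$mean, x$sd, x$delta_noon))
  invisible(x)
}

#' Exact two-sided Wilcoxon signed-rank test for paired fold scores
#'
#' Zero differences are dropped with a warning (if all differences are zero
#' the test returns p = 1). Ties among the absolute differences receive
#' average ranks and the exact null distribution of the signed-rank statistic
#' is computed by dynamic programming over the (doubled) ranks, so the test
#' stays exact under ties.
#'
#' @param scoresA,scoresB equal-length paired score vectors (one per fold).
#' @return list with `p.value`, `statistic` (rank sum of positive
#'   differences) and `n` (non-zero differences used).
#' @export
wilcoxonFoldTest <- function(scoresA, scoresB) {
  stopifnot(length(scoresA) == length(scoresB))
  d <- scoresA - scoresB
  if (any(d == 0)) {
    warning("dropping ", sum(d == 0), " zero difference(s)")
    d <- d[d != 0]
  }
  if (length(d) == 0) {
    warning("all differences are zero; p = 1")
    return(list(p.value = 1, statistic = NA_real_, n = 0L))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))    # doubled ranks are integers even with ties
  tot <- sum(r2)
  counts <- numeric(tot + 1)        # counts[s + 1] = #assignments with sum s
  counts[1] <- 1
  for (rr in r2) {
    shifted <- c(numeric(rr), counts[seq_len(tot + 1 - rr)])
    counts <- counts + shifted
  }
  w2 <- as.integer(round(2 * W))
  pLe <- sum(counts[seq_len(w2 + 1)]) / 2^length(d)
  pGe <- sum(counts[(w2 + 1):(tot + 1)]) / 2^length(d)
  list(p.value = min(1, 2 * min(pLe, pGe)), statistic = W, n = length(d))
}
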