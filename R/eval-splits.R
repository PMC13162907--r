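## Leakage-aware partitioning: compound group tokens, grouped holdout and
## k-fold splits, and session-wise leave-one-session-out splits. Group and
## pig exclusivity are asserted, never assumed.

#' Compound group token of every manifest record
#'
#' Routine samples are grouped by `(pen_id, date, session)`; close-range
#' cough samples are grouped by pig identity so that all directed coughs
#' from one pig stay in a single subset; estrus samples use their
#' session-level `(stall, date, session)` token.
#'
#' @param manifest a [BarnManifest-class].
#' @return character vector of tokens, named by record id.
#' @export
assignGroups <- function(manifest) {
  r <- manifestRecords(manifest)
  if (any(is.na(r$pen_id) | is.na(r$date) | is.na(r$session)))
    stopInvalid("manifest has incomplete group metadata")
  tok <- ifelse(r$close_range,
                paste0("pig:", r$pig_id),
                paste("grp", r$pen_id, r$date, r$session, sep = ":"))
  names(tok) <- r$id
  tok
}

# greedy allocation of groups to named partitions approaching per-class
# target sample counts; largest groups are placed first (they fit only where
# the remaining deficit is large) and overflow is penalized, so small
# partitions end close to their targets; deterministic given the seed
#' @keywords internal
greedyAllocate <- function(tokens, labels, ratios, partNames, seed) {
  ratios <- ratios / sum(ratios)
  classes <- sort(unique(labels))
  grpOf <- split(seq_along(tokens), tokens)
  ord <- withLocalSeed(seed, sample(names(grpOf)))
  ord <- ord[order(-vapply(grpOf[ord], length, integer(1)))]
  target <- outer(as.numeric(table(factor(labels, classes))), ratios)
  dimnames(target) <- list(classes, partNames)
  current <- target * 0
  assign <- character(length(tokens))
  for (g in ord) {
    idx <- grpOf[[g]]
    cnt <- as.numeric(table(factor(labels[idx], classes)))
    score <- vapply(partNames, function(p) {
      deficit <- pmax(0, target[, p] - current[, p])
      sum(pmin(cnt, deficit) - pmax(0, cnt - deficit))
    }, numeric(1))
    best <- partNames[which.max(score)]
    assign[idx] <- best
    current[, best] <- current[, best] + cnt
  }
  assign
}

#' Grouped holdout split with an intended 8:1:1 ratio
#'
#' Allocates whole groups (never single samples) greedily to the train,
#' validation and test partitions, approaching per-class 8:1:1 sample
#' ratios. Because allocation is at group level the achieved ratios are
#' approximate.
#'
#' @param manifest a [BarnManifest-class].
#' @param ratios length-3 numeric ratio (default `c(8, 1, 1)`).
#' @param seed shuffle seed.
#' @return named character vector (record id -> "train"/"val"/"test") with
#'   attribute `type = "holdout"`.
#' @export
groupedHoldoutSplit <- function(manifest, ratios = c(8, 1, 1), seed = 1) {
  r <- manifestRecords(manifest)
  tok <- assignGroups(manifest)
  perClassGroups <- tapply(tok, r$label, function(x) length(unique(x)))
  if (any(perClassGroups < 3))
    stopInvalid("split infeasible: classes with fewer than 3 groups: ",
                paste(names(perClassGroups)[perClassGroups < 3], collapse = ", "))
  parts <- c("train", "val", "test")
  assign <- greedyAllocate(tok, r$label, ratios, parts, seed)
  names(assign) <- r$id
  attr(assign, "type") <- "holdout"
  assign
}

# distribute group tokens over k folds balancing sample counts (LPT greedy)
#' @keywords internal
tokensToFolds <- function(tokens, k, seed) {
  sizes <- table(tokens)
  ord <- withLocalSeed(seed, sample(names(sizes)))
  ord <- ord[order(-as.numeric(sizes[ord]))]
  foldOf <- integer(0)
  load <- numeric(k)
  for (g in ord) {
    f <- which.min(load)
    foldOf[g] <- f
    load[f] <- load[f] + sizes[[g]]
  }
  foldOf[tokens]
}

#' Grouped k-fold assignment
#'
#' Groups are partitioned into `k` folds with greedily balanced sample
#' counts; all samples of a group share a fold.
#'
#' @param manifest a [BarnManifest-class].
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return named integer vector (record id -> fold in `1..k`) with attribute
#'   `type = "kfold"`.
#' @export
groupedKfold <- function(manifest, k = 5, seed = 1) {
  tok <- assignGroups(manifest)
  if (length(unique(tok)) < k)
    stopInvalid("fewer groups (", length(unique(tok)), ") than folds (", k, ")")
  assign <- tokensToFolds(tok, k, seed)
  names(assign) <- names(tok)
  attr(assign, "type") <- "kfold"
  assign
}

#' Leave-one-session-out splits
#'
#' For each recording session (morning, noon, evening) the session becomes
#' the test domain and the remaining two sessions are split group-wise into
#' train and validation.
#'
#' @param manifest a [BarnManifest-class].
#' @param valRatio fraction of non-test samples used for validation
#'   (default 1/9).
#' @param seed shuffle seed.
#' @return named list (session -> split assignment as in
#'   [groupedHoldoutSplit()]).
#' @export
losoBySession <- function(manifest, valRatio = 1 / 9, seed = 1) {
  r <- manifestRecords(manifest)
  sessions <- c("morning", "noon", "evening")
  if (!all(sessions %in% r$session))
    stopInvalid("missing sessions: ",
                paste(setdiff(sessions, unique(r$session)), collapse = ", "))
  tok <- assignGroups(manifest)
  out <- list()
  for (s in sessions) {
    isTest <- r$session == s
    rest <- which(!isTest)
    sub <- greedyAllocate(tok[rest], r$label[rest],
                          c(1 - valRatio, valRatio), c("train", "val"),
                          deriveSeed(seed, match(s, sessions)))
    assign <- character(nrow(r))
    assign[isTest] <- "test"
    assign[rest] <- sub
    names(assign) <- r$id
    attr(assign, "type") <- "holdout"
    out[[s]] <- assign
  }
  out
}

#' Verify group and pig exclusivity of a split
#'
#' Every group token and every close-range pig identity must map to exactly
#' one partition/fold. Returns TRUE invisibly, or stops with a leakage error.
#'
#' @param manifest a [BarnManifest-class].
#' @param assignment a split from [groupedHoldoutSplit()], [groupedKfold()]
#'   or one element of [losoBySession()].
#' @export
assertNoLeakage <- function(manifest, assignment) {
  r <- manifestRecords(manifest)
  tok <- assignGroups(manifest)
  part <- assignment[r$id]
  if (any(is.na(part))) stopInvalid("assignment does not cover all records")
  spanTok <- tapply(part, tok, function(x) length(unique(x)))
  if (any(spanTok > 1))
    stopInvalid("leakage: group tokens span partitions: ",
                paste(names(spanTok)[spanTok > 1], collapse = ", "))
  cr <- which(r$close_range)
  if (length(cr)) {
    spanPig <- tapply(part[cr], r$pig_id[cr], function(x) length(unique(x)))
    if (any(spanPig > 1))
      stopInvalid("leakage: pig ids span partitions: ",
                  paste(names(spanPig)[spanPig > 1], collapse = ", "))
  }
  invisible(TRUE)
}

#' Write / read a split assignment as a delimited text file
#' @param assignment a split assignment.
#' @param path file path.
#' @export
writeSplit <- function(assignment, path) {
  utils::write.table(
    data.frame(id = names(assignment), partition = as.character(assignment)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out <- tab$partition
  names(out) <- tab$id
  out
}
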