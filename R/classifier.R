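entropy2 <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Gain ratio of a binary split
#'
#' Information gain (log base 2) of splitting `labels` by a binary feature,
#' divided by the split's own entropy — the C4.5 split selection criterion.
#' A degenerate split with an empty side scores 0.
#'
#' @param feature binary (0/1) feature values.
#' @param labels class labels, same length.
#' @return list with `gain`, `splitInfo` and `ratio` (all in bits).
#' @examples
#' gainRatio(rep(c(1, 0), each = 10), rep(c("a", "b"), each = 10))$ratio  # 1
#' @export
gainRatio <- function(feature, labels) {
  stopifnot(length(feature) == length(labels), length(labels) >= 2L)
  labels <- as.character(labels)
  n <- length(labels)
  on <- feature > 0
  n1 <- sum(on); n0 <- n - n1
  if (n0 == 0L || n1 == 0L)
    return(list(gain = 0, splitInfo = 0, ratio = 0))
  h <- entropy2(table(labels))
  h1 <- entropy2(table(labels[on]))
  h0 <- entropy2(table(labels[!on]))
  gain <- h - (n1 / n) * h1 - (n0 / n) * h0
  splitInfo <- entropy2(c(n0, n1))
  list(gain = gain, splitInfo = splitInfo, ratio = gain / splitInfo)
}

## C4.5 pessimistic error: upper confidence limit of the binomial error
## rate at confidence level cf, times n (expected errors at the node)
pessimisticErrors <- function(e, n, cf = 0.25) {
  if (n == 0L) return(0)
  n * stats::qbeta(1 - cf, e + 1, n - e)
}

leafNode <- function(y) {
  counts <- c(sum(y == POSITIVE_CLASS), sum(y == NEGATIVE_CLASS))
  names(counts) <- c(POSITIVE_CLASS, NEGATIVE_CLASS)
  cls <- if (counts[2L] > counts[1L]) NEGATIVE_CLASS else POSITIVE_CLASS
  list(leaf = TRUE, class = cls, counts = counts)
}

## best single-step information gain achievable on (x, y), 0 if none
bestGain <- function(x, y, minLeaf, feats) {
  out <- 0
  n <- length(y)
  for (f in feats) {
    n1 <- sum(x[, f] > 0)
    if (n1 < minLeaf || n - n1 < minLeaf) next
    g <- gainRatio(x[, f], y)$gain
    if (g > out) out <- g
  }
  out
}

growTree <- function(x, y, minLeaf, maxDepth, depth, used) {
  n <- length(y)
  if (length(unique(y)) == 1L || n < 2L * minLeaf || depth >= maxDepth)
    return(leafNode(y))
  feats <- setdiff(colnames(x), used)
  best <- NULL; bestRatio <- 0
  for (f in feats) {   # colnames ascend in mass: first max wins ties
    v <- x[, f]
    n1 <- sum(v > 0)
    if (n1 < minLeaf || n - n1 < minLeaf) next
    g <- gainRatio(v, y)
    if (g$gain <= 1e-12) next
    if (g$ratio > bestRatio + 1e-12) {
      bestRatio <- g$ratio
      best <- f
    }
  }
  if (is.null(best)) {
    ## no single feature is informative on its own; one-step lookahead so
    ## interactions (e.g. exclusive-or structure) are still separable
    bestG2 <- 0
    for (f in feats) {
      v <- x[, f] > 0
      n1 <- sum(v)
      if (n1 < minLeaf || n - n1 < minLeaf) next
      rest <- setdiff(feats, f)
      g2 <- gainRatio(v * 1, y)$gain +
        (n1 / n) * bestGain(x[v, , drop = FALSE], y[v], minLeaf, rest) +
        ((n - n1) / n) * bestGain(x[!v, , drop = FALSE], y[!v], minLeaf, rest)
      if (g2 > bestG2 + 1e-9) {
        bestG2 <- g2
        best <- f
      }
    }
  }
  if (is.null(best)) return(leafNode(y))
  on <- x[, best] > 0
  list(leaf = FALSE, feature = best,
       absent = growTree(x[!on, , drop = FALSE], y[!on], minLeaf, maxDepth,
                         depth + 1L, c(used, best)),
       present = growTree(x[on, , drop = FALSE], y[on], minLeaf, maxDepth,
                          depth + 1L, c(used, best)))
}

## C4.5 error-based pruning with the training samples at hand: at each
## internal node the choices are (a) keep the subtree, (b) collapse to a
## leaf, (c) raise the more populated branch and re-route all the node's
## samples through it — whichever has the smallest pessimistic error
## estimate. Leaf classes and counts are recomputed from the routed data.
pruneNode <- function(node, x, y, cf) {
  if (isTRUE(node$leaf)) {
    lf <- leafNode(y)
    lf$estErrors <- pessimisticErrors(length(y) - max(lf$counts), length(y), cf)
    return(lf)
  }
  v <- x[, node$feature] > 0
  node$absent <- pruneNode(node$absent, x[!v, , drop = FALSE], y[!v], cf)
  node$present <- pruneNode(node$present, x[v, , drop = FALSE], y[v], cf)
  subtreeErr <- node$absent$estErrors + node$present$estErrors
  lf <- leafNode(y)
  leafErr <- pessimisticErrors(length(y) - max(lf$counts), length(y), cf)
  larger <- if (sum(v) > sum(!v)) node$present else node$absent
  raised <- if (isTRUE(larger$leaf)) NULL
            else pruneNode(larger, x, y, cf)
  raisedErr <- if (is.null(raised)) Inf else raised$estErrors
  if (leafErr <= min(subtreeErr, raisedErr) + 1e-9) {
    lf$estErrors <- leafErr
    lf
  } else if (raisedErr <= subtreeErr + 1e-9) {
    raised
  } else {
    node$estErrors <- subtreeErr
    node
  }
}

nodeCounts <- function(node) {
  if (isTRUE(node$leaf)) node$counts
  else nodeCounts(node$absent) + nodeCounts(node$present)
}

stripEst <- function(node) {
  node$estErrors <- NULL
  if (!isTRUE(node$leaf)) {
    node$absent <- stripEst(node$absent)
    node$present <- stripEst(node$present)
  }
  node
}

#' Train a gain-ratio decision tree on binary peak features
#'
#' Greedy top-down induction in the C4.5 style: at each node the binary
#' feature with the highest gain ratio (among features with positive gain
#' and both children of size >= `minLeaf`) is chosen, ties resolved toward
#' the lowest reference mass; growth stops on purity, size or depth, and
#' the grown tree is simplified by pessimistic-error pruning with confidence
#' factor `pruneCf`. Deterministic given its inputs.
#'
#' @param x binary feature matrix, samples x features; column names are bin
#'   reference masses.
#' @param y class labels (`periodontitis`/`control`).
#' @param minLeaf minimum samples on each side of a split (default 2).
#' @param pruneCf pruning confidence factor (default 0.25); `NA` disables
#'   pruning.
#' @param maxDepth optional depth cap (default unlimited).
#' @param meta list of training metadata stored on the tree.
#' @return A [PeakTree-class].
#' @export
trainTree <- function(x, y, minLeaf = 2, pruneCf = 0.25, maxDepth = Inf,
                      meta = list()) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  root <- growTree(x, y, minLeaf, maxDepth, 0L, character())
  if (!is.na(pruneCf)) root <- stripEst(pruneNode(root, x, y, pruneCf))
  meta$n <- length(y)
  meta$minLeaf <- minLeaf
  meta$pruneCf <- pruneCf
  new("PeakTree", root = root, meta = meta)
}

#' Predict with a peak decision tree
#'
#' Routes one sample (or each row of a matrix) down the tree. A feature
#' missing from `newdata` (or `NA`) is treated as absent (0). With
#' `path = TRUE` the ordered list of (feature, branch) decisions is
#' returned for explainability.
#'
#' @param tree a [PeakTree-class].
#' @param newdata named binary vector, or matrix samples x features.
#' @param path return the decision path (single sample only).
#' @return Character vector of predicted classes, or a list with `class`
#'   and `path` when `path = TRUE`.
#' @export
predictTree <- function(tree, newdata, path = FALSE) {
  stopifnot(is(tree, "PeakTree"))
  one <- function(v) {
    node <- tree@root
    steps <- list()
    while (!isTRUE(node$leaf)) {
      val <- v[node$feature]
      present <- !is.na(val) && val > 0
      steps[[length(steps) + 1L]] <-
        list(feature = node$feature,
             branch = if (present) "present" else "absent")
      node <- if (present) node$present else node$absent
    }
    list(class = node$class, path = steps)
  }
  if (is.matrix(newdata) || is.data.frame(newdata)) {
    m <- as.matrix(newdata)
    out <- vapply(seq_len(nrow(m)), function(i) one(m[i, ])$class,
                  character(1))
    names(out) <- rownames(m)
    return(out)
  }
  r <- one(newdata)
  if (path) r else r$class
}

#' Stratified k-fold cross-validation of the diagnostic pipeline
#'
#' Partitions the samples into `k` stratified folds (sizes within one, both
#' classes in every fold) from a seeded RNG, and re-fits the entire feature
#' pipeline on each training fold only: dichotomization thresholds from
#' training group means, binary-discriminant ranking, selection of the top
#' `topK` bins, tree induction — then predicts the held-out fold with the
#' frozen thresholds and tree. Sensitivity is TP/(TP+FN) with periodontitis
#' positive; specificity TN/(TN+FP).
#'
#' @param pm a [PeakMatrix-class] with an `"intensity"` assay.
#' @param labels group labels (default `colData(pm)$group`).
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold partition.
#' @param topK number of top-ranked bins offered to the tree (default 30).
#' @param stratified stratify folds by class (default TRUE).
#' @param minLeaf,pruneCf tree parameters, see [trainTree()].
#' @return list of class `"CVResult"`: `folds` (per-fold data.frame),
#'   `foldAssignments` (fold index per sample), `sensitivity`,
#'   `specificity` (each `mean`/`sd`), `k`, `seed`.
#' @export
crossValidate <- function(pm, labels = NULL, k = 10, seed = 1, topK = 30,
                          stratified = TRUE, minLeaf = 2, pruneCf = 0.25) {
  a <- SummarizedExperiment::assay(pm, "intensity")
  bm <- SummarizedExperiment::rowData(pm)$binMass
  labels <- as.character(labels %||% SummarizedExperiment::colData(pm)$group)
  n <- ncol(a)
  stopifnot(length(labels) == n)
  if (k > n) stopf("k = %d folds but only %d samples", k, n)
  case <- labels == POSITIVE_CLASS
  if (stratified && (sum(case) < k || sum(!case) < k))
    stopf("stratified %d-fold CV needs >= %d samples per class", k, k)
  fold <- integer(n)
  withStageSeed(seed, "crossval-folds", {
    if (stratified) {
      for (cls in list(which(case), which(!case)))
        fold[cls[sample.int(length(cls))]] <-
          rep_len(seq_len(k), length(cls))
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  folds <- data.frame(fold = seq_len(k), tp = 0L, fn = 0L, tn = 0L, fp = 0L,
                      sensitivity = NA_real_, specificity = NA_real_)
  for (f in seq_len(k)) {
    test <- fold == f
    atr <- a[, !test, drop = FALSE]
    ltr <- labels[!test]
    thr <- (rowMeans(atr[, ltr == POSITIVE_CLASS, drop = FALSE]) +
            rowMeans(atr[, ltr == NEGATIVE_CLASS, drop = FALSE])) / 2
    btr <- applyThresholds(atr, thr)
    rk <- bindaRank(btr, ltr, binMass = bm)
    sel <- match(rk$binMass[seq_len(min(topK, nrow(rk)))], bm)
    xtr <- t(btr[sel, , drop = FALSE])
    colnames(xtr) <- sprintf("%.9g", bm[sel])
    tree <- trainTree(xtr, ltr, minLeaf = minLeaf, pruneCf = pruneCf)
    bte <- applyThresholds(a[, test, drop = FALSE], thr)
    xte <- t(bte[sel, , drop = FALSE])
    colnames(xte) <- colnames(xtr)
    pred <- predictTree(tree, xte)
    truth <- labels[test]
    folds$tp[f] <- sum(pred == POSITIVE_CLASS & truth == POSITIVE_CLASS)
    folds$fn[f] <- sum(pred == NEGATIVE_CLASS & truth == POSITIVE_CLASS)
    folds$tn[f] <- sum(pred == NEGATIVE_CLASS & truth == NEGATIVE_CLASS)
    folds$fp[f] <- sum(pred == POSITIVE_CLASS & truth == NEGATIVE_CLASS)
  }
  folds$sensitivity <- with(folds, ifelse(tp + fn > 0, tp / (tp + fn), NA))
  folds$specificity <- with(folds, ifelse(tn + fp > 0, tn / (tn + fp), NA))
  structure(list(
    folds = folds,
    foldAssignments = fold,
    sensitivity = c(mean = mean(folds$sensitivity, na.rm = TRUE),
                    sd = stats::sd(folds$sensitivity[!is.na(folds$sensitivity)])),
    specificity = c(mean = mean(folds$specificity, na.rm = TRUE),
                    sd = stats::sd(folds$specificity[!is.na(folds$specificity)])),
    k = k, seed = seed, topK = topK), class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d):\n", x$k, x$seed))
  cat(sprintf("  sensitivity %.3f +/- %.3f\n", x$sensitivity["mean"],
              x$sensitivity["sd"]))
  cat(sprintf("  specificity %.3f +/- %.3f\n", x$specificity["mean"],
              x$specificity["sd"]))
  invisible(x)
}
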