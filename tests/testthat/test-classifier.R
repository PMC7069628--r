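posneg <- c("periodontitis", "control")

test_that("gain ratio matches the entropy formula", {
  y <- rep(posneg, each = 10)

  ## perfect separator: gain 1 bit, split entropy 1, ratio 1
  g <- gainRatio(rep(c(1, 0), each = 10), y)
  expect_equal(g$gain, 1)
  expect_equal(g$splitInfo, 1)
  expect_equal(g$ratio, 1)

  ## label-independent feature: zero gain
  g2 <- gainRatio(rep(c(1, 0), 10), y)
  expect_equal(g2$gain, 0, tolerance = 1e-12)

  ## degenerate split: one empty side
  expect_equal(gainRatio(rep(1, 20), y)$ratio, 0)

  ## class counts (8/2 on, 3/7 off): brute-force entropy arithmetic
  f <- c(rep(1, 8), rep(0, 2), rep(1, 3), rep(0, 7))
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  gain <- h(0.5) - (11 / 20) * h(8 / 11) - (9 / 20) * h(2 / 9)
  split <- h(11 / 20)
  g3 <- gainRatio(f, y)
  expect_equal(g3$gain, gain, tolerance = 1e-12)
  expect_equal(g3$ratio, gain / split, tolerance = 1e-12)
})

test_that("tree induction finds planted structure and stays deterministic", {
  set.seed(61)
  y <- rep(posneg, each = 25)

  ## one perfect feature among 50 noise features -> depth-1 tree on it
  x <- matrix(rbinom(50 * 50, 1, 0.5), nrow = 50)
  colnames(x) <- sprintf("%.9g", 2000 + 300 * (1:50))
  x[, 17] <- as.integer(y == "periodontitis")
  tr <- trainTree(x, y)
  expect_equal(periospec:::treeDepth(tr@root), 1L)
  expect_equal(tr@root$feature, colnames(x)[17])
  expect_equal(unname(mean(predictTree(tr, x) == y)), 1)

  ## pure labels -> single leaf
  tr2 <- trainTree(x, rep("control", 50))
  expect_true(isTRUE(tr2@root$leaf))
  expect_equal(tr2@root$class, "control")

  ## exclusive-or of two features, 4 x 25 samples: depth-2 tree, both used
  cells <- expand.grid(f1 = 0:1, f2 = 0:1)
  xx <- cells[rep(1:4, each = 25), ]
  yy <- ifelse(xor(xx$f1 == 1, xx$f2 == 1), "periodontitis", "control")
  xm <- as.matrix(xx) * 1
  colnames(xm) <- c("3000", "4000")
  tr3 <- trainTree(xm, yy)
  expect_equal(periospec:::treeDepth(tr3@root), 2L)
  expect_equal(unname(mean(predictTree(tr3, xm) == yy)), 1)

  ## deterministic: same inputs, same tree
  expect_identical(trainTree(x, y)@root, tr@root)
})

test_that("prediction is self-consistent and treats missing peaks as absent", {
  y <- rep(posneg, each = 15)
  set.seed(62)
  x <- matrix(rbinom(30 * 10, 1, 0.4), nrow = 30,
              dimnames = list(NULL, sprintf("%d", 3001:3010)))
  x[, 4] <- as.integer(y == "periodontitis")
  tr <- trainTree(x, y)

  ## training confusion reproduced exactly
  pred <- predictTree(tr, x)
  cnt <- periospec:::nodeCounts(tr@root)
  expect_equal(sum(cnt), 30)
  expect_equal(unname(pred), unname(ifelse(x[, 4] == 1, "periodontitis",
                                           "control")))

  ## all features missing routes down absent branches
  r <- predictTree(tr, setNames(rep(NA_real_, 10), colnames(x)), path = TRUE)
  expect_true(all(vapply(r$path, `[[`, character(1), "branch") == "absent"))
  expect_equal(r$class, "control")

  ## depth-1 tree, feature present -> case class
  expect_equal(unname(predictTree(tr, c(`3004` = 1))), "periodontitis")
})

test_that("pruning never grows the tree and never lowers training error", {
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 40
    y <- sample(rep(posneg, each = n / 2))
    x <- matrix(rbinom(n * 12, 1, 0.5), nrow = n,
                dimnames = list(NULL, sprintf("%d", 3001:3012)))
    unpruned <- trainTree(x, y, pruneCf = NA)
    pruned <- trainTree(x, y, pruneCf = 0.25)
    expect_lte(periospec:::treeLeafCount(pruned@root),
               periospec:::treeLeafCount(unpruned@root))
    errU <- mean(predictTree(unpruned, x) != y)
    errP <- mean(predictTree(pruned, x) != y)
    expect_gte(errP, errU)
  }
})

test_that("leave-one-out on a perfect marker is perfect", {
  set.seed(63)
  y <- rep(posneg, each = 10)
  mat <- matrix(rexp(5 * 20), nrow = 5)
  mat[3, ] <- ifelse(y == "periodontitis", 20, 0) + rnorm(20, 0, 0.1)
  pm <- toyPeakMatrix(pmax(mat, 0), group = y)
  cv <- crossValidate(pm, k = 20, seed = 1, stratified = FALSE)
  expect_equal(unname(cv$sensitivity["mean"]), 1)
  expect_equal(unname(cv$specificity["mean"]), 1)
})

test_that("cross-validation is seeded, stratified and leak-free", {
  cfg <- simConfig("recovery", seed = 4)
  sim <- simulateIntensityMatrix(cfg)

  cv1 <- crossValidate(sim$pm, k = 10, seed = 99)
  cv2 <- crossValidate(sim$pm, k = 10, seed = 99)
  expect_identical(cv1, cv2)
  expect_false(identical(cv1$foldAssignments,
                         crossValidate(sim$pm, k = 10, seed = 100)$foldAssignments))

  ## folds partition the samples with sizes within one, both classes present
  tab <- table(cv1$foldAssignments)
  expect_equal(sum(tab), ncol(sim$pm))
  expect_lte(diff(range(tab)), 1)
  grp <- SummarizedExperiment::colData(sim$pm)$group
  strat <- table(cv1$foldAssignments, grp)
  expect_true(all(strat > 0))

  expect_error(crossValidate(sim$pm, k = 500, seed = 1), "folds")

  ## leak canary: fit on half A, evaluate on half B whose canary feature
  ## encodes the truth; the fit must ignore it because it never saw it
  set.seed(64)
  nA <- 60
  grpA <- rep(posneg, each = nA / 2)
  grpB <- rep(posneg, each = 30)
  noiseA <- matrix(rbinom(nA * 20, 1, 0.5), nrow = 20)
  noiseB <- matrix(rbinom(60 * 20, 1, 0.5), nrow = 20)
  canaryA <- rbinom(nA, 1, 0.5)
  canaryB <- as.integer(grpB == "periodontitis")
  bm <- 2000 + 400 * (1:21)
  rk <- bindaRank(rbind(noiseA, canaryA), grpA, binMass = bm)
  sel <- match(rk$binMass[1:10], bm)
  xA <- t(rbind(noiseA, canaryA)[sel, , drop = FALSE])
  colnames(xA) <- sprintf("%.9g", bm[sel])
  tr <- trainTree(xA, grpA)
  xB <- t(rbind(noiseB, canaryB)[sel, , drop = FALSE])
  colnames(xB) <- colnames(xA)
  accB <- mean(predictTree(tr, xB) == grpB)
  ## chance-level on null data despite the predictive validation canary
  expect_lt(accB, 0.75)
  ## flipping the canary in B must not change predictions unless the tree
  ## used it, and it cannot have preferred it (it was noise in A)
  xB2 <- xB
  if (any(colnames(xB2) == sprintf("%.9g", bm[21])))
    xB2[, sprintf("%.9g", bm[21])] <- 1 - xB2[, sprintf("%.9g", bm[21])]
  usedFeatures <- unlist(lapply(seq_len(nrow(xB)), function(i)
    vapply(predictTree(tr, xB[i, ], path = TRUE)$path, `[[`,
           character(1), "feature")))
  if (!sprintf("%.9g", bm[21]) %in% usedFeatures)
    expect_equal(predictTree(tr, xB2), predictTree(tr, xB))
})
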