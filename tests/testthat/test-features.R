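mkMsp <- function(mzv, iv, source = NA_character_) {
  new("MainSpectrumProfile",
      MassPeaks(mzv, iv, snr = rep(10, length(mzv)), source = source),
      replicateCount = 6L)
}

test_that("peak binning follows the divisive spread rule", {
  ## 3000 vs 3010: spread 10/3005 = 0.0033 <= 2 * 0.002 -> one bin at 3005
  b1 <- binPeaks(list(mkMsp(3000, 1), mkMsp(3010, 1)))
  expect_equal(b1$binMass, 3005)

  ## 3000 vs 3020: spread 20/3010 = 0.0066 > 0.004 -> two bins
  b2 <- binPeaks(list(mkMsp(3000, 1), mkMsp(3020, 1)))
  expect_equal(b2$binMass, c(3000, 3020))

  ## single profile: bins are its own masses
  m <- mkMsp(c(2500, 7000, 15000), c(1, 2, 3))
  b3 <- binPeaks(list(m))
  expect_equal(b3$binMass, c(2500, 7000, 15000))

  ## idempotence: binning the bin references leaves them unchanged
  b4 <- binPeaks(list(mkMsp(b3$binMass, c(1, 1, 1))))
  expect_equal(b4$binMass, b3$binMass)

  ## one peak per profile per bin: the strongest wins
  b5 <- binPeaks(list(mkMsp(c(5000, 5004), c(1, 9)), mkMsp(5002, 5)))
  expect_equal(length(b5$binMass), 1L)
  expect_equal(nrow(b5$assignment), 2L)
})

test_that("matrix building conserves peak counts and zero-fills gaps", {
  m1 <- mkMsp(c(3000, 5000), c(1, 2), "S01.saliva")
  m2 <- mkMsp(c(3001, 8000), c(3, 4), "S02.saliva")
  bins <- binPeaks(list(m1, m2))
  pm <- buildIntensityMatrix(list(m1, m2), bins)
  a <- SummarizedExperiment::assay(pm, "intensity")
  expect_equal(dim(a), c(3L, 2L))
  ## shared bin filled for both, unique bins zero elsewhere
  expect_equal(sum(a > 0), 4L)
  expect_equal(sum(a > 0), nrow(bins$assignment))
  expect_equal(a[SummarizedExperiment::rowData(pm)$binMass == 8000, 1],
               unname(c(`8000` = 0)))

  ## shared-everything profiles leave no zero cells
  s1 <- mkMsp(c(3000, 5000), c(1, 2))
  s2 <- mkMsp(c(3000, 5000), c(3, 4))
  pm2 <- buildIntensityMatrix(list(s1, s2), binPeaks(list(s1, s2)))
  expect_true(all(SummarizedExperiment::assay(pm2, "intensity") > 0))

  ## count conservation on a random pool of profiles
  set.seed(31)
  msps <- lapply(1:8, function(i) {
    k <- sample(3:12, 1)
    mkMsp(sort(runif(k, 2000, 20000)), rexp(k))
  })
  bb <- binPeaks(msps)
  pmr <- buildIntensityMatrix(msps, bb)
  expect_equal(sum(SummarizedExperiment::assay(pmr, "intensity") > 0),
               nrow(bb$assignment))
})

test_that("peak screening matches exact rank-sum enumeration and handles
           symmetric ties", {
  ## identical distributions in both groups -> p = 1
  v <- c(1, 2, 3, 4, 5)
  pm <- toyPeakMatrix(matrix(c(v, v), nrow = 1),
                      group = rep(c("periodontitis", "control"), each = 5))
  sc <- screenPeaks(pm)
  expect_equal(sc$p, 1)

  ## complete separation, 10 vs 10: exact tail of the rank-sum null
  x <- 1:10
  y <- 11:20
  pm2 <- toyPeakMatrix(matrix(c(y, x), nrow = 1),
                       group = rep(c("periodontitis", "control"), each = 10))
  sc2 <- screenPeaks(pm2)
  expect_equal(sc2$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(sc2$direction, "higher-in-periodontitis")

  ## random data against full enumeration, n <= 12 per group
  for (s in 1:6) {
    set.seed(40 + s)
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    a <- round(rexp(n1), 3)
    b <- round(rexp(n2) * 1.5, 3)
    pmr <- toyPeakMatrix(matrix(c(a, b), nrow = 1),
                         group = rep(c("periodontitis", "control"),
                                     c(n1, n2)))
    expect_equal(screenPeaks(pmr)$p, enumRankSumP(a, b), tolerance = 1e-9)
  }

  expect_error(screenPeaks(toyPeakMatrix(matrix(1:4, nrow = 1),
                                         group = rep("periodontitis", 4))),
               "two groups")
})

test_that("screening holds its nominal type-I error on null bins", {
  fp <- numeric(200)
  for (s in 1:200) {
    set.seed(500 + s)
    mat <- matrix(rexp(50 * 20), nrow = 50)
    pm <- toyPeakMatrix(mat, binMass = 2000 + 300 * (1:50),
                        group = rep(c("periodontitis", "control"), each = 10))
    sc <- screenPeaks(pm)
    fp[s] <- mean(sc$p < 0.05)
  }
  expect_gte(mean(fp), 0.03)
  expect_lte(mean(fp), 0.07)
})

test_that("dichotomization thresholds at the group-mean midpoint", {
  grp <- rep(c("periodontitis", "control"), each = 4)
  mat <- rbind(c(2, 2, 2, 2, 6, 6, 6, 6),    # means 2 and 6 -> threshold 4
               rep(0, 8),                     # constant: uninformative
               c(5, 5, 3, 3, 5, 3, 5, 3))
  pm <- toyPeakMatrix(mat, group = grp)
  d <- dichotomize(pm)
  rd <- SummarizedExperiment::rowData(d)
  b <- SummarizedExperiment::assay(d, "binary")
  expect_equal(rd$threshold[1], 4)
  expect_equal(unname(b[3, mat[3, ] > 4]), rep(1L, 4))
  expect_equal(unname(b[3, mat[3, ] < 4]), rep(0L, 4))
  expect_true(rd$uninformative[2])
  expect_equal(unname(b[2, ]), rep(0L, 8))

  ## presence/absence column is recovered exactly
  set.seed(9)
  pres <- rbinom(8, 1, 0.5)
  pres[1] <- 1; pres[5] <- 0   # both groups represented
  mat2 <- matrix(pres * rexp(8, 1 / 10), nrow = 1)
  pm2 <- toyPeakMatrix(mat2, group = grp)
  d2 <- dichotomize(pm2)
  expect_equal(unname(SummarizedExperiment::assay(d2, "binary")[1, ]),
               as.integer(mat2[1, ] > 0))
})

test_that("binary discriminant scores match the likelihood-ratio formula
           and rank perfect markers first", {
  grp <- rep(c("periodontitis", "control"), each = 10)

  ## identical group frequencies score zero
  same <- matrix(rep(c(1, 1, 0, 0, 0), 4), nrow = 1)
  expect_lt(abs(bindaRank(same, grp)$score), 1e-12)

  ## hand computation for counts 8/10 vs 2/10
  hand <- local({
    p1 <- (8 + 0.5) / 11; p2 <- (2 + 0.5) / 11; p0 <- (p1 + p2) / 2
    f <- function(p, q) p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
    10 * f(p1, p0) + 10 * f(p2, p0)
  })
  col <- matrix(c(rep(1, 8), 0, 0, 1, 1, rep(0, 8)), nrow = 1)
  expect_equal(bindaRank(col, grp)$score, hand, tolerance = 1e-12)

  ## perfect marker beats every other count pair (exhaustive, n = 20 + 20)
  g2 <- rep(c("periodontitis", "control"), each = 20)
  perfect <- periospec:::bindaScore(20, 20, 0, 20)
  grid <- expand.grid(x1 = 0:20, x2 = 0:20)
  grid <- grid[!(grid$x1 == 20 & grid$x2 == 0) &
                 !(grid$x1 == 0 & grid$x2 == 20), ]
  scores <- periospec:::bindaScore(grid$x1, 20, grid$x2, 20)
  expect_true(all(scores < perfect))

  ## ties break toward the lower reference mass
  two <- rbind(c(rep(1, 8), 0, 0, 1, 1, rep(0, 8)),
               c(rep(1, 8), 0, 0, 1, 1, rep(0, 8)))
  rk <- bindaRank(two, grp, binMass = c(5000, 3000))
  expect_equal(rk$binMass, c(3000, 5000))
})

test_that("ranking is invariant to column order, to zero-preserving monotone
           transforms, and to balanced duplication", {
  set.seed(55)
  grp <- rep(c("periodontitis", "control"), each = 12)
  ## presence patterns at per-bin constant intensity: dichotomization then
  ## recovers presence exactly, in any strictly monotone zero-fixing scale
  pres <- matrix(rbinom(10 * 24, 1, 0.4), nrow = 10)
  pres[1, ] <- c(rbinom(12, 1, 0.9), rbinom(12, 1, 0.15))
  mat <- pres * (10 + 5 * seq_len(10))
  pm <- toyPeakMatrix(mat, group = grp)
  rk <- bindaRank(dichotomize(pm), grp)

  ## sample order
  perm <- sample(24)
  pmP <- toyPeakMatrix(mat[, perm], group = grp[perm])
  expect_equal(bindaRank(dichotomize(pmP), grp[perm])$binMass, rk$binMass)

  ## bin (feature) order
  rperm <- sample(10)
  bm <- 3000 + 100 * seq_len(10)
  rk2 <- bindaRank((mat > SummarizedExperiment::rowData(
    dichotomize(pm))$threshold) * 1, grp, binMass = bm)
  rkPerm <- bindaRank((mat[rperm, ] >
    SummarizedExperiment::rowData(dichotomize(pm))$threshold[rperm]) * 1,
    grp, binMass = bm[rperm])
  expect_equal(rkPerm$binMass, rk2$binMass)

  ## strictly monotone transforms fixing zero, thresholds re-estimated
  for (f in list(sqrt, function(x) x^1.5)) {
    pmT <- toyPeakMatrix(f(mat), group = grp)
    expect_equal(bindaRank(dichotomize(pmT), grp)$binMass, rk$binMass)
  }

  ## duplicating every sample preserves the ranking order
  pmD <- toyPeakMatrix(cbind(mat, mat), group = c(grp, grp))
  expect_equal(bindaRank(dichotomize(pmD), c(grp, grp))$binMass, rk$binMass)
})
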