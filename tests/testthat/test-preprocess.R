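test_that("QC accepts strong spectra and names the failing criterion", {
  sp <- noisySpectrum(800, noiseSD = 10, base = 100, peaksAt = 400,
                      height = 5e4)
  expect_true(qcSpectrum(sp)$accept)

  weak <- MassSpectrum(mz(sp), intensity(sp) * 1e-3)
  r <- qcSpectrum(weak)
  expect_false(r$accept)
  expect_true("max-intensity" %in% r$reasons)

  flat <- MassSpectrum(2000 + 4 * (0:499), rep(2e4, 500))
  r2 <- qcSpectrum(flat)
  expect_false(r2$accept)
  expect_equal(r2$reasons, "spectrum-snr")
})

test_that("moving-average smoothing equals the brute-force windowed mean", {
  ## constant in, constant out
  const <- MassSpectrum(2000 + (0:99), rep(3.3, 100))
  expect_equal(intensity(smoothSpectrum(const)), rep(3.3, 100))

  ## interior unit impulse spreads to 1/17
  y <- rep(0, 101); y[51] <- 1
  imp <- smoothSpectrum(MassSpectrum(2000 + (0:100), y))
  expect_equal(intensity(imp)[51], 1 / 17)
  expect_equal(intensity(imp)[43], 1 / 17)
  expect_equal(intensity(imp)[42], 0)

  ## random spectra against a direct O(n*w) oracle, many seeds
  for (s in 1:100) {
    set.seed(s)
    n <- sample(30:200, 1)
    w <- sample(1:8, 1)
    yy <- runif(n)
    sm <- smoothSpectrum(MassSpectrum(2000 + (0:(n - 1)), yy), halfWindow = w)
    oracle <- vapply(seq_len(n), function(i)
      mean(yy[max(1, i - w):min(n, i + w)]), numeric(1))
    expect_equal(intensity(sm), oracle, tolerance = 1e-12)
  }

  expect_error(smoothSpectrum(MassSpectrum(1:10 + 2000, 1:10), 8), "at least")
})

test_that("SNIP baseline reproduces known decompositions", {
  n <- 1000
  mzv <- seq(2000, by = 4, length.out = n)

  ## peak-free ramp: the ramp is its own baseline
  ramp <- seq(0, 1e4, length.out = n)
  r <- snipBaseline(MassSpectrum(mzv, ramp))
  expect_lt(max(intensity(r$corrected)), 0.02 * 1e4)
  expect_true(all(r$baseline <= ramp + 1e-9))

  ## ramp + narrow Gaussian: apex recovered within 10%
  for (s in 1:100) {
    set.seed(s)
    pos <- sample(200:800, 1)
    h <- runif(1, 1e4, 1e5)
    g <- h * exp(-0.5 * ((seq_len(n) - pos) / 5)^2)
    r2 <- snipBaseline(MassSpectrum(mzv, ramp + g))
    expect_lt(abs(max(intensity(r2$corrected)) - h) / h, 0.1)
  }

  ## all-zero spectrum
  r3 <- snipBaseline(MassSpectrum(mzv[1:10], rep(0, 10)))
  expect_equal(r3$baseline, rep(0, 10))
  expect_equal(intensity(r3$corrected), rep(0, 10))

  ## negative intensities are rejected at construction already
  expect_error(MassSpectrum(c(2000, 2001), c(1, -1)), "non-negative")
})

test_that("TIC normalisation is scale-invariant and sums to one", {
  sp <- noisySpectrum(500, seed = 3)
  t1 <- ticNormalize(sp)
  t2 <- ticNormalize(MassSpectrum(mz(sp), 7.3 * intensity(sp)))
  expect_equal(intensity(t1), intensity(t2), tolerance = 1e-12)
  expect_equal(sum(intensity(t1)), 1, tolerance = 1e-12)
  expect_error(ticNormalize(MassSpectrum(c(2000, 2001), c(0, 0))),
               "zero total")
})

test_that("noise estimation is the scaled MAD", {
  expect_equal(estimateNoise(MassSpectrum(2000 + (0:9), rep(5, 10))), 0)
  expect_equal(estimateNoise(MassSpectrum(2000 + (0:9), rep(c(0, 2), 5))),
               1.4826)
  set.seed(11)
  y <- rnorm(1e4, 100, 7)
  expect_lt(abs(estimateNoise(pmax(y, 0)) - 7) / 7, 0.05)
  expect_error(estimateNoise(MassSpectrum(c(2000, 2001), c(1, 2))),
               "at least 3")
})

test_that("peak detection finds constructed peaks and matches a Monte-Carlo
           false-positive oracle on pure noise", {
  ## single strong Gaussian over a corrected-like trace: one high-SNR peak
  ## at the apex (+/- 1 grid point)
  sp <- noisySpectrum(1000, noiseSD = 10, base = 30, peaksAt = 300,
                      height = 200, seed = 5)
  pk <- detectPeaks(sp)
  strong <- which(peakSNR(pk) > 10)
  expect_equal(length(strong), 1L)
  expect_lt(abs(mz(pk)[strong] - (2000 + 4 * 299)), 4.1)

  ## two Gaussians 50 points apart resolve into two peaks
  sp2 <- noisySpectrum(1000, noiseSD = 10, base = 30, peaksAt = c(300, 350),
                       height = 200, seed = 6)
  pk2 <- detectPeaks(sp2)
  expect_equal(sum(peakSNR(pk2) > 10), 2L)

  ## pure-noise spurious rate: empirical detector rate must agree with an
  ## independent Monte-Carlo oracle of the same rule (strict 17-point max
  ## and intensity >= 3 * MAD)
  oracleHits <- detHits <- 0L
  npts <- 1e4
  for (s in 1:5) {
    set.seed(100 + s)
    y <- rnorm(npts, 50, 5)
    noise <- mad(y)
    isMax <- vapply(9:(npts - 8), function(i)
      y[i] == max(y[(i - 8):(i + 8)]) & sum(y[(i - 8):(i + 8)] == y[i]) == 1,
      logical(1))
    oracleHits <- oracleHits + sum(isMax & y[9:(npts - 8)] / noise >= 3)
    pk <- detectPeaks(MassSpectrum(2000 + (seq_len(npts) - 1) * 0.5, y))
    inner <- mz(pk) >= 2000 + 8 * 0.5 & mz(pk) <= 2000 + (npts - 9) * 0.5
    detHits <- detHits + sum(inner)
  }
  expect_equal(detHits, oracleHits)
})

test_that("quadratic warp fitting recovers known distortions", {
  ## aligned input -> identity coefficients
  p <- MassPeaks(c(3000, 5000, 8000, 12000), rep(1, 4))
  w <- fitWarp(p, p)
  expect_equal(w@coefficients, c(0, 1, 0), tolerance = 1e-9)
  expect_false(w@identity)

  ## known quadratic distortion m' = 1.5 + 1.0002 m + 1e-9 m^2: the fitted
  ## model reproduces it so anchor residuals vanish
  obs <- c(3000, 5000, 8000, 12000, 16000)
  truth <- 1.5 + 1.0002 * obs + 1e-9 * obs^2
  w2 <- fitWarp(MassPeaks(obs, rep(1, 5)), MassPeaks(truth, rep(1, 5)))
  expect_lt(max(abs(applyWarp(w2, obs) - truth) / truth), 1e-5)
  expect_equal(w2@nAnchors, 5L)

  ## fewer than 3 matches degrades to identity with a warning
  expect_warning(
    w3 <- fitWarp(MassPeaks(c(3000, 5000), c(1, 1)),
                  MassPeaks(c(3001, 5002), c(1, 1))),
    "identity")
  expect_true(w3@identity)
  expect_equal(applyWarp(w3, c(4000)), 4000)
})

test_that("alignment shrinks between-spectrum mass scatter of shared peaks", {
  base <- c(2500, 4000, 6000, 9000, 13000, 18000)
  set.seed(21)
  lists <- lapply(1:10, function(i) {
    c1 <- runif(1, -0.00075, 0.00075)
    c2 <- runif(1, -0.00075, 0.00075)
    MassPeaks(base * (1 + c1 + c2 * base / 20000), rep(1, length(base)))
  })
  al <- alignSpectra(lists)
  sdBefore <- sapply(seq_along(base), function(j)
    sd(sapply(lists, function(p) mz(p)[j])))
  sdAfter <- sapply(seq_along(base), function(j)
    sd(sapply(al$peaklists, function(p) mz(p)[j])))
  expect_true(all(sdAfter <= sdBefore / 5))

  ## identical peaklists stay unchanged
  same <- lapply(1:3, function(i) MassPeaks(base, rep(1, length(base))))
  al2 <- alignSpectra(same)
  expect_equal(mz(al2$peaklists[[1]]), base, tolerance = 1e-9)

  ## disjoint peaklists: warning, unchanged
  d1 <- MassPeaks(c(3000, 5000), c(1, 1))
  d2 <- MassPeaks(c(7000, 9000), c(1, 1))
  expect_warning(al3 <- alignSpectra(list(d1, d2)), "skipped")
  expect_equal(mz(al3$peaklists[[1]]), c(3000, 5000))
})

test_that("replicate averaging applies the frequency threshold and divides
           by the replicate count", {
  mk <- function(mzv, iv) MassPeaks(mzv, iv, snr = rep(10, length(mzv)))
  six <- replicate(6, mk(c(3000, 5000), c(2, 4)), simplify = FALSE)
  msp <- averageReplicates(six)
  expect_s4_class(msp, "MainSpectrumProfile")
  expect_equal(replicateCount(msp), 6L)
  expect_equal(mz(msp), c(3000, 5000))
  expect_equal(intensity(msp), c(2, 4))

  ## peak in 1 of 6 replicates at minFrequency 0.25 (ceil(1.5) = 2): dropped
  five <- replicate(5, mk(3000, 2), simplify = FALSE)
  one <- list(mk(c(3000, 7000), c(2, 9)))
  msp2 <- averageReplicates(c(five, one))
  expect_equal(mz(msp2), 3000)

  ## peak in 3 of 6 at intensity 2.0 -> retained at 3 * 2 / 6 = 1.0
  lists <- c(replicate(3, mk(c(3000, 5000), c(8, 2)), simplify = FALSE),
             replicate(3, mk(3000, 8), simplify = FALSE))
  msp3 <- averageReplicates(lists)
  expect_equal(intensity(msp3)[mz(msp3) == 5000], 1.0)

  expect_error(averageReplicates(list()), "no replicate")
})

test_that("the replicate chain is deterministic, TIC-invariant and
           order-invariant", {
  cfg <- simConfig("smoke", seed = 5)
  sp <- simulateSpectrum(cfg, "S001", "periodontitis", "saliva", 1)

  r1 <- preprocessSpectrum(sp)
  r2 <- preprocessSpectrum(sp)
  expect_identical(mz(r1$peaks), mz(r2$peaks))

  ## positive rescaling of the raw trace leaves peaks unchanged
  scaled <- MassSpectrum(mz(sp), 7.3 * intensity(sp), spectrumMetadata(sp))
  r3 <- preprocessSpectrum(scaled)
  expect_equal(mz(r3$peaks), mz(r1$peaks), tolerance = 1e-12)
  expect_equal(intensity(r3$peaks), intensity(r1$peaks), tolerance = 1e-9)

  ## permuting replicate order leaves the MSP peak set unchanged
  reps <- lapply(1:4, function(r)
    preprocessSpectrum(simulateSpectrum(cfg, "S001", "periodontitis",
                                        "saliva", r))$peaks)
  m1 <- averageReplicates(reps)
  m2 <- averageReplicates(rev(reps))
  expect_equal(mz(m1), mz(m2), tolerance = 1e-9)
  expect_equal(intensity(m1), intensity(m2), tolerance = 1e-12)
})
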