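## shared in-code fixtures

## flat-noise spectrum with optional Gaussian peaks (positions in points)
noisySpectrum <- function(n = 1000, noiseSD = 10, base = 100,
                          peaksAt = integer(), height = 500, sigma = 5,
                          seed = 1) {
  set.seed(seed)
  y <- pmax(stats::rnorm(n, base, noiseSD), 0)
  for (p in peaksAt)
    y <- y + height * exp(-0.5 * ((seq_len(n) - p) / sigma)^2)
  MassSpectrum(2000 + 4 * (seq_len(n) - 1), y)
}

## binary PeakMatrix-like intensity matrix from a plain matrix (bins x samples)
toyPeakMatrix <- function(mat, binMass = NULL, group = NULL) {
  if (is.null(binMass)) binMass <- 3000 + 100 * seq_len(nrow(mat))
  n <- ncol(mat)
  if (is.null(group))
    group <- rep(c("periodontitis", "control"), length.out = n)
  cd <- data.frame(subject = sprintf("S%02d", seq_len(n)),
                   sampleType = "saliva", group = group,
                   row.names = sprintf("S%02d.saliva", seq_len(n)),
                   stringsAsFactors = FALSE)
  colnames(mat) <- rownames(cd)
  periospec:::newPeakMatrix(mat, binMass = binMass, colData = cd)
}

## printed-precision comparison: journals truncate as often as they round,
## so a computed value agrees with a printed one when either rounding or
## truncating at the printed digits reproduces it
agreesAtPrintedPrecision <- function(computed, printed) {
  digits <- nchar(sub("^-?[0-9]*\\.", "", as.character(printed)))
  isTRUE(all.equal(round(computed, digits), printed, tolerance = 1e-9)) ||
    isTRUE(all.equal(trunc(computed * 10^digits) / 10^digits, printed,
                     tolerance = 1e-9))
}

## exact two-sided rank-sum p-value by full enumeration over group
## assignments (oracle; independent of wilcox.test)
enumRankSumP <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(v), n1)
  ws <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}
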