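#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson chi-square with one degree of freedom,
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, the test that reproduces
#' the printed between-group p-values of the cohort table from its printed
#' counts. The continuity-corrected or exact variants do not.
#'
#' @param a,b,c,d cell counts: (a, b) = cases with/without the trait,
#'   (c, d) = controls with/without.
#' @return list with `chi2`, `df` (= 1) and `p`.
#' @examples
#' chiSquare2x2(16, 51, 4, 70)$p   # 0.0017
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stopf("chi-square undefined: zero marginal total")
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Welch two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t-test computed from group means, standard
#' deviations and sizes (as printed in a cohort table), with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param m1,sd1,n1 mean, sd, size of group 1.
#' @param m2,sd2,n2 mean, sd, size of group 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welchFromSummary(50.18, 13.85, 67, 24.50, 3.28, 74)$p   # < 0.0001
#' @export
welchFromSummary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Stage-by-grade relative frequencies
#'
#' Converts a stage (columns) by grade (rows) count table of the diseased
#' group into percentages of the group total, rounded to one decimal, with
#' row/column margins.
#'
#' @param counts numeric matrix of counts (grades x stages).
#' @param total denominator; defaults to `sum(counts)`.
#' @return list with `percent` (matrix incl. margins, 1 decimal) and
#'   `counts` (with margins).
#' @examples
#' stageGradeFrequencies(matrix(c(0, 31), 1))$percent
#' @export
stageGradeFrequencies <- function(counts, total = sum(counts)) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  if (total <= 0) stopf("zero total count")
  withm <- rbind(cbind(counts, Total = rowSums(counts)),
                 Total = c(colSums(counts), sum(counts)))
  list(percent = round(100 * withm / total, 1), counts = withm)
}

#' Association screen between top-ranked peaks and cohort covariates
#'
#' Z-scores the joint matrix of top-ranked peak intensities and
#' epidemiological covariates, runs a principal component analysis on it,
#' and reports every peak-covariate absolute Pearson correlation plus, per
#' pair, whether both load most strongly on the same leading component.
#' The peaks are flagged "independent" of the risk factors when the largest
#' absolute correlation stays below `bound`.
#'
#' @param peaks numeric matrix, subjects x top peaks (columns named by mass).
#' @param cohort data.frame of covariates per subject (numeric or 0/1);
#'   constant columns are dropped with a warning.
#' @param bound independence bound on max |r| (default 0.3).
#' @return list with `correlations` (peaks x covariates matrix of |r|),
#'   `maxCorrelation`, `independent` (logical), `pca` (sdev + rotation),
#'   `sharedLoadings` (data.frame of pairs loading on one component).
#' @export
peakCovariateAssociation <- function(peaks, cohort, bound = 0.3) {
  peaks <- as.matrix(peaks)
  stopifnot(nrow(peaks) >= 3L)
  cov_ <- as.data.frame(cohort)
  cov_ <- cov_[vapply(cov_, is.numeric, logical(1))]
  keep <- vapply(cov_, function(x) stats::sd(x) > 0, logical(1))
  if (any(!keep))
    warnf("dropping constant covariate(s): %s",
          paste(names(cov_)[!keep], collapse = ", "))
  cov_ <- cov_[keep]
  if (!ncol(cov_)) stopf("no non-constant covariate available")
  if (nrow(cov_) != nrow(peaks))
    stopf("peaks and cohort must describe the same subjects")
  keepPk <- apply(peaks, 2L, stats::sd) > 0
  pk <- peaks[, keepPk, drop = FALSE]
  joint <- scale(cbind(pk, as.matrix(cov_)))
  pca <- stats::prcomp(joint, center = FALSE, scale. = FALSE)
  cors <- abs(stats::cor(pk, as.matrix(cov_)))
  ## component on which each variable loads most strongly
  lead <- apply(abs(pca$rotation), 1L, which.max)
  np <- ncol(pk)
  shared <- expand.grid(peak = colnames(pk), covariate = colnames(cov_),
                        stringsAsFactors = FALSE)
  shared$sameComponent <- lead[shared$peak] == lead[shared$covariate]
  maxCor <- max(cors)
  list(correlations = cors, maxCorrelation = maxCor,
       independent = maxCor < bound, bound = bound,
       pca = list(sdev = pca$sdev, rotation = pca$rotation),
       sharedLoadings = shared[shared$sameComponent, , drop = FALSE])
}

#' Printed cohort-table counts
#'
#' The binary covariate counts of the study cohort (67 periodontitis, 74
#' control subjects): per covariate the number of positives in each group,
#' plus the age summary statistics. Used to reproduce the between-group
#' p-values.
#'
#' @return list with `binary` (data.frame: covariate, casesYes, casesNo,
#'   controlsYes, controlsNo), `age` (named list of summary stats),
#'   `stageGrade` (3x4 count matrix, grades A-C x stages 1-4) and `nCases`,
#'   `nControls`.
#' @export
cohortTableCounts <- function() {
  nCases <- 67L; nControls <- 74L
  cov_ <- data.frame(
    covariate = c("current_smoker", "former_smoker", "diabetes",
                  "cardiovascular_disease", "hypothyroidism", "arthritis",
                  "respiratory_disease", "antidiabetic_medication",
                  "antibiotics", "antiinflammatory", "antihypertensive",
                  "anticoagulants", "thyroxine", "contraception", "stress"),
    casesYes = c(18L, 16L, 4L, 8L, 10L, 2L, 4L, 4L, 2L, 2L, 6L, 6L, 8L,
                 11L, 29L),
    controlsYes = c(17L, 4L, 0L, 3L, 1L, 1L, 3L, 0L, 3L, 11L, 1L, 1L, 1L,
                    21L, 41L),
    stringsAsFactors = FALSE)
  cov_$casesNo <- nCases - cov_$casesYes
  cov_$controlsNo <- nControls - cov_$controlsYes
  sg <- matrix(c(0L, 3L, 0L, 0L,
                 0L, 5L, 15L, 6L,
                 0L, 0L, 16L, 22L),
               nrow = 3L, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("1", "2", "3", "4")))
  list(binary = cov_[, c("covariate", "casesYes", "casesNo", "controlsYes",
                         "controlsNo")],
       age = list(meanCases = 50.18, sdCases = 13.85, nCases = nCases,
                  meanControls = 24.50, sdControls = 3.28,
                  nControls = nControls),
       stageGrade = sg, nCases = nCases, nControls = nControls)
}

#' Reproduce the cohort-table between-group statistics
#'
#' Runs [chiSquare2x2()] on every binary covariate of
#' [cohortTableCounts()] and [welchFromSummary()] on the age row.
#'
#' @return data.frame: covariate, chi2, p (age row carries t in `chi2`).
#' @export
cohortTableTests <- function() {
  ct <- cohortTableCounts()
  b <- ct$binary
  out <- data.frame(covariate = b$covariate, statistic = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(b))) {
    r <- chiSquare2x2(b$casesYes[i], b$casesNo[i], b$controlsYes[i],
                      b$controlsNo[i])
    out$statistic[i] <- r$chi2
    out$p[i] <- r$p
  }
  ag <- ct$age
  w <- welchFromSummary(ag$meanCases, ag$sdCases, ag$nCases,
                        ag$meanControls, ag$sdControls, ag$nControls)
  rbind(data.frame(covariate = "age", statistic = w$t, p = w$p,
                   stringsAsFactors = FALSE), out)
}
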