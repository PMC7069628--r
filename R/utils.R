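## internal helpers shared across modules

SAMPLE_TYPES <- c("saliva", "gcf", "plaque")
GROUPS <- c("periodontitis", "control", "unknown")
POSITIVE_CLASS <- "periodontitis"
NEGATIVE_CLASS <- "control"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

checkSampleType <- function(x) {
  bad <- setdiff(unique(x), SAMPLE_TYPES)
  if (length(bad))
    stopf("unknown sample type(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(SAMPLE_TYPES, collapse = "/"))
  invisible(x)
}

checkGroup <- function(x) {
  bad <- setdiff(unique(x), GROUPS)
  if (length(bad))
    stopf("unknown group label(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(GROUPS, collapse = "/"))
  invisible(x)
}

## Divisive clustering of sorted masses: a block is one cluster iff its
## relative spread (max - min)/mean <= 2 * tolerance, otherwise it is split
## at its largest internal gap. Returns an integer cluster id per input mass
## (ids ordered by ascending mass). Deterministic; ties in the largest gap
## split at the left-most such gap.
clusterMasses <- function(masses, tolerance) {
  n <- length(masses)
  if (n == 0L) return(integer())
  o <- order(masses)
  m <- masses[o]
  ids <- integer(n)
  nextId <- 0L
  stack <- list(c(1L, n))
  repeat {
    if (!length(stack)) break
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- rng[1]; hi <- rng[2]
    if (lo == hi || (m[hi] - m[lo]) / mean(m[lo:hi]) <= 2 * tolerance) {
      nextId <- nextId + 1L
      ids[lo:hi] <- nextId
    } else {
      gaps <- diff(m[lo:hi])
      cut <- lo + which.max(gaps) - 1L   # split between cut and cut+1
      ## push right first so the left block is processed first (ascending ids)
      stack[[length(stack) + 1L]] <- c(cut + 1L, hi)
      stack[[length(stack) + 1L]] <- c(lo, cut)
    }
  }
  out <- integer(n)
  out[o] <- ids
  out
}

## Deterministic 32-bit-safe stage seed derived from a master seed and a
## stage name, so optional stages cannot shift each other's RNG draws.
stageSeed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

withStageSeed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stageSeed(seed, stage))
  expr
}
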