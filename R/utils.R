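# Shared internal helpers: deterministic seeding, weighted percentiles,
# column statistics.

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

# Derive a child seed from a master seed and a counter, staying below 2^31.
# A fixed LCG-style mix keeps streams distinct across subsamples, reference
# sets and tree nodes while remaining platform independent.
.deriveSeed <- function(seed, counter) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  x <- (s * 48271 + as.numeric(counter) * 7919 + 12345) %% 2147483647
  as.integer(x)
}

# Stable integer hash of a node identifier such as "0.2.1".
.hashString <- function(x) {
  codes <- utf8ToInt(x)
  h <- 7
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Nearest-rank weighted percentile: index (into d/w) of the element at the
# p-th percentile of the weighted empirical CDF of d.  Ties in d resolve to
# the lowest original index (stable order).
.weightedPercentileIndex <- function(d, w, p) {
  stopifnot(length(d) == length(w), length(d) >= 1L)
  ord <- order(d, seq_along(d))
  cw <- cumsum(w[ord])
  target <- p / 100 * cw[length(cw)]
  pos <- which(cw >= target - 1e-12)[1L]
  if (is.na(pos)) pos <- length(ord)
  ord[pos]
}

# Sample column variances without forming a centred copy per column.
.colVars <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("at least two observations are required for variances")
  mu <- colMeans(m)
  v <- (colSums(m * m) - n * mu * mu) / (n - 1)
  pmax(v, 0)
}

.valuesOf <- function(m) {
  if (is(m, "AbundanceMatrix")) m@values else as.matrix(m)
}

.collectLeaves <- function(node) {
  if (length(node$children) == 0L) return(list(node))
  out <- list()
  for (ch in node$children) out <- c(out, .collectLeaves(ch))
  out
}
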