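# Local, data-driven feature filtering: 1-D Gaussian-mixture decomposition
# of per-feature log statistics, with crossing-point thresholds.

#' Per-feature log10 statistics
#'
#' Base-10 logarithm of the per-feature mean abundance or of the per-feature
#' sample variance across the observations of a (sub)cluster.  Features
#' whose raw statistic is exactly zero receive a `-Inf` sentinel: they are
#' excluded from mixture fitting and always dropped by the filters.
#'
#' @param m an [AbundanceMatrix-class] or nonnegative numeric matrix.
#' @param which `"mean"` or `"variance"`.
#' @return numeric vector of length `n_feat` (log10 scale, `-Inf` allowed).
#' @export
logFeatureStats <- function(m, which = c("mean", "variance")) {
  which <- match.arg(which)
  v <- .valuesOf(m)
  if (which == "variance" && nrow(v) < 2L) {
    stop("variance statistics need at least two observations", call. = FALSE)
  }
  s <- if (which == "mean") colMeans(v) else .colVars(v)
  out <- rep(-Inf, length(s))
  pos <- s > 0
  out[pos] <- log10(s[pos])
  out
}

#' Fit a one-dimensional Gaussian mixture with BIC model selection
#'
#' EM fits with 1 to `maxComponents` components; the component count
#' minimising BIC (\eqn{-2\log L + p\log n}) is selected, with ties broken
#' towards fewer components.  Components to which fewer than 1\% of the
#' points are assigned by the maximum-posterior rule are discarded and the
#' remaining weights renormalised.  EM is delegated to
#' \code{mclust::Mclust} with unequal-variance one-dimensional models and
#' its deterministic model-based hierarchical initialisation, so repeated
#' fits are bit-identical.
#'
#' @param x finite numeric vector, length at least 10.
#' @param maxComponents largest component count tried.
#' @param rngSeed accepted for interface stability; the initialisation is
#'   deterministic, so the fit does not depend on it.
#' @param minShare minimum maximum-posterior share a component must hold.
#' @return a [GaussianMixture1D-class].
#' @export
fitGmm1d <- function(x, maxComponents = 10L, rngSeed = 0L, minShare = 0.01) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  n <- length(x)
  if (n < 10L) stop("at least 10 points are required", call. = FALSE)
  if (diff(range(x)) < sqrt(.Machine$double.eps)) {
    stop("degenerate input: all values are (numerically) identical",
         call. = FALSE)
  }
  best <- NULL
  bestBic <- Inf
  for (G in seq_len(max(1L, as.integer(maxComponents)))) {
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(
        x, G = G, modelNames = if (G == 1L) "X" else "V", verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || is.null(fit$loglik) || !is.finite(fit$loglik)) next
    bic <- -2 * fit$loglik + fit$df * log(n)
    if (bic < bestBic - 1e-9) {  # strict improvement: ties keep smaller G
      bestBic <- bic
      best <- fit
    }
  }
  if (is.null(best)) stop("Gaussian mixture fitting failed", call. = FALSE)

  w <- as.numeric(best$parameters$pro)
  if (is.null(w)) w <- 1
  mu <- as.numeric(best$parameters$mean)
  sg <- sqrt(as.numeric(best$parameters$variance$sigmasq))
  if (length(sg) == 1L) sg <- rep(sg, length(mu))
  sg <- pmax(sg, 1e-6 * stats::sd(x))

  assign1 <- .mapAssign(x, w, mu, sg)
  share <- tabulate(assign1, nbins = length(mu)) / n
  keep <- share >= minShare
  if (!any(keep)) keep[which.max(share)] <- TRUE
  w <- w[keep] / sum(w[keep])
  mu <- mu[keep]
  sg <- sg[keep]
  assign2 <- .mapAssign(x, w, mu, sg)
  share <- tabulate(assign2, nbins = length(mu)) / n

  ord <- order(mu)
  new("GaussianMixture1D",
      weights = w[ord], means = mu[ord], sds = sg[ord],
      nComponents = length(mu), bic = bestBic,
      componentShares = share[ord])
}

# Maximum-posterior component assignment for a 1-D mixture.
.mapAssign <- function(x, w, mu, sg) {
  ld <- vapply(seq_along(mu), function(j) {
    log(w[j]) + stats::dnorm(x, mu[j], sg[j], log = TRUE)
  }, numeric(length(x)))
  if (is.null(dim(ld))) ld <- matrix(ld, nrow = length(x))
  max.col(ld, ties.method = "first")
}

#' Crossing points between adjacent mixture components
#'
#' For each pair of components adjacent in mean order, the point strictly
#' between the two means where the weighted component densities are equal,
#' located by bracketed root finding on the log-density difference.  When
#' the difference does not change sign between the means (strongly
#' overlapping or extremely unbalanced components) the midpoint of the two
#' means is used instead and a message is emitted.
#'
#' @param g a [GaussianMixture1D-class].
#' @return sorted numeric vector of thresholds, one per adjacent pair;
#'   empty for a single-component model.
#' @export
crossingThresholds <- function(g) {
  stopifnot(is(g, "GaussianMixture1D"))
  k <- g@nComponents
  if (k < 2L) return(numeric(0))
  out <- numeric(k - 1L)
  for (i in seq_len(k - 1L)) {
    w1 <- g@weights[i];  m1 <- g@means[i];  s1 <- g@sds[i]
    w2 <- g@weights[i + 1L]; m2 <- g@means[i + 1L]; s2 <- g@sds[i + 1L]
    f <- function(x) {
      (log(w1) + stats::dnorm(x, m1, s1, log = TRUE)) -
        (log(w2) + stats::dnorm(x, m2, s2, log = TRUE))
    }
    eps <- 1e-9 * max(1, abs(m2 - m1))
    a <- m1 + eps
    b <- m2 - eps
    if (b <= a || !is.finite(f(a)) || !is.finite(f(b)) ||
        sign(f(a)) == sign(f(b))) {
      message("crossing point not bracketed between component means ",
              format(m1), " and ", format(m2), "; using midpoint")
      out[i] <- (m1 + m2) / 2
    } else {
      out[i] <- stats::uniroot(f, c(a, b), tol = 1e-10)$root
    }
  }
  sort(out)
}

# Shared scaffolding of the two filters: returns list(stat, finite, model)
# with model NULL when fewer than 10 finite statistics are available.
.fitFilterModel <- function(m, which, maxComponents) {
  stat <- logFeatureStats(m, which)
  finite <- is.finite(stat)
  model <- NULL
  if (sum(finite) >= 10L &&
      diff(range(stat[finite])) >= sqrt(.Machine$double.eps)) {
    model <- fitGmm1d(stat[finite], maxComponents = maxComponents)
  }
  list(stat = stat, finite = finite, model = model)
}

#' Global abundance (noise) filter
#'
#' Decomposes the distribution of per-feature log10 mean abundance into a
#' Gaussian mixture and removes every feature whose log mean falls below
#' the first (leftmost) crossing point — the noise floor.  Applied once, on
#' the root data.  A single-component model keeps all features; features
#' with zero mean abundance are always removed.
#'
#' @param m an [AbundanceMatrix-class] or matrix.
#' @param maxComponents largest mixture size tried.
#' @return a [FeatureFilter-class] with `kind = "abundance"`.
#' @export
abundanceFilter <- function(m, maxComponents = 10L) {
  parts <- .fitFilterModel(m, "mean", maxComponents)
  stat <- parts$stat
  mask <- parts$finite
  thresholds <- numeric(0)
  chosen <- NA_real_
  if (!is.null(parts$model) && parts$model@nComponents > 1L) {
    thresholds <- crossingThresholds(parts$model)
    chosen <- thresholds[1L]
    mask <- parts$finite & stat >= chosen
    if (!any(mask)) mask <- seq_along(stat) == which.max(stat)
  }
  new("FeatureFilter", kind = "abundance", statistic = stat,
      model = parts$model, thresholds = thresholds,
      chosenThreshold = chosen, mask = mask)
}

#' Local variance filter
#'
#' Decomposes the distribution of per-feature log10 abundance variance
#' (computed across the observations of the current subcluster) into a
#' Gaussian mixture and keeps only the features above the topmost crossing
#' point, provided at least `ceiling(minFeatureFraction * n_feat)` features
#' survive; otherwise successively lower crossing points are tried.  If no
#' crossing point satisfies the bound, the top features by variance are
#' kept up to the bound.  A single-component model keeps all features;
#' zero-variance features are always removed.
#'
#' @param m an [AbundanceMatrix-class] or matrix with at least two rows.
#' @param minFeatureFraction minimum retained fraction of the feature pool,
#'   in (0, 1].
#' @param maxComponents largest mixture size tried.
#' @return a [FeatureFilter-class] with `kind = "variance"`.
#' @export
varianceFilter <- function(m, minFeatureFraction = 0.01, maxComponents = 10L) {
  stopifnot(minFeatureFraction > 0, minFeatureFraction <= 1)
  parts <- .fitFilterModel(m, "variance", maxComponents)
  stat <- parts$stat
  nFeat <- length(stat)
  minKeep <- min(ceiling(minFeatureFraction * nFeat), sum(parts$finite))
  minKeep <- max(minKeep, 1L)
  mask <- parts$finite
  thresholds <- numeric(0)
  chosen <- NA_real_
  if (!is.null(parts$model) && parts$model@nComponents > 1L) {
    thresholds <- crossingThresholds(parts$model)
    for (t in rev(thresholds)) {  # topmost first
      cand <- parts$finite & stat >= t
      if (sum(cand) >= minKeep) {
        chosen <- t
        mask <- cand
        break
      }
    }
    if (is.na(chosen)) {
      ord <- order(stat, decreasing = TRUE)
      mask <- logical(nFeat)
      mask[ord[seq_len(minKeep)]] <- TRUE
    }
  }
  if (!any(mask)) mask <- seq_along(stat) == which.max(stat)
  new("FeatureFilter", kind = "variance", statistic = stat,
      model = parts$model, thresholds = thresholds,
      chosenThreshold = chosen, mask = mask)
}

setMethod("show", "GaussianMixture1D", function(object) {
  cat("GaussianMixture1D with", object@nComponents, "component(s), BIC",
      format(object@bic, digits = 6), "\n")
  print(data.frame(weight = round(object@weights, 4),
                   mean = round(object@means, 4),
                   sd = round(object@sds, 4),
                   share = round(object@componentShares, 4)))
})

setMethod("show", "FeatureFilter", function(object) {
  cat("FeatureFilter (", object@kind, "): keeps ", sum(object@mask), " of ",
      length(object@mask), " features\n", sep = "")
  if (!is.na(object@chosenThreshold)) {
    cat("  threshold (log10):", format(object@chosenThreshold, digits = 5),
        "\n")
  }
})
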