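# Synthetic benchmark generators: a 3000-point two-dimensional mixture with
# planted hierarchical structure (overlapping uniform / curve / line /
# Gaussian components), and binary-set data with planted Jaccard clusters.

#' Default two-dimensional mixture specification
#'
#' A frozen 3000-point benchmark with the structure used throughout the
#' package's tests: a uniform box containing a sine curve and a Gaussian, a
#' line segment grazing a second Gaussian, and a third free-standing
#' Gaussian.  Component densities contrast (Gaussian cores dense, box and
#' line sparse) so the overlapped structures merge at coarse observation
#' scales and separate at finer ones.
#'
#' @return a list of component descriptions consumed by
#'   \code{\link{makeMixture}}.
#' @export
defaultMixtureSpec <- function() {
  list(
    list(shape = "uniform", label = "uniform", n = 550L,
         box = c(0, 20, 0, 20)),
    list(shape = "curve", label = "curve", n = 400L,
         xlim = c(1, 19), base = 10, amp = 3.5, freq = 0.55, noise = 0.12),
    list(shape = "gaussian", label = "gauss1", n = 600L,
         center = c(5, 3.5), sd = 0.7),
    list(shape = "line", label = "line", n = 250L,
         from = c(24, 2), to = c(44, 16), noise = 0.12),
    list(shape = "gaussian", label = "gauss2", n = 600L,
         center = c(32.97, 10.47), sd = 0.7),
    list(shape = "gaussian", label = "gauss3", n = 600L,
         center = c(40, 2), sd = 0.7))
}

#' Generate a planted two-dimensional mixture
#'
#' Component shapes: \code{gaussian} (isotropic normal around a centre),
#' \code{line} (uniform positions along a segment plus normal noise),
#' \code{curve} (uniform abscissa along a sine arc plus normal noise) and
#' \code{uniform} (uniform in an axis-aligned box).  Deterministic under
#' \code{seed}; every point carries its component label.
#'
#' @param spec list of component descriptions (see
#'   \code{\link{defaultMixtureSpec}}).
#' @param seed RNG seed.
#' @return list with \code{data} (n x 2 matrix) and \code{labels} (character).
#' @examples
#' mix <- makeMixture(seed = 1)
#' table(mix$labels)
#' @export
makeMixture <- function(spec = defaultMixtureSpec(), seed = 1L) {
  if (any(vapply(spec, function(co) co$n, numeric(1)) <= 0))
    stop("component point counts must be positive")
  withSeed(seed, {
    parts <- lapply(spec, function(co) {
      n <- as.integer(co$n)
      pts <- switch(co$shape,
        gaussian = cbind(rnorm(n, co$center[1L], co$sd),
                         rnorm(n, co$center[2L], co$sd)),
        uniform = cbind(runif(n, co$box[1L], co$box[2L]),
                        runif(n, co$box[3L], co$box[4L])),
        line = {
          u <- runif(n)
          cbind(co$from[1L] + u * (co$to[1L] - co$from[1L]) +
                  rnorm(n, 0, co$noise),
                co$from[2L] + u * (co$to[2L] - co$from[2L]) +
                  rnorm(n, 0, co$noise))
        },
        curve = {
          x <- runif(n, co$xlim[1L], co$xlim[2L])
          cbind(x + rnorm(n, 0, co$noise),
                co$base + co$amp * sin(co$freq * (x - co$xlim[1L])) +
                  rnorm(n, 0, co$noise))
        },
        stop("unknown component shape: ", co$shape))
      list(pts = pts, label = rep(co$label, n))
    })
    list(data = do.call(rbind, lapply(parts, `[[`, "pts")),
         labels = unlist(lapply(parts, `[[`, "label")))
  })
}

#' Generate binary codes with planted Jaccard clusters
#'
#' Each cluster owns a disjoint core marker set; a point of the cluster
#' carries each core marker independently with probability \code{1 - flip}
#' and each non-core dimension with probability \code{background}.  Expected
#' within-cluster Jaccard exceeds the between-cluster expectation by
#' construction (see \code{\link{expectedPlantedJaccard}}).
#'
#' @param nClusters number of planted clusters.
#' @param perCluster points per cluster.
#' @param D code length; the disjoint cores must fit (nClusters * coreSize
#'   <= D).
#' @param coreSize markers per cluster core.
#' @param flip probability a core marker is dropped.
#' @param background marking probability for non-core dimensions.
#' @param seed RNG seed.
#' @return list with \code{codes} (\linkS4class{BinaryCodes}) and
#'   \code{labels}.
#' @export
makePlantedBinary <- function(nClusters = 5L, perCluster = 100L, D = 500L,
                              coreSize = 30L, flip = 0.1, background = 0.01,
                              seed = 1L) {
  nClusters <- as.integer(nClusters)
  if (nClusters * coreSize > D)
    stop("disjoint cores overflow code length D")
  withSeed(seed, {
    markers <- list()
    labels <- character(0)
    for (cl in seq_len(nClusters)) {
      core <- ((cl - 1L) * coreSize + 1L):(cl * coreSize)
      noncore <- setdiff(seq_len(D), core)
      for (p in seq_len(perCluster)) {
        m <- c(core[runif(coreSize) > flip],
               noncore[runif(length(noncore)) < background])
        if (!length(m)) m <- core[1L]   # degenerate all-flipped point
        markers[[length(markers) + 1L]] <- m
        labels <- c(labels, paste0("c", cl))
      }
    }
    list(codes = BinaryCodes(markers, D), labels = labels)
  })
}

#' Expected within/between Jaccard of the planted-binary model
#'
#' First-order (ratio of expectations) approximation: for two points of the
#' same cluster each core marker is shared with probability
#' \eqn{(1-flip)^2} and present in the union with probability
#' \eqn{1-flip^2}; non-core markers contribute \eqn{g^2} and \eqn{2g - g^2}
#' with background rate g.  Between clusters only background markers and the
#' other core's markers can coincide.
#'
#' @inheritParams makePlantedBinary
#' @return list with \code{within} and \code{between} expected Jaccard.
#' @export
expectedPlantedJaccard <- function(D = 500L, coreSize = 30L, flip = 0.1,
                                   background = 0.01) {
  g <- background
  q <- 1 - flip
  within <- (coreSize * q^2 + (D - coreSize) * g^2) /
            (coreSize * (1 - flip^2) + (D - coreSize) * (2 * g - g^2))
  # distinct cores: each core dim marked w.p. q in one point, g in the other
  between <- (2 * coreSize * q * g + (D - 2 * coreSize) * g^2) /
             (2 * coreSize * (q + g - q * g) +
              (D - 2 * coreSize) * (2 * g - g^2))
  list(within = within, between = between)
}
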