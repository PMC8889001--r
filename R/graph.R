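# The WFC driver: per-scale graph construction, union-find connected
# components, cross-scale hierarchy, automatic coding selection.

#' Connected components of an edge stream
#'
#' Union-find with path compression and union by size.  Labels are
#' canonicalised so each cluster id is the smallest member point index;
#' singletons are reported as isolated.
#'
#' @param n number of points.
#' @param edges integer matrix with two columns of endpoints in \code{1..n}
#'   (zero rows allowed).
#' @param scale scale index recorded in the result.
#' @return a \linkS4class{ScaleClustering}.
#' @examples
#' clusterSizes(connectedComponents(5, rbind(c(1, 2), c(2, 3))))
#' @export
connectedComponents <- function(n, edges, scale = 1L) {
  n <- as.integer(n)
  if (is.null(edges)) edges <- matrix(integer(0), 0L, 2L)
  storage.mode(edges) <- "integer"
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n))
    stop("edge endpoint out of range 1..", n)
  parent <- seq_len(n)
  size <- rep.int(1L, n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {        # path compression
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
      if (ra != rb) {
        if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
        parent[rb] <- ra
        size[ra] <- size[ra] + size[rb]
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  minIdx <- vapply(split(seq_len(n), comp), min, integer(1))
  labels <- unname(minIdx[as.character(comp)])
  sizes <- table(labels)
  sizesInt <- as.integer(sizes)
  names(sizesInt) <- names(sizes)
  new("ScaleClustering", scale = as.integer(scale), labels = labels,
      sizes = sizesInt,
      isolated = as.integer(names(sizes))[sizesInt == 1L])
}

# Multi-scale components in one union-find pass: edges are sorted by
# descending similarity and added once, from the finest threshold down to the
# grossest; the component labelling is snapshotted at each scale.  Total
# union work is one pass over the edges instead of one per scale.
multiScaleComponents <- function(n, edges, sims, thresholds) {
  storage.mode(edges) <- "integer"
  o <- order(-sims)
  edges <- edges[o, , drop = FALSE]
  sims <- sims[o]
  parent <- seq_len(n)
  size <- rep.int(1L, n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  out <- vector("list", length(thresholds))
  ptr <- 1L
  for (s in rev(seq_along(thresholds))) {
    while (ptr <= nrow(edges) && sims[ptr] >= thresholds[s] - 1e-12) {
      ra <- find(edges[ptr, 1L]); rb <- find(edges[ptr, 2L])
      if (ra != rb) {
        if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
        parent[rb] <- ra
        size[ra] <- size[ra] + size[rb]
      }
      ptr <- ptr + 1L
    }
    comp <- vapply(seq_len(n), find, integer(1))
    minIdx <- vapply(split(seq_len(n), comp), min, integer(1))
    labels <- unname(minIdx[as.character(comp)])
    sizes <- table(labels)
    sizesInt <- as.integer(sizes)
    names(sizesInt) <- names(sizes)
    out[[s]] <- new("ScaleClustering", scale = as.integer(s),
                    labels = labels, sizes = sizesInt,
                    isolated = as.integer(names(sizes))[sizesInt == 1L])
  }
  out
}

#' Automatic SD/DM coding selection
#'
#' SD grid linking enumerates \code{3^d} neighbour cells and is only viable
#' in low dimension; the choice between SD and DM therefore depends on the
#' data dimension (and dataset size, through the sub-quadratic contract of
#' each coding).  SD is chosen for \code{d <= 12}, DM otherwise; an explicit
#' override is honoured, except that SD is refused in high dimension.
#'
#' @param n,d dataset size and dimension.
#' @param override optional \code{"sd"} or \code{"dm"}.
#' @return \code{"sd"} or \code{"dm"}.
#' @export
selectCoding <- function(n, d, override = NULL) {
  if (n < 1L || d < 1L) stop("need n >= 1 and d >= 1")
  if (!is.null(override)) {
    override <- match.arg(override, c("sd", "dm"))
    if (override == "sd" && d > .SD_MAX_DIM)
      stop("SD coding infeasible for d = ", d,
           " (neighbour enumeration is 3^d); use DM")
    return(override)
  }
  chosen <- if (d <= .SD_MAX_DIM) "sd" else "dm"
  message(sprintf("selectCoding: n = %d, d = %d -> %s coding", n, d, chosen))
  chosen
}

#' Assemble the cross-scale cluster hierarchy
#'
#' The parent of a scale-s cluster is the scale-(s-1) cluster containing its
#' members.  If the members span several coarser clusters (possible only in
#' SD mode, where grid adjacency is not strictly nested across scales) the
#' majority parent is assigned and the event counted; with
#' \code{strict = TRUE} (DM mode with exact verification) the subset property
#' is asserted instead of repaired.
#'
#' @param perScale list of \linkS4class{ScaleClustering} over the same n.
#' @param strict error on any non-nested cluster instead of repairing.
#' @return a \linkS4class{WFCHierarchy}.
#' @export
buildHierarchy <- function(perScale, strict = FALSE) {
  stopifnot(length(perScale) >= 1L)
  n <- length(perScale[[1L]]@labels)
  if (any(vapply(perScale, function(p) length(p@labels), integer(1)) != n))
    stop("inconsistent number of points across scales")
  nodes <- list()
  repaired <- 0L
  for (s in seq_along(perScale)) {
    cl <- perScale[[s]]
    ids <- as.integer(names(cl@sizes))
    parent <- rep(NA_integer_, length(ids))
    if (s > 1L) {
      prev <- perScale[[s - 1L]]@labels
      for (ci in seq_along(ids)) {
        pl <- prev[cl@labels == ids[ci]]
        tab <- table(pl)
        if (length(tab) > 1L) {
          if (strict)
            stop("hierarchy violation: scale-", s, " cluster ", ids[ci],
                 " spans ", length(tab), " coarser clusters")
          repaired <- repaired + 1L
        }
        parent[ci] <- as.integer(names(tab))[which.max(tab)]
      }
    }
    nodes[[s]] <- data.frame(scale = s, id = ids,
                             size = unname(cl@sizes), parent = parent)
  }
  new("WFCHierarchy", nodes = do.call(rbind, nodes), repaired = repaired)
}

#' Run multi-scale Weber-Fechner clustering
#'
#' The full pipeline: (1) build binary/grid codes (DM once; SD re-encoded at
#' each scale's cell side \eqn{\delta^s}); (2) estimate the similarity
#' bounds; (3) build the scale schedule; (4) at each scale link all pairs
#' whose similarity meets the threshold and take connected components as
#' clusters; (5) assemble the hierarchy across scales.  Deterministic given
#' (X, lambda, config, seed).
#'
#' In DM mode, LSH candidate pairs are pooled over all scheduled thresholds
#' and exact-verified once, so the per-scale edge sets are nested by
#' construction and the partitions refine each other exactly.
#'
#' @param X numeric matrix of points, a sparse \code{Matrix}, or a
#'   \linkS4class{BinaryCodes} object (forces DM mode on precomputed codes).
#' @param lambda Weber fraction, the only required parameter.
#' @param coding \code{"auto"}, \code{"sd"} or \code{"dm"}.
#' @param config optional list overriding defaults: \code{policy},
#'   \code{dmMode}, \code{topM}, \code{bins}, \code{k} (MinHash signatures),
#'   \code{exactVerify}, \code{bruteCutoff}, \code{bandSafety},
#'   \code{sampleSize}.
#' @param seed seed for every randomised step (bound sampling, hash family).
#' @return a \linkS4class{WFCResult}.
#' @examples
#' mix <- makeMixture(seed = 7)
#' res <- runWFC(mix$data[1:300, ], lambda = 1)
#' nScales(res)
#' @export
runWFC <- function(X, lambda = 1, coding = c("auto", "sd", "dm"),
                   config = list(), seed = 1L) {
  coding <- match.arg(coding)
  if (lambda <= 0) stop("lambda must be positive")
  cfg <- modifyList(list(policy = "weber_fechner", dmMode = NULL, topM = NULL,
                         bins = 8L, k = 256L, exactVerify = TRUE,
                         bruteCutoff = 512L, bandSafety = 0.5,
                         sampleSize = 2000L), config)
  preEncoded <- is(X, "BinaryCodes")
  if (preEncoded) {
    if (coding == "sd") stop("precomputed binary codes require DM coding")
    coding <- "dm"
    codes <- X
    n <- length(codes)
  } else {
    n <- nrow(X); d <- ncol(X)
    if (coding == "auto")
      coding <- selectCoding(n, d)
  }
  perScale <- vector("list", 0L)
  stats <- list()
  if (coding == "sd") {
    X <- asDenseMatrix(X)
    bounds <- estimateSimilarityBounds(X, "sd", sampleSize = cfg$sampleSize,
                                       seed = seed)
    sched <- buildSchedule(bounds$simMin, bounds$simMax, lambda,
                           policy = cfg$policy)
    origin <- apply(X, 2L, min)
    for (s in seq_len(sched@sEnd)) {
      delta <- 1 / sched@thresholds[s]
      edges <- sdLink(sdEncode(X, delta, scale = s, origin = origin))
      cc <- connectedComponents(n, edges, scale = s)
      perScale[[s]] <- cc
      stats[[s]] <- data.frame(scale = s, threshold = sched@thresholds[s],
                               delta = delta, nEdges = nrow(edges),
                               nClusters = length(cc@sizes),
                               nIsolated = length(cc@isolated))
    }
    hier <- buildHierarchy(perScale, strict = FALSE)
  } else {
    if (!preEncoded) {
      dmMode <- cfg$dmMode
      if (is.null(dmMode))
        dmMode <- if (is(X, "sparseMatrix")) "nonzero" else "binned"
      codes <- dmEncode(X, mode = dmMode, m = cfg$topM, bins = cfg$bins)
      cfg$dmMode <- dmMode
    }
    bounds <- estimateSimilarityBounds(mode = "dm", codes = codes,
                                       sampleSize = cfg$sampleSize,
                                       seed = seed)
    sched <- buildSchedule(bounds$simMin, bounds$simMax, lambda,
                           policy = cfg$policy)
    if (n <= cfg$bruteCutoff) {
      J <- jaccardMatrix(codes)
      pairs <- which(upper.tri(J) & J > 0, arr.ind = TRUE)
      pairSim <- J[pairs]
    } else {
      index <- minhashSignatures(codes, k = cfg$k, seed = seed)
      bandings <- t(vapply(sched@thresholds, bandingFor, integer(2),
                           k = cfg$k, bandSafety = cfg$bandSafety))
      needExact <- vapply(seq_len(sched@sEnd), function(s)
        useInvertedIndex(bandings[s, ], sched@thresholds[s]), logical(1))
      pool <- if (any(needExact)) invertedIndexCandidates(codes) else NULL
      bandings <- unique(bandings[!needExact, , drop = FALSE])
      for (bi in seq_len(nrow(bandings)))
        pool <- lshCandidates(index, bandings[bi, "b"], bandings[bi, "r"],
                              pool)
      pairs <- if (is.null(pool)) matrix(integer(0), 0L, 2L) else pool
      pairSim <- pairJaccard(codes, pairs[, 1L], pairs[, 2L])
    }
    perScale <- multiScaleComponents(n, pairs, pairSim, sched@thresholds)
    for (s in seq_len(sched@sEnd)) {
      cc <- perScale[[s]]
      stats[[s]] <- data.frame(scale = s, threshold = sched@thresholds[s],
                               delta = NA_real_,
                               nEdges = sum(pairSim >=
                                            sched@thresholds[s] - 1e-12),
                               nClusters = length(cc@sizes),
                               nIsolated = length(cc@isolated))
    }
    hier <- buildHierarchy(perScale, strict = isTRUE(cfg$exactVerify))
  }
  new("WFCResult", schedule = sched, perScale = perScale, hierarchy = hier,
      coding = coding,
      config = c(list(lambda = lambda, seed = as.integer(seed),
                      coding = coding), cfg),
      stats = do.call(rbind, stats))
}

#' @rdname WFCResult-class
#' @export
setMethod("nScales", "WFCResult", function(x) length(x@perScale))

#' @rdname WFCResult-class
#' @param scale scale index.
#' @export
setMethod("scaleClustering", "WFCResult", function(x, scale) {
  if (scale < 1L || scale > length(x@perScale)) stop("scale out of range")
  x@perScale[[scale]]
})

#' @rdname WFCResult-class
#' @export
setMethod("clusterLabels", "WFCResult",
          function(x, scale) scaleClustering(x, scale)@labels)

#' @rdname WFCResult-class
#' @export
setMethod("hierarchyTable", "WFCResult", function(x) x@hierarchy@nodes)

#' @rdname WFCResult-class
#' @export
setMethod("repairedParents", "WFCResult", function(x) x@hierarchy@repaired)

#' @rdname WFCResult-class
#' @export
setMethod("wfcSchedule", "WFCResult", function(x) x@schedule)

#' @rdname WFCResult-class
#' @export
setMethod("sEnd", "WFCResult", function(x) x@schedule@sEnd)

#' @rdname ScaleClustering-class
#' @export
setMethod("clusterSizes", "ScaleClustering", function(x) x@sizes)

#' @rdname ScaleClustering-class
#' @export
setMethod("isolatedPoints", "ScaleClustering", function(x) x@isolated)

#' @rdname ScaleClustering-class
#' @export
setMethod("clusterLabels", "ScaleClustering", function(x, scale) x@labels)

setMethod("show", "ScaleClustering", function(object) {
  cat(sprintf("ScaleClustering (scale %d): %d points, %d clusters, %d isolated\n",
              object@scale, length(object@labels), length(object@sizes),
              length(object@isolated)))
})

setMethod("show", "WFCHierarchy", function(object) {
  cat(sprintf("WFCHierarchy: %d nodes over %d scales, %d repaired parents\n",
              nrow(object@nodes), max(object@nodes$scale), object@repaired))
})

setMethod("show", "WFCResult", function(object) {
  cat(sprintf("WFCResult: %s coding, lambda = %g, %d scales, n = %d\n",
              object@coding, object@schedule@lambda, length(object@perScale),
              length(object@perScale[[1L]]@labels)))
  cat(sprintf("  clusters per scale: %s\n",
              paste(object@stats$nClusters, collapse = " ")))
})
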