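#' @import methods
#' @importFrom stats dist var rnorm runif
#' @importFrom utils read.table write.table combn
NULL

#' Scale schedule of the Weber-Fechner observation system
#'
#' Holds the similarity bounds of a dataset, the threshold update policy and
#' the per-scale similarity thresholds \eqn{sim_{min}^s}.  Under the
#' Weber-Fechner policy the threshold grows by one just-noticeable difference
#' per scale, \eqn{sim_{min}^{s+1} = (1+\lambda)\, sim_{min}^s}, and the number
#' of scales is \eqn{s_{end} = \lfloor \log_{1+\lambda}(sim_{max}/sim_{min})
#' \rfloor} (clamped to at least 1).
#'
#' @slot lambda Weber fraction \eqn{\lambda > 0}.
#' @slot policy one of \code{"weber_fechner"}, \code{"hyper_exponential"},
#'   \code{"linear"}.
#' @slot simMin,simMax global minimum / maximum pairwise similarity.
#' @slot sEnd number of scales.
#' @slot thresholds numeric vector of length \code{sEnd}, strictly increasing,
#'   anchored at \code{thresholds[1] == simMin}.
#' @exportClass ScaleSchedule
setClass("ScaleSchedule",
  representation(lambda = "numeric", policy = "character",
                 simMin = "numeric", simMax = "numeric",
                 sEnd = "integer", thresholds = "numeric"))

setValidity("ScaleSchedule", function(object) {
  msg <- character(0)
  if (length(object@lambda) != 1L || object@lambda <= 0)
    msg <- c(msg, "lambda must be a positive scalar")
  if (!object@policy %in% c("weber_fechner", "hyper_exponential", "linear"))
    msg <- c(msg, "unknown policy")
  if (object@simMin <= 0 || object@simMax < object@simMin)
    msg <- c(msg, "need 0 < simMin <= simMax")
  if (object@sEnd < 1L) msg <- c(msg, "sEnd must be >= 1")
  if (length(object@thresholds) != object@sEnd)
    msg <- c(msg, "thresholds length must equal sEnd")
  if (object@sEnd > 1L && any(diff(object@thresholds) <= 0))
    msg <- c(msg, "thresholds must be strictly increasing")
  if (abs(object@thresholds[1L] - object@simMin) >
      1e-9 * max(1, object@simMin))
    msg <- c(msg, "thresholds must be anchored at simMin")
  if (length(msg)) msg else TRUE
})

#' Grid-cell (SD) code of a dataset at one scale
#'
#' Each point is mapped to the integer coordinates of the half-open grid cell
#' of side \code{delta} containing it, anchored at the per-dimension data
#' minima.  Two points are similar at this scale iff their cells coincide or
#' are Chebyshev-adjacent.
#'
#' @slot cells n x d matrix of non-negative integer cell coordinates
#'   (stored as doubles to avoid overflow at fine scales).
#' @slot delta cell side \eqn{\delta^s = 1 / sim_{min}^s}.
#' @slot scale the scale index s.
#' @exportClass CellCode
setClass("CellCode",
  representation(cells = "matrix", delta = "numeric", scale = "integer"))

setValidity("CellCode", function(object) {
  if (object@delta <= 0) return("delta must be positive")
  if (any(object@cells < 0)) return("cell coordinates must be non-negative")
  TRUE
})

#' Dimension-marker (DM) binary codes
#'
#' One marker set per point: the indices (1-based, in \code{1..D}) of the
#' point's informative dimensions.  Pairwise similarity is the Jaccard index
#' \eqn{H(A_{x,y})/H(O_{x,y})} of the marker sets.
#'
#' @slot markers list of sorted integer vectors, one per point, each non-empty.
#' @slot D code length (number of possible markers).
#' @exportClass BinaryCodes
setClass("BinaryCodes",
  representation(markers = "list", D = "integer"))

setValidity("BinaryCodes", function(object) {
  lens <- lengths(object@markers)
  if (any(lens == 0L))
    return(sprintf("empty marker set for point(s): %s",
                   paste(utils::head(which(lens == 0L), 10L), collapse = ", ")))
  rng <- range(unlist(object@markers))
  if (rng[1L] < 1L || rng[2L] > object@D)
    return("marker indices must lie in 1..D")
  TRUE
})

#' MinHash signature index
#'
#' k seeded universal hash functions over marker indices; signature
#' coordinate (i, x) is the minimum of hash i over the markers of point x.
#' The probability that two signatures agree at one coordinate equals the
#' Jaccard similarity of the underlying marker sets.
#'
#' @slot signatures k x n numeric matrix of minimum hash values.
#' @slot k number of hash functions.
#' @slot seed RNG seed the hash family was drawn with.
#' @exportClass MinHashIndex
setClass("MinHashIndex",
  representation(signatures = "matrix", k = "integer", seed = "integer"))

#' Clustering at a single scale
#'
#' Connected components of the scale's similarity graph, with canonical
#' labels: each cluster id is the smallest (1-based) member point index.
#'
#' @slot scale scale index.
#' @slot labels integer vector, \code{labels[i]} = cluster id of point i.
#' @slot sizes named integer vector of cluster sizes (names = cluster ids).
#' @slot isolated integer vector of singleton cluster ids.
#' @exportClass ScaleClustering
setClass("ScaleClustering",
  representation(scale = "integer", labels = "integer",
                 sizes = "integer", isolated = "integer"))

setValidity("ScaleClustering", function(object) {
  if (sum(object@sizes) != length(object@labels))
    return("cluster sizes must sum to n")
  TRUE
})

#' Cross-scale cluster hierarchy
#'
#' @slot nodes data.frame with columns scale, id, size, parent (parent = id of
#'   the containing cluster at scale s-1; NA for scale-1 roots).
#' @slot repaired number of clusters whose members spanned several
#'   coarser-scale clusters and were assigned their majority parent (possible
#'   only in SD mode, where grid adjacency is not strictly nested across
#'   scales).
#' @exportClass WFCHierarchy
setClass("WFCHierarchy",
  representation(nodes = "data.frame", repaired = "integer"))

#' Result of a multi-scale WFC run
#'
#' @slot schedule the \linkS4class{ScaleSchedule} used.
#' @slot perScale list of \linkS4class{ScaleClustering}, one per scale.
#' @slot hierarchy the assembled \linkS4class{WFCHierarchy}.
#' @slot coding "sd" or "dm".
#' @slot config snapshot of all parameters (lambda, seed, coding options).
#' @slot stats per-scale data.frame: scale, threshold, delta (SD only),
#'   nEdges, nClusters, nIsolated.
#' @exportClass WFCResult
setClass("WFCResult",
  representation(schedule = "ScaleSchedule", perScale = "list",
                 hierarchy = "WFCHierarchy", coding = "character",
                 config = "list", stats = "data.frame"))

setValidity("WFCResult", function(object) {
  if (length(object@perScale) != object@schedule@sEnd)
    return("perScale length must equal sEnd")
  TRUE
})
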