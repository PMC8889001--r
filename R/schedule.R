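# Weber-Fechner observation system: similarity bounds, per-scale thresholds
# and the number of scales.

#' Estimate the global similarity bounds of a dataset
#'
#' Computes \code{simMin} and \code{simMax}, the minimum and maximum pairwise
#' similarity among all points, which anchor the scale schedule.
#'
#' In SD mode similarity is the reciprocal Chebyshev distance, so
#' \code{simMin = 1 / Chebyshev diameter} (the diameter is the maximum over
#' dimensions of the column range, computed exactly in one pass) and
#' \code{simMax = 1 / (smallest nonzero pairwise Chebyshev distance)}.  The
#' closest pair is found exactly for \code{n <= sampleSize}; for larger data
#' it is estimated from the nearest neighbours (within the full dataset) of a
#' seeded random sample of \code{sampleSize} points.
#'
#' In DM mode the bounds are the maximum and minimum \emph{nonzero} Jaccard
#' similarity over distinct pairs, exact over all pairs for
#' \code{n <= sampleSize}, otherwise over all pairs within a seeded random
#' sample.  \code{simMin} is clamped below by \code{1/(2 D)} so that a single
#' near-disjoint pair cannot inflate the number of scales unboundedly.
#'
#' @param X numeric matrix of points (rows = points); ignored in DM mode.
#' @param mode \code{"sd"} or \code{"dm"}.
#' @param codes a \linkS4class{BinaryCodes} object (DM mode only).
#' @param sampleSize exact computation below this size; sampled estimate above.
#' @param seed RNG seed for the sampling estimator.
#' @return named list with elements \code{simMin} and \code{simMax}.
#' @examples
#' estimateSimilarityBounds(rbind(c(0, 0), c(3, 4)), "sd")
#' @export
estimateSimilarityBounds <- function(X = NULL, mode = c("sd", "dm"),
                                     codes = NULL, sampleSize = 2000L,
                                     seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "sd") {
    X <- asDenseMatrix(X)
    n <- nrow(X)
    if (n < 2L) stop("need at least two points")
    rng <- apply(X, 2L, range)
    diam <- max(rng[2L, ] - rng[1L, ])
    if (diam <= 0) stop("zero similarity range: all points identical")
    if (n <= sampleSize) {
      dd <- stats::dist(X, method = "maximum")
      dmin <- min(dd[dd > 0])
    } else {
      idx <- withSeed(seed, sample.int(n, sampleSize))
      dmin <- Inf
      for (i in idx) {
        di <- rowChebyshev(X, X[i, ])
        di <- di[di > 0]
        if (length(di)) dmin <- min(dmin, min(di))
      }
      if (!is.finite(dmin)) stop("zero similarity range: all points identical")
    }
    list(simMin = 1 / diam, simMax = 1 / dmin)
  } else {
    if (is.null(codes)) stop("DM mode requires binary codes")
    n <- length(codes@markers)
    if (n < 2L) stop("need at least two points")
    idx <- if (n <= sampleSize) seq_len(n)
           else sort(withSeed(seed, sample.int(n, sampleSize)))
    J <- jaccardMatrix(codes, idx)
    up <- J[upper.tri(J)]
    up <- up[up > 0]
    if (!length(up)) stop("zero similarity range: no pair shares a marker")
    list(simMin = max(min(up), 1 / (2 * codes@D)), simMax = max(up))
  }
}

#' Build a scale schedule
#'
#' The number of scales follows the closed form
#' \eqn{s_{end} = \lfloor \log_{1+\lambda}(sim_{max}/sim_{min}) \rfloor},
#' clamped to at least 1, computed in log space.  Thresholds are anchored at
#' \code{thresholds[1] = simMin} (the grossest scale must link the most
#' dissimilar pair) and grow per policy:
#' \describe{
#'   \item{weber_fechner}{\eqn{sim_{min}^s = (1+\lambda)^{s-1}\, sim_{min}}
#'     (one just-noticeable difference per scale).}
#'   \item{hyper_exponential}{\eqn{sim_{min}^s = (1+\lambda)^{(s-1)^2}\,
#'     sim_{min}}; the scale count is the largest s whose threshold does not
#'     exceed \code{simMax}, i.e. \eqn{\lfloor\sqrt{\log_{1+\lambda}
#'     (sim_{max}/sim_{min})}\rfloor + 1} — far fewer scales, at the price of
#'     structure missed between them.}
#'   \item{linear}{\eqn{sim_{min}^s = (1 + (s-1)\lambda)\, sim_{min}}, a
#'     comparison baseline.}
#' }
#'
#' @param simMin,simMax similarity bounds, \code{0 < simMin <= simMax}.
#' @param lambda Weber fraction, > 0.
#' @param policy threshold update policy.
#' @return a \linkS4class{ScaleSchedule}.
#' @examples
#' sEnd(buildSchedule(1, 2^25, lambda = 1))   # 25
#' @export
buildSchedule <- function(simMin, simMax, lambda,
                          policy = c("weber_fechner", "hyper_exponential",
                                     "linear")) {
  policy <- match.arg(policy)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive scalar")
  if (simMin <= 0) stop("simMin must be positive")
  if (simMax < simMin) stop("simMax must be >= simMin")
  L <- (log(simMax) - log(simMin)) / log1p(lambda)  # log-space ratio exponent
  eps <- 1e-9
  sEnd <- switch(policy,
    weber_fechner     = floor(L + eps),
    hyper_exponential = floor(sqrt(max(L, 0)) + eps) + 1,
    linear            = floor((simMax / simMin - 1) / lambda + eps) + 1)
  if (policy == "linear" && sEnd > 1e5)
    stop("linear policy yields ", sEnd,
         " scales for these bounds; use weber_fechner or a larger lambda")
  sEnd <- max(1L, as.integer(sEnd))
  s <- seq_len(sEnd)
  thresholds <- switch(policy,
    weber_fechner     = simMin * exp((s - 1) * log1p(lambda)),
    hyper_exponential = simMin * exp((s - 1)^2 * log1p(lambda)),
    linear            = simMin * (1 + (s - 1) * lambda))
  new("ScaleSchedule", lambda = as.numeric(lambda), policy = policy,
      simMin = as.numeric(simMin), simMax = as.numeric(simMax),
      sEnd = sEnd, thresholds = thresholds)
}

#' Threshold at a given scale
#'
#' @param schedule a \linkS4class{ScaleSchedule}.
#' @param s scale index in \code{1..sEnd(schedule)}.
#' @return the similarity threshold \eqn{sim_{min}^s}.
#' @export
thresholdAt <- function(schedule, s) {
  stopifnot(is(schedule, "ScaleSchedule"))
  if (length(s) != 1L || s < 1L || s > schedule@sEnd)
    stop("scale out of range 1..", schedule@sEnd)
  schedule@thresholds[as.integer(s)]
}

#' Serialize a schedule to JSON
#'
#' @param schedule a \linkS4class{ScaleSchedule}.
#' @param path optional file to write to; if \code{NULL} the JSON string is
#'   returned.
#' @export
scheduleToJSON <- function(schedule, path = NULL) {
  obj <- list(lambda = schedule@lambda, policy = schedule@policy,
              sim_min = schedule@simMin, sim_max = schedule@simMax,
              s_end = schedule@sEnd, thresholds = schedule@thresholds)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ScaleSchedule-class
#' @export
setMethod("sEnd", "ScaleSchedule", function(x) x@sEnd)

#' @rdname ScaleSchedule-class
#' @export
setMethod("thresholds", "ScaleSchedule", function(x) x@thresholds)

#' @rdname ScaleSchedule-class
#' @export
setMethod("distanceThresholds", "ScaleSchedule",
          function(x) 1 / x@thresholds)

setMethod("show", "ScaleSchedule", function(object) {
  cat(sprintf(
    "ScaleSchedule: %s, lambda = %g\n  simMin = %.6g, simMax = %.6g, s_end = %d\n",
    object@policy, object@lambda, object@simMin, object@simMax, object@sEnd))
  th <- object@thresholds
  shown <- if (length(th) > 6L)
    paste(c(sprintf("%.4g", utils::head(th, 3L)), "...",
            sprintf("%.4g", utils::tail(th, 2L))), collapse = " ")
  else paste(sprintf("%.4g", th), collapse = " ")
  cat("  thresholds:", shown, "\n")
})
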