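# Dimension-marker (DM) coding: binary marker sets, Jaccard similarity, and
# sub-quadratic thresholded pair retrieval via MinHash + LSH banding.

.MINHASH_PRIME <- 2147483647  # 2^31 - 1; double arithmetic is exact below 2^53

#' Construct binary marker codes
#'
#' @param markers list of integer vectors of marked dimension indices, one per
#'   point; each must be non-empty.
#' @param D code length (number of possible marker indices).
#' @return a \linkS4class{BinaryCodes}.
#' @export
BinaryCodes <- function(markers, D) {
  markers <- lapply(markers, function(m) sort(unique(as.integer(m))))
  new("BinaryCodes", markers = markers, D = as.integer(D))
}

#' @rdname BinaryCodes-class
#' @export
setMethod("markerSets", "BinaryCodes", function(x) x@markers)

#' @rdname BinaryCodes-class
#' @export
setMethod("codeLength", "BinaryCodes", function(x) x@D)

#' @rdname BinaryCodes-class
#' @export
setMethod("length", "BinaryCodes", function(x) length(x@markers))

setMethod("show", "BinaryCodes", function(object) {
  cat(sprintf("BinaryCodes: %d points, code length D = %d, mean |markers| = %.1f\n",
              length(object@markers), object@D,
              mean(lengths(object@markers))))
})

#' Encode points as dimension-marker binary codes
#'
#' Three marking rules cover sparse counts and dense embeddings:
#' \describe{
#'   \item{nonzero}{dimension j is marked iff \code{x[j] != 0}
#'     (\code{D = d}); natural for sparse expression data.}
#'   \item{top_m}{the m largest-magnitude dimensions are marked
#'     (\code{D = d}).}
#'   \item{binned}{each dimension is quantised into \code{bins} equal-width
#'     bins over its observed range and the marker index is
#'     \code{(j-1)*bins + bin(x[j]) + 1} (\code{D = d*bins}); Jaccard then
#'     measures the fraction of dimensions falling in identical bins, suited
#'     to dense embeddings.}
#' }
#'
#' @param X numeric matrix (rows = points) or a \code{Matrix} sparse matrix.
#' @param mode marking rule.
#' @param m number of dimensions to mark in \code{top_m} mode.
#' @param bins number of bins per dimension in \code{binned} mode.
#' @return a \linkS4class{BinaryCodes}.
#' @examples
#' markerSets(dmEncode(rbind(c(0, 2.5, 0, 1)), mode = "nonzero"))
#' @export
dmEncode <- function(X, mode = c("nonzero", "top_m", "binned"),
                     m = NULL, bins = 8L) {
  mode <- match.arg(mode)
  if (mode == "nonzero") {
    if (is(X, "Matrix")) {
      nz <- Matrix::which(X != 0, arr.ind = TRUE)
      d <- ncol(X); n <- nrow(X)
    } else {
      X <- asDenseMatrix(X)
      nz <- which(X != 0, arr.ind = TRUE)
      d <- ncol(X); n <- nrow(X)
    }
    markers <- split(nz[, 2L], factor(nz[, 1L], levels = seq_len(n)))
    bad <- which(lengths(markers) == 0L)
    if (length(bad))
      stop("no marked dimension for point(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
    return(BinaryCodes(markers, d))
  }
  X <- asDenseMatrix(X)
  n <- nrow(X); d <- ncol(X)
  if (mode == "top_m") {
    if (is.null(m) || m < 1L || m > d)
      stop("top_m mode needs m in 1..d")
    markers <- lapply(seq_len(n), function(i)
      sort(order(-abs(X[i, ]), seq_len(d))[seq_len(m)]))
    return(BinaryCodes(markers, d))
  }
  # binned
  bins <- as.integer(bins)
  if (bins < 2L) stop("binned mode needs at least 2 bins")
  lo <- apply(X, 2L, min)
  width <- (apply(X, 2L, max) - lo) / bins
  width[width <= 0] <- 1               # constant column -> everything in bin 0
  B <- floor(sweep(sweep(X, 2L, lo), 2L, width, "/"))
  B[B >= bins] <- bins - 1             # right edge closed at the top bin
  M <- sweep(B, 2L, (seq_len(d) - 1L) * bins, "+") + 1L
  BinaryCodes(lapply(seq_len(n), function(i) M[i, ]), d * bins)
}

#' Jaccard similarity of two marker sets
#'
#' \eqn{H(A_{x,y})/H(O_{x,y})} where A and O are the AND and OR of the binary
#' codes and H is the Hamming weight.
#'
#' @param cx,cy integer vectors of marker indices.
#' @return similarity in [0, 1]; 1 iff the sets are equal, 0 when disjoint.
#' @examples
#' jaccardSim(c(1, 3, 4), c(1, 4, 5))  # 0.5
#' @export
jaccardSim <- function(cx, cy) {
  if (!length(cx) && !length(cy)) stop("both codes empty")
  i <- length(intersect(cx, cy))
  i / (length(cx) + length(cy) - i)
}

# Sparse 0/1 matrix D x n of marker indicators.
codeMatrix <- function(codes) {
  Matrix::sparseMatrix(i = unlist(codes@markers),
                       j = rep.int(seq_along(codes@markers),
                                   lengths(codes@markers)),
                       x = 1, dims = c(codes@D, length(codes@markers)))
}

# Dense Jaccard similarity matrix over (a subset of) the codes.
jaccardMatrix <- function(codes, idx = seq_along(codes@markers)) {
  M <- codeMatrix(codes)[, idx, drop = FALSE]
  inter <- as.matrix(Matrix::crossprod(M))
  sz <- diag(inter)
  uni <- outer(sz, sz, "+") - inter
  J <- inter / uni
  diag(J) <- 1
  J
}

# Exact Jaccard for given pairs (I[t], J[t]).  For moderate n the full
# sparse cross-product is cheapest; for large n pairs are verified by
# chunked sparse column products, keeping memory proportional to the
# candidate count.
pairJaccard <- function(codes, I, J, M = NULL) {
  if (!length(I)) return(numeric(0))
  if (is.null(M)) M <- codeMatrix(codes)
  sz <- Matrix::colSums(M)
  n <- ncol(M)
  if (n <= 4096L) {
    inter <- as.matrix(Matrix::crossprod(M))[cbind(I, J)]
  } else {
    inter <- numeric(length(I))
    for (ch in split(seq_along(I), ceiling(seq_along(I) / 50000L))) {
      inter[ch] <- Matrix::colSums(M[, I[ch], drop = FALSE] *
                                   M[, J[ch], drop = FALSE])
    }
  }
  inter / (sz[I] + sz[J] - inter)
}

#' Build MinHash signatures
#'
#' k seeded universal hash functions \code{h_i(j) = (a_i j + b_i) mod p}
#' (p = 2^31 - 1) over marker indices; the signature of a point is the
#' minimum hash value per function.  The probability that two signatures
#' agree at one coordinate equals the Jaccard similarity of the marker sets.
#' Deterministic given (codes, k, seed).
#'
#' @param codes a \linkS4class{BinaryCodes}.
#' @param k number of hash functions (>= 16).
#' @param seed RNG seed for drawing the hash family.
#' @return a \linkS4class{MinHashIndex}.
#' @export
minhashSignatures <- function(codes, k = 256L, seed = 1L) {
  k <- as.integer(k)
  if (k < 16L) stop("k must be at least 16")
  p <- .MINHASH_PRIME
  ab <- withSeed(seed, list(a = sample.int(p - 1L, k, replace = TRUE),
                            b = sample.int(p, k, replace = TRUE) - 1))
  sig <- vapply(codes@markers, function(m) {
    hv <- (outer(ab$a, as.numeric(m)) + ab$b) %% p
    if (length(m) == 1L) hv[, 1L]
    else do.call(pmin, lapply(seq_len(ncol(hv)), function(c) hv[, c]))
  }, numeric(k))
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = k)
  new("MinHashIndex", signatures = sig, k = k, seed = as.integer(seed))
}

#' Choose an LSH banding for a similarity threshold
#'
#' Among factorisations \code{b * r = k}, picks the one whose S-curve
#' midpoint \code{(1/b)^(1/r)} is closest to but not exceeding t; ties are
#' broken toward larger r (fewer false positives).
#'
#' @param k signature length.
#' @param t similarity threshold in (0, 1].
#' @return named integer vector \code{c(b = , r = )}.
#' @export
chooseBands <- function(k, t) {
  if (t <= 0 || t > 1) stop("t must lie in (0, 1]")
  r <- which(k %% seq_len(k) == 0L)
  b <- k %/% r
  mid <- (1 / b)^(1 / r)
  ok <- mid <= t + 1e-12
  if (!any(ok))
    stop("no (b, r) factorisation of k = ", k,
         " has S-curve midpoint <= ", t, "; use a larger k")
  r <- r[ok]; b <- b[ok]; mid <- mid[ok]
  best <- which(mid == max(mid))
  pick <- best[which.max(r[best])]
  c(b = b[pick], r = r[pick])
}

# Banding actually used for a threshold t: tuned against bandSafety * t
# (floored at 1/k) so the S-curve midpoint sits safely below t.
bandingFor <- function(k, t, bandSafety) {
  chooseBands(k, min(t, max(t * bandSafety, 1 / k + 1e-9)))
}

# Probability that a pair with Jaccard exactly t collides in no band.
bandingMissProb <- function(br, t) (1 - t^br[["r"]])^br[["b"]]

# For very low thresholds banding degenerates: either no (b, r) split of the
# k signature rows is sensitive enough at J = t, or the best choice is
# single-row bands (r = 1), which retrieve pairs agreeing on any one minhash
# value — a lossy version of the shared-marker inverted index.  In both
# regimes candidates come instead from the exact inverted index (pairs
# sharing at least one marker), valid for any positive threshold.  The
# sparse cross-product below is the posting-list self-join.
.LSH_MISS_TOL <- 0.005

useInvertedIndex <- function(br, t) {
  br[["r"]] == 1L || bandingMissProb(br, t) > .LSH_MISS_TOL
}
invertedIndexCandidates <- function(codes, M = NULL) {
  if (is.null(M)) M <- codeMatrix(codes)
  co <- Matrix::summary(methods::as(Matrix::crossprod(M), "TsparseMatrix"))
  canonicalEdges(cbind(co$i, co$j))
}

# Collect LSH candidate pairs for one (b, r) banding, merging with an
# optional existing pool; per-band blocks are accumulated and deduplicated
# in one pass at the end.
lshCandidates <- function(index, b, r, pool = NULL) {
  sig <- index@signatures
  n <- ncol(sig)
  acc <- if (is.null(pool) || !nrow(pool)) list() else list(pool)
  for (band in seq_len(b)) {
    rows <- ((band - 1L) * r + 1L):(band * r)
    keys <- if (r == 1L) as.character(sig[rows, ])
            else do.call(paste, c(lapply(rows, function(rr) sig[rr, ]),
                                  sep = ","))
    grp <- split(seq_len(n), keys)
    grp <- grp[lengths(grp) > 1L]
    if (length(grp))
      acc[[length(acc) + 1L]] <-
        t(do.call(cbind, lapply(grp, utils::combn, m = 2L)))
  }
  if (!length(acc)) return(matrix(integer(0), 0L, 2L))
  canonicalEdges(do.call(rbind, acc))
}

#' Retrieve point pairs with Jaccard similarity above a threshold
#'
#' Candidates are pairs whose MinHash signatures collide in at least one LSH
#' band; with \code{exactVerify} (the default) each candidate is checked with
#' the exact Jaccard similarity and kept iff >= t, so the output contains no
#' false positives.  Banding is tuned against \code{bandSafety * t} so the
#' S-curve midpoint sits safely below the verification threshold, keeping
#' false negatives rare.  At very low thresholds, where no banding of k rows
#' is sensitive enough at J = t, candidates are drawn instead from the
#' shared-marker inverted index (a sparse posting-list self-join), which is
#' exact for any positive threshold.  For \code{n <= bruteCutoff} an exact
#' all-pairs scan is used instead (also the testing oracle path).
#'
#' @param index a \linkS4class{MinHashIndex} built from \code{codes}.
#' @param codes the \linkS4class{BinaryCodes}.
#' @param t similarity threshold in (0, 1].
#' @param exactVerify verify candidates with exact Jaccard (default TRUE;
#'   with FALSE the output may contain pairs below t).
#' @param bruteCutoff below this n, enumerate all pairs exactly.
#' @param bandSafety banding is tuned for \code{bandSafety * t} (recall
#'   margin).
#' @return integer edge matrix (two columns, i < j, deduplicated, ordered).
#' @export
lshPairs <- function(index, codes, t, exactVerify = TRUE,
                     bruteCutoff = 512L, bandSafety = 0.5) {
  n <- length(codes@markers)
  if (t <= 0 || t > 1) stop("t must lie in (0, 1]")
  if (n <= bruteCutoff) {
    J <- jaccardMatrix(codes)
    hit <- which(upper.tri(J) & J >= t - 1e-12, arr.ind = TRUE)
    return(canonicalEdges(hit))
  }
  if (!is(index, "MinHashIndex") || ncol(index@signatures) != n)
    stop("index does not match codes")
  br <- bandingFor(index@k, t, bandSafety)
  M <- codeMatrix(codes)
  cand <- if (useInvertedIndex(br, t)) invertedIndexCandidates(codes, M)
          else lshCandidates(index, br[["b"]], br[["r"]])
  if (exactVerify && nrow(cand)) {
    keep <- pairJaccard(codes, cand[, 1L], cand[, 2L], M) >= t - 1e-12
    cand <- cand[keep, , drop = FALSE]
  }
  cand
}
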