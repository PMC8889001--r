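# Splicing/decomposable (SD) coding: grid cells of side delta, linking of
# same-or-Chebyshev-adjacent cells in time linear in n for fixed d.

# Neighbour enumeration is 3^d per cell; beyond this dimension SD is refused
# and DM coding must be used (see selectCoding()).
.SD_MAX_DIM <- 12L

#' Chebyshev (L-infinity) distance between two points
#'
#' @param x,y numeric vectors of equal length.
#' @return \code{max(abs(x - y))}.
#' @examples
#' chebyshevDist(c(0, 0), c(3, 4))  # 4
#' @export
chebyshevDist <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch")
  max(abs(x - y))
}

#' Encode points as grid cells (SD coding)
#'
#' Maps each point to the half-open cell \code{[k*delta, (k+1)*delta)} of a
#' d-dimensional mesh grid anchored at the per-dimension data minima.
#'
#' @param X numeric matrix of points.
#' @param delta cell side, > 0 (at scale s this is
#'   \eqn{\delta^s = 1/sim_{min}^s}).
#' @param scale scale index carried along for bookkeeping.
#' @param origin optional anchor (defaults to per-dimension minima of X).
#' @return a \linkS4class{CellCode}.
#' @examples
#' sdEncode(cbind(c(0, 0.9, 2.1)), delta = 1)
#' @export
sdEncode <- function(X, delta, scale = 1L, origin = NULL) {
  X <- asDenseMatrix(X)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive scalar")
  if (is.null(origin)) origin <- apply(X, 2L, min)
  cells <- floor(sweep(X, 2L, origin) / delta)
  # guard against floating-point droop just below the anchor
  cells[cells < 0] <- 0
  new("CellCode", cells = cells, delta = as.numeric(delta),
      scale = as.integer(scale))
}

#' Link points in identical or Chebyshev-adjacent grid cells
#'
#' Two points are linked iff their cell coordinate vectors differ by at most 1
#' in every dimension.  Points are grouped by cell key via hashing (one link
#' per point into its cell's representative); each occupied cell then probes
#' the canonical half of its \code{3^d - 1} neighbour keys, linking
#' representatives of occupied neighbours.  Expected time is proportional to
#' \code{n * 3^d}, i.e. linear in n for fixed d.
#'
#' @param code a \linkS4class{CellCode}.
#' @return integer edge matrix (two columns, i < j, deduplicated, ordered).
#' @export
sdLink <- function(code) {
  stopifnot(is(code, "CellCode"))
  cells <- code@cells
  n <- nrow(cells)
  d <- ncol(cells)
  if (d > .SD_MAX_DIM)
    stop("SD neighbour enumeration infeasible for d = ", d,
         " (> ", .SD_MAX_DIM, "); use DM coding")
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  key <- pasteKey(cells)
  rep1 <- match(key, key)              # first occurrence index per cell
  inCell <- which(rep1 != seq_len(n))
  edges <- cbind(rep1[inCell], inCell)
  reps <- which(rep1 == seq_len(n))    # one representative point per cell
  ucells <- cells[reps, , drop = FALSE]
  ukey <- key[reps]
  offs <- as.matrix(expand.grid(rep(list(-1:1), d)))
  nz <- apply(offs != 0, 1L, function(z) if (any(z)) which(z)[1L] else 0L)
  # canonical half: first nonzero offset component is +1
  offs <- offs[nz > 0L & offs[cbind(seq_len(nrow(offs)), pmax(nz, 1L))] == 1L,
               , drop = FALSE]
  nbr <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    shifted <- sweep(ucells, 2L, offs[o, ], "+")
    hit <- match(pasteKey(shifted), ukey)
    ok <- !is.na(hit)
    if (any(ok)) nbr[[o]] <- cbind(reps[ok], reps[hit[ok]])
  }
  canonicalEdges(rbind(edges, do.call(rbind, nbr)))
}

#' Interleaved-bit splice codes (lambda = 1 export)
#'
#' For a halving schedule (lambda = 1, cell side halved per scale) the binary
#' expansions of the cell coordinates interleaved across dimensions form a
#' decomposable code: a point's code at a coarser scale is a prefix of its
#' code at any finer scale.  Provided as an optional export documenting the
#' decomposability property; correctness of the algorithm only needs the
#' integer cell coordinates.
#'
#' @param code a \linkS4class{CellCode}.
#' @param bits number of bits per coordinate (defaults to the fewest that fit
#'   the largest coordinate).
#' @return character vector of bit strings of length \code{bits * d}.
#' @export
sdSpliceCodes <- function(code, bits = NULL) {
  stopifnot(is(code, "CellCode"))
  cells <- code@cells
  maxc <- max(cells, 1)
  if (is.null(bits)) bits <- max(1L, ceiling(log2(maxc + 1)))
  apply(cells, 1L, function(cc) {
    bm <- vapply(cc, function(v)
      as.integer(bitwAnd(floor(v / 2^((bits - 1):0)), 1L)), integer(bits))
    paste(as.vector(t(bm)), collapse = "")   # interleave across dimensions
  })
}
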