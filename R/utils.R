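# Internal helpers shared across modules.

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# restored afterwards so library code never perturbs user-level randomness.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Chebyshev distance from every row of X to a single point x.
rowChebyshev <- function(X, x) {
  A <- abs(X - matrix(x, nrow(X), length(x), byrow = TRUE))
  if (ncol(A) == 1L) return(A[, 1L])
  do.call(pmax, lapply(seq_len(ncol(A)), function(j) A[, j]))
}

# One string key per row of an integer/numeric matrix (grid-cell hashing).
pasteKey <- function(M) {
  if (ncol(M) == 1L) return(as.character(M[, 1L]))
  do.call(paste, c(lapply(seq_len(ncol(M)), function(j) M[, j]), sep = ","))
}

asDenseMatrix <- function(X) {
  if (is(X, "Matrix")) X <- as.matrix(X)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("expected a numeric matrix of points (rows = points)")
  if (anyNA(X)) stop("missing values are not allowed")
  X
}

# Deterministic ordering of an (i, j) edge matrix with i < j.
canonicalEdges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(matrix(integer(0), 0L, 2L))
  i <- pmin(edges[, 1L], edges[, 2L])
  j <- pmax(edges[, 1L], edges[, 2L])
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  key <- (i - 1) * 2^31 + j            # doubles are exact here (n << 2^22)
  o <- order(key)
  dup <- duplicated(key[o])
  cbind(i[o][!dup], j[o][!dup])
}
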