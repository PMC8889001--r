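# Flat-clustering validation measures: purity and F1, plus the
# high-quality-cluster filter (size and per-cluster purity thresholds).

#' Cluster-versus-class contingency table
#'
#' Co-occurrence counts |c intersect l| between clusters C (rows) and labelled
#' classes L (columns).  Row sums are cluster sizes, column sums class sizes.
#'
#' @param clusters vector of cluster assignments (one per point).
#' @param truth vector of ground-truth class labels (one per point).
#' @return an integer matrix (clusters x classes).
#' @export
clusterContingency <- function(clusters, truth) {
  if (!length(clusters) || length(clusters) != length(truth))
    stop("clusters and truth must be non-empty and of equal length")
  tab <- table(cluster = clusters, class = truth)
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

#' Global purity of a clustering
#'
#' \deqn{Purity(C) = \frac{1}{|X|} \sum_{c \in C} \max_{l \in L} |c \cap l|}
#'
#' Every point assigned to the majority class of its cluster counts as
#' correct; singletons are trivially pure, so purity rewards fine partitions.
#'
#' @param table contingency table from \code{\link{clusterContingency}}.
#' @return purity in (0, 1].
#' @examples
#' purityScore(rbind(c(5, 1), c(2, 4)))  # 0.75
#' @export
purityScore <- function(table) {
  if (!length(table) || sum(table) < 1) stop("empty contingency table")
  sum(apply(table, 1L, max)) / sum(table)
}

#' Per-cluster purity and majority class
#'
#' @param table contingency table (clusters x classes).
#' @return data.frame with cluster, size, majorityClass (ties toward the
#'   smaller column index) and purity.
#' @export
perClusterPurity <- function(table) {
  if (!length(table)) stop("empty contingency table")
  sizes <- rowSums(table)
  maj <- apply(table, 1L, which.max)       # which.max ties -> smaller index
  data.frame(cluster = rownames(table) %||% as.character(seq_len(nrow(table))),
             size = as.integer(sizes),
             majorityClass = colnames(table)[maj] %||% as.character(maj),
             purity = apply(table, 1L, max) / sizes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global F1-measure of a clustering
#'
#' With recall \eqn{R_{c,l} = |c \cap l| / |l|} and precision
#' \eqn{P_{c,l} = |c \cap l| / |c|},
#' \deqn{F1(C) = \frac{1}{|L|} \sum_{l \in L} \max_{c \in C}
#'   \frac{2 R_{c,l} P_{c,l}}{R_{c,l} + P_{c,l}}}
#' Pairs with \eqn{R + P = 0} contribute 0; the max over clusters breaks ties
#' toward the smaller row index.
#'
#' @param table contingency table (clusters x classes).
#' @return F1-measure in [0, 1].
#' @export
f1Score <- function(table) {
  if (!length(table) || sum(table) < 1) stop("empty contingency table")
  classSize <- colSums(table)
  if (any(classSize == 0)) stop("empty class in contingency table")
  clusterSize <- rowSums(table)
  best <- vapply(seq_len(ncol(table)), function(l) {
    R <- table[, l] / classSize[l]
    P <- table[, l] / clusterSize
    F <- ifelse(R + P == 0, 0, 2 * R * P / (R + P))
    max(F)
  }, numeric(1))
  mean(best)
}

#' High-quality clusters at one scale
#'
#' The presentation filter used when reporting validated clusters: keep
#' clusters with at least \code{minSize} members and per-cluster purity at
#' least \code{minPurity} (defaults 100 and 0.9).
#'
#' @param clusters cluster assignments at one scale.
#' @param truth ground-truth labels.
#' @param minSize minimum cluster size.
#' @param minPurity minimum per-cluster purity.
#' @return character vector of retained cluster ids.
#' @export
highQualityClusters <- function(clusters, truth, minSize = 100L,
                                minPurity = 0.9) {
  pc <- perClusterPurity(clusterContingency(clusters, truth))
  pc$cluster[pc$size >= minSize & pc$purity >= minPurity]
}

#' Per-scale metrics report for a WFC result
#'
#' @param result a \linkS4class{WFCResult}.
#' @param truth ground-truth labels (one per point).  Isolated points are
#'   scored as singleton clusters, so over-fragmented scales are penalised
#'   by F1.
#' @return data.frame: scale, nClusters, nIsolated, purity, f1.
#' @export
metricsReport <- function(result, truth) {
  stopifnot(is(result, "WFCResult"))
  do.call(rbind, lapply(seq_along(result@perScale), function(s) {
    cl <- result@perScale[[s]]
    tab <- clusterContingency(cl@labels, truth)
    data.frame(scale = s, nClusters = length(cl@sizes),
               nIsolated = length(cl@isolated),
               purity = purityScore(tab), f1 = f1Score(tab))
  }))
}
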