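# Readers, writers and the preprocessing rules: dense CSV/TSV, MatrixMarket
# sparse single-cell matrices, highly-variable-gene selection and the
# grid-density outlier filter.

#' Read a dense point matrix from CSV/TSV
#'
#' Rows are points, columns numeric coordinates.  A header line and a leading
#' non-numeric id column are auto-detected (the detection is reported via
#' \code{message}).  Row order is preserved.
#'
#' @param path file path; the separator defaults to "," for .csv and tab
#'   otherwise, override with \code{sep}.
#' @param sep optional field separator.
#' @return numeric matrix (points x dimensions).
#' @export
readDense <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (!nzchar(first)) stop("empty file: ", path)
  tokens <- strsplit(first, sep, fixed = TRUE)[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(tokens[-1L]))) ||
            (length(tokens) == 1L &&
             is.na(suppressWarnings(as.numeric(tokens))))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  idCol <- !is.numeric(df[[1L]])
  if (idCol) df <- df[, -1L, drop = FALSE]
  message(sprintf("readDense: %s, header=%s, id column=%s, n=%d, d=%d",
                  basename(path), header, idCol, nrow(df), ncol(df)))
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric column(s): ", paste(bad, collapse = ", "))
  as.matrix(df)
}

#' Write a dense point matrix as CSV
#'
#' @param X numeric matrix.
#' @param path output path.
#' @export
writeDense <- function(X, path) {
  utils::write.table(X, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket sparse expression matrix
#'
#' @param path .mtx file in coordinate format.
#' @param rowNames,colNames optional files with one name per line.
#' @param transpose set TRUE when the file is genes x cells so that cells
#'   become rows (points).
#' @return a sparse \code{Matrix} with cells as rows.
#' @export
readMtx <- function(path, rowNames = NULL, colNames = NULL,
                    transpose = FALSE) {
  M <- Matrix::readMM(path)
  if (!is.null(rowNames)) {
    rn <- readLines(rowNames)
    if (length(rn) != nrow(M))
      stop("row name file length (", length(rn),
           ") does not match matrix rows (", nrow(M), ")")
    rownames(M) <- rn
  }
  if (!is.null(colNames)) {
    cn <- readLines(colNames)
    if (length(cn) != ncol(M))
      stop("column name file length (", length(cn),
           ") does not match matrix columns (", ncol(M), ")")
    colnames(M) <- cn
  }
  if (transpose) M <- Matrix::t(M)
  methods::as(M, "CsparseMatrix")
}

#' Select highly variable genes (columns)
#'
#' Columns are ranked by population variance (ties broken toward the smaller
#' column index) and the top k are retained in their original relative order
#' — the standard informative-gene preselection for single-cell clustering
#' (default 2000 genes).
#'
#' @param X numeric or sparse matrix, cells x genes.
#' @param k number of columns to keep.
#' @param lognorm apply \code{log1p} before computing variances (off by
#'   default; variances are taken on the values as given).
#' @return the column-subset matrix, with the selection reported via
#'   \code{attr(, "selected")}.
#' @export
selectHVG <- function(X, k = 2000L, lognorm = FALSE) {
  d <- ncol(X)
  if (k > d) stop("k = ", k, " exceeds number of columns ", d)
  if (lognorm) X <- log1p(X)
  n <- nrow(X)
  mu <- Matrix::colMeans(X)
  mu2 <- Matrix::colMeans(X^2)
  v <- mu2 - mu^2                       # population variance
  keep <- sort(order(-v, seq_len(d))[seq_len(k)])
  out <- X[, keep, drop = FALSE]
  attr(out, "selected") <- keep
  out
}

#' Grid-density outlier filter for two-dimensional location data
#'
#' Bins points into half-open \code{cellSize x cellSize} cells (anchored at
#' the coordinate origin) and drops every point falling in a cell with fewer
#' than \code{minCount} points — the low-density outlier filter used for
#' location records (default: at least 90 locations per 0.01-degree cell).
#'
#' @param X numeric matrix with two columns (e.g. longitude, latitude).
#' @param cellSize cell side in coordinate units.
#' @param minCount minimum points per retained cell.
#' @return the filtered matrix; the number retained is reported.
#' @export
densityFilter <- function(X, cellSize = 0.01, minCount = 90L) {
  X <- asDenseMatrix(X)
  if (ncol(X) != 2L) stop("density filter expects two-dimensional data")
  if (cellSize <= 0) stop("cellSize must be positive")
  key <- pasteKey(floor(X / cellSize))
  counts <- table(key)
  keep <- counts[key] >= minCount
  message(sprintf("densityFilter: retained %d of %d points", sum(keep),
                  nrow(X)))
  X[keep, , drop = FALSE]
}

#' Write a WFC result directory
#'
#' Writes \code{labels.tsv} (point_id and one column per scale),
#' \code{hierarchy.json}, \code{schedule.json}, \code{config.json} and
#' \code{log.txt} (per-scale threshold, edge/cluster/isolated counts).
#' Rerunning \code{runWFC} with the stored config reproduces the label files
#' bit-identically.
#'
#' @param result a \linkS4class{WFCResult}.
#' @param dir output directory (created if missing).
#' @export
writeResult <- function(result, dir) {
  stopifnot(is(result, "WFCResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- do.call(cbind, lapply(result@perScale, function(p) p@labels))
  colnames(lab) <- paste0("scale_", seq_along(result@perScale))
  df <- data.frame(point_id = seq_len(nrow(lab)), lab)
  utils::write.table(df, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(hierarchyTable(result),
                       file.path(dir, "hierarchy.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  scheduleToJSON(result@schedule, file.path(dir, "schedule.json"))
  cfg <- result@config
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  st <- result@stats
  writeLines(c(sprintf("coding=%s lambda=%g s_end=%d repaired_parents=%d",
                       result@coding, result@schedule@lambda,
                       result@schedule@sEnd, repairedParents(result)),
               sprintf("scale=%d threshold=%.8g edges=%d clusters=%d isolated=%d",
                       st$scale, st$threshold, st$nEdges, st$nClusters,
                       st$nIsolated)),
             file.path(dir, "log.txt"))
  invisible(dir)
}

#' Read back the per-scale labels of a result directory
#'
#' @param dir a directory written by \code{\link{writeResult}}.
#' @return integer matrix of labels (points x scales).
#' @export
readResultLabels <- function(dir) {
  df <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                          header = TRUE)
  as.matrix(df[, -1L, drop = FALSE])
}
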