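#' Read an expression matrix from disk
#'
#' Dense input is a delimited text file with a header row of gene ids and a
#' first column of cell ids. Sparse input is a Matrix Market coordinate
#' file accompanied by two one-column text files with row and column
#' names. Orientation is cells-in-rows; set `genesInRows = TRUE` to
#' transpose genes-in-rows input on load.
#'
#' @param path path to the matrix file.
#' @param format `"dense"` (delimited text) or `"matrix-market"`.
#' @param sep field separator for dense input; `NULL` picks `","` for
#'   `.csv` files and tab otherwise.
#' @param genesInRows if `TRUE` the file stores genes in rows and is
#'   transposed after reading.
#' @param rowNamesFile,colNamesFile for Matrix Market input, files holding
#'   one row/column name per line (row = cell unless `genesInRows`).
#' @return a validated [CellStateSet-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("cell,gA,gB", "c1,0,1", "c2,2,3", "c3,4,5"), f)
#' cs <- readExpressionMatrix(f)
#' exprValues(cs)
#' @export
readExpressionMatrix <- function(path,
                                 format = c("dense", "matrix-market"),
                                 sep = NULL, genesInRows = FALSE,
                                 rowNamesFile = NULL,
                                 colNamesFile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    if (is.null(sep))
      sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                        check.names = FALSE, comment.char = "",
                        quote = "\""),
      error = function(e) stop("malformed dense matrix file '", path,
                               "': ", conditionMessage(e)))
    values <- as.matrix(df)
    if (!is.numeric(values)) {
      bad <- which(!vapply(df, is.numeric, logical(1L)))[1L]
      stop("non-numeric entries in column '", colnames(df)[bad],
           "' of ", path)
    }
  } else {
    if (is.null(rowNamesFile) || is.null(colNamesFile))
      stop("matrix-market input needs 'rowNamesFile' and 'colNamesFile'")
    mm <- tryCatch(Matrix::readMM(path),
                   error = function(e) stop("malformed Matrix Market file '",
                                            path, "': ",
                                            conditionMessage(e)))
    values <- as.matrix(mm)
    rn <- readLines(rowNamesFile)
    cn <- readLines(colNamesFile)
    if (length(rn) != nrow(values) || length(cn) != ncol(values))
      stop("name files do not match matrix dimensions (",
           nrow(values), " x ", ncol(values), " vs ", length(rn),
           " row names, ", length(cn), " column names)")
    dimnames(values) <- list(rn, cn)
  }
  if (genesInRows) values <- t(values)
  CellStateSet(values)
}

#' Write a CellStateSet as a dense delimited file
#'
#' The inverse of [readExpressionMatrix()]: a header row of gene ids, a
#' first column of cell ids, cells in rows. Values are written with full
#' precision (`format(..., digits = 17)`) so a read-back reproduces the
#' matrix bit-exactly.
#'
#' @param cs a [CellStateSet-class].
#' @param path output path.
#' @param sep field separator (default `","`).
#' @export
writeExpressionMatrix <- function(cs, path, sep = ",") {
  v <- exprValues(cs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cell", colnames(v)), collapse = sep), con)
  body <- apply(v, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = sep))
  writeLines(paste(rownames(v), body, sep = sep), con)
  invisible(path)
}

#' Pre-process an expression matrix
#'
#' Standard light-weight single-cell pre-processing: drop genes expressed
#' (value > 0) in fewer than `minExpressingFraction` of cells, optionally
#' log(1 + x)-transform, and optionally compute a PCA embedding used for
#' all subsequent *distance* computations (the gene space itself is kept
#' for the network and burst analyses).
#'
#' @param cs a [CellStateSet-class].
#' @param minExpressingFraction genes expressed in fewer than this
#'   fraction of cells are dropped (default 0.05).
#' @param logTransform apply log(1 + x) (default TRUE).
#' @param reduceTo optional number of principal components for the
#'   distance space.
#' @return a new [CellStateSet-class]; cell count is never altered, gene
#'   count never increases.
#' @export
preprocessCells <- function(cs, minExpressingFraction = 0.05,
                            logTransform = TRUE, reduceTo = NULL) {
  .checkScalar(minExpressingFraction, "minExpressingFraction", 0, 1)
  v <- exprValues(cs)
  expressed <- colMeans(v > 0)
  keep <- expressed >= minExpressingFraction
  if (!any(keep))
    stop("pre-processing removed all genes ",
         "(minExpressingFraction = ", minExpressingFraction, ")")
  v <- v[, keep, drop = FALSE]
  if (logTransform) v <- log1p(v)
  reduced <- NULL
  if (!is.null(reduceTo)) {
    reduceTo <- as.integer(reduceTo)
    .checkScalar(reduceTo, "reduceTo", 1, min(dim(v)))
    pc <- prcomp(v, center = TRUE, scale. = FALSE, rank. = reduceTo)
    reduced <- pc$x
    rownames(reduced) <- rownames(v)
  }
  CellStateSet(v, reduced = reduced)
}

#' Derive the Gaussian kernel bandwidth from pairwise distances
#'
#' Sets sigma to the `sigmaQuantile` quantile of the m(m-1)/2 distinct
#' pairwise cell-cell distances (linear interpolation between order
#' statistics). A small quantile keeps the density estimate local.
#'
#' @param cs a [CellStateSet-class] with at least two cells.
#' @param sigmaQuantile quantile in (0, 1); default 0.02.
#' @return a [DistanceContext-class].
#' @export
deriveSigma <- function(cs, sigmaQuantile = 0.02) {
  .checkScalar(sigmaQuantile, "sigmaQuantile", 0, 1,
               openLo = TRUE, openHi = TRUE)
  if (nCells(cs) < 2L) stop("need at least two cells to derive sigma")
  d <- dist(stateCoords(cs))
  if (all(d == 0))
    stop("degenerate geometry: all cells are identical ",
         "(every pairwise distance is 0)")
  sigma <- .quantileLinear(as.numeric(d), sigmaQuantile)
  if (sigma <= 0) {
    sigma <- min(d[d > 0])
    warning("the requested quantile of pairwise distances is 0 ",
            "(duplicated cells); using the smallest positive distance ",
            format(sigma, digits = 4), " instead")
  }
  new("DistanceContext", metric = "euclidean", sigma = sigma,
      sigmaQuantile = sigmaQuantile)
}
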