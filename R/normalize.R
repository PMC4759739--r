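#' Quantile normalization
#'
#' Forces every column (sample) of a log2 intensity matrix onto one
#' common distribution: the across-column means of the order statistics.
#' Tied values within a column receive the mean of the reference values
#' at their tied ranks. Row and column identities are preserved, the
#' operation is idempotent, and after it all columns share a single
#' sorted value vector.
#'
#' @param x a numeric matrix (genes x samples) or an
#'   [HscExperiment-class], whose `exprs` assay is normalized in place.
#' @return An object of the same class as `x`.
#' @examples
#' m <- matrix(c(5, 2, 3, 2, 4, 3), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' quantileNormalize(m)
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
  if (ncol(x) < 1L) stop("matrix must have at least one column")
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    g <- if (is.null(rownames(x))) bad[1, 1] else rownames(x)[bad[1, 1]]
    s <- if (is.null(colnames(x))) bad[1, 2] else colnames(x)[bad[1, 2]]
    stop("non-finite value at gene ", g, ", sample ", s)
  }
  if (ncol(x) == 1L) return(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # half-integer ranks from ties interpolate between reference values
    lo <- floor(rk); hi <- ceiling(rk)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "HscExperiment", function(x) {
  SummarizedExperiment::assay(x, "exprs") <-
    quantileNormalize(SummarizedExperiment::assay(x, "exprs"))
  x
})
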