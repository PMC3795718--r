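#' Fold-change filter
#'
#' Keeps a gene when its maximal expression over all samples divided by its
#' minimal expression is at least `minFold` (linear scale). On log2-scale
#' data (`logScale = TRUE`) the criterion is max - min >= log2(minFold).
#' Gene order is preserved. The data's scale is never guessed: the caller
#' states it through `logScale`.
#'
#' @param x a TimecourseExperiment
#' @param minFold minimal fold change, > 1.
#' @param logScale are the stored values log2-scale?
#' @return the filtered TimecourseExperiment (possibly with zero genes, with
#'   a warning).
#' @export
foldChangeFilter <- function(x, minFold = 2, logScale = FALSE) {
    if (minFold <= 1) stop("minFold must be > 1")
    m <- exprValues(x)
    hi <- apply(m, 1L, max)
    lo <- apply(m, 1L, min)
    if (logScale) {
        keep <- (hi - lo) >= log2(minFold)
    } else {
        if (any(lo <= 0))
            stop("non-positive values under a linear-scale fold-change ",
                 "filter; use logScale = TRUE for log data")
        keep <- (hi / lo) >= minFold
    }
    if (!any(keep))
        warning("fold-change filter removed every gene")
    x[keep, ]
}

#' Quantile normalization of the expression matrix
#'
#' Forces every sample (column) to share the across-sample mean distribution
#' of order statistics while preserving within-sample ranks; ties within a
#' sample receive the mean of the reference values they span. Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param x a TimecourseExperiment with at least two samples.
#' @return the normalized TimecourseExperiment.
#' @export
quantileNormalize <- function(x) {
    if (ncol(x) < 2L)
        stop("quantile normalization needs at least 2 samples")
    m <- exprValues(x)
    qn <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(qn) <- dimnames(m)
    SummarizedExperiment::assay(x, "exprs") <- qn
    x
}

#' Permute condition labels
#'
#' Randomly reassigns the expression columns to the sample metadata slots
#' (the metadata grid stays fixed; the values move). This severs every
#' gene-condition association and is the null model used for chance-level
#' calibration of the classifier.
#'
#' @param x a TimecourseExperiment
#' @return a TimecourseExperiment with shuffled columns.
#' @export
permuteLabels <- function(x) {
    m <- exprValues(x)
    perm <- sample.int(ncol(m))
    m2 <- m[, perm, drop = FALSE]
    colnames(m2) <- colnames(m)
    SummarizedExperiment::assay(x, "exprs") <- m2
    x
}
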