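#' Construct a TimecourseExperiment
#'
#' @param exprs numeric matrix, genes x samples, with unique rownames (gene
#'   identifiers) and colnames (sample identifiers).
#' @param sampleInfo data.frame with one row per sample and columns
#'   `sample_id`, `condition_id`, `factors` (semicolon-separated factor
#'   labels), `time_point` (numeric) and `replicate` (1-based integer).
#'   Rows are matched to `exprs` columns by `sample_id`; a mismatch in
#'   either direction is an error.
#' @param provenance free-text label stored in `metadata()`.
#' @return A \linkS4class{TimecourseExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' si <- data.frame(sample_id = paste0("s", 1:4), condition_id = "cold_root",
#'                  factors = "cold;root", time_point = c(0, 0, 1, 1),
#'                  replicate = c(1L, 2L, 1L, 2L))
#' tce <- TimecourseExperiment(m, si)
#' conditionIds(tce)
#' @export
TimecourseExperiment <- function(exprs, sampleInfo, provenance = "unspecified") {
    exprs <- as.matrix(exprs)
    if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
        stop("expression matrix needs gene rownames and sample colnames")
    need <- c("sample_id", "condition_id", "factors", "time_point", "replicate")
    miss <- setdiff(need, colnames(sampleInfo))
    if (length(miss))
        stop("sampleInfo lacks column(s): ", paste(miss, collapse = ", "))
    extraCols <- setdiff(colnames(exprs), sampleInfo$sample_id)
    if (length(extraCols))
        stop("expression columns absent from metadata: ",
             paste(utils::head(extraCols, 5L), collapse = ", "))
    extraMeta <- setdiff(sampleInfo$sample_id, colnames(exprs))
    if (length(extraMeta))
        stop("metadata rows without a matching expression column: ",
             paste(utils::head(extraMeta, 5L), collapse = ", "))
    sampleInfo <- sampleInfo[match(colnames(exprs), sampleInfo$sample_id), ,
                             drop = FALSE]
    cd <- S4Vectors::DataFrame(
        condition_id = as.character(sampleInfo$condition_id),
        time_point = as.numeric(sampleInfo$time_point),
        replicate = as.integer(sampleInfo$replicate),
        factors = .canonFactors(sampleInfo$factors),
        row.names = colnames(exprs))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd)
    S4Vectors::metadata(se)$provenance <- provenance
    methods::new("TimecourseExperiment", se)
}

## semicolon-joined factor labels in a canonical (sorted, trimmed) order so
## the factor SET, not its spelling, is the identity
.canonFactors <- function(f) {
    vapply(strsplit(as.character(f), ";", fixed = TRUE), function(v) {
        v <- sort(unique(trimws(v)))
        paste(v[nzchar(v)], collapse = ";")
    }, character(1))
}

.factorSet <- function(f) strsplit(f, ";", fixed = TRUE)[[1L]]

#' @describeIn TimecourseExperiment unique condition identifiers, in order
#'   of first appearance.
#' @param x a TimecourseExperiment
#' @export
setMethod("conditionIds", "TimecourseExperiment", function(x)
    unique(as.character(SummarizedExperiment::colData(x)$condition_id)))

#' Experimental factor sets per condition
#'
#' @param x a TimecourseExperiment
#' @return named list, per condition the character vector of its factor
#'   labels.
#' @export
setMethod("conditionFactors", "TimecourseExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    ids <- conditionIds(x)
    out <- lapply(ids, function(k)
        .factorSet(cd$factors[match(k, cd$condition_id)]))
    names(out) <- ids
    out
})

#' Time points of one condition
#'
#' @param x a TimecourseExperiment
#' @param condition condition identifier
#' @return sorted unique numeric time points of the condition.
#' @export
setMethod("timePoints", "TimecourseExperiment", function(x, condition) {
    cd <- SummarizedExperiment::colData(x)
    sel <- cd$condition_id == condition
    if (!any(sel)) stop("unknown condition: ", condition)
    sort(unique(cd$time_point[sel]))
})

#' Replicate counts per time point of one condition
#'
#' @param x a TimecourseExperiment
#' @param condition condition identifier
#' @return named integer vector, replicates available at each time point.
#' @export
setMethod("replicateCounts", "TimecourseExperiment", function(x, condition) {
    cd <- SummarizedExperiment::colData(x)
    sel <- cd$condition_id == condition
    if (!any(sel)) stop("unknown condition: ", condition)
    tp <- cd$time_point[sel]
    tab <- table(tp)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
})

#' @describeIn TimecourseExperiment the expression matrix (genes x samples).
#' @export
setMethod("exprValues", "TimecourseExperiment", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @describeIn TimecourseExperiment sample metadata as a plain data.frame
#'   with a `sample_id` column.
#' @export
setMethod("sampleInfo", "TimecourseExperiment", function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    data.frame(sample_id = rownames(cd), cd, row.names = NULL,
               stringsAsFactors = FALSE)
})

setMethod("show", "TimecourseExperiment", function(object) {
    cat("TimecourseExperiment:", nrow(object), "genes x", ncol(object),
        "samples,", length(conditionIds(object)), "conditions\n")
    callNextMethod()
})

## column indices of (condition [, time point]) under an optional logical
## training mask over columns
.sampleCols <- function(x, condition, time = NULL, mask = NULL) {
    cd <- SummarizedExperiment::colData(x)
    sel <- cd$condition_id == condition
    if (!is.null(time)) sel <- sel & cd$time_point == time
    if (!is.null(mask)) sel <- sel & mask
    which(sel)
}
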