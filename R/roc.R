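#' AUC by the rank-sum formulation
#'
#' Area under the ROC curve of a score vector against binary labels,
#' computed as the normalized Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counting one half (equivalent to the trapezoidal area of the cut-off
#' sweep).
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical (or 0/1) vector, TRUE = positive.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
    labels <- as.logical(labels)
    if (length(scores) != length(labels)) stop("length mismatch")
    nP <- sum(labels); nN <- sum(!labels)
    if (nP == 0L || nN == 0L)
        stop("AUC needs at least one positive and one negative")
    r <- rank(scores)  # average ranks handle ties at half credit
    (sum(r[labels]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Query-versus-database ROC evaluation
#'
#' Every experiment (a condition/replicate pair at the dataset's two
#' pseudo-time points) queries all remaining experiments: the score of a
#' database experiment is the Pearson similarity between the two transition
#' profiles, computed on the gene subset selected for the database
#' experiment's condition (selector fitted on the database, i.e. with the
#' query held out); its label records whether it shares the query's
#' condition. Per-query AUCs (ties half-credit) are averaged; queries with
#' no positive or no negative database entry are excluded with a warning.
#'
#' @param x a TimecourseExperiment of paired two-state experiments.
#' @param config a \linkS4class{CVConfig}; `selector`, `nGenes`, `cutoff`,
#'   `profileKind` and `seed` are used.
#' @param links optional \linkS4class{GeneLinkSet} for selector
#'   "string_gene".
#' @return A \linkS4class{ROCResult}.
#' @export
rocAucQuery <- function(x, config = cvConfig(), links = NULL) {
    set.seed(config@seed)
    ex <- .experiments(x)
    if (length(unique(ex$condition)) < 2L)
        stop("ROC evaluation needs at least 2 conditions")
    queries <- list(); aucs <- numeric(0); excluded <- 0L
    for (q in seq_len(nrow(ex))) {
        qCols <- .experimentCols(x, ex$condition[q], ex$replicate[q])
        mask <- rep(TRUE, ncol(x))
        mask[qCols] <- FALSE
        selections <- .fitSelections(x, mask, config, links)
        dbProfs <- .experimentProfiles(x, mask, config@profileKind)
        qProf <- .experimentProfiles(x, !mask, config@profileKind)[[1L]]
        score <- vapply(dbProfs, function(p) {
            sel <- if (is.null(selections) ||
                       is.null(selections[[p@conditionId]]))
                names(p@values) else selections[[p@conditionId]]
            g <- intersect(sel, names(qProf@values))
            pearsonSimilarity(qProf@values[g], p@values[g])
        }, numeric(1))
        label <- vapply(dbProfs, function(p)
            p@conditionId == ex$condition[q], logical(1))
        queries[[length(queries) + 1L]] <-
            data.frame(score = score, label = label)
        if (!any(label) || all(label)) {
            excluded <- excluded + 1L
            aucs <- c(aucs, NA_real_)
        } else {
            aucs <- c(aucs, aucScore(score, label))
        }
    }
    if (excluded)
        warning(excluded, " query(ies) excluded: no positive or no ",
                "negative database entry")
    methods::new("ROCResult", queries = queries, aucPerQuery = aucs,
                 meanAuc = mean(aucs, na.rm = TRUE), nExcluded = excluded)
}

#' @describeIn rocAucQuery mean AUC over queries with defined AUC.
#' @param x a ROCResult
#' @export
setMethod("meanAuc", "ROCResult", function(x) x@meanAuc)

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROCResult: mean AUC %.3f over %d queries",
                object@meanAuc, length(object@aucPerQuery)))
    if (object@nExcluded) cat(" (", object@nExcluded, " excluded)", sep = "")
    cat("\n")
})
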