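## expression columns of (condition, time) under a mask; error when absent
.tpCols <- function(x, condition, time, mask = NULL) {
    idx <- .sampleCols(x, condition, time, mask)
    if (!length(idx))
        stop("no sample for condition '", condition, "' at time ", time,
             if (!is.null(mask)) " within the training mask" else "")
    idx
}

.newProfile <- function(condition, tx, ty, kind, values, tag,
                        ownTime = NA_real_) {
    methods::new("TransitionProfile", conditionId = condition,
                 timePair = c(tx, ty), kind = kind, ownTime = ownTime,
                 values = values, replicateTag = tag)
}

## builds DTP/MTP/TIMEPOINT profiles from two time points of one condition.
## policy "average": replicates at each time point are averaged -> a single
## profile (TIMEPOINT: a list of two). policy "each": one profile per
## replicate combination.
.buildProfiles <- function(x, condition, tx, ty, kind, replicatePolicy,
                           mask = NULL) {
    if (tx == ty) stop("the two time points must differ")
    if (tx > ty) { tmp <- tx; tx <- ty; ty <- tmp }
    cx <- .tpCols(x, condition, tx, mask)
    cy <- .tpCols(x, condition, ty, mask)
    m <- exprValues(x)
    combine <- function(a, b, tagA, tagB) {
        switch(kind,
            DTP = list(.newProfile(condition, tx, ty, "DTP", b - a,
                                   paste(tagA, tagB, sep = "/"))),
            MTP = list(.newProfile(condition, tx, ty, "MTP", (a + b) / 2,
                                   paste(tagA, tagB, sep = "/"))),
            TIMEPOINT = list(
                .newProfile(condition, tx, ty, "TIMEPOINT", a, tagA,
                            ownTime = tx),
                .newProfile(condition, tx, ty, "TIMEPOINT", b, tagB,
                            ownTime = ty)))
    }
    if (replicatePolicy == "average") {
        a <- rowMeans(m[, cx, drop = FALSE])
        b <- rowMeans(m[, cy, drop = FALSE])
        combine(a, b, "averaged", "averaged")
    } else {
        out <- list()
        for (i in cx) for (j in cy)
            out <- c(out, combine(m[, i], m[, j],
                                  colnames(m)[i], colnames(m)[j]))
        out
    }
}

#' Differential transition profile (DTP)
#'
#' The per-gene change in expression between two time points of one
#' condition: value(g) = E(g, ty) - E(g, tx).
#'
#' @param x a TimecourseExperiment
#' @param condition condition identifier
#' @param tx,ty the two time points, tx < ty (swapped if given reversed).
#' @param replicatePolicy "average" pools replicates at each time point into
#'   their mean and returns a single profile; "each" returns one profile per
#'   replicate combination (a list).
#' @param mask optional logical column mask restricting the samples used
#'   (e.g. a training mask).
#' @return A \linkS4class{TransitionProfile}, or a list of them under
#'   `replicatePolicy = "each"`.
#' @export
makeDTP <- function(x, condition, tx, ty, replicatePolicy = "average",
                    mask = NULL) {
    p <- .buildProfiles(x, condition, tx, ty, "DTP", replicatePolicy, mask)
    if (replicatePolicy == "average") p[[1L]] else p
}

#' Mean transition profile (MTP)
#'
#' The per-gene mean expression between two time points of one condition:
#' value(g) = (E(g, tx) + E(g, ty)) / 2.
#'
#' @inheritParams makeDTP
#' @return A \linkS4class{TransitionProfile}, or a list of them under
#'   `replicatePolicy = "each"`.
#' @export
makeMTP <- function(x, condition, tx, ty, replicatePolicy = "average",
                    mask = NULL) {
    p <- .buildProfiles(x, condition, tx, ty, "MTP", replicatePolicy, mask)
    if (replicatePolicy == "average") p[[1L]] else p
}

#' Single-time-point expression profiles of a pair
#'
#' Returns the two individual expression profiles of a pair of time points,
#' for classification that compares each time point separately.
#'
#' @inheritParams makeDTP
#' @return list of two (or more, under `replicatePolicy = "each"`)
#'   \linkS4class{TransitionProfile}s of kind "TIMEPOINT".
#' @export
makeTimepointProfiles <- function(x, condition, tx, ty,
                                  replicatePolicy = "average", mask = NULL) {
    .buildProfiles(x, condition, tx, ty, "TIMEPOINT", replicatePolicy, mask)
}

#' @describeIn makeDTP the profile's named value vector.
#' @export
setMethod("profileValues", "TransitionProfile", function(x) x@values)

setMethod("show", "TransitionProfile", function(object) {
    cat(object@kind, "profile of condition", object@conditionId,
        "at times", paste(object@timePair, collapse = "-"),
        sprintf("(%d features, replicates: %s)\n", length(object@values),
                object@replicateTag))
})

#' Convert a gene profile into a link profile
#'
#' Each link's value is the mean of its two incident genes' values in the
#' gene profile. Links with an endpoint absent from the profile are dropped
#' with a warning; an empty result is an error.
#'
#' @param p a \linkS4class{TransitionProfile} over genes.
#' @param links a \linkS4class{GeneLinkSet}.
#' @return A \linkS4class{LinkProfile} whose values are named
#'   `"geneA|geneB"`.
#' @export
toLinkProfile <- function(p, links) {
    lt <- linkTable(links)
    v <- profileValues(p)
    present <- lt$gene_a %in% names(v) & lt$gene_b %in% names(v)
    if (!all(present)) {
        warning(sum(!present), " link(s) dropped: gene absent from profile")
        lt <- lt[present, , drop = FALSE]
    }
    if (!nrow(lt)) stop("no link has both genes in the profile")
    lv <- (v[lt$gene_a] + v[lt$gene_b]) / 2
    names(lv) <- paste(lt$gene_a, lt$gene_b, sep = "|")
    methods::new("LinkProfile", conditionId = p@conditionId,
                 timePair = p@timePair, kind = p@kind, ownTime = p@ownTime,
                 values = lv, replicateTag = p@replicateTag,
                 linkTable = lt[, c("gene_a", "gene_b"), drop = FALSE])
}

#' All training profiles of a dataset
#'
#' Builds, for every condition with at least two available time points under
#' the mask, transition profiles of the requested kind for all ordered time
#' point pairs (`pairPolicy = "all"`) or consecutive pairs only
#' (`"consecutive"`); for kind "TIMEPOINT", one profile per available time
#' point instead.
#'
#' @param x a TimecourseExperiment
#' @param mask logical column mask (TRUE = sample is in training); `NULL`
#'   uses everything.
#' @param kind "DTP", "MTP" or "TIMEPOINT".
#' @param pairPolicy "all" or "consecutive".
#' @param replicatePolicy passed to the profile builders.
#' @return list of \linkS4class{TransitionProfile}s.
#' @export
trainingProfiles <- function(x, mask = NULL, kind = "MTP",
                             pairPolicy = "all",
                             replicatePolicy = "average") {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(mask)) mask <- rep(TRUE, ncol(x))
    out <- list()
    for (k in conditionIds(x)) {
        tps <- sort(unique(cd$time_point[cd$condition_id == k & mask]))
        if (length(tps) < 2L) next
        if (kind == "TIMEPOINT") {
            m <- exprValues(x)
            for (t in tps) {
                cols <- .sampleCols(x, k, t, mask)
                if (replicatePolicy == "average") {
                    out <- c(out, list(.newProfile(
                        k, t, t, "TIMEPOINT",
                        rowMeans(m[, cols, drop = FALSE]), "averaged",
                        ownTime = t)))
                } else {
                    for (j in cols)
                        out <- c(out, list(.newProfile(
                            k, t, t, "TIMEPOINT", m[, j], colnames(m)[j],
                            ownTime = t)))
                }
            }
        } else {
            pairs <- if (pairPolicy == "consecutive") {
                cbind(tps[-length(tps)], tps[-1L])
            } else {
                t(utils::combn(tps, 2L))
            }
            for (r in seq_len(nrow(pairs)))
                out <- c(out, .buildProfiles(x, k, pairs[r, 1L], pairs[r, 2L],
                                             kind, replicatePolicy, mask))
        }
    }
    out
}
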