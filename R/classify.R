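#' Pearson similarity with a deterministic degenerate sentinel
#'
#' Standard product-moment correlation of two equal-length vectors
#' (length >= 3). When either vector has zero variance the correlation is
#' undefined; `-Inf` is returned, which compares below every valid
#' correlation, so constant profiles can never be nearest neighbors.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], or `-Inf`.
#' @export
pearsonSimilarity <- function(x, y) {
    if (length(x) != length(y)) stop("vectors differ in length")
    if (length(x) < 3L) stop("at least 3 values are required")
    xc <- x - mean(x); yc <- y - mean(y)
    den <- sum(xc^2) * sum(yc^2)
    if (den == 0) return(-Inf)
    sum(xc * yc) / sqrt(den)
}

## correlations of one vector against matrix columns; zero-variance columns
## (or vector) give -Inf
.pearsonVec <- function(x, M) {
    xc <- x - mean(x)
    sx <- sum(xc^2)
    Mc <- sweep(M, 2L, colMeans(M))
    d <- colSums(Mc^2)
    if (sx == 0) return(rep(-Inf, ncol(M)))
    r <- as.vector(crossprod(xc, Mc)) / sqrt(sx * d)
    r[d == 0] <- -Inf
    r
}

## similarity of a test profile to every training profile, honoring
## per-condition gene selections; profiles with < 3 usable genes get NA
.similarities <- function(testProfile, trainingProfiles, selections = NULL) {
    tv <- profileValues(testProfile)
    conds <- vapply(trainingProfiles, function(p) p@conditionId, character(1))
    r <- rep(NA_real_, length(trainingProfiles))
    skipped <- 0L
    for (k in unique(conds)) {
        idx <- which(conds == k)
        sel <- if (is.null(selections) || is.null(selections[[k]]))
            names(tv) else selections[[k]]
        common <- intersect(sel, names(tv))
        common <- intersect(common,
                            names(profileValues(trainingProfiles[[idx[1L]]])))
        if (length(common) < 3L) { skipped <- skipped + length(idx); next }
        M <- vapply(trainingProfiles[idx],
                    function(p) profileValues(p)[common],
                    numeric(length(common)))
        r[idx] <- .pearsonVec(tv[common],
                              matrix(M, nrow = length(common)))
    }
    if (skipped)
        warning(skipped, " training profile(s) skipped: fewer than 3 ",
                "usable genes after selection")
    if (all(is.na(r)))
        stop("no training profile has 3 or more usable genes")
    r
}

## deterministic argmax over training profiles: highest similarity, ties by
## (condition_id, time pair, position)
.bestProfile <- function(trainingProfiles, r) {
    conds <- vapply(trainingProfiles, function(p) p@conditionId, character(1))
    pairs <- vapply(trainingProfiles,
                    function(p) paste(p@timePair, collapse = "-"),
                    character(1))
    use <- which(!is.na(r))
    use[order(-r[use], conds[use], pairs[use], use)][1L]
}

#' Vote of one test profile (1-nearest-neighbor)
#'
#' Computes the Pearson similarity between a test transition profile and
#' every training profile, restricting each comparison to the gene subset
#' selected for the training profile's condition (all genes when no
#' selection is given), and votes for the condition of the most similar
#' profile. Exact similarity ties are broken by (condition id, time pair)
#' lexicographic order. Training profiles with fewer than 3 usable genes are
#' skipped with a warning; if all are skipped, an error is raised.
#'
#' @param testProfile a \linkS4class{TransitionProfile}.
#' @param trainingProfiles list of training profiles.
#' @param selections named list, per condition a character vector of genes
#'   (or `NULL` for all genes).
#' @return list with elements `condition`, `similarity` and `index` (the
#'   winning training profile).
#' @export
classifyPair <- function(testProfile, trainingProfiles, selections = NULL) {
    r <- .similarities(testProfile, trainingProfiles, selections)
    best <- .bestProfile(trainingProfiles, r)
    list(condition = trainingProfiles[[best]]@conditionId,
         similarity = r[best], index = best)
}

#' Classify a test unit by majority voting
#'
#' Each test transition profile casts one vote via [classifyPair()]; the
#' condition with the most votes is predicted. Tied vote counts are broken
#' by the highest sum of the winning similarity scores among the tied
#' conditions (then lexicographically, for exact sum ties).
#'
#' @param testProfiles list of test transition profiles (one per consecutive
#'   time-point pair of the test unit).
#' @param trainingProfiles list of training profiles.
#' @param selections per-condition gene subsets (see [classifyPair()]).
#' @param testId identifier recorded in the result.
#' @return A \linkS4class{Prediction}.
#' @export
classifyTestUnit <- function(testProfiles, trainingProfiles,
                             selections = NULL, testId = "test") {
    stopifnot(length(testProfiles) >= 1L)
    votes <- lapply(testProfiles, classifyPair, trainingProfiles, selections)
    vcond <- vapply(votes, `[[`, character(1), "condition")
    vsim <- vapply(votes, `[[`, numeric(1), "similarity")
    tab <- table(vcond)
    counts <- as.integer(tab); names(counts) <- names(tab)
    sums <- vapply(names(tab), function(k) sum(vsim[vcond == k]), numeric(1))
    tied <- names(tab)[counts == max(counts)]
    tieBroken <- length(tied) > 1L
    if (tieBroken) {
        s <- sums[tied]
        predicted <- sort(tied[s == max(s)])[1L]
    } else {
        predicted <- tied
    }
    methods::new("Prediction", testId = testId, predicted = predicted,
                 votes = counts, similaritySums = sums,
                 tieBroken = tieBroken)
}

#' Classify two single-time-point test profiles
#'
#' For classification on individual expression profiles the test unit is a
#' set of two single-time-point profiles. All pairwise similarities between
#' the two test profiles and all training profiles are computed; the
#' prediction is the condition of the globally most similar training
#' profile.
#'
#' @param testProfiles list of exactly two "TIMEPOINT" profiles.
#' @param trainingProfiles list of training "TIMEPOINT" profiles.
#' @inheritParams classifyTestUnit
#' @return A \linkS4class{Prediction}.
#' @export
classifyTimepointMode <- function(testProfiles, trainingProfiles,
                                  selections = NULL, testId = "test") {
    if (length(testProfiles) != 2L)
        stop("time-point mode expects exactly two test profiles")
    r1 <- .similarities(testProfiles[[1L]], trainingProfiles, selections)
    r2 <- .similarities(testProfiles[[2L]], trainingProfiles, selections)
    r <- pmax(r1, r2, na.rm = TRUE)
    r[is.na(r1) & is.na(r2)] <- NA_real_
    best <- .bestProfile(trainingProfiles, r)
    cond <- trainingProfiles[[best]]@conditionId
    methods::new("Prediction", testId = testId, predicted = cond,
                 votes = stats::setNames(1L, cond),
                 similaritySums = stats::setNames(r[best], cond),
                 tieBroken = FALSE)
}

setMethod("show", "Prediction", function(object) {
    cat("Prediction for", object@testId, "->", object@predicted,
        sprintf("(%d/%d votes%s)\n", max(object@votes), sum(object@votes),
                if (object@tieBroken) ", tie broken by similarity sum" else ""))
})
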