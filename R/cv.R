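#' Cross-validation configuration constructor
#'
#' @param scenario 1 keeps replicates of the test time points in training;
#'   2 (default) removes every replicate of the two test time points from
#'   training.
#' @param profileKind "MTP" (default), "DTP" or "TIMEPOINT".
#' @param selector "all", "rsnr", "snr_c", "welch_t", "random" or
#'   "string_gene".
#' @param nGenes genes kept per condition by ranking selectors (NA: all).
#' @param sectionStart optional first rank of a ranking section to use
#'   instead of the top.
#' @param cutoff STRING confidence cutoff for selector "string_gene".
#' @param foldsPerCondition folds per condition per repetition (default 10).
#' @param repetitions repetitions of the sub-sampling scheme (default 30).
#' @param seed RNG seed.
#' @param replicatePolicy training-profile replicate handling ("average" or
#'   "each").
#' @param pairPolicy training time-point pair enumeration ("all" ordered
#'   pairs, or "consecutive").
#' @return A \linkS4class{CVConfig}.
#' @export
cvConfig <- function(scenario = 2, profileKind = "MTP", selector = "all",
                     nGenes = NA, sectionStart = NA, cutoff = NA,
                     foldsPerCondition = 10, repetitions = 30, seed = 1,
                     replicatePolicy = "average", pairPolicy = "all") {
    methods::new("CVConfig", scenario = as.integer(scenario),
                 profileKind = profileKind, selector = selector,
                 nGenes = as.integer(nGenes),
                 sectionStart = as.integer(sectionStart),
                 cutoff = as.integer(cutoff),
                 foldsPerCondition = as.integer(foldsPerCondition),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed),
                 replicatePolicy = replicatePolicy, pairPolicy = pairPolicy)
}

setMethod("show", "CVConfig", function(object) {
    cat("CVConfig: scenario", object@scenario, "|", object@profileKind,
        "profiles | selector", object@selector,
        if (!is.na(object@nGenes)) paste0("(n=", object@nGenes, ")") else "",
        "|", object@foldsPerCondition, "folds/condition x",
        object@repetitions, "repetitions | seed", object@seed, "\n")
})

## size-safe uniform draw (sample() would expand a length-1 numeric)
.resample <- function(x, n) x[sample.int(length(x), n)]

## conditions usable as test sources: the validation framework needs at
## least 4 time points (scenario 2 must keep >= 2 training time points)
.eligibleConditions <- function(x, warn = TRUE) {
    ids <- conditionIds(x)
    nt <- vapply(ids, function(k) length(timePoints(x, k)), integer(1))
    short <- ids[nt < 4L]
    if (length(short) && warn)
        warning("condition(s) skipped (fewer than 4 time points): ",
                paste(short, collapse = ", "))
    ids[nt >= 4L]
}

#' Draw cross-validation folds for time-course data
#'
#' Scenario 2: the test unit is one replicate at each of 2 randomly chosen
#' time points of a condition; every replicate of those two time points is
#' removed from the training data. Scenario 1: a random number of time
#' points (uniform on 2..T), random time points, one random replicate each;
#' only the selected test samples themselves leave the training data.
#' `foldsPerCondition` folds are drawn for every eligible condition
#' (conditions with fewer than 4 time points are skipped with a warning).
#' Draws consume the current RNG stream; [runCV()] seeds it.
#'
#' @param x a TimecourseExperiment
#' @param config a \linkS4class{CVConfig}
#' @return list of folds, each a list with elements `condition`, `testCols`
#'   (sample names), `testTimePoints` and `trainingMask` (logical over
#'   columns).
#' @export
makeFoldsTimecourse <- function(x, config) {
    cd <- SummarizedExperiment::colData(x)
    folds <- list()
    for (k in .eligibleConditions(x)) {
        tps <- timePoints(x, k)
        for (f in seq_len(config@foldsPerCondition)) {
            nT <- if (config@scenario == 2L) 2L else
                .resample(2:length(tps), 1L)
            testTps <- sort(.resample(tps, nT))
            testCols <- vapply(testTps, function(t) {
                cols <- .sampleCols(x, k, t)
                colnames(x)[.resample(cols, 1L)]
            }, character(1))
            mask <- rep(TRUE, ncol(x))
            if (config@scenario == 2L) {
                ## all replicates of the test time points leave training
                drop <- cd$condition_id == k & cd$time_point %in% testTps
                mask[drop] <- FALSE
            } else {
                mask[match(testCols, colnames(x))] <- FALSE
            }
            folds[[length(folds) + 1L]] <-
                list(condition = k, testCols = testCols,
                     testTimePoints = testTps, trainingMask = mask,
                     scenario = config@scenario)
        }
    }
    folds
}

#' Leave-one-experiment-out folds for static two-state data
#'
#' For datasets where each condition consists of paired experiments at two
#' pseudo-time points (e.g. normal = 0, diseased = 1), each (condition,
#' replicate) experiment is selected as test exactly once and its two
#' samples are removed from training.
#'
#' @param x a TimecourseExperiment
#' @return list of folds as in [makeFoldsTimecourse()].
#' @export
makeFoldsStatic <- function(x) {
    ex <- .experiments(x)
    lapply(seq_len(nrow(ex)), function(i) {
        cols <- .experimentCols(x, ex$condition[i], ex$replicate[i])
        mask <- rep(TRUE, ncol(x))
        mask[cols] <- FALSE
        list(condition = ex$condition[i], replicate = ex$replicate[i],
             testCols = colnames(x)[cols],
             testTimePoints = sort(unique(
                 SummarizedExperiment::colData(x)$time_point[cols])),
             trainingMask = mask, scenario = 2L)
    })
}

## experiment table: one row per (condition, replicate) pair
.experiments <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    unique(data.frame(condition = as.character(cd$condition_id),
                      replicate = as.integer(cd$replicate),
                      stringsAsFactors = FALSE))
}

.experimentCols <- function(x, condition, replicate) {
    cd <- SummarizedExperiment::colData(x)
    which(cd$condition_id == condition & cd$replicate == replicate)
}

#' Per-fold training/test hygiene assertion
#'
#' Verifies that no test sample is in the fold's training mask, and, for
#' scenario 2, that no replicate of any test time point of the test
#' condition remains in training.
#'
#' @param x a TimecourseExperiment
#' @param fold one fold from [makeFoldsTimecourse()].
#' @return `TRUE` invisibly; violations are errors.
#' @export
assertFoldHygiene <- function(x, fold) {
    cd <- SummarizedExperiment::colData(x)
    inTrain <- fold$trainingMask[match(fold$testCols, colnames(x))]
    if (any(inTrain)) stop("test sample(s) present in the training mask")
    if (fold$scenario == 2L) {
        sib <- cd$condition_id == fold$condition &
            cd$time_point %in% fold$testTimePoints
        if (any(fold$trainingMask[sib]))
            stop("replicate(s) of a test time point remain in training")
    }
    invisible(TRUE)
}

## fit per-condition gene selections on training data only
.fitSelections <- function(x, mask, config, links = NULL) {
    sel <- config@selector
    if (sel == "all") return(NULL)
    genes <- rownames(x)
    n <- if (is.na(config@nGenes)) length(genes) else config@nGenes
    cd <- SummarizedExperiment::colData(x)
    trainConds <- unique(as.character(cd$condition_id[mask]))
    pick <- function(rk) {
        if (is.na(config@sectionStart)) selectTop(rk, n)
        else selectSection(rk, config@sectionStart, n)
    }
    if (sel == "random") {
        g <- selectTop(randomSelection(genes, n), n)
        out <- rep(list(g), length(trainConds))
        names(out) <- trainConds
        return(out)
    }
    if (sel == "string_gene") {
        if (is.null(links)) stop("selector 'string_gene' needs links")
        g <- stringGeneSelection(genes, links, config@cutoff)
        out <- rep(list(g), length(trainConds))
        names(out) <- trainConds
        return(out)
    }
    out <- lapply(trainConds, function(k) {
        if (sel == "rsnr") return(pick(rsnrRanking(x, k, mask)))
        cls1 <- colnames(x)[cd$condition_id == k & mask]
        cls2 <- colnames(x)[cd$condition_id != k & mask]
        rk <- if (sel == "snr_c") snrcScores(x, cls1, cls2, condition = k)
              else welchTScores(x, cls1, cls2, condition = k)
        pick(rk)
    })
    names(out) <- trainConds
    out
}

## test profiles of a fold: consecutive pairs of the sorted test time
## points, built from the selected replicate columns
.testProfiles <- function(x, fold, kind) {
    m <- exprValues(x)
    tps <- fold$testTimePoints
    cols <- fold$testCols
    out <- list()
    for (i in seq_len(length(tps) - 1L)) {
        a <- m[, cols[i]]; b <- m[, cols[i + 1L]]
        tx <- tps[i]; ty <- tps[i + 1L]
        tag <- paste(cols[i], cols[i + 1L], sep = "/")
        out <- c(out, switch(kind,
            DTP = list(.newProfile(fold$condition, tx, ty, "DTP", b - a, tag)),
            MTP = list(.newProfile(fold$condition, tx, ty, "MTP",
                                   (a + b) / 2, tag)),
            TIMEPOINT = list(
                .newProfile(fold$condition, tx, ty, "TIMEPOINT", a, cols[i],
                            ownTime = tx),
                .newProfile(fold$condition, tx, ty, "TIMEPOINT", b,
                            cols[i + 1L], ownTime = ty))))
    }
    out
}

## classify one fold; returns the Prediction
.classifyFold <- function(x, fold, config, selections, trainProfs) {
    testId <- paste(fold$condition,
                    paste(fold$testTimePoints, collapse = "-"), sep = "@")
    tp <- .testProfiles(x, fold, config@profileKind)
    if (config@profileKind == "TIMEPOINT") {
        ## one vote per consecutive pair, each decided on its two
        ## single-time-point profiles
        nPairs <- length(tp) / 2L
        vcond <- character(nPairs); vsim <- numeric(nPairs)
        for (i in seq_len(nPairs)) {
            p <- classifyTimepointMode(tp[(2L * i - 1L):(2L * i)],
                                       trainProfs, selections, testId)
            vcond[i] <- p@predicted
            vsim[i] <- p@similaritySums[[1L]]
        }
        .aggregateVotes(vcond, vsim, testId)
    } else {
        classifyTestUnit(tp, trainProfs, selections, testId)
    }
}

.aggregateVotes <- function(vcond, vsim, testId) {
    tab <- table(vcond)
    counts <- as.integer(tab); names(counts) <- names(tab)
    sums <- vapply(names(tab), function(k) sum(vsim[vcond == k]), numeric(1))
    tied <- names(tab)[counts == max(counts)]
    tieBroken <- length(tied) > 1L
    predicted <- if (tieBroken) {
        s <- sums[tied]; sort(tied[s == max(s)])[1L]
    } else tied
    methods::new("Prediction", testId = testId, predicted = predicted,
                 votes = counts, similaritySums = sums,
                 tieBroken = tieBroken)
}

#' Run the leave-one-out cross-validation
#'
#' For every repetition, folds are drawn per condition
#' ([makeFoldsTimecourse()]); on each fold the feature selector is fitted on
#' the training data only, training transition profiles are built, and the
#' test unit is classified by majority voting over its consecutive
#' time-point pairs. A fold on which the selector or classifier fails is
#' recorded as an error row (`correct = NA`) and excluded from the accuracy
#' denominator.
#'
#' @param x a TimecourseExperiment
#' @param config a \linkS4class{CVConfig}
#' @param links optional \linkS4class{GeneLinkSet} for selector
#'   "string_gene".
#' @param permuteTrainingLabels when TRUE, the condition labels of the
#'   training data are shuffled (a fresh random bijection per fold) before
#'   classification — the permutation null under which any
#'   nearest-neighbor prediction is correct with probability exactly 1/N.
#'   Used for chance-level calibration.
#' @return A \linkS4class{CVResult}.
#' @export
runCV <- function(x, config, links = NULL, permuteTrainingLabels = FALSE) {
    set.seed(config@seed)
    ctx <- .cvContext(x)
    eligible <- .eligibleConditions(x)
    n <- config@repetitions * config@foldsPerCondition * length(eligible)
    rep_ <- integer(n); foldNo <- integer(n); testCond <- character(n)
    predCond <- rep(NA_character_, n); correct <- rep(NA, n)
    nG <- if (is.na(config@nGenes)) nrow(x) else config@nGenes
    i <- 0L
    for (r in seq_len(config@repetitions)) {
        folds <- .fastFolds(ctx, config, eligible)
        for (fi in seq_along(folds)) {
            fold <- folds[[fi]]
            i <- i + 1L
            rep_[i] <- r; foldNo[i] <- fi; testCond[i] <- fold$condition
            res <- tryCatch({
                selections <- .fastSelections(ctx, fold$trainingMask,
                                              config, links)
                if (config@replicatePolicy == "each") {
                    ## reference path: one profile per replicate combination
                    trainProfs <- trainingProfiles(
                        x, fold$trainingMask, config@profileKind,
                        config@pairPolicy, "each")
                    .classifyFold(x, fold, config, selections, trainProfs)
                } else {
                    TP <- .fastTrainProf(ctx, fold$trainingMask,
                                         config@profileKind,
                                         config@pairPolicy)
                    if (permuteTrainingLabels) {
                        ids <- unique(TP$cond)
                        map <- stats::setNames(sample(ids), ids)
                        TP$cond <- unname(map[TP$cond])
                        if (!is.null(selections))
                            names(selections) <-
                                unname(map[names(selections)])
                    }
                    .fastClassifyFold(ctx, fold, config, selections, TP)
                }
            }, error = function(e) e)
            if (!inherits(res, "error")) {
                predCond[i] <- res@predicted
                correct[i] <- res@predicted == fold$condition
            }
        }
    }
    df <- data.frame(repetition = rep_, fold = foldNo,
                     test_condition = testCond,
                     predicted_condition = predCond, correct = correct,
                     n_genes = nG, method = config@selector,
                     stringsAsFactors = FALSE)
    .summarizeCV(df, config)
}

#' Leave-one-experiment-out cross-validation for static data
#'
#' Each (condition, replicate) experiment — two paired samples at the two
#' pseudo-time points — is held out once; training profiles are one
#' transition profile per remaining experiment (matched replicate at both
#' time points), the selector is fitted on the training samples, and the
#' held-out experiment's profile is classified by the nearest neighbor.
#'
#' @inheritParams runCV
#' @return A \linkS4class{CVResult} (one "repetition").
#' @export
runStaticCV <- function(x, config = cvConfig(repetitions = 1), links = NULL) {
    set.seed(config@seed)
    folds <- makeFoldsStatic(x)
    nG <- if (is.na(config@nGenes)) nrow(x) else config@nGenes
    rows <- list()
    for (fi in seq_along(folds)) {
        fold <- folds[[fi]]
        row <- data.frame(repetition = 1L, fold = fi,
                          test_condition = fold$condition,
                          predicted_condition = NA_character_,
                          correct = NA, n_genes = nG,
                          method = config@selector, stringsAsFactors = FALSE)
        res <- tryCatch({
            selections <- .fitSelections(x, fold$trainingMask, config, links)
            trainProfs <- .experimentProfiles(x, fold$trainingMask,
                                              config@profileKind)
            tp <- .testProfiles(x, fold, config@profileKind)
            if (config@profileKind == "TIMEPOINT")
                classifyTimepointMode(tp, trainProfs, selections)
            else classifyTestUnit(tp, trainProfs, selections)
        }, error = function(e) e)
        if (!inherits(res, "error")) {
            row$predicted_condition <- res@predicted
            row$correct <- res@predicted == fold$condition
        }
        rows[[length(rows) + 1L]] <- row
    }
    .summarizeCV(do.call(rbind, rows), config)
}

## one profile per experiment (matched replicate index at both time points)
.experimentProfiles <- function(x, mask, kind = "MTP") {
    ex <- .experiments(x)
    m <- exprValues(x)
    out <- list()
    for (i in seq_len(nrow(ex))) {
        cols <- .experimentCols(x, ex$condition[i], ex$replicate[i])
        cols <- cols[mask[cols]]
        if (length(cols) < 2L) next
        cd <- SummarizedExperiment::colData(x)
        ord <- order(cd$time_point[cols])
        cols <- cols[ord][c(1L, length(cols))]
        tx <- cd$time_point[cols[1L]]; ty <- cd$time_point[cols[2L]]
        a <- m[, cols[1L]]; b <- m[, cols[2L]]
        tag <- paste0("rep", ex$replicate[i])
        out <- c(out, switch(kind,
            DTP = list(.newProfile(ex$condition[i], tx, ty, "DTP", b - a, tag)),
            MTP = list(.newProfile(ex$condition[i], tx, ty, "MTP",
                                   (a + b) / 2, tag)),
            TIMEPOINT = list(
                .newProfile(ex$condition[i], tx, ty, "TIMEPOINT", a, tag,
                            ownTime = tx),
                .newProfile(ex$condition[i], tx, ty, "TIMEPOINT", b, tag,
                            ownTime = ty))))
    }
    out
}

.summarizeCV <- function(df, config) {
    ok <- !is.na(df$correct)
    repAcc <- vapply(split(df[ok, , drop = FALSE], df$repetition[ok]),
                     function(d) mean(d$correct), numeric(1))
    methods::new("CVResult", predictions = df,
                 repetitionAccuracy = repAcc,
                 meanAccuracy = mean(repAcc),
                 sdRepetition = if (length(repAcc) > 1L) stats::sd(repAcc)
                                else NA_real_,
                 sdFold = if (sum(ok) > 1L) stats::sd(df$correct[ok])
                          else NA_real_,
                 nErrors = sum(!ok), config = config)
}

#' Classification accuracy
#'
#' Fraction of correct predictions among folds that produced one; error
#' folds (`correct = NA`) are excluded from the denominator.
#'
#' @param predictions a \linkS4class{CVResult} or a data.frame with a
#'   logical `correct` column.
#' @return accuracy in [0, 1].
#' @export
accuracy <- function(predictions) {
    if (methods::is(predictions, "CVResult"))
        predictions <- predictions@predictions
    ok <- !is.na(predictions$correct)
    if (!nrow(predictions) || !any(ok)) stop("no predictions to score")
    mean(predictions$correct[ok])
}

#' @describeIn runCV the per-fold prediction table.
#' @param x a CVResult
#' @export
setMethod("cvPredictions", "CVResult", function(x) x@predictions)

#' @describeIn runCV mean accuracy across repetitions.
#' @export
setMethod("meanAccuracy", "CVResult", function(x) x@meanAccuracy)

setMethod("show", "CVResult", function(object) {
    cat(sprintf(
        "CVResult: accuracy %.3f (sd over %d repetitions %.3f, over folds %.3f)\n",
        object@meanAccuracy, length(object@repetitionAccuracy),
        object@sdRepetition, object@sdFold))
    if (object@nErrors)
        cat("  ", object@nErrors, "fold(s) errored and were excluded\n")
    cat("  folds:", nrow(object@predictions), "| selector:",
        object@config@selector, "\n")
})
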