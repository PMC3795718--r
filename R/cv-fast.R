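## Internal fast path for the cross-validation loops. The exported profile
## and scoring functions are the reference implementations; these helpers
## compute the same quantities on a plain-matrix context so that thousands
## of folds stay cheap (S4 accessor dispatch is hoisted out of the loop).
## Tests assert the equivalence of the two routes.

.cvContext <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    list(m = SummarizedExperiment::assay(x, "exprs"),
         cond = as.character(cd$condition_id),
         tp = as.numeric(cd$time_point),
         genes = rownames(x),
         sampleNames = colnames(x),
         conds = unique(as.character(cd$condition_id)),
         facs = conditionFactors(x))
}

## replicate-averaged training profile matrix: one column per (condition,
## time-point pair) [or per (condition, time point) for TIMEPOINT]
.fastTrainProf <- function(ctx, mask, kind, pairPolicy) {
    cols <- list(); conds <- character(0); pairs <- character(0)
    for (k in ctx$conds) {
        sel <- which(ctx$cond == k & mask)
        tps <- sort(unique(ctx$tp[sel]))
        if (length(tps) < 2L) next
        avg <- vapply(tps, function(t)
            rowMeans(ctx$m[, sel[ctx$tp[sel] == t], drop = FALSE]),
            numeric(nrow(ctx$m)))
        if (kind == "TIMEPOINT") {
            for (j in seq_along(tps)) {
                cols[[length(cols) + 1L]] <- avg[, j]
                conds <- c(conds, k)
                pairs <- c(pairs, sprintf("%g", tps[j]))
            }
        } else {
            pr <- if (pairPolicy == "consecutive")
                cbind(seq_len(length(tps) - 1L), 2:length(tps))
            else t(utils::combn(seq_along(tps), 2L))
            for (r in seq_len(nrow(pr))) {
                a <- avg[, pr[r, 1L]]; b <- avg[, pr[r, 2L]]
                cols[[length(cols) + 1L]] <-
                    if (kind == "DTP") b - a else (a + b) / 2
                conds <- c(conds, k)
                pairs <- c(pairs, sprintf("%g-%g", tps[pr[r, 1L]],
                                          tps[pr[r, 2L]]))
            }
        }
    }
    if (!length(cols)) stop("no training profiles could be built")
    list(M = matrix(unlist(cols), nrow = nrow(ctx$m),
                    dimnames = list(ctx$genes, NULL)),
         cond = conds, pair = pairs)
}

## rSNR score vector on the context (same rules as rsnrScores)
.fastRsnr <- function(ctx, mask, target) {
    tf <- ctx$facs[[target]]
    trainConds <- unique(ctx$cond[mask])
    pos <- which(ctx$cond == target & mask)
    if (length(pos) < 2L)
        stop("positive set needs at least 2 values per gene")
    neg <- Filter(function(k) !any(ctx$facs[[k]] %in% tf),
                  setdiff(trainConds, target))
    if (!length(neg))
        stop("empty negative set: every training condition shares an ",
             "experimental factor with '", target, "'")
    if (length(neg) < 2L)
        stop("negative set needs at least 2 conditions")
    pm <- ctx$m[, pos, drop = FALSE]
    muP <- rowMeans(pm); sdP <- .rowSds(pm)
    condMeans <- vapply(neg, function(k)
        rowMeans(ctx$m[, ctx$cond == k & mask, drop = FALSE]),
        numeric(nrow(ctx$m)))
    muN <- rowMeans(condMeans); sdN <- .rowSds(condMeans)
    .rsnrQuotient(muP, sdP, muN, sdN)
}

## per-condition gene selections on the context
.fastSelections <- function(ctx, mask, config, links = NULL) {
    sel <- config@selector
    if (sel == "all") return(NULL)
    genes <- ctx$genes
    n <- if (is.na(config@nGenes)) length(genes) else config@nGenes
    start <- if (is.na(config@sectionStart)) 1L else config@sectionStart
    trainConds <- unique(ctx$cond[mask])
    takeSection <- function(score) {
        if (start + n - 1L > length(genes))
            stop("section out of bounds")
        genes[order(-score, genes)][seq(start, length.out = n)]
    }
    if (sel == "random") {
        g <- sample(genes, n)
        return(stats::setNames(rep(list(g), length(trainConds)), trainConds))
    }
    if (sel == "string_gene") {
        if (is.null(links)) stop("selector 'string_gene' needs links")
        g <- stringGeneSelection(genes, links, config@cutoff)
        return(stats::setNames(rep(list(g), length(trainConds)), trainConds))
    }
    out <- lapply(trainConds, function(k) {
        if (sel == "rsnr") return(takeSection(.fastRsnr(ctx, mask, k)))
        c1 <- ctx$m[, ctx$cond == k & mask, drop = FALSE]
        c2 <- ctx$m[, ctx$cond != k & mask, drop = FALSE]
        if (ncol(c1) < 2L || ncol(c2) < 2L)
            stop("both classes need at least 2 samples")
        num <- abs(rowMeans(c1) - rowMeans(c2))
        den <- if (sel == "snr_c") .rowSds(c1) + .rowSds(c2)
               else sqrt(.rowSds(c1)^2 / ncol(c1) +
                         .rowSds(c2)^2 / ncol(c2))
        takeSection(ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den))
    })
    stats::setNames(out, trainConds)
}

## vote of one test vector against the profile matrix; NA where a condition
## was skipped for lack of usable genes
.fastVote <- function(tv, TP, selIdx) {
    r <- rep(NA_real_, ncol(TP$M))
    for (k in unique(TP$cond)) {
        idx <- which(TP$cond == k)
        rows <- if (is.null(selIdx)) seq_along(tv) else selIdx[[k]]
        if (is.null(rows) || length(rows) < 3L) next
        r[idx] <- .pearsonVec(tv[rows], TP$M[rows, idx, drop = FALSE])
    }
    if (all(is.na(r)))
        stop("no training profile has 3 or more usable genes")
    use <- which(!is.na(r))
    best <- use[order(-r[use], TP$cond[use], TP$pair[use], use)][1L]
    list(condition = TP$cond[best], similarity = r[best])
}

## classify one fold on the context; mirrors .classifyFold
.fastClassifyFold <- function(ctx, fold, config, selections, TP) {
    selIdx <- if (is.null(selections)) NULL else
        lapply(selections, function(g) {
            i <- match(g, ctx$genes)
            i[!is.na(i)]
        })
    testId <- paste(fold$condition,
                    paste(fold$testTimePoints, collapse = "-"), sep = "@")
    tcols <- match(fold$testCols, ctx$sampleNames)
    tps <- fold$testTimePoints
    nPairs <- length(tps) - 1L
    vcond <- character(0); vsim <- numeric(0)
    for (i in seq_len(nPairs)) {
        a <- ctx$m[, tcols[i]]; b <- ctx$m[, tcols[i + 1L]]
        if (config@profileKind == "TIMEPOINT") {
            v1 <- .fastVoteNA(a, TP, selIdx)
            v2 <- .fastVoteNA(b, TP, selIdx)
            ## global maximum over the two single-time-point profiles
            r <- pmax(v1$r, v2$r, na.rm = TRUE)
            r[is.na(v1$r) & is.na(v2$r)] <- NA_real_
            use <- which(!is.na(r))
            if (!length(use))
                stop("no training profile has 3 or more usable genes")
            best <- use[order(-r[use], TP$cond[use], TP$pair[use], use)][1L]
            vcond <- c(vcond, TP$cond[best]); vsim <- c(vsim, r[best])
        } else {
            tv <- if (config@profileKind == "DTP") b - a else (a + b) / 2
            v <- .fastVote(tv, TP, selIdx)
            vcond <- c(vcond, v$condition); vsim <- c(vsim, v$similarity)
        }
    }
    .aggregateVotes(vcond, vsim, testId)
}

## similarity vector variant used by the TIMEPOINT branch
.fastVoteNA <- function(tv, TP, selIdx) {
    r <- rep(NA_real_, ncol(TP$M))
    for (k in unique(TP$cond)) {
        idx <- which(TP$cond == k)
        rows <- if (is.null(selIdx)) seq_along(tv) else selIdx[[k]]
        if (is.null(rows) || length(rows) < 3L) next
        r[idx] <- .pearsonVec(tv[rows], TP$M[rows, idx, drop = FALSE])
    }
    list(r = r)
}

## fold draws on the context (same scheme as makeFoldsTimecourse)
.fastFolds <- function(ctx, config, eligible) {
    folds <- list()
    for (k in eligible) {
        kCols <- which(ctx$cond == k)
        tps <- sort(unique(ctx$tp[kCols]))
        for (f in seq_len(config@foldsPerCondition)) {
            nT <- if (config@scenario == 2L) 2L else
                .resample(2:length(tps), 1L)
            testTps <- sort(.resample(tps, nT))
            testCols <- vapply(testTps, function(t)
                ctx$sampleNames[.resample(kCols[ctx$tp[kCols] == t], 1L)],
                character(1))
            mask <- rep(TRUE, length(ctx$cond))
            if (config@scenario == 2L) {
                mask[ctx$cond == k & ctx$tp %in% testTps] <- FALSE
            } else {
                mask[match(testCols, ctx$sampleNames)] <- FALSE
            }
            folds[[length(folds) + 1L]] <-
                list(condition = k, testCols = testCols,
                     testTimePoints = testTps, trainingMask = mask,
                     scenario = config@scenario)
        }
    }
    folds
}
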