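## sample (n-1) row standard deviations
.rowSds <- function(m) {
    n <- ncol(m)
    if (n < 2L) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (n - 1))
}

.makeRanking <- function(genes, scores, condition, method) {
    ord <- order(-scores, genes)  # descending score, gene-id tie-break
    methods::new("GeneRanking", conditionId = condition, method = method,
                 table = data.frame(gene_id = genes[ord],
                                    score = scores[ord],
                                    stringsAsFactors = FALSE))
}

#' @describeIn selectTop the ordered (gene, score) table of a ranking.
#' @export
setMethod("rankingTable", "GeneRanking", function(x) x@table)

setMethod("show", "GeneRanking", function(object) {
    cat("GeneRanking (", object@method, ") for condition ",
        object@conditionId, ": ", nrow(object@table), " genes\n", sep = "")
    print(utils::head(object@table, 5L))
})

#' Positive/negative split for one target condition
#'
#' Divides the training data for the rSNR of `target`: the positive set is
#' the target condition's training samples; the negative set is every other
#' training condition whose experimental factor set is disjoint from the
#' target's; conditions sharing at least one factor are excluded from the
#' computation. For example, with target factors \{cold, root\} the negative
#' set contains only conditions involving neither cold nor root.
#'
#' @param x a TimecourseExperiment
#' @param target target condition identifier.
#' @param mask logical column mask (TRUE = training); `NULL` = all samples.
#' @return A \linkS4class{PositiveNegativeSplit}. An empty negative set is
#'   an error: the rSNR is undefined for such a design.
#' @export
buildSplit <- function(x, target, mask = NULL) {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(mask)) mask <- rep(TRUE, ncol(x))
    pos <- colnames(x)[cd$condition_id == target & mask]
    if (!length(pos))
        stop("target condition '", target, "' has no training samples")
    facs <- conditionFactors(x)
    if (!target %in% names(facs)) stop("unknown condition: ", target)
    tf <- facs[[target]]
    trainConds <- unique(as.character(cd$condition_id[mask]))
    others <- setdiff(trainConds, target)
    disjoint <- vapply(others, function(k)
        !any(facs[[k]] %in% tf), logical(1))
    neg <- others[disjoint]
    if (!length(neg))
        stop("empty negative set: every training condition shares an ",
             "experimental factor with '", target, "'; the rSNR is ",
             "undefined for this design")
    methods::new("PositiveNegativeSplit", targetCondition = target,
                 positiveSamples = pos, negativeConditions = neg,
                 excludedConditions = setdiff(others, neg))
}

#' Relative signal-to-noise ratio (rSNR) per gene
#'
#' For each gene g and target condition k the rSNR is the ratio of the
#' signal-to-noise ratio in the positive set (the target condition's
#' training data) to the signal-to-noise ratio in the negative set (training
#' conditions sharing no experimental factor with the target):
#' \deqn{rSNR(g,k) = \frac{|\mu_{pos}|/\sigma_{pos}}{|\mu_{neg}|/\sigma_{neg}}
#'       = \frac{CV_{neg}}{CV_{pos}}}
#' where \eqn{\mu_{pos}, \sigma_{pos}} are the mean and sample standard
#' deviation of g's values pooled over the positive set (all time points and
#' replicates), and \eqn{\mu_{neg}, \sigma_{neg}} are the mean and sample
#' standard deviation of g's per-condition mean values across the negative
#' conditions. Equivalently the rSNR is the negative set's coefficient of
#' variation over the positive set's: genes stable within the condition of
#' interest but variable across unrelated conditions score high.
#'
#' Magnitudes of the means are used, so the score is non-negative on
#' log-ratio data with negative values. Degenerate cases are deterministic:
#' \eqn{\sigma_{pos} = 0} gives `Inf` (ranked above every finite score),
#' \eqn{\sigma_{neg} = 0} gives 0 (the gene does not vary across
#' conditions), a gene with both means zero gives 0 with a warning.
#'
#' @param x a TimecourseExperiment
#' @param split a \linkS4class{PositiveNegativeSplit} from [buildSplit()].
#' @param mask the same training mask the split was built with.
#' @param positiveSigma "pooled" (default; one standard deviation over all
#'   positive-set values) or "per_timepoint" (per-time-point means and
#'   standard deviations, then averaged).
#' @param negativeAxis "per_condition" (default; one mean per negative
#'   condition, spread taken across conditions) or "per_timepoint" (one mean
#'   per negative condition and time point, spread across all of them).
#' @return A \link[S4Vectors]{DataFrame} with one row per gene and columns
#'   mu_pos, sigma_pos, mu_neg, sigma_neg, snr_pos, snr_neg, rsnr.
#' @export
rsnrScores <- function(x, split, mask = NULL,
                       positiveSigma = c("pooled", "per_timepoint"),
                       negativeAxis = c("per_condition", "per_timepoint")) {
    positiveSigma <- match.arg(positiveSigma)
    negativeAxis <- match.arg(negativeAxis)
    cd <- SummarizedExperiment::colData(x)
    if (is.null(mask)) mask <- rep(TRUE, ncol(x))
    m <- exprValues(x)
    pm <- m[, split@positiveSamples, drop = FALSE]
    if (ncol(pm) < 2L)
        stop("positive set needs at least 2 values per gene")
    if (positiveSigma == "pooled") {
        muP <- rowMeans(pm)
        sdP <- .rowSds(pm)
    } else {
        tpOf <- cd[split@positiveSamples, "time_point"]
        mus <- sds <- NULL
        for (t in sort(unique(tpOf))) {
            sub <- pm[, tpOf == t, drop = FALSE]
            mus <- cbind(mus, rowMeans(sub))
            sds <- cbind(sds, if (ncol(sub) >= 2L) .rowSds(sub) else
                         rep(NA_real_, nrow(sub)))
        }
        muP <- rowMeans(mus)
        sdP <- rowMeans(sds, na.rm = TRUE)  # time points with 1 replicate
                                            # carry no spread information
    }
    negConds <- split@negativeConditions
    if (length(negConds) < 2L && negativeAxis == "per_condition")
        stop("negative set needs at least 2 conditions")
    condMeans <- NULL
    for (k in negConds) {
        cols <- which(cd$condition_id == k & mask)
        if (negativeAxis == "per_condition") {
            condMeans <- cbind(condMeans, rowMeans(m[, cols, drop = FALSE]))
        } else {
            tpk <- cd$time_point[cols]
            for (t in sort(unique(tpk)))
                condMeans <- cbind(condMeans,
                    rowMeans(m[, cols[tpk == t], drop = FALSE]))
        }
    }
    muN <- rowMeans(condMeans)
    sdN <- .rowSds(condMeans)
    snrP <- ifelse(sdP == 0, Inf, abs(muP) / sdP)
    snrN <- ifelse(sdN == 0, Inf, abs(muN) / sdN)
    rsnr <- .rsnrQuotient(muP, sdP, muN, sdN)
    S4Vectors::DataFrame(mu_pos = unname(muP), sigma_pos = unname(sdP),
                         mu_neg = unname(muN), sigma_neg = unname(sdN),
                         snr_pos = unname(snrP), snr_neg = unname(snrN),
                         rsnr = unname(rsnr), row.names = rownames(m))
}

## deterministic degenerate handling of the CV quotient; shared with the
## documentation above
.rsnrQuotient <- function(muP, sdP, muN, sdN) {
    out <- numeric(length(muP))
    bothFlat <- sdP == 0 & sdN == 0
    posFlat <- sdP == 0 & !bothFlat
    negFlat <- sdN == 0 & !bothFlat
    rest <- !(bothFlat | posFlat | negFlat)
    out[bothFlat] <- 0
    out[posFlat] <- Inf
    out[negFlat] <- 0
    zz <- rest & muP == 0 & muN == 0
    if (any(zz)) {
        warning(sum(zz), " gene(s) with zero mean in both sets scored 0")
        out[zz] <- 0
        rest <- rest & !zz
    }
    cvP <- sdP[rest] / abs(muP[rest])   # Inf when mu_pos == 0
    cvN <- sdN[rest] / abs(muN[rest])   # Inf when mu_neg == 0
    q <- cvN / cvP
    q[is.infinite(cvP)] <- 0            # unbounded intrinsic noise
    out[rest] <- q
    out
}

#' rSNR gene ranking for one target condition
#'
#' Convenience wrapper: [buildSplit()] then [rsnrScores()] then a descending
#' ranking with lexicographic gene-id tie-break.
#'
#' @inheritParams rsnrScores
#' @param target target condition identifier.
#' @return A \linkS4class{GeneRanking} with method "rsnr".
#' @export
rsnrRanking <- function(x, target, mask = NULL, ...) {
    split <- buildSplit(x, target, mask)
    comp <- rsnrScores(x, split, mask, ...)
    .makeRanking(rownames(comp), comp$rsnr, target, "rsnr")
}

## pooled two-class mean/sd pairs for the baseline selectors
.twoClassStats <- function(x, class1, class2) {
    m <- exprValues(x)
    m1 <- m[, class1, drop = FALSE]
    m2 <- m[, class2, drop = FALSE]
    if (ncol(m1) < 2L || ncol(m2) < 2L)
        stop("both classes need at least 2 samples")
    list(mu1 = rowMeans(m1), mu2 = rowMeans(m2),
         sd1 = .rowSds(m1), sd2 = .rowSds(m2),
         n1 = ncol(m1), n2 = ncol(m2))
}

#' Two-class signal-to-noise ratio (SNR) gene ranking
#'
#' The classical two-class feature score
#' \eqn{|\mu_1 - \mu_2| / (\sigma_1 + \sigma_2)} with sample standard
#' deviations; genes are ranked by descending absolute score (both
#' directions of change are informative for selection). A zero denominator
#' scores `Inf` when the means differ and 0 when they agree.
#'
#' @param x a TimecourseExperiment
#' @param class1,class2 sample (column) names or indices of the two classes.
#' @param condition label for the resulting ranking (e.g. the target
#'   condition of a one-vs-rest split); default "global".
#' @return A \linkS4class{GeneRanking} with method "snr_c".
#' @export
snrcScores <- function(x, class1, class2, condition = "global") {
    s <- .twoClassStats(x, class1, class2)
    num <- abs(s$mu1 - s$mu2)
    den <- s$sd1 + s$sd2
    score <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
    .makeRanking(rownames(x), score, condition, "snr_c")
}

#' Welch's t statistic gene ranking
#'
#' The unequal-variance two-sample statistic
#' \eqn{|\mu_1 - \mu_2| / \sqrt{\sigma_1^2/n_1 + \sigma_2^2/n_2}},
#' differing from the two-class SNR only in its estimate of the variance.
#' Used as a ranking score, not as a test (no p-values).
#'
#' @inheritParams snrcScores
#' @return A \linkS4class{GeneRanking} with method "welch_t".
#' @export
welchTScores <- function(x, class1, class2, condition = "global") {
    s <- .twoClassStats(x, class1, class2)
    num <- abs(s$mu1 - s$mu2)
    den <- sqrt(s$sd1^2 / s$n1 + s$sd2^2 / s$n2)
    score <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
    .makeRanking(rownames(x), score, condition, "welch_t")
}

#' Random gene selection (control)
#'
#' Uniform sample of `n` genes without replacement, as the control against
#' which informed selectors are compared. Reproducible given `seed`;
#' without a seed the current RNG stream is consumed.
#'
#' @param genes character vector of gene identifiers.
#' @param n number of genes to draw, 0 < n <= length(genes).
#' @param seed optional integer seed.
#' @param condition label for the resulting ranking.
#' @return A \linkS4class{GeneRanking} with method "random"; scores encode
#'   the draw order.
#' @export
randomSelection <- function(genes, n, seed = NULL, condition = "global") {
    if (n < 1L || n > length(genes))
        stop("n must lie in [1, ", length(genes), "]")
    if (!is.null(seed)) set.seed(seed)
    sel <- sample(genes, n)
    methods::new("GeneRanking", conditionId = condition, method = "random",
                 table = data.frame(gene_id = sel,
                                    score = as.numeric(rev(seq_len(n))),
                                    stringsAsFactors = FALSE))
}

#' Interaction-based gene and link selection
#'
#' `stringGeneSelection` keeps the genes on the array having at least one
#' link with confidence score strictly greater than `cutoff` to another gene
#' on the array; `stringLinkSelection` keeps exactly those links. At every
#' cutoff the two selections cover the same genes.
#'
#' @param genes gene identifiers present on the array.
#' @param links a \linkS4class{GeneLinkSet}.
#' @param cutoff confidence cutoff in [0, 1000]; links must score strictly
#'   above it (typical grid: 0, 250, 500, 750, 900).
#' @return `stringGeneSelection`: a character vector of genes;
#'   `stringLinkSelection`: a \linkS4class{GeneLinkSet}. An empty selection
#'   is an error reporting the cutoff.
#' @export
stringGeneSelection <- function(genes, links, cutoff) {
    kept <- stringLinkSelection(genes, links, cutoff)
    sort(unique(c(kept@links$gene_a, kept@links$gene_b)))
}

#' @rdname stringGeneSelection
#' @export
stringLinkSelection <- function(genes, links, cutoff) {
    if (cutoff < 0 || cutoff > 1000) stop("cutoff must lie in [0, 1000]")
    lt <- linkTable(links)
    keep <- lt$score > cutoff & lt$gene_a %in% genes & lt$gene_b %in% genes
    if (!any(keep))
        stop("no link on the array passes cutoff ", cutoff)
    GeneLinkSet(lt[keep, , drop = FALSE])
}

#' Take genes from a ranking
#'
#' `selectTop` returns the `n` best-ranked genes; `selectSection` the `n`
#' genes starting at `startRank` (1 = best). Both are deterministic: exact
#' score ties inside a ranking are already broken lexicographically.
#'
#' @param ranking a \linkS4class{GeneRanking}.
#' @param n number of genes.
#' @param startRank first rank of the section.
#' @return character vector of gene identifiers in rank order.
#' @export
selectTop <- function(ranking, n) selectSection(ranking, 1L, n)

#' @rdname selectTop
#' @export
selectSection <- function(ranking, startRank, n) {
    tb <- rankingTable(ranking)
    if (startRank < 1L || startRank + n - 1L > nrow(tb))
        stop("section [", startRank, ", ", startRank + n - 1L,
             "] out of bounds for a ranking of ", nrow(tb), " genes")
    tb$gene_id[seq(startRank, length.out = n)]
}
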