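#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TimecourseExperiment: multi-condition expression data
#'
#' A \linkS4class{SummarizedExperiment} whose columns are samples of a
#' multi-condition experiment. `colData` carries, for every sample, the
#' experimental condition it belongs to, the set of experimental factors
#' defining that condition, a numeric time point and a 1-based replicate
#' index. Rows are genes; the single assay `"exprs"` holds (typically
#' log-scale) expression values with no missing cells.
#'
#' An \emph{experimental condition} is a unique combination of experimental
#' factors (e.g. a stress treatment crossed with a tissue type); all samples
#' of a condition must declare the same factor set. Conditions may have
#' different time grids and ragged replicate counts.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso [TimecourseExperiment()], [readDataset()], [simulateTimecourse()]
#' @export
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

.validTimecourseExperiment <- function(object) {
    msg <- NULL
    cd <- SummarizedExperiment::colData(object)
    need <- c("condition_id", "time_point", "replicate", "factors")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
    if (nrow(object) < 1L || ncol(object) < 1L)
        msg <- c(msg, "at least one gene and one sample are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    a <- SummarizedExperiment::assay(object)
    if (!is.numeric(a))
        msg <- c(msg, "expression assay must be numeric")
    if (anyNA(a))
        msg <- c(msg, "expression assay contains missing values")
    if (!is.numeric(cd$time_point))
        msg <- c(msg, "time_point must be numeric")
    if (anyNA(cd$replicate) || any(cd$replicate < 1L))
        msg <- c(msg, "replicate indices must be positive integers")
    ## one factor set per condition
    byc <- split(as.character(cd$factors), as.character(cd$condition_id))
    bad <- names(byc)[vapply(byc, function(f) length(unique(f)) != 1L, TRUE)]
    if (length(bad))
        msg <- c(msg, paste("inconsistent factor sets within condition(s):",
                            paste(bad, collapse = ", ")))
    if (any(!nzchar(as.character(cd$factors))))
        msg <- c(msg, "every condition needs a non-empty factor set")
    dup <- duplicated(cd[, c("condition_id", "time_point", "replicate")])
    if (any(dup))
        msg <- c(msg, "duplicate (condition, time point, replicate) sample keys")
    if (is.null(msg)) TRUE else msg
}
setValidity("TimecourseExperiment", .validTimecourseExperiment)

#' Transition profile of one condition
#'
#' A gene-indexed vector summarizing two time points of one experimental
#' condition. Kinds: `"DTP"` (difference of the two expression profiles),
#' `"MTP"` (their mean), `"TIMEPOINT"` (a single time point's profile, kept
#' together with the pair it was drawn from).
#'
#' @slot conditionId character(1), condition the profile was built from.
#' @slot timePair numeric(2), the two time points (ascending).
#' @slot kind one of "DTP", "MTP", "TIMEPOINT".
#' @slot ownTime for kind "TIMEPOINT", which of the two time points this
#'   profile represents; `NA` otherwise.
#' @slot values named numeric vector, one value per gene (or link).
#' @slot replicateTag which replicate(s) entered the profile, or "averaged".
#' @export
setClass("TransitionProfile",
    representation(conditionId = "character", timePair = "numeric",
                   kind = "character", ownTime = "numeric",
                   values = "numeric", replicateTag = "character"))

setValidity("TransitionProfile", function(object) {
    msg <- NULL
    if (length(object@timePair) != 2L)
        msg <- c(msg, "timePair must have length 2")
    if (!object@kind %in% c("DTP", "MTP", "TIMEPOINT"))
        msg <- c(msg, "kind must be DTP, MTP or TIMEPOINT")
    if (is.null(names(object@values)))
        msg <- c(msg, "values must be named by gene (or link)")
    if (object@kind == "TIMEPOINT" && is.na(object@ownTime))
        msg <- c(msg, "TIMEPOINT profiles must record which time point they carry")
    if (is.null(msg)) TRUE else msg
})

#' Link-level transition profile
#'
#' A \linkS4class{TransitionProfile} whose entries are protein-interaction
#' links rather than genes; each link value is the mean of the two incident
#' genes' values in the underlying gene profile. `values` is named
#' `"geneA|geneB"` and `linkTable` records the pairs.
#'
#' @slot linkTable data.frame with columns gene_a, gene_b.
#' @export
setClass("LinkProfile", contains = "TransitionProfile",
    representation(linkTable = "data.frame"))

#' Scored gene-gene interaction set
#'
#' Undirected links between genes with an integer confidence score in
#' [0, 1000], the dialect of STRING combined scores. Pairs are stored in
#' canonical order (gene_a < gene_b); self links and duplicates are rejected.
#'
#' @slot links data.frame with columns gene_a, gene_b, score.
#' @export
setClass("GeneLinkSet", representation(links = "data.frame"))

setValidity("GeneLinkSet", function(object) {
    l <- object@links
    msg <- NULL
    if (!all(c("gene_a", "gene_b", "score") %in% colnames(l)))
        return("links needs columns gene_a, gene_b, score")
    if (any(l$gene_a == l$gene_b)) msg <- c(msg, "self links are not allowed")
    if (any(l$gene_a > l$gene_b)) msg <- c(msg, "pairs must be in canonical order")
    if (anyDuplicated(paste(l$gene_a, l$gene_b))) msg <- c(msg, "duplicate links")
    if (nrow(l) && (any(l$score < 0) || any(l$score > 1000)))
        msg <- c(msg, "scores must lie in [0, 1000]")
    if (is.null(msg)) TRUE else msg
})

#' Per-condition gene ranking under a named selector
#'
#' Genes ordered by descending score; exact score ties are broken by
#' lexicographic gene identifier so rankings are reproducible.
#'
#' @slot conditionId condition the ranking is specific to, or "global".
#' @slot method selector name (rsnr, snr_c, welch_t, random, ...).
#' @slot table data.frame with columns gene_id, score, ordered.
#' @export
setClass("GeneRanking",
    representation(conditionId = "character", method = "character",
                   table = "data.frame"))

setValidity("GeneRanking", function(object) {
    tb <- object@table
    msg <- NULL
    if (!all(c("gene_id", "score") %in% colnames(tb)))
        return("table needs columns gene_id, score")
    if (anyDuplicated(tb$gene_id)) msg <- c(msg, "duplicate genes in ranking")
    if (nrow(tb) > 1L) {
        s <- tb$score
        if (any(diff(s) > 0, na.rm = TRUE))
            msg <- c(msg, "scores must be non-increasing")
    }
    if (is.null(msg)) TRUE else msg
})

#' Positive/negative split for the rSNR of one target condition
#'
#' The positive set is the training data of the target condition; the
#' negative set is every training condition whose factor set is disjoint
#' from the target's; conditions sharing at least one factor are excluded
#' from the rSNR computation altogether.
#'
#' @slot targetCondition character(1).
#' @slot positiveSamples sample (column) names of the target condition
#'   present in the training mask.
#' @slot negativeConditions condition ids with factor sets disjoint from the
#'   target's.
#' @slot excludedConditions conditions sharing a factor with the target.
#' @export
setClass("PositiveNegativeSplit",
    representation(targetCondition = "character",
                   positiveSamples = "character",
                   negativeConditions = "character",
                   excludedConditions = "character"))

#' Cross-validation configuration
#'
#' @slot scenario 1 (test replicates retained in training) or 2 (all
#'   replicates of the test time points removed from training; test size
#'   fixed at 2 time points).
#' @slot profileKind "DTP", "MTP" or "TIMEPOINT".
#' @slot selector one of "all", "rsnr", "snr_c", "welch_t", "random",
#'   "string_gene".
#' @slot nGenes genes kept per condition by ranking selectors (NA = all).
#' @slot sectionStart if not NA, ranking selectors keep the `nGenes` genes
#'   starting at this rank instead of the top.
#' @slot cutoff STRING confidence cutoff for selector "string_gene".
#' @slot foldsPerCondition folds drawn per condition per repetition.
#' @slot repetitions number of repetitions of the whole sub-sampling scheme.
#' @slot seed RNG seed for fold draws and random selections.
#' @slot replicatePolicy "average" (training profiles average replicates) or
#'   "each".
#' @slot pairPolicy "all" (training transition profiles from all ordered
#'   time-point pairs) or "consecutive".
#' @export
setClass("CVConfig",
    representation(scenario = "integer", profileKind = "character",
                   selector = "character", nGenes = "integer",
                   sectionStart = "integer", cutoff = "integer",
                   foldsPerCondition = "integer", repetitions = "integer",
                   seed = "integer", replicatePolicy = "character",
                   pairPolicy = "character"),
    prototype(scenario = 2L, profileKind = "MTP", selector = "all",
              nGenes = NA_integer_, sectionStart = NA_integer_,
              cutoff = NA_integer_, foldsPerCondition = 10L,
              repetitions = 30L, seed = 1L, replicatePolicy = "average",
              pairPolicy = "all"))

setValidity("CVConfig", function(object) {
    msg <- NULL
    if (!object@scenario %in% c(1L, 2L)) msg <- c(msg, "scenario must be 1 or 2")
    if (!object@profileKind %in% c("DTP", "MTP", "TIMEPOINT"))
        msg <- c(msg, "profileKind must be DTP, MTP or TIMEPOINT")
    if (!object@selector %in% c("all", "rsnr", "snr_c", "welch_t", "random",
                                "string_gene"))
        msg <- c(msg, "unknown selector")
    if (!object@replicatePolicy %in% c("average", "each"))
        msg <- c(msg, "replicatePolicy must be 'average' or 'each'")
    if (!object@pairPolicy %in% c("all", "consecutive"))
        msg <- c(msg, "pairPolicy must be 'all' or 'consecutive'")
    if (object@foldsPerCondition < 1L || object@repetitions < 1L)
        msg <- c(msg, "foldsPerCondition and repetitions must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Cross-validation result
#'
#' @slot predictions data.frame, one row per fold: repetition, fold,
#'   test_condition, predicted_condition, correct, n_genes, method.
#' @slot repetitionAccuracy accuracy per repetition.
#' @slot meanAccuracy mean of repetition accuracies.
#' @slot sdRepetition standard deviation of accuracy across repetitions.
#' @slot sdFold standard deviation of the per-fold 0/1 correctness.
#' @slot nErrors folds on which the selector or classifier failed.
#' @slot config the CVConfig used.
#' @export
setClass("CVResult",
    representation(predictions = "data.frame", repetitionAccuracy = "numeric",
                   meanAccuracy = "numeric", sdRepetition = "numeric",
                   sdFold = "numeric", nErrors = "integer",
                   config = "CVConfig"))

#' Query-versus-database ROC result
#'
#' @slot queries list, one data.frame(score, label) per query experiment.
#' @slot aucPerQuery AUC per query (rank-sum, ties half-credit).
#' @slot meanAuc arithmetic mean over queries with defined AUC.
#' @slot nExcluded queries with no positive or no negative database entry.
#' @export
setClass("ROCResult",
    representation(queries = "list", aucPerQuery = "numeric",
                   meanAuc = "numeric", nExcluded = "integer"))

#' Classification outcome for one test unit
#'
#' @slot testId identifier of the test unit.
#' @slot predicted predicted condition.
#' @slot votes named integer vector, votes per condition.
#' @slot similaritySums named numeric vector, per condition the sum of the
#'   Pearson similarities of the votes it won.
#' @slot tieBroken whether the vote-count tie-break (highest similarity sum)
#'   was needed.
#' @export
setClass("Prediction",
    representation(testId = "character", predicted = "character",
                   votes = "integer", similaritySums = "numeric",
                   tieBroken = "logical"))
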