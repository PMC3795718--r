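#' Simulate a multi-condition time-course dataset with planted
#' condition-specific genes
#'
#' Values are drawn on a log2-like additive scale. Background genes are
#' i.i.d. Normal(`muBackground`, `sdBackground`) in every sample. A gene
#' planted for condition k is, within k, Normal around a per-gene elevated
#' level (`muBackground + plantedShift` plus a per-gene jitter of sd
#' `plantedShiftSd`) with small within-condition sd `sdSignal` — stable and
#' highly expressed in its own condition; in every other condition it gets
#' a per-condition mean drawn with spread `conditionSpread` around the
#' background level and within-condition sd `sdBackground` — variable
#' across unrelated conditions. This is exactly the expression pattern the
#' rSNR is designed to reward, so planted genes are the ground truth for
#' recovery experiments.
#'
#' @param nConditions number of conditions (ignored when `factorGrid` is
#'   given); each condition gets its own single experimental factor, so
#'   every condition has a valid (factor-disjoint) negative set.
#' @param factorGrid optional named list of factor axes (e.g.
#'   `list(treatment = paste0("trt", 1:9), tissue = c("root", "shoot"))`);
#'   conditions are all combinations.
#' @param timePoints number of time points (a scalar; times 0, 1, ...), a
#'   numeric vector shared by all conditions, or a named list per condition
#'   (ragged designs).
#' @param replicates replicates per time point: a scalar, or a named list
#'   per condition of per-time-point counts (ragged designs).
#' @param nGenes total genes.
#' @param nPlantedPerCondition planted genes per condition (disjoint sets).
#' @param muBackground,sdBackground background level and noise sd.
#' @param sdSignal within-own-condition sd of planted genes.
#' @param plantedShift,plantedShiftSd own-condition mean lift of planted
#'   genes and its per-gene jitter sd.
#' @param conditionSpread sd of the per-condition mean shifts of planted
#'   genes outside their own condition (the "extrinsic noise" the rSNR's
#'   negative set measures).
#' @param seed optional RNG seed.
#' @return list with elements `dataset` (a
#'   \linkS4class{TimecourseExperiment}) and `truth` (list: `planted`,
#'   per-condition planted gene ids; `ownLevels`, the per-gene elevated
#'   levels; `shifts`, the per-(gene, condition) means of planted genes).
#' @export
simulateTimecourse <- function(nConditions = 6, factorGrid = NULL,
                               timePoints = 8, replicates = 2,
                               nGenes = 1000, nPlantedPerCondition = 20,
                               muBackground = 8, sdBackground = 2,
                               sdSignal = 0.15, plantedShift = 1.5,
                               plantedShiftSd = 1, conditionSpread = 0.75,
                               seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(factorGrid)) {
        conds <- sprintf("c%02d", seq_len(nConditions))
        facs <- stats::setNames(as.list(sprintf("f%02d",
                                                seq_len(nConditions))),
                                conds)
    } else {
        grid <- expand.grid(factorGrid, stringsAsFactors = FALSE)
        conds <- apply(grid, 1L, paste, collapse = "_")
        facs <- stats::setNames(
            lapply(seq_len(nrow(grid)), function(i)
                unname(unlist(grid[i, ]))), conds)
    }
    N <- length(conds)
    ## every condition needs at least one factor-disjoint partner
    ok <- vapply(conds, function(k) any(vapply(setdiff(conds, k),
        function(j) !any(facs[[j]] %in% facs[[k]]), logical(1))), logical(1))
    if (!all(ok))
        stop("factor design leaves condition(s) without a disjoint ",
             "negative set: ", paste(conds[!ok], collapse = ", "))
    if (nPlantedPerCondition * N > nGenes)
        stop("more planted genes than genes")
    tpOf <- function(k) {
        if (is.list(timePoints)) timePoints[[k]]
        else if (length(timePoints) == 1L) seq(0, timePoints - 1)
        else timePoints
    }
    repOf <- function(k, tps) {
        if (is.list(replicates)) replicates[[k]]
        else rep(replicates, length(tps))
    }
    meta <- do.call(rbind, lapply(seq_along(conds), function(i) {
        k <- conds[i]
        tps <- tpOf(k); reps <- repOf(k, tps)
        do.call(rbind, lapply(seq_along(tps), function(j) {
            if (reps[j] < 1L) return(NULL)
            data.frame(sample_id = sprintf("%s_t%g_r%d", k, tps[j],
                                           seq_len(reps[j])),
                       condition_id = k,
                       factors = paste(facs[[k]], collapse = ";"),
                       time_point = tps[j],
                       replicate = seq_len(reps[j]),
                       stringsAsFactors = FALSE)
        }))
    }))
    genes <- sprintf("g%04d", seq_len(nGenes))
    S <- nrow(meta)
    m <- matrix(stats::rnorm(nGenes * S, muBackground, sdBackground),
                nGenes, S, dimnames = list(genes, meta$sample_id))
    planted <- list(); ownLevels <- numeric(0)
    shifts <- list()
    next_ <- 1L
    for (k in conds) {
        gs <- genes[seq(next_, length.out = nPlantedPerCondition)]
        next_ <- next_ + nPlantedPerCondition
        planted[[k]] <- gs
        lev <- muBackground + plantedShift +
            stats::rnorm(length(gs), 0, plantedShiftSd)
        names(lev) <- gs
        ownLevels <- c(ownLevels, lev)
        for (i in conds) {
            cols <- which(meta$condition_id == i)
            if (i == k) {
                mu <- lev; sdv <- sdSignal
            } else {
                mu <- muBackground + stats::rnorm(length(gs), 0,
                                                  conditionSpread)
                names(mu) <- gs
                sdv <- sdBackground
            }
            m[gs, cols] <- mu + matrix(
                stats::rnorm(length(gs) * length(cols), 0, sdv),
                length(gs), length(cols))
            shifts[[length(shifts) + 1L]] <-
                data.frame(gene_id = gs, condition_id = i, mean = unname(mu),
                           stringsAsFactors = FALSE)
        }
    }
    ds <- TimecourseExperiment(m, meta, provenance = "synthetic")
    list(dataset = ds,
         truth = list(planted = planted, ownLevels = ownLevels,
                      shifts = do.call(rbind, shifts)))
}

#' Dataset-shaped simulation presets
#'
#' Ready-made argument sets for [simulateTimecourse()] emulating the shapes
#' of three published study designs: `"default"` (6 single-factor
#' conditions, 8 time points, 2 replicates, 1000 genes — the package's
#' reference conditions for recovery experiments), `"atgenexpress"` (9
#' treatments x 2 tissues = 18 conditions, 8 time points, 2 replicates),
#' `"edge"` (3 toxins x 2 dosages = 6 conditions, ragged 4-12 time points,
#' ragged 1-3 replicates), and `"engreitz"` (3 single-factor disease
#' classes, two pseudo-time points 0 = normal / 1 = diseased, 10/9/8 paired
#' experiments as replicates). All presets are synthetic stand-ins shaped
#' like those designs, not the published data.
#'
#' @param name preset name.
#' @param nGenes override the preset's gene count.
#' @param seed optional RNG seed (used for ragged-design draws too).
#' @param ... further overrides passed to [simulateTimecourse()].
#' @return as [simulateTimecourse()].
#' @export
simulatePreset <- function(name = c("default", "atgenexpress", "edge",
                                    "engreitz"),
                           nGenes = NULL, seed = NULL, ...) {
    name <- match.arg(name)
    if (!is.null(seed)) set.seed(seed)
    args <- switch(name,
        default = list(nConditions = 6, timePoints = 8, replicates = 2,
                       nGenes = 1000),
        atgenexpress = list(
            factorGrid = list(treatment = sprintf("trt%d", 1:9),
                              tissue = c("root", "shoot")),
            timePoints = 8, replicates = 2, nGenes = 2000),
        edge = local({
            fg <- list(toxin = sprintf("tox%d", 1:3),
                       dose = c("lowdose", "highdose"))
            conds <- apply(expand.grid(fg, stringsAsFactors = FALSE), 1L,
                           paste, collapse = "_")
            nt <- c(12L, 10L, 8L, 6L, 5L, 4L)
            tps <- stats::setNames(
                lapply(nt, function(n) cumsum(c(2, rep(2, n - 1L)))), conds)
            reps <- stats::setNames(lapply(nt, function(n)
                sample(1:3, n, replace = TRUE)), conds)
            list(factorGrid = fg, timePoints = tps, replicates = reps,
                 nGenes = 1600)
        }),
        engreitz = list(
            factorGrid = list(disease = c("dmd", "brca", "hd")),
            timePoints = c(0, 1),
            replicates = list(dmd = c(10L, 10L), brca = c(9L, 9L),
                              hd = c(8L, 8L)),
            nGenes = 1000, sdSignal = 0.5))
    if (!is.null(nGenes)) args$nGenes <- nGenes
    over <- list(...)
    args[names(over)] <- over
    if (is.null(args$nPlantedPerCondition)) {
        nCond <- switch(name, default = 6L, atgenexpress = 18L, edge = 6L,
                        engreitz = 3L)
        ## cap planted genes at half the pool for down-scaled runs
        args$nPlantedPerCondition <-
            max(1L, min(20L, args$nGenes %/% (2L * nCond)))
    }
    do.call(simulateTimecourse, args)
}

#' Simulate a scored interaction network over the synthetic genes
#'
#' Links are drawn preferentially among the genes planted for the same
#' condition (probability `pSignal` per within-condition pair, scores
#' uniform on `scoreSignal`) and sparsely among all other pairs
#' (probability `pNoise`, scores uniform on `scoreNoise`).
#'
#' @param truth the `truth` element returned by [simulateTimecourse()].
#' @param genes all gene identifiers of the dataset.
#' @param pSignal link probability for within-condition planted pairs.
#' @param pNoise link probability for any other pair.
#' @param scoreSignal,scoreNoise integer score ranges, within [0, 1000].
#' @param seed optional RNG seed.
#' @return A \linkS4class{GeneLinkSet}.
#' @export
simulateInteractions <- function(truth, genes, pSignal = 0.5,
                                 pNoise = 0.002,
                                 scoreSignal = c(700, 1000),
                                 scoreNoise = c(0, 1000), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    rows <- list()
    for (gs in truth$planted) {
        if (length(gs) < 2L) next
        prs <- t(utils::combn(gs, 2L))
        keep <- stats::runif(nrow(prs)) < pSignal
        if (any(keep))
            rows[[length(rows) + 1L]] <- data.frame(
                gene_a = prs[keep, 1L], gene_b = prs[keep, 2L],
                score = round(stats::runif(sum(keep), scoreSignal[1L],
                                           scoreSignal[2L])),
                stringsAsFactors = FALSE)
    }
    G <- length(genes)
    nNoise <- stats::rbinom(1L, as.integer(G * (G - 1) / 2), pNoise)
    if (nNoise > 0L) {
        i <- sample.int(G, nNoise, replace = TRUE)
        j <- sample.int(G, nNoise, replace = TRUE)
        ok <- i != j
        rows[[length(rows) + 1L]] <- data.frame(
            gene_a = genes[pmin(i[ok], j[ok])],
            gene_b = genes[pmax(i[ok], j[ok])],
            score = round(stats::runif(sum(ok), scoreNoise[1L],
                                       scoreNoise[2L])),
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(GeneLinkSet(data.frame(gene_a = character(0),
                                      gene_b = character(0),
                                      score = integer(0))))
    tab <- do.call(rbind, rows)
    a <- pmin(tab$gene_a, tab$gene_b); b <- pmax(tab$gene_a, tab$gene_b)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -tab$score)
    keep <- ord[!duplicated(key[ord])]
    GeneLinkSet(data.frame(gene_a = a[keep], gene_b = b[keep],
                           score = tab$score[keep],
                           stringsAsFactors = FALSE))
}

#' Write a simulated dataset (and truth) to TSV files
#'
#' Writes `expression.tsv`, `metadata.tsv`, `truth.tsv` (columns
#' condition_id, gene_id) and, when links are given, `interactions.tsv`
#' into a directory.
#'
#' @param sim result of [simulateTimecourse()] / [simulatePreset()].
#' @param dir output directory (created if missing).
#' @param links optional \linkS4class{GeneLinkSet}.
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir, links = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeDataset(sim$dataset, file.path(dir, "expression.tsv"),
                 file.path(dir, "metadata.tsv"))
    tr <- do.call(rbind, lapply(names(sim$truth$planted), function(k)
        data.frame(condition_id = k, gene_id = sim$truth$planted[[k]],
                   stringsAsFactors = FALSE)))
    utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(links)) {
        lt <- linkTable(links)
        names(lt)[names(lt) == "score"] <- "combined_score"
        utils::write.table(lt, file.path(dir, "interactions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}
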