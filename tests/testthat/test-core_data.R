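test_that("reading a small matrix yields a fully indexed dataset", {
    m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 3, 4,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
    meta <- data.frame(sample_id = paste0("s", 1:4), condition_id = "cold_root",
                       factors = "cold;root", time_point = c(0, 0, 6, 6),
                       replicate = c(1L, 2L, 1L, 2L))
    ef <- tempfile(); mf <- tempfile()
    utils::write.table(data.frame(gene_id = rownames(m), m), ef, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(meta, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    ds <- readDataset(ef, mf)
    expect_equal(dim(ds), c(3L, 4L))
    expect_equal(conditionIds(ds), "cold_root")
    expect_equal(timePoints(ds, "cold_root"), c(0, 6))
    expect_equal(conditionFactors(ds)$cold_root, c("cold", "root"))
    expect_equal(unname(exprValues(ds)["g2", "s3"]), 8)
})

test_that("malformed inputs are rejected at load", {
    m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
    meta <- data.frame(sample_id = c("s1", "s2"), condition_id = "a",
                       factors = "a", time_point = c(0, 1),
                       replicate = c(1L, 1L))
    ef <- tempfile(); mf <- tempfile()
    utils::write.table(data.frame(gene_id = rownames(m), m), ef, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(meta, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readDataset(ef, mf), "duplicate gene")

    ## non-numeric cell
    tab <- data.frame(gene_id = c("g1", "g2"), s1 = c("1.0", "oops"),
                      s2 = c("2", "3"))
    utils::write.table(tab, ef, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readDataset(ef, mf), "non-numeric")

    ## metadata/matrix mismatches, both directions
    m2 <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "sX")))
    utils::write.table(data.frame(gene_id = rownames(m2), m2), ef,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readDataset(ef, mf), "absent from metadata")
    meta2 <- rbind(meta, data.frame(sample_id = "sY", condition_id = "a",
                                    factors = "a", time_point = 2,
                                    replicate = 1L))
    m3 <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
    utils::write.table(data.frame(gene_id = rownames(m3), m3), ef,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(meta2, mf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readDataset(ef, mf), "without a matching")
})

test_that("datasets round-trip through the TSV writers bit-exactly", {
    sim <- simulateTimecourse(nConditions = 3, timePoints = 4,
                              nGenes = 30, nPlantedPerCondition = 3,
                              seed = 11)
    ef <- tempfile(); mf <- tempfile()
    writeDataset(sim$dataset, ef, mf)
    back <- readDataset(ef, mf)
    expect_identical(exprValues(back), exprValues(sim$dataset))
    expect_equal(sampleInfo(back), sampleInfo(sim$dataset))
})

test_that("a grid-shaped preset has the requested design dimensions", {
    sim <- simulatePreset("atgenexpress", nGenes = 40, seed = 2)
    ds <- sim$dataset
    expect_equal(length(conditionIds(ds)), 18L)        # 9 treatments x 2 tissues
    expect_true(all(vapply(conditionIds(ds), function(k)
        length(timePoints(ds, k)), integer(1)) == 8L))
    expect_true(all(vapply(conditionIds(ds), function(k)
        replicateCounts(ds, k), FUN.VALUE = integer(8)) == 2L))
    ## two-factor identity: cold-root-style exclusion needs the factor sets
    f <- conditionFactors(ds)[["trt1_root"]]
    expect_setequal(f, c("trt1", "root"))
})

test_that("fold-change filter keeps genes by max/min ratio", {
    m <- rbind(g1 = c(2, 8, 2, 4), g2 = c(5, 5, 5, 5), g3 = c(3, 5.9, 3, 3))
    colnames(m) <- paste0("s", 1:4)
    ds <- makeToyDataset(m, rep("a", 4), c(0, 0, 1, 1), c(1L, 2L, 1L, 2L))
    kept <- foldChangeFilter(ds, minFold = 2)
    expect_equal(rownames(kept), "g1")   # ratio 4; constant and 1.97 removed

    ## log2 scale: difference of 1.0 is exactly a 2-fold change (boundary kept)
    ml <- rbind(g1 = c(1, 2, 1, 1), g2 = c(1, 1.5, 1, 1))
    colnames(ml) <- paste0("s", 1:4)
    dl <- makeToyDataset(ml, rep("a", 4), c(0, 0, 1, 1), c(1L, 2L, 1L, 2L))
    expect_equal(rownames(foldChangeFilter(dl, 2, logScale = TRUE)), "g1")

    expect_error(foldChangeFilter(ds, minFold = 1), "minFold")
    expect_warning(out <- foldChangeFilter(ds, minFold = 1e6), "every gene")
    expect_equal(nrow(out), 0L)

    ## minFold barely above 1 keeps every non-constant gene
    kept2 <- foldChangeFilter(ds, minFold = 1 + 1e-9)
    expect_setequal(rownames(kept2), c("g1", "g3"))
})

test_that("quantile normalization equalizes sample distributions", {
    m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
    rownames(m) <- paste0("g", 1:3)
    ds <- makeToyDataset(m, c("a", "a"), c(0, 1), c(1L, 1L))
    qn <- exprValues(quantileNormalize(ds))
    expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
    expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

    ## identical samples are left unchanged
    m2 <- cbind(s1 = c(3, 1, 2), s2 = c(3, 1, 2))
    rownames(m2) <- paste0("g", 1:3)
    d2 <- makeToyDataset(m2, c("a", "a"), c(0, 1), c(1L, 1L))
    expect_equal(exprValues(quantileNormalize(d2)), m2)

    ## ties: tied entries receive the mean of the reference values they span,
    ## checked against an independent rank-and-average computation
    m3 <- cbind(s1 = c(1, 1, 3), s2 = c(2, 4, 6))
    rownames(m3) <- paste0("g", 1:3)
    d3 <- makeToyDataset(m3, c("a", "a"), c(0, 1), c(1L, 1L))
    qn3 <- exprValues(quantileNormalize(d3))
    ref <- rowMeans(cbind(sort(m3[, 1]), sort(m3[, 2])))  # 1.5 2.5 4.5
    oracle <- vapply(seq_len(ncol(m3)), function(j) {
        r <- rank(m3[, j])              # average ranks at ties
        approx(seq_along(ref), ref, xout = r)$y
    }, numeric(3))
    expect_equal(unname(qn3), oracle)
    expect_equal(unname(qn3[1:2, 1]), c(2, 2))

    ## idempotence on tie-free data
    d4 <- randomDataset(G = 20, N = 2, T_ = 3, R = 1, seed = 4)
    once <- exprValues(quantileNormalize(d4))
    twice <- exprValues(quantileNormalize(quantileNormalize(d4)))
    expect_equal(twice, once, tolerance = 1e-12)

    d1 <- makeToyDataset(m[, 1, drop = FALSE], "a", 0, 1L)
    expect_error(quantileNormalize(d1), "2 samples")
})

test_that("ranking and CV tables round-trip through their writers", {
    rk <- rsnrRanking(simulateTimecourse(nConditions = 3, timePoints = 4,
                                         nGenes = 12,
                                         nPlantedPerCondition = 2,
                                         seed = 3)$dataset, "c01")
    p <- tempfile()
    writeRanking(rk, p)
    back <- readRanking(p)
    expect_equal(rankingTable(back), rankingTable(rk))
    expect_equal(back@method, "rsnr")
    expect_equal(back@conditionId, "c01")

    ## empty ranking -> header-only file
    empty <- new("GeneRanking", conditionId = "c01", method = "rsnr",
                 table = data.frame(gene_id = character(0),
                                    score = numeric(0)))
    writeRanking(empty, p)
    expect_equal(length(readLines(p)), 1L)

    ds <- simulateTimecourse(nConditions = 4, nGenes = 60,
                             nPlantedPerCondition = 5, seed = 5)$dataset
    res <- runCV(ds, cvConfig(foldsPerCondition = 1, repetitions = 2,
                              seed = 1))
    writeCVResult(res, p)
    back <- readCVResult(p)
    expect_equal(cvPredictions(back), cvPredictions(res))
    expect_equal(meanAccuracy(back), meanAccuracy(res))
})
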