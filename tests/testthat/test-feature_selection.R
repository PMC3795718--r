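test_that("the positive/negative split follows factor disjointness", {
    ## two-factor grid: target trt1_root excludes everything sharing trt1
    ## or root, keeps the rest as negatives
    sim <- simulatePreset("atgenexpress", nGenes = 30, seed = 1)
    split <- buildSplit(sim$dataset, "trt1_root")
    facs <- conditionFactors(sim$dataset)
    for (k in split@negativeConditions)
        expect_false(any(facs[[k]] %in% c("trt1", "root")))
    for (k in split@excludedConditions)
        expect_true(any(facs[[k]] %in% c("trt1", "root")))
    expect_length(split@negativeConditions, 8L)   # 8 treatments x shoot
    expect_length(split@excludedConditions, 9L)

    ## single-factor design: negatives are simply the other conditions
    ds <- randomDataset(N = 3)
    s <- buildSplit(ds, "c01")
    expect_setequal(s@negativeConditions, c("c02", "c03"))

    ## shared factor everywhere -> error
    m <- exprValues(ds)
    si <- sampleInfo(ds)
    si$factors <- paste0(si$factors, ";shared")
    ds2 <- TimecourseExperiment(m, si)
    expect_error(buildSplit(ds2, "c01"), "empty negative set")
})

test_that("rSNR matches direct substitution into its formula", {
    ## positive values [9,10,11,10]; negative per-condition means [5,10,15]
    m <- rbind(g1 = c(9, 10, 11, 10, 5, 5, 10, 10, 15, 15))
    colnames(m) <- paste0("s", 1:10)
    ds <- makeToyDataset(
        m,
        cond = c(rep("a", 4), rep("b", 2), rep("c", 2), rep("d", 2)),
        tp = c(0, 0, 1, 1, 0, 1, 0, 1, 0, 1),
        repl = rep(1:2, 5))
    comp <- rsnrScores(ds, buildSplit(ds, "a"))
    expect_equal(comp$mu_pos, 10)
    expect_equal(comp$sigma_pos, sqrt(2 / 3))
    expect_equal(comp$mu_neg, 10)
    expect_equal(comp$sigma_neg, 5)
    expect_equal(comp$snr_pos, 10 / sqrt(2 / 3))
    expect_equal(comp$snr_neg, 2)
    expect_equal(comp$rsnr, (10 / sqrt(2 / 3)) / 2)  # ~ 6.1237
})

test_that("degenerate rSNR quotients are deterministic sentinels", {
    ## gene constant in the positive set -> Inf, ranked first; gene with
    ## identical negative-condition means -> 0
    m <- rbind(flat_pos = c(7, 7, 7, 7, 1, 1, 5, 5, 9, 9),
               flat_neg = c(1, 2, 3, 4, 6, 6, 6, 6, 6, 6),
               normal = c(9, 10, 11, 10, 5, 5, 10, 10, 15, 15))
    colnames(m) <- paste0("s", 1:10)
    ds <- makeToyDataset(
        m,
        cond = c(rep("a", 4), rep("b", 2), rep("c", 2), rep("d", 2)),
        tp = c(0, 0, 1, 1, 0, 1, 0, 1, 0, 1),
        repl = rep(1:2, 5))
    comp <- rsnrScores(ds, buildSplit(ds, "a"))
    expect_equal(comp["flat_pos", "rsnr"], Inf)
    expect_equal(comp["flat_neg", "rsnr"], 0)
    rk <- rsnrRanking(ds, "a")
    expect_equal(rankingTable(rk)$gene_id[1], "flat_pos")

    ## both means zero -> 0 with a warning
    m2 <- rbind(zz = c(-1, 1, -1, 1, -2, -2, 0, 0, 2, 2),
                normal = c(9, 10, 11, 10, 5, 5, 10, 10, 15, 15))
    colnames(m2) <- paste0("s", 1:10)
    d2 <- makeToyDataset(
        m2,
        cond = c(rep("a", 4), rep("b", 2), rep("c", 2), rep("d", 2)),
        tp = c(0, 0, 1, 1, 0, 1, 0, 1, 0, 1),
        repl = rep(1:2, 5))
    expect_warning(c2 <- rsnrScores(d2, buildSplit(d2, "a")), "zero mean")
    expect_equal(c2["zz", "rsnr"], 0)
})

test_that("rSNR equals the coefficient-of-variation quotient", {
    ds <- randomDataset(G = 40, N = 5, T_ = 4, R = 2, seed = 21)
    comp <- rsnrScores(ds, buildSplit(ds, "c02"))
    cvq <- (comp$sigma_neg / abs(comp$mu_neg)) /
           (comp$sigma_pos / abs(comp$mu_pos))
    expect_equal(comp$rsnr, cvq, tolerance = 1e-10)
    expect_equal(comp$rsnr, comp$snr_pos / comp$snr_neg, tolerance = 1e-10)
})

test_that("vectorized scores equal the per-gene scalar-loop oracles", {
    for (seed in 1:5) {
        ds <- randomDataset(G = 25, N = 4, T_ = 3, R = 2, seed = seed)
        comp <- rsnrScores(ds, buildSplit(ds, "c01"))
        expect_equal(unname(comp$rsnr), unname(oracleRsnr(ds, "c01")),
                     tolerance = 1e-10)
        si <- sampleInfo(ds)
        c1 <- si$sample_id[si$condition_id == "c01"]
        c2 <- si$sample_id[si$condition_id != "c01"]
        snr <- rankingTable(snrcScores(ds, c1, c2))
        orc <- oracleTwoClass(ds, c1, c2, "snr_c")
        expect_equal(snr$score, unname(orc[snr$gene_id]), tolerance = 1e-10)
        wt <- rankingTable(welchTScores(ds, c1, c2))
        orw <- oracleTwoClass(ds, c1, c2, "welch_t")
        expect_equal(wt$score, unname(orw[wt$gene_id]), tolerance = 1e-10)
    }
})

test_that("two-class scores match hand-computed values", {
    ## class means 10 vs 8, both sds 2, n = 4 each
    set.seed(1)
    a <- c(8, 12, 8, 12); b <- c(6, 10, 6, 10)   # mu 10/8, sd 2.309...
    sdv <- sd(a)
    m <- rbind(g1 = c(a, b))
    colnames(m) <- paste0("s", 1:8)
    ds <- makeToyDataset(m, rep(c("x", "y"), each = 4),
                         rep(c(0, 0, 1, 1), 2), rep(1:2, 4))
    cls1 <- paste0("s", 1:4); cls2 <- paste0("s", 5:8)
    expect_equal(rankingTable(snrcScores(ds, cls1, cls2))$score,
                 2 / (2 * sdv))
    expect_equal(rankingTable(welchTScores(ds, cls1, cls2))$score,
                 2 / sqrt(2 * sdv^2 / 4))
    ## identical classes score zero
    m2 <- rbind(g1 = rep(c(1, 2), 4))
    colnames(m2) <- paste0("s", 1:8)
    d2 <- makeToyDataset(m2, rep(c("x", "y"), each = 4),
                         rep(c(0, 0, 1, 1), 2), rep(1:2, 4))
    expect_equal(rankingTable(snrcScores(d2, cls1, cls2))$score, 0)
    expect_equal(rankingTable(welchTScores(d2, cls1, cls2))$score, 0)
})

test_that("Welch and SNR rankings agree under equal n and equal sds", {
    ## class2 = class1 + per-gene shift: sds equal exactly, n1 = n2
    ds <- randomDataset(G = 30, N = 2, T_ = 2, R = 2, seed = 31)
    m <- exprValues(ds)
    si <- sampleInfo(ds)
    c1 <- si$sample_id[si$condition_id == "c01"]
    c2 <- si$sample_id[si$condition_id == "c02"]
    m[, c2] <- m[, c1] + rnorm(nrow(m))
    d2 <- TimecourseExperiment(m, si)
    expect_equal(rankingTable(snrcScores(d2, c1, c2))$gene_id,
                 rankingTable(welchTScores(d2, c1, c2))$gene_id)
})

test_that("selector rankings are scale invariant", {
    ds <- randomDataset(G = 30, N = 4, T_ = 4, R = 2, seed = 41)
    scaled <- ds
    SummarizedExperiment::assay(scaled, "exprs") <- exprValues(ds) * 3.7
    expect_equal(rankingTable(rsnrRanking(ds, "c01"))$gene_id,
                 rankingTable(rsnrRanking(scaled, "c01"))$gene_id)
    si <- sampleInfo(ds)
    c1 <- si$sample_id[si$condition_id == "c01"]
    c2 <- si$sample_id[si$condition_id != "c01"]
    expect_equal(rankingTable(snrcScores(ds, c1, c2))$gene_id,
                 rankingTable(snrcScores(scaled, c1, c2))$gene_id)
    expect_equal(rankingTable(welchTScores(ds, c1, c2))$gene_id,
                 rankingTable(welchTScores(scaled, c1, c2))$gene_id)
})

test_that("random selection is reproducible and uniform", {
    genes <- sprintf("g%02d", 1:5)
    expect_setequal(rankingTable(randomSelection(genes, 5))$gene_id, genes)
    expect_equal(rankingTable(randomSelection(genes, 3, seed = 9)),
                 rankingTable(randomSelection(genes, 3, seed = 9)))
    expect_error(randomSelection(genes, 6), "must lie")
    ## single draws over many seeds hit each gene at ~uniform frequency
    draws <- vapply(1:500, function(s)
        rankingTable(randomSelection(genes, 1, seed = s))$gene_id,
        character(1))
    freq <- table(factor(draws, levels = genes)) / 500
    ## 5 x binomial(500, 0.2): +-4 sd band
    expect_true(all(abs(freq - 0.2) < 4 * sqrt(0.2 * 0.8 / 500)))
})

test_that("interaction-based selection thresholds on confidence", {
    genes <- c("a", "b", "c", "d")
    links <- GeneLinkSet(data.frame(gene_a = c("a", "b"),
                                    gene_b = c("b", "c"),
                                    score = c(950L, 400L)))
    expect_setequal(stringGeneSelection(genes, links, 900), c("a", "b"))
    kept <- linkTable(stringLinkSelection(genes, links, 900))
    expect_equal(nrow(kept), 1L)
    expect_equal(kept$score, 950L)
    expect_setequal(stringGeneSelection(genes, links, 0), c("a", "b", "c"))
    ## the gene sets of link and gene selection coincide at every cutoff
    for (ct in c(0, 250, 500, 750, 900)) {
        ls <- tryCatch(stringLinkSelection(genes, links, ct),
                       error = function(e) NULL)
        if (is.null(ls)) next
        expect_setequal(unique(c(linkTable(ls)$gene_a, linkTable(ls)$gene_b)),
                        stringGeneSelection(genes, links, ct))
    }
    expect_error(stringGeneSelection(genes, links, 999), "cutoff 999")
    ## links to genes off the array never qualify
    expect_error(stringGeneSelection(c("a", "z"), links, 0), "cutoff")
})

test_that("rank sections are deterministic with lexicographic tie-break", {
    tb <- new("GeneRanking", conditionId = "k", method = "rsnr",
              table = data.frame(gene_id = c("gb", "gc", "ga", "gd"),
                                 score = c(3, 1, 1, 0)))
    expect_error(validObject(tb), NA)
    expect_equal(selectTop(tb, 4), c("gb", "gc", "ga", "gd"))
    expect_equal(selectSection(tb, 3, 2), c("ga", "gd"))
    expect_error(selectSection(tb, 4, 2), "out of bounds")
    ## equal scores order by gene id when the ranking is built
    rk <- rsnr:::.makeRanking(c("gb", "ga", "gc"), c(1, 1, 2), "k", "t")
    expect_equal(rankingTable(rk)$gene_id, c("gc", "ga", "gb"))
})
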