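test_that("scenario-2 folds remove every replicate of the test time points", {
    sim <- simulateTimecourse(nConditions = 3, timePoints = 6,
                              nGenes = 20, nPlantedPerCondition = 2,
                              seed = 2)
    ds <- sim$dataset
    cfg <- cvConfig(scenario = 2, foldsPerCondition = 3, repetitions = 1,
                    seed = 7)
    set.seed(cfg@seed)
    folds <- makeFoldsTimecourse(ds, cfg)
    expect_length(folds, 9L)
    si <- sampleInfo(ds)
    for (fold in folds) {
        expect_silent(assertFoldHygiene(ds, fold))
        ## training keeps T - 2 time points of the test condition
        kept <- unique(si$time_point[fold$trainingMask &
                                     si$condition_id == fold$condition])
        expect_length(kept, 4L)
        expect_length(intersect(kept, fold$testTimePoints), 0L)
        ## other conditions are untouched
        others <- si$condition_id != fold$condition
        expect_true(all(fold$trainingMask[others]))
    }
    ## determinism: same seed, same folds
    set.seed(cfg@seed)
    again <- makeFoldsTimecourse(ds, cfg)
    expect_equal(folds, again)

    ## T = 4 condition: exactly 2 training time points remain
    sim4 <- simulateTimecourse(nConditions = 3, timePoints = 4,
                               nGenes = 20, nPlantedPerCondition = 2,
                               seed = 3)
    set.seed(1)
    f4 <- makeFoldsTimecourse(sim4$dataset, cfg)[[1]]
    si4 <- sampleInfo(sim4$dataset)
    kept <- unique(si4$time_point[f4$trainingMask &
                                  si4$condition_id == f4$condition])
    expect_length(kept, 2L)
})

test_that("scenario 1 keeps sibling replicates in training", {
    sim <- simulateTimecourse(nConditions = 3, timePoints = 5,
                              nGenes = 20, nPlantedPerCondition = 2,
                              seed = 2)
    cfg <- cvConfig(scenario = 1, foldsPerCondition = 5, repetitions = 1,
                    seed = 7)
    set.seed(cfg@seed)
    folds <- makeFoldsTimecourse(sim$dataset, cfg)
    si <- sampleInfo(sim$dataset)
    for (fold in folds) {
        ## only the selected test samples leave training
        expect_equal(colnames(sim$dataset)[!fold$trainingMask],
                     fold$testCols)
        ## every test time point still has its sibling replicate in training
        sib <- si$condition_id == fold$condition &
            si$time_point %in% fold$testTimePoints &
            !(si$sample_id %in% fold$testCols)
        expect_true(all(fold$trainingMask[sib]))
        expect_gte(length(fold$testTimePoints), 2L)
    }
})

test_that("conditions with fewer than 4 time points are skipped", {
    sim <- simulateTimecourse(
        nConditions = 3,
        timePoints = list(c01 = 0:5, c02 = 0:2, c03 = 0:4),
        nGenes = 20, nPlantedPerCondition = 2, seed = 5)
    cfg <- cvConfig(foldsPerCondition = 2, repetitions = 1, seed = 1)
    set.seed(1)
    expect_warning(folds <- makeFoldsTimecourse(sim$dataset, cfg),
                   "fewer than 4 time points")
    expect_setequal(unique(vapply(folds, `[[`, character(1), "condition")),
                    c("c01", "c03"))
})

test_that("static folds hold each experiment out exactly once", {
    st <- simulatePreset("engreitz", nGenes = 20, seed = 4)
    folds <- makeFoldsStatic(st$dataset)
    expect_length(folds, 27L)            # 10 + 9 + 8 experiments
    keys <- vapply(folds, function(f)
        paste(f$condition, f$replicate), character(1))
    expect_equal(anyDuplicated(keys), 0L)
    for (f in folds[1:5]) {
        expect_length(f$testCols, 2L)
        expect_false(any(f$trainingMask[match(f$testCols,
                                              colnames(st$dataset))]))
    }
})

test_that("perfectly separable data classifies at accuracy 1", {
    sim <- simulateTimecourse(nConditions = 4, nGenes = 80,
                              nPlantedPerCondition = 10,
                              sdBackground = 0.5, plantedShift = 4,
                              conditionSpread = 2, seed = 19)
    res <- runCV(sim$dataset, cvConfig(selector = "all",
                                       foldsPerCondition = 2,
                                       repetitions = 2, seed = 23))
    expect_equal(meanAccuracy(res), 1.0)
    expect_equal(res@nErrors, 0L)
})

test_that("accuracy is the fraction of correct folds", {
    df <- data.frame(repetition = 1, fold = 1:10,
                     correct = c(rep(TRUE, 9), FALSE))
    expect_equal(accuracy(df), 0.9)
    df$correct <- TRUE
    expect_equal(accuracy(df), 1.0)
    df$correct <- FALSE
    expect_equal(accuracy(df), 0.0)
    expect_error(accuracy(df[0, ]), "no predictions")
})

test_that("fitted selections depend on the training data only", {
    sim <- simulateTimecourse(nConditions = 4, nGenes = 60,
                              nPlantedPerCondition = 5, seed = 29)
    ds <- sim$dataset
    cfg <- cvConfig(selector = "rsnr", nGenes = 10, foldsPerCondition = 1,
                    repetitions = 1, seed = 31)
    set.seed(cfg@seed)
    fold <- makeFoldsTimecourse(ds, cfg)[[1]]
    sel1 <- selectTop(rsnrRanking(ds, fold$condition, fold$trainingMask), 10)
    ## scramble the held-out samples: the fitted ranking must not move
    m <- exprValues(ds)
    m[, !fold$trainingMask] <- matrix(rnorm(sum(!fold$trainingMask) * nrow(m),
                                            50, 10),
                                      nrow(m))
    ds2 <- TimecourseExperiment(m, sampleInfo(ds))
    sel2 <- selectTop(rsnrRanking(ds2, fold$condition, fold$trainingMask), 10)
    expect_identical(sel1, sel2)
})

test_that("AUC handles perfect separation, ties, and matches brute force", {
    expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1),
                          c(TRUE, TRUE, FALSE, FALSE)), 1.0)
    expect_equal(aucScore(rep(0.5, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                         FALSE)), 0.5)
    expect_equal(aucScore(c(0.1, 0.9), c(TRUE, FALSE)), 0.0)
    set.seed(37)
    for (i in 1:25) {
        n <- sample(4:20, 1)
        s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
        l <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(l) || all(l)) next
        expect_equal(aucScore(s, l), oracleAuc(s, l), tolerance = 1e-12)
    }
    expect_error(aucScore(c(1, 2), c(TRUE, TRUE)), "positive and")
})

test_that("query-vs-database ROC averages per-query AUCs", {
    st <- simulatePreset("engreitz", nGenes = 60, seed = 43)
    roc <- rocAucQuery(st$dataset, cvConfig(selector = "all", seed = 1))
    expect_length(roc@aucPerQuery, 27L)
    expect_true(all(roc@aucPerQuery >= 0 & roc@aucPerQuery <= 1))
    expect_equal(meanAuc(roc), mean(roc@aucPerQuery))
    ## per-query AUC agrees with the brute-force pair count
    q <- roc@queries[[3]]
    expect_equal(roc@aucPerQuery[3], oracleAuc(q$score, q$label),
                 tolerance = 1e-12)
    ## each query sees all other experiments
    expect_equal(nrow(q), 26L)
})

test_that("experiment grids tile sections and sizes as requested", {
    sim <- simulateTimecourse(nConditions = 3, nGenes = 50,
                              nPlantedPerCondition = 4, seed = 47)
    cfg <- cvConfig(foldsPerCondition = 1, repetitions = 1, seed = 3)
    rs <- rankSectionExperiment(sim$dataset, cfg, sectionSize = 10)
    sec <- rs[rs$method == "rsnr_section", ]
    expect_equal(sec$section_start, seq(1, 41, by = 10))
    expect_true("random" %in% rs$method)
    sw <- stepwiseReductionExperiment(sim$dataset, cfg, step = 15)
    expect_equal(unique(sw$n_genes), c(50, 35, 20, 5))
    ## at n = G the rSNR selection and the random control use all genes
    full <- sw[sw$n_genes == 50, ]
    expect_equal(full$accuracy_mean[1], full$accuracy_mean[2])
})

test_that("the training-label permutation null sits at chance", {
    sim <- simulateTimecourse(nConditions = 5, nGenes = 80,
                              nPlantedPerCondition = 5, seed = 53)
    cfg <- cvConfig(selector = "all", foldsPerCondition = 2,
                    repetitions = 10, seed = 59)
    res <- runCV(sim$dataset, cfg, permuteTrainingLabels = TRUE)
    se <- res@sdRepetition / sqrt(length(res@repetitionAccuracy))
    expect_lt(abs(meanAccuracy(res) - 1 / 5), max(3 * se, 0.12))
})
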