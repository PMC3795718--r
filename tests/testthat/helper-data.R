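## Small deterministic fixture builders used across the suite.

## dataset from an explicit value matrix: conditions given as a named list
## cond -> list(factors=, samples=data.frame(time, replicate))
makeToyDataset <- function(values, cond, tp, repl, factors = NULL) {
    conds <- unique(cond)
    if (is.null(factors))
        factors <- stats::setNames(paste0("f_", conds), conds)
    meta <- data.frame(
        sample_id = colnames(values),
        condition_id = cond,
        factors = unname(factors[cond]),
        time_point = tp,
        replicate = repl,
        stringsAsFactors = FALSE)
    TimecourseExperiment(values, meta)
}

## G genes x (N conditions x T time points x R replicates) Gaussian dataset
randomDataset <- function(G = 10, N = 4, T_ = 4, R = 2, seed = 1) {
    set.seed(seed)
    conds <- sprintf("c%02d", seq_len(N))
    grid <- expand.grid(replicate = seq_len(R), time_point = seq_len(T_) - 1,
                        condition = conds, stringsAsFactors = FALSE)
    m <- matrix(rnorm(G * nrow(grid), 8, 1), G, nrow(grid))
    rownames(m) <- sprintf("g%03d", seq_len(G))
    colnames(m) <- sprintf("%s_t%d_r%d", grid$condition, grid$time_point,
                           grid$replicate)
    makeToyDataset(m, grid$condition, grid$time_point, grid$replicate)
}

## per-gene scalar-loop oracle for the rSNR (independent of the package's
## vectorized route): plain sums, one gene at a time
oracleRsnr <- function(ds, target) {
    si <- sampleInfo(ds)
    m <- exprValues(ds)
    facs <- conditionFactors(ds)
    tf <- facs[[target]]
    neg <- names(facs)[vapply(names(facs), function(k)
        k != target && !any(facs[[k]] %in% tf), logical(1))]
    posCols <- si$sample_id[si$condition_id == target]
    vapply(rownames(m), function(g) {
        pv <- as.numeric(m[g, posCols])
        muP <- sum(pv) / length(pv)
        sdP <- sqrt(sum((pv - muP)^2) / (length(pv) - 1))
        cm <- vapply(neg, function(k) {
            v <- as.numeric(m[g, si$sample_id[si$condition_id == k]])
            sum(v) / length(v)
        }, numeric(1))
        muN <- sum(cm) / length(cm)
        sdN <- sqrt(sum((cm - muN)^2) / (length(cm) - 1))
        if (sdP == 0 && sdN == 0) return(0)
        if (sdP == 0) return(Inf)
        if (sdN == 0) return(0)
        if (muP == 0 && muN == 0) return(0)
        if (muP == 0) return(0)
        (sdN / abs(muN)) / (sdP / abs(muP))
    }, numeric(1))
}

## scalar-loop oracles for the two-class scores
oracleTwoClass <- function(ds, cls1, cls2, kind = c("snr_c", "welch_t")) {
    kind <- match.arg(kind)
    m <- exprValues(ds)
    vapply(rownames(m), function(g) {
        a <- as.numeric(m[g, cls1]); b <- as.numeric(m[g, cls2])
        mu1 <- mean(a); mu2 <- mean(b)
        s1 <- sd(a); s2 <- sd(b)
        num <- abs(mu1 - mu2)
        den <- if (kind == "snr_c") s1 + s2
               else sqrt(s1^2 / length(a) + s2^2 / length(b))
        if (den == 0) { if (num == 0) 0 else Inf } else num / den
    }, numeric(1))
}

## brute-force AUC: concordant-pair count with ties at half credit
oracleAuc <- function(scores, labels) {
    pos <- scores[as.logical(labels)]
    neg <- scores[!as.logical(labels)]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

## Rscript invocation of the installed CLI with the test library path
runCli <- function(args, workDir) {
    cli <- system.file("scripts", "rsnr-cli.R", package = "rsnr")
    res <- withr::with_dir(workDir, system2(
        file.path(R.home("bin"), "Rscript"), c(cli, args),
        stdout = TRUE, stderr = TRUE,
        env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0)
        stop("CLI failed: ", paste(res, collapse = "\n"))
    invisible(res)
}
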