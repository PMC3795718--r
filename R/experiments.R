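## copy a config with field overrides
.cfgWith <- function(config, ...) {
    mods <- list(...)
    for (nm in names(mods)) methods::slot(config, nm) <- mods[[nm]]
    methods::validObject(config)
    config
}

#' Rank-section experiment
#'
#' Splits each condition's rSNR-sorted gene list into consecutive
#' non-overlapping sections of `sectionSize` genes (any remainder shorter
#' than a section at the bottom of the list is dropped) and runs the
#' cross-validation once per section, classifying on that section only;
#' a random control of the same size is included. Genes relevant to a
#' condition should concentrate at the top of its list, so accuracy should
#' fall from the top section to the bottom one.
#'
#' @param x a TimecourseExperiment
#' @param config a \linkS4class{CVConfig}; its selector field is ignored
#'   (rsnr and random are run).
#' @param sectionSize genes per section (default 200).
#' @return data.frame with columns method, section_start, n_genes,
#'   accuracy_mean, accuracy_sd_rep, accuracy_sd_fold (section_start 1 is
#'   the top of the ranking; NA for the random control).
#' @export
rankSectionExperiment <- function(x, config, sectionSize = 200) {
    G <- nrow(x)
    if (G < sectionSize) stop("fewer genes than one section")
    starts <- (seq_len(G %/% sectionSize) - 1L) * sectionSize + 1L
    rows <- lapply(starts, function(s) {
        res <- runCV(x, .cfgWith(config, selector = "rsnr",
                                 nGenes = as.integer(sectionSize),
                                 sectionStart = as.integer(s)))
        data.frame(method = "rsnr_section", section_start = s,
                   n_genes = sectionSize, accuracy_mean = res@meanAccuracy,
                   accuracy_sd_rep = res@sdRepetition,
                   accuracy_sd_fold = res@sdFold)
    })
    ctl <- runCV(x, .cfgWith(config, selector = "random",
                             nGenes = as.integer(sectionSize),
                             sectionStart = NA_integer_))
    rows[[length(rows) + 1L]] <-
        data.frame(method = "random", section_start = NA_integer_,
                   n_genes = sectionSize, accuracy_mean = ctl@meanAccuracy,
                   accuracy_sd_rep = ctl@sdRepetition,
                   accuracy_sd_fold = ctl@sdFold)
    do.call(rbind, rows)
}

#' Step-wise feature-reduction experiment
#'
#' Decreases the number of genes from all of them down in steps of `step`;
#' at every size the cross-validation is run with the top-n rSNR selection
#' and with an equal-size random control. At n = G the two coincide (both
#' use every gene).
#'
#' @param x a TimecourseExperiment
#' @param config a \linkS4class{CVConfig}; selector field ignored.
#' @param step genes removed per step (default 200).
#' @return data.frame with columns method, n_genes, accuracy_mean,
#'   accuracy_sd_rep, accuracy_sd_fold.
#' @export
stepwiseReductionExperiment <- function(x, config, step = 200) {
    G <- nrow(x)
    if (step >= G) stop("step must be smaller than the number of genes")
    sizes <- seq(G, 1L, by = -step)
    rows <- list()
    for (n in sizes) {
        for (meth in c("rsnr", "random")) {
            res <- runCV(x, .cfgWith(config, selector = meth,
                                     nGenes = as.integer(n),
                                     sectionStart = NA_integer_))
            rows[[length(rows) + 1L]] <-
                data.frame(method = meth, n_genes = n,
                           accuracy_mean = res@meanAccuracy,
                           accuracy_sd_rep = res@sdRepetition,
                           accuracy_sd_fold = res@sdFold)
        }
    }
    do.call(rbind, rows)
}
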