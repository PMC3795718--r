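#' Read an expression dataset from TSV files
#'
#' The expression file is tab-separated with a header row of sample
#' identifiers and first column `gene_id`; the metadata file maps every
#' sample identifier to its condition, factor set, time point and replicate
#' index (columns `sample_id`, `condition_id`, `factors`, `time_point`,
#' `replicate`). Values are taken as given (no scale transformation).
#'
#' @param expressionPath path to the expression TSV.
#' @param metadataPath path to the sample metadata TSV.
#' @param provenance free-text provenance label.
#' @return A \linkS4class{TimecourseExperiment}.
#' @export
readDataset <- function(expressionPath, metadataPath,
                        provenance = expressionPath) {
    expr <- utils::read.delim(expressionPath, check.names = FALSE,
                              stringsAsFactors = FALSE)
    if (colnames(expr)[1L] != "gene_id")
        stop("expression file must have 'gene_id' as its first column")
    genes <- as.character(expr[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene identifier(s): ",
             paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
    m <- as.matrix(expr[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric expression cell(s) in ", expressionPath)
    rownames(m) <- genes
    meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
    TimecourseExperiment(m, meta, provenance = provenance)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [readDataset()]; `readDataset(writeDataset(x, ...))`
#' round-trips the dataset.
#'
#' @param x a TimecourseExperiment
#' @param expressionPath,metadataPath output paths.
#' @return invisibly, the two paths.
#' @export
writeDataset <- function(x, expressionPath, metadataPath) {
    m <- exprValues(x)
    ## 17 significant digits: doubles survive the text round trip exactly
    fm <- formatC(m, digits = 17, format = "g")
    dim(fm) <- dim(m); dimnames(fm) <- dimnames(m)
    df <- data.frame(gene_id = rownames(m), fm, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, expressionPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sampleInfo(x), metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(expressionPath, metadataPath))
}

#' Construct a scored gene-gene interaction set
#'
#' @param links data.frame with columns `gene_a`, `gene_b`, `score`
#'   (integer 0-1000). Pairs are canonicalized (unordered); self links and
#'   duplicate pairs are errors.
#' @return A \linkS4class{GeneLinkSet}.
#' @export
GeneLinkSet <- function(links) {
    links <- as.data.frame(links, stringsAsFactors = FALSE)
    a <- as.character(links$gene_a); b <- as.character(links$gene_b)
    ga <- pmin(a, b); gb <- pmax(a, b)
    out <- data.frame(gene_a = ga, gene_b = gb,
                      score = as.integer(links$score),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
    methods::new("GeneLinkSet", links = out)
}

#' @describeIn GeneLinkSet the canonical link table.
#' @param x a GeneLinkSet
#' @export
setMethod("linkTable", "GeneLinkSet", function(x) x@links)

setMethod("show", "GeneLinkSet", function(object) {
    cat("GeneLinkSet with", nrow(object@links), "links among",
        length(unique(c(object@links$gene_a, object@links$gene_b))),
        "genes\n")
})

#' Read a STRING-style interaction table
#'
#' Tab-separated columns `gene_a`, `gene_b`, `combined_score` (0-1000).
#' An optional two-column protein-to-gene map (`protein_id`, `gene_id`) is
#' applied to both endpoints first; unmapped endpoints drop the link with a
#' warning. Duplicate pairs after mapping keep the highest score.
#'
#' @param path interaction TSV.
#' @param mapPath optional protein-to-gene map TSV.
#' @return A \linkS4class{GeneLinkSet}.
#' @export
readInteractions <- function(path, mapPath = NULL) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b", "combined_score") %in% colnames(tab)))
        stop("interaction file needs columns gene_a, gene_b, combined_score")
    if (!is.null(mapPath)) {
        mp <- utils::read.delim(mapPath, stringsAsFactors = FALSE)
        idx <- stats::setNames(as.character(mp[[2L]]), as.character(mp[[1L]]))
        tab$gene_a <- unname(idx[tab$gene_a])
        tab$gene_b <- unname(idx[tab$gene_b])
        bad <- is.na(tab$gene_a) | is.na(tab$gene_b)
        if (any(bad)) {
            warning(sum(bad), " link(s) dropped: endpoint not in the map")
            tab <- tab[!bad, , drop = FALSE]
        }
    }
    a <- pmin(tab$gene_a, tab$gene_b); b <- pmax(tab$gene_a, tab$gene_b)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -tab$combined_score)
    keep <- ord[!duplicated(key[ord])]
    GeneLinkSet(data.frame(gene_a = a[keep], gene_b = b[keep],
                           score = tab$combined_score[keep],
                           stringsAsFactors = FALSE))
}

#' Write / read a gene ranking
#'
#' Tab-separated columns: condition_id, rank, gene_id, score, method.
#'
#' @param ranking a \linkS4class{GeneRanking}
#' @param path output path
#' @return `writeRanking` invisibly returns `path`; `readRanking` returns
#'   the \linkS4class{GeneRanking}.
#' @export
writeRanking <- function(ranking, path) {
    tb <- ranking@table
    df <- data.frame(condition_id = rep(ranking@conditionId, nrow(tb)),
                     rank = seq_len(nrow(tb)),
                     gene_id = tb$gene_id,
                     score = tb$score,
                     method = rep(ranking@method, nrow(tb)),
                     stringsAsFactors = FALSE)
    if (!nrow(df))  # header-only file for an empty ranking
        df <- df[0L, , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRanking
#' @export
readRanking <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    cond <- if (nrow(df)) df$condition_id[1L] else "global"
    meth <- if (nrow(df)) df$method[1L] else "unknown"
    methods::new("GeneRanking", conditionId = as.character(cond),
                 method = as.character(meth),
                 table = data.frame(gene_id = as.character(df$gene_id),
                                    score = as.numeric(df$score),
                                    stringsAsFactors = FALSE))
}

#' Write / read a cross-validation result table
#'
#' Tab-separated columns: repetition, fold, test_condition,
#' predicted_condition, correct, n_genes, method.
#'
#' @param res a \linkS4class{CVResult}
#' @param path output path
#' @return `writeCVResult` invisibly returns `path`; `readCVResult` returns
#'   a \linkS4class{CVResult} with accuracies recomputed from the table.
#' @export
writeCVResult <- function(res, path) {
    utils::write.table(res@predictions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCVResult
#' @export
readCVResult <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$correct <- as.logical(df$correct)
    .summarizeCV(df, methods::new("CVConfig"))
}
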