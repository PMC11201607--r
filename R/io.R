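#' Read a tab-delimited methylation count table
#'
#' The count table has columns \code{chrom}, \code{pos}, then one
#' \code{<sample>.y} / \code{<sample>.n} column pair per sample (an
#' optional \code{strand} column is carried through untouched).  The
#' metadata table has columns \code{sample_id}, \code{group} and any
#' further covariate columns.  Rows are sorted by position; entries with
#' \code{n = 0} or \code{NA} are flagged missing; a row with \eqn{y > n}
#' or a duplicated position is a hard error.
#'
#' @param path count table path.
#' @param metadataPath sample metadata path.
#' @return A \linkS4class{MethylCounts} object (metadata in
#'   \code{colData}).
#' @seealso \code{\link{writeCountTable}}, \code{\link{readBedGraphs}}
#' @export
readCountTable <- function(path, metadataPath) {
    tab <- read.delim(path, check.names = FALSE)
    meta <- read.delim(metadataPath, check.names = FALSE)
    if (!all(c("chrom", "pos") %in% colnames(tab)))
        stop("count table must have 'chrom' and 'pos' columns")
    if (!all(c("sample_id", "group") %in% colnames(meta)))
        stop("metadata must have 'sample_id' and 'group' columns")
    ycols <- grep("\\.y$", colnames(tab), value = TRUE)
    ncols <- grep("\\.n$", colnames(tab), value = TRUE)
    ids <- sub("\\.y$", "", ycols)
    if (!setequal(ids, sub("\\.n$", "", ncols)))
        stop("unpaired y/n columns in count table")
    if (!setequal(ids, meta$sample_id))
        stop("sample mismatch between count table and metadata")
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    o <- order(tab$pos)
    tab <- tab[o, , drop = FALSE]
    if (anyDuplicated(tab$pos))
        stop(sprintf("duplicate position %d in count table",
                     tab$pos[which(duplicated(tab$pos))[1L]]))
    y <- as.matrix(tab[, paste0(ids, ".y"), drop = FALSE])
    n <- as.matrix(tab[, paste0(ids, ".n"), drop = FALSE])
    obs <- !(is.na(y) | is.na(n))
    bad <- which(obs & y > n)
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(y))
        stop(sprintf("y > n at position %d, sample '%s'",
                     tab$pos[rc[1L]], ids[rc[2L]]))
    }
    sd <- data.frame(group = meta$group, row.names = meta$sample_id)
    for (cc in setdiff(colnames(meta), c("sample_id", "group")))
        sd[[cc]] <- meta[[cc]]
    mc <- MethylCounts(tab$pos, y, n, sd, chrom = tab$chrom[1L])
    if ("strand" %in% colnames(tab))
        metadata(mc)$strand <- tab$strand
    mc
}

#' Write a MethylCounts object as a count table + metadata
#'
#' Inverse of \code{\link{readCountTable}}: a round trip reproduces the
#' counts and missing mask bit-exactly (missing entries are written as
#' \code{y = 0, n = 0}).
#'
#' @param x a \linkS4class{MethylCounts} object.
#' @param path count table path to write.
#' @param metadataPath metadata path to write (optional).
#' @return Invisibly, \code{path}.
#' @export
writeCountTable <- function(x, path, metadataPath = NULL) {
    ids <- colnames(x)
    y <- methReads(x); n <- totalReads(x)
    out <- data.frame(chrom = as.character(seqnames(x)),
                      pos = start(rowRanges(x)), check.names = FALSE)
    for (i in seq_along(ids)) {
        out[[paste0(ids[i], ".y")]] <- y[, i]
        out[[paste0(ids[i], ".n")]] <- n[, i]
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metadataPath)) {
        cd <- as.data.frame(colData(x))
        md <- cbind(data.frame(sample_id = ids), cd)
        write.table(md, metadataPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}

#' Read per-sample bedGraph-like coverage files
#'
#' Each file holds one sample with columns \code{chrom}, \code{start}
#' (0-based), \code{end}, \code{y}, \code{n}.  Files are merged by
#' position (union of positions, missing where a sample has no record).
#'
#' @param paths named character vector of file paths; names are the
#'   sample ids.
#' @param sampleData data.frame with one row per sample (rownames =
#'   sample ids) including the \code{group} column.
#' @return A \linkS4class{MethylCounts} object.
#' @export
readBedGraphs <- function(paths, sampleData) {
    if (is.null(names(paths)))
        stop("'paths' must be named by sample id")
    per <- lapply(paths, function(p) {
        b <- read.delim(p, header = FALSE)
        colnames(b)[1:5] <- c("chrom", "start", "end", "y", "n")
        b$pos <- b$start + 1L   # BED is 0-based half-open
        b
    })
    chrom <- per[[1L]]$chrom[1L]
    pos <- sort(unique(unlist(lapply(per, `[[`, "pos"))))
    M <- length(paths)
    y <- matrix(0, length(pos), M); n <- matrix(0, length(pos), M)
    for (i in seq_len(M)) {
        idx <- match(per[[i]]$pos, pos)
        y[idx, i] <- per[[i]]$y
        n[idx, i] <- per[[i]]$n
    }
    sampleData <- sampleData[names(paths), , drop = FALSE]
    MethylCounts(pos, y, n, sampleData, chrom = chrom)
}

#' Write DMC calls as a BED-like table
#'
#' One row per CpG and contrast, 0-based half-open single-base
#' intervals, with the posterior-mean logit contrast, credible bounds,
#' DMC flag and direction.  An empty result yields a header-only file.
#'
#' @param result a \linkS4class{DMCResult}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeDmcBed <- function(result, path) {
    header <- paste("#chrom", "start", "end", "contrast", "meanDiff",
                    "ciLower", "ciUpper", "dmc", "direction", sep = "\t")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(header, con)
    TT <- length(result@pos)
    if (TT == 0L || length(result@contrasts) == 0L) return(invisible(path))
    chrom <- as.character(seqnames(result@pos))
    pos <- start(result@pos)
    for (j in seq_along(result@contrasts)) {
        dirj <- result@direction[, j]
        dirj[is.na(dirj)] <- "."
        df <- data.frame(chrom, pos - 1L, pos, result@contrasts[j],
                         signif(result@estimate[, j], 6),
                         signif(result@lower[, j], 6),
                         signif(result@upper[, j], 6),
                         as.integer(result@dmc[, j]), dirj)
        write.table(df, con, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Write posterior group methylation profiles
#'
#' TSV with one row per CpG and group: position, group, posterior mean
#' methylation level and credible bounds of the group-level curve.
#'
#' @param result a \linkS4class{DMCResult} (carries the group means).
#' @param fit the \linkS4class{MethylFit} the result came from (for the
#'   group-curve credible bounds).
#' @param path output path.
#' @param alpha credible level for the profile bounds.
#' @return Invisibly, \code{path}.
#' @export
writePosteriorProfiles <- function(result, fit, path, alpha = 0.05) {
    gl <- colnames(result@groupMeans)
    pos <- start(result@pos)
    qs <- groupCurveQuantiles(fit, c(alpha / 2, 1 - alpha / 2))
    out <- do.call(rbind, lapply(seq_along(gl), function(g) {
        data.frame(pos = pos, group = gl[g],
                   betaMean = signif(result@groupMeans[, g], 6),
                   ciLower = signif(plogis(qs[, g, 1L]), 6),
                   ciUpper = signif(plogis(qs[, g, 2L]), 6))
    }))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
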