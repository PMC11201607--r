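# ---- end-to-end pipeline entry points ---------------------------------
#
# These functions tie the package together for scripted use (a thin
# Rscript wrapper lives in inst/scripts/methylfr.R).  Every run writes a
# config echo (with the seed and package version) to the output
# directory so results are reproducible from the echo alone.

writeConfigEcho <- function(outDir, config) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    config$package <- as.character(packageVersion("methylFR"))
    lines <- vapply(names(config), function(k)
        sprintf("%s: %s", k, paste(format(config[[k]]), collapse = ",")),
        "")
    writeLines(lines, file.path(outDir, "config.txt"))
}

#' Fit pipeline: counts in, DMC tables out
#'
#' Reads a count table and metadata, fits the partitioned model, and
#' writes per-alpha DMC BED files (\code{dmc_<alpha>.bed}), a posterior
#' profile TSV, per-alpha call summaries and a config echo into
#' \code{outDir}.  Draws are reused across the alpha levels, so the
#' call sets are nested by construction.
#'
#' @param countsFile,metadataFile input paths
#'   (see \code{\link{readCountTable}}).
#' @param outDir output directory.
#' @param p spline resolution.
#' @param partitionSize region size.
#' @param prior \code{"common"} or \code{"invgamma"}; \code{tau} NULL =
#'   empirical Bayes.
#' @param tau optional prior scale.
#' @param alphas credible levels (repeatable).
#' @param nIter,burnin,thin,strategy,seed,workers chain settings.
#' @param covariates covariate column names.
#' @param depthCovariate include the log(n+1) depth covariate.
#' @return The \linkS4class{MethylFit}, invisibly.
#' @export
runFitPipeline <- function(countsFile, metadataFile, outDir,
                           p = 30L, partitionSize = 500L,
                           prior = c("common", "invgamma"), tau = NULL,
                           alphas = 0.05, nIter = 15000L,
                           burnin = 5000L, thin = 10L,
                           strategy = "gauss", seed = 1L, workers = 1L,
                           covariates = character(),
                           depthCovariate = TRUE) {
    prior <- match.arg(prior)
    counts <- readCountTable(countsFile, metadataFile)
    cfg <- chainConfig(nIter = nIter, burnin = burnin, thin = thin,
                       seed = seed, strategy = strategy)
    if (is.null(tau)) ps <- estimateTau(counts)
    else ps <- priorSpec(tau = tau)
    if (prior == "invgamma") {
        basis0 <- splineBasis(
            start(rowRanges(counts))[seq_len(min(nrow(counts), partitionSize))],
            p)
        sub0 <- counts[seq_len(min(nrow(counts), partitionSize)), ]
        lay0 <- designLayout(basis0, sub0,
                             depthCovariate = depthCovariate,
                             covariates = covariates)
        ps <- estimateInvGamma(sub0, lay0, tau0 = ps@tau)
    }
    writeConfigEcho(outDir, list(
        subcommand = "fit", counts = countsFile,
        metadata = metadataFile, p = p, partitionSize = partitionSize,
        prior = prior, tau = ps@tau, alphas = alphas, nIter = nIter,
        burnin = burnin, thin = thin, strategy = strategy, seed = seed,
        workers = workers, covariates = covariates))
    fit <- runPartitioned(counts, p = p, prior = ps, config = cfg,
                          partitionSize = partitionSize,
                          workers = workers,
                          depthCovariate = depthCovariate,
                          covariates = covariates)
    for (a in alphas) {
        res <- callDMCs(fit, alpha = a)
        tag <- format(a, scientific = TRUE)
        writeDmcBed(res, file.path(outDir, sprintf("dmc_%s.bed", tag)))
        write.table(summarizeCalls(res),
                    file.path(outDir, sprintf("summary_%s.tsv", tag)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        if (a == alphas[[1L]])
            writePosteriorProfiles(res, fit,
                                   file.path(outDir, "profiles.tsv"),
                                   alpha = a)
    }
    invisible(fit)
}

#' Simulation pipeline: write replicate datasets with truth
#'
#' @param design \code{"example1"} .. \code{"example4"}.
#' @param reps number of replicate datasets.
#' @param outDir output directory; per replicate r writes
#'   \code{rep<r>_counts.tsv}, \code{rep<r>_metadata.tsv} and
#'   \code{rep<r>_truth.tsv} (per-CpG true label and group curves).
#' @param seed master seed; replicate r uses \code{seed + r - 1}.
#' @param ... passed to the design generator.
#' @return Invisibly, \code{outDir}.
#' @export
runSimulatePipeline <- function(design = c("example1", "example2",
                                           "example3", "example4"),
                                reps = 1L, outDir, seed = 1L, ...) {
    design <- match.arg(design)
    gen <- switch(design, example1 = simulateExample1,
                  example2 = simulateExample2,
                  example3 = simulateExample3,
                  example4 = simulateExample4)
    writeConfigEcho(outDir, list(subcommand = "simulate",
                                 design = design, reps = reps,
                                 seed = seed))
    for (r in seq_len(reps)) {
        sim <- gen(seed = seed + r - 1L, ...)
        writeCountTable(sim$counts,
                        file.path(outDir, sprintf("rep%d_counts.tsv", r)),
                        file.path(outDir, sprintf("rep%d_metadata.tsv", r)))
        tr <- data.frame(pos = start(rowRanges(sim$counts)),
                         dmc = as.integer(sim$truth@dmc),
                         group1 = signif(sim$truth@group1, 6),
                         group2 = signif(sim$truth@group2, 6))
        write.table(tr, file.path(outDir, sprintf("rep%d_truth.tsv", r)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(sim$truth@dmrs,
                    file.path(outDir, sprintf("rep%d_dmrs.tsv", r)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(outDir)
}

#' Evaluation pipeline: score call files against truth files
#'
#' Reads a DMC BED file (as written by the fit pipeline) and the truth
#' files (as written by the simulate pipeline) and writes a metrics TSV.
#'
#' @param callsBed path to the BED-like DMC table.
#' @param truthFile per-CpG truth TSV.
#' @param dmrFile DMR table TSV.
#' @param outFile metrics TSV path.
#' @return The one-row metrics \code{data.frame}, invisibly.
#' @export
runEvaluatePipeline <- function(callsBed, truthFile, dmrFile, outFile) {
    bed <- read.delim(callsBed, comment.char = "#", header = FALSE)
    colnames(bed)[1:9] <- c("chrom", "start", "end", "contrast", "est",
                            "lo", "hi", "dmc", "dir")
    tr <- read.delim(truthFile)
    dm <- read.delim(dmrFile)
    calls <- vapply(split(bed$dmc == 1, bed$start), any, TRUE)
    calls <- calls[match(tr$pos - 1L, as.integer(names(calls)))]
    calls[is.na(calls)] <- FALSE
    truth <- makeTruth(tr$group1, tr$group2, dm)
    metrics <- evaluateCalls(calls, truth)
    write.table(metrics, outFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(metrics)
}
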