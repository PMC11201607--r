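#' Call differentially methylated cytosines from posterior draws
#'
#' For every CpG and every requested group contrast, computes the
#' equal-tailed \eqn{(\alpha/2, 1-\alpha/2)} quantile interval of the
#' posterior draws of the logit-scale contrast curve
#' \eqn{x_t(\delta_g - \delta_{g'})} (contrasts against the baseline use
#' \eqn{\delta_g} directly since \eqn{\delta_1 \equiv 0}).  A contrast
#' flags the CpG when its interval excludes zero; the CpG is an overall
#' DMC when at least one contrast flags it.  Direction is the sign of
#' the posterior-mean contrast: \code{"hyper"} when the first group of
#' the pair is more methylated.  With \eqn{G} groups and no contrast
#' list, all \eqn{G(G-1)/2} pairs are evaluated.  No multiplicity
#' correction beyond the choice of \eqn{\alpha} is applied; stringency
#' is controlled through \eqn{\alpha} (e.g. 0.05, 1e-5, 1e-8), and
#' equal-tailed intervals make the calls nest across \eqn{\alpha}.
#'
#' @param object a \linkS4class{MethylFit} (or a single
#'   \linkS4class{PosteriorDraws}).
#' @param alpha credible level in (0, 1).
#' @param contrasts list of character pairs \code{c(group, refGroup)};
#'   NULL = all pairs.
#' @param ... unused.
#' @return A \linkS4class{DMCResult}.
#' @aliases dmcCalls
#' @export
setMethod("callDMCs", "MethylFit", function(object, alpha = 0.05,
                                            contrasts = NULL, ...) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
        alpha >= 1)
        stop("alpha must be a single value in (0, 1)")
    gl <- levels(sampleGroups(object@counts))
    G <- length(gl)
    if (G < 2L) stop("DMC calling needs at least two groups")
    if (is.null(contrasts)) {
        contrasts <- list()
        for (a in seq_len(G)) for (b in seq_len(G))
            if (a > b) contrasts[[length(contrasts) + 1L]] <- c(gl[a], gl[b])
    }
    for (ct in contrasts)
        if (!all(ct %in% gl))
            stop(sprintf("unknown group in contrast %s vs %s", ct[1L], ct[2L]))
    C <- length(contrasts)
    cn <- vapply(contrasts, function(ct) paste0(ct[1L], ".vs.", ct[2L]), "")
    TT <- nrow(object@counts)
    est <- low <- upp <- matrix(NA_real_, TT, C,
                                dimnames = list(NULL, cn))
    pm <- posteriorMeans(object)
    grp <- sampleGroups(object@counts)
    gm <- vapply(gl, function(g)
        rowMeans(pm[, grp == g, drop = FALSE]), numeric(TT))
    for (k in seq_along(object@results)) {
        r <- object@results[[k]]
        if (is.null(r)) next
        idx <- regionIndices(object@partition, k)
        for (j in seq_len(C)) {
            ga <- match(contrasts[[j]][1L], gl)
            gb <- match(contrasts[[j]][2L], gl)
            d <- matrix(r@groupCurves[, ga, ] - r@groupCurves[, gb, ],
                        nrow = length(idx))
            est[idx, j] <- rowMeans(d)
            qs <- t(apply(d, 1L, quantile,
                          probs = c(alpha / 2, 1 - alpha / 2),
                          names = FALSE))
            low[idx, j] <- qs[, 1L]
            upp[idx, j] <- qs[, 2L]
        }
    }
    dmc <- (low > 0 | upp < 0)
    dmc[is.na(dmc)] <- FALSE
    dir <- matrix(NA_character_, TT, C, dimnames = list(NULL, cn))
    dir[dmc & est > 0] <- "hyper"
    dir[dmc & est <= 0] <- "hypo"
    new("DMCResult", pos = rowRanges(object@counts), contrasts = cn,
        alpha = alpha, estimate = est, lower = low, upper = upp,
        dmc = dmc, direction = dir, groupMeans = gm)
})

#' @rdname callDMCs
#' @export
setMethod("dmcCalls", "DMCResult", function(object) {
    as.vector(rowSums(object@dmc) > 0)
})

setMethod("show", "DMCResult", function(object) {
    cat(sprintf("DMCResult: %d CpGs, %d contrast(s), alpha = %g\n",
                length(object@pos), length(object@contrasts),
                object@alpha))
    ov <- dmcCalls(object)
    cat(sprintf("  overall DMCs: %d (%.2f%%)\n", sum(ov),
                100 * mean(ov)))
})

#' Summarize DMC calls per contrast
#'
#' One row per contrast plus an "All positions" overall row, with the
#' percentage of non-DMCs and DMCs and, among DMCs, the percentage
#' hyper- and hypomethylated (NA, printed as a dash, when a contrast
#' has no DMCs; the overall row has no single direction).
#'
#' @param object a \linkS4class{DMCResult}.
#' @return A \code{data.frame} with columns \code{contrast},
#'   \code{ndmc_pct}, \code{dmc_pct}, \code{hyper_pct}, \code{hypo_pct}.
#' @export
setMethod("summarizeCalls", "DMCResult", function(object) {
    rows <- lapply(seq_along(object@contrasts), function(j) {
        f <- object@dmc[, j]
        nd <- sum(f)
        data.frame(contrast = object@contrasts[j],
                   ndmc_pct = 100 * mean(!f),
                   dmc_pct = 100 * mean(f),
                   hyper_pct = if (nd)
                       100 * sum(object@direction[, j] == "hyper",
                                 na.rm = TRUE) / nd else NA_real_,
                   hypo_pct = if (nd)
                       100 * sum(object@direction[, j] == "hypo",
                                 na.rm = TRUE) / nd else NA_real_)
    })
    ov <- dmcCalls(object)
    rows[[length(rows) + 1L]] <-
        data.frame(contrast = "All positions",
                   ndmc_pct = 100 * mean(!ov), dmc_pct = 100 * mean(ov),
                   hyper_pct = NA_real_, hypo_pct = NA_real_)
    do.call(rbind, rows)
})
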