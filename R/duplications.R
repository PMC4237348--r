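## Large collapsed repeat / segmental duplication detection from coverage.

#' Flag large collapsed repeats / segmental duplications
#'
#' Scans each scaffold in fixed windows for contiguous stretches whose
#' fragment+unpaired valid coverage is at least \code{dupCoverageRatio}
#' times the per-scaffold median baseline; runs longer than
#' \code{dupMinLength} are reported with their mean coverage ratio.
#' Long-insert coverage is excluded (it is far more variable across
#' genomes), and nothing is modified: these regions are report-only.
#'
#' @param pileups A \linkS4class{PileupTable} (fragment/unpaired coverage is
#'   tracked separately during accumulation).
#' @param config A \linkS4class{PolishConfig}.
#' @return data.frame: scaffold, start, end (0-based half-open), meanRatio.
#' @export
detectLargeDuplications <- function(pileups, config = polishConfig()) {
    out <- list()
    w <- config@dupWindow
    for (scaf in names(pileups@scaffolds)) {
        cov <- pileups@scaffolds[[scaf]]$fragCov
        L <- length(cov)
        if (L < w) next
        baseline <- stats::median(cov)
        if (baseline <= 0) next
        nw <- L %/% w
        wm <- vapply(seq_len(nw), function(i)
            mean(cov[((i - 1L) * w + 1L):(i * w)]), 0)
        hot <- wm >= config@dupCoverageRatio * baseline
        if (!any(hot)) next
        r <- rle(hot)
        endsAt <- cumsum(r$lengths)
        startsAt <- endsAt - r$lengths + 1L
        for (j in which(r$values)) {
            runLen <- r$lengths[j] * w
            if (runLen <= config@dupMinLength) next
            st <- (startsAt[j] - 1L) * w
            en <- endsAt[j] * w
            out[[length(out) + 1L]] <- data.frame(
                scaffold = scaf, start = st, end = en,
                meanRatio = mean(wm[startsAt[j]:endsAt[j]]) / baseline,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(scaffold = character(), start = integer(),
                          end = integer(), meanRatio = numeric(),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}
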