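## Discontiguity scanning: flag regions where alignments contradict the
## input genome's contiguity, and assemble the reassembly work list.

runningMax <- function(x, w) {
    ## max over a centered window of half-width w (used for drop detection)
    n <- length(x)
    out <- x
    if (n == 0 || w <= 0) return(out)
    ## coarse but adequate: compare against max of shifted copies at a few lags
    lags <- unique(pmin(w, c(seq_len(min(w, 32L)), round(seq(1, w, length.out = 16)))))
    for (l in lags) {
        out <- pmax(out, data.table::shift(x, l, fill = 0),
                    data.table::shift(x, -l, fill = 0))
    }
    out
}

#' Flag suspicious regions from pileup discontiguity signals
#'
#' Four heuristics seed suspicious positions: (i) a large fraction of
#' covering reads soft-clipped at a position, (ii) a large ratio of invalid
#' to valid reads, (iii) extremely low valid coverage relative to the
#' scaffold mean, and (iv) a rapid coverage drop within one read length.
#' Clusters of Ambiguous bases also seed regions when classifications are
#' supplied. Seeds within one modal read length merge into one region,
#' padded by the flank trim.
#'
#' Positions inside N-gaps, or within one read length of a scaffold end or
#' gap edge, are excluded from the low-coverage and drop heuristics
#' (coverage necessarily ramps there); gaps enter the reassembly work list
#' through their own trigger.
#'
#' @param pileups A \linkS4class{PileupTable}.
#' @param genome An \linkS4class{InputGenome}.
#' @param config A \linkS4class{PolishConfig}.
#' @param classifications optional output of \code{\link{classifyBases}} for
#'   ambiguous-cluster seeding.
#' @param stats optional list of \linkS4class{LibraryStats}; when given, the
#'   end/gap exclusion margin for coverage heuristics grows to the widest
#'   paired insert span (coverage ramps over a template length, not a read
#'   length, at sequence boundaries).
#' @return \link[GenomicRanges]{GRanges} of regions with metadata columns
#'   \code{triggers} (comma-joined) and \code{status} ("pending").
#' @export
flagSuspiciousRegions <- function(pileups, genome, config = polishConfig(),
                                  classifications = NULL, stats = NULL) {
    grs <- list()
    rlm <- pileups@readLengthMode
    margin <- 2L * rlm
    if (!is.null(stats)) {
        ## coverage deficiency near an end is dominated by the library with
        ## the smallest template span; wider libraries only shave a fraction
        spans <- vapply(stats, function(s)
            if (is.na(s@insertMean)) Inf else s@insertMean + 3 * s@insertSd, 0)
        if (any(is.finite(spans)))
            margin <- as.integer(max(margin, min(spans)))
    }
    gt <- gapTable(genome)
    for (scaf in names(pileups@scaffolds)) {
        P <- pileups@scaffolds[[scaf]]
        L <- length(P$validCov)
        edgeOK <- rep(TRUE, L)
        if (L > 2 * margin) {
            edgeOK[seq_len(margin)] <- FALSE
            edgeOK[(L - margin + 1L):L] <- FALSE
        } else edgeOK[] <- FALSE
        gsub_ <- gt[gt$scaffold == scaf, , drop = FALSE]
        for (j in seq_len(nrow(gsub_))) {
            lo <- max(1L, gsub_$start[j] - rlm + 1L)
            hi <- min(L, gsub_$end[j] + rlm)
            edgeOK[lo:hi] <- FALSE
        }
        clip <- P$clipStarts / pmax(1L, P$totalCov) >=
            config@clipFractionThreshold & P$clipStarts >= 5L
        invalid <- P$badCov / pmax(1L, P$validCov) >=
            config@invalidRatioThreshold & P$badCov >= 5L
        scafMean <- mean(P$validCov[edgeOK | !any(edgeOK)])
        if (!is.finite(scafMean)) scafMean <- mean(P$validCov)
        low <- edgeOK & P$validCov < config@lowCoverageFraction * scafMean
        rmax <- runningMax(P$validCov, rlm)
        drop_ <- edgeOK & rmax > 0 &
            P$validCov <= (1 - config@coverageDropFraction) * rmax &
            P$validCov < scafMean * (1 - config@coverageDropFraction)
        amb <- rep(FALSE, L)
        if (!is.null(classifications) && !is.null(classifications[[scaf]])) {
            isAmb <- classifications[[scaf]]$category == "Ambiguous"
            if (any(isAmb)) {
                ai <- which(isAmb)
                ## >=3 Ambiguous within 50 bp
                cnt <- vapply(ai, function(p) sum(abs(ai - p) <= 50L), 0L)
                amb[ai[cnt >= 3L]] <- TRUE
            }
        }
        seeds <- which(clip | invalid | low | drop_ | amb)
        if (!length(seeds)) next
        ## merge seeds within one read length
        brk <- c(0L, which(diff(seeds) > rlm), length(seeds))
        for (b in seq_len(length(brk) - 1L)) {
            grp <- seeds[(brk[b] + 1L):brk[b + 1L]]
            trg <- character()
            if (any(clip[grp])) trg <- c(trg, "clip")
            if (any(invalid[grp])) trg <- c(trg, "invalid_pairs")
            if (any(low[grp])) trg <- c(trg, "low_coverage")
            if (any(drop_[grp])) trg <- c(trg, "coverage_drop")
            if (any(amb[grp])) trg <- c(trg, "ambiguous_cluster")
            st <- max(1L, min(grp) - config@flankTrim)
            en <- min(L, max(grp) + config@flankTrim)
            grs[[length(grs) + 1L]] <- data.frame(
                scaffold = scaf, start = st, end = en,
                triggers = paste(trg, collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(grs))
        return(GRanges(character(), IRanges(integer(), integer()),
                       triggers = character(), status = character()))
    df <- do.call(rbind, grs)
    GRanges(df$scaffold, IRanges(df$start, df$end),
            triggers = df$triggers, status = "pending")
}

#' Build the ordered local-reassembly work list
#'
#' Captured gaps are appended as regions with trigger "gap"; overlapping
#' regions are merged (triggers unioned); ordering is deterministic by
#' (scaffold, start).
#'
#' @param regions Output of \code{\link{flagSuspiciousRegions}}.
#' @param genome An \linkS4class{InputGenome}.
#' @return \link[GenomicRanges]{GRanges} work list with \code{triggers} and
#'   \code{status} columns.
#' @export
enumerateReassemblyTargets <- function(regions, genome) {
    g <- genome@gaps
    g <- g[mcols(g)$captured]
    if (length(g)) {
        gr2 <- GRanges(seqnames(g), ranges(g),
                       triggers = "gap", status = "pending")
        all_ <- c(regions, gr2)
    } else all_ <- regions
    if (!length(all_)) return(all_)
    red <- reduce(all_, with.revmap = TRUE)
    trig <- vapply(mcols(red)$revmap, function(i) {
        paste(sort(unique(unlist(strsplit(mcols(all_)$triggers[i], ",")))),
              collapse = ",")
    }, "")
    out <- GRanges(seqnames(red), ranges(red), triggers = trig,
                   status = "pending")
    out[order(as.character(seqnames(out)), start(out))]
}
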