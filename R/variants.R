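## Small-variant calling: indel left-normalization, tallying, and calls.

#' Shift an indel to its leftmost equivalent coordinate
#'
#' Indel alignments representing the same edit can appear at different
#' coordinates (in the genome ACCCCT, deleting any one C yields ACCCT).
#' Normalizing to the leftmost equivalent edit lets all observations of one
#' event be combined. The edited genome string is unchanged by normalization
#' and the operation is idempotent.
#'
#' @param genomeSeq Scaffold sequence (character scalar).
#' @param pos 0-based position: for a deletion, the first deleted base; for
#'   an insertion, the base before which the sequence is inserted.
#' @param kind "insertion" or "deletion".
#' @param seq Inserted or deleted bases.
#' @return list(pos, seq) of the leftmost equivalent edit.
#' @examples
#' normalizeIndelLeft("ACCCCT", 4, "deletion", "C")$pos  # 1
#' @export
normalizeIndelLeft <- function(genomeSeq, pos, kind, seq) {
    n <- nchar(seq)
    stopifnot(n > 0)
    if (kind == "deletion") {
        if (pos + n > nchar(genomeSeq))
            stop("deletion extends past scaffold end")
        if (substring(genomeSeq, pos + 1L, pos + n) != seq)
            stop("deletion sequence does not match the genome")
        while (pos > 0L &&
               substring(genomeSeq, pos, pos) ==
               substring(genomeSeq, pos + n, pos + n)) {
            pos <- pos - 1L
        }
        list(pos = pos, seq = substring(genomeSeq, pos + 1L, pos + n))
    } else {
        while (pos > 0L &&
               substring(genomeSeq, pos, pos) == substring(seq, n, n)) {
            seq <- paste0(substring(genomeSeq, pos, pos),
                          substring(seq, 1L, n - 1L))
            pos <- pos - 1L
        }
        list(pos = pos, seq = seq)
    }
}

#' Normalize and merge raw indel observations
#'
#' Every raw observation is shifted to its leftmost equivalent edit, then
#' observations of the same (scaffold, position, kind, sequence) are merged;
#' support is the number of distinct contributing reads.
#'
#' @param observations Raw observation data.frame from
#'   \code{\link{accumulatePileups}} (columns scaffold, pos, kind, seq,
#'   qname, weight).
#' @param genome An \linkS4class{InputGenome}.
#' @return data.frame with columns scaffold, pos, kind, seq, supportCount,
#'   supportWeight, sorted by (scaffold, pos).
#' @export
tallyIndels <- function(observations, genome) {
    empty <- data.frame(scaffold = character(), pos = integer(),
                        kind = character(), seq = character(),
                        supportCount = integer(), supportWeight = numeric(),
                        stringsAsFactors = FALSE)
    if (nrow(observations) == 0) return(empty)
    lens <- scaffoldLengths(genome)
    rows <- vector("list", nrow(observations))
    drop <- logical(nrow(observations))
    for (scaf in unique(observations$scaffold)) {
        gseq <- scaffoldSeq(genome, scaf)
        idx <- which(observations$scaffold == scaf)
        for (i in idx) {
            o <- observations[i, ]
            if (o$kind == "deletion" &&
                (o$pos + nchar(o$seq) > lens[[scaf]] ||
                 substring(gseq, o$pos + 1L, o$pos + nchar(o$seq)) != o$seq)) {
                drop[i] <- TRUE
                next
            }
            nrm <- normalizeIndelLeft(gseq, o$pos, o$kind, o$seq)
            rows[[i]] <- data.frame(scaffold = scaf, pos = nrm$pos,
                                    kind = o$kind, seq = nrm$seq,
                                    qname = o$qname, weight = o$weight,
                                    stringsAsFactors = FALSE)
        }
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) return(empty)
    dt <- data.table::rbindlist(rows)
    agg <- dt[, list(supportCount = length(unique(qname)),
                     supportWeight = sum(weight)),
              by = c("scaffold", "pos", "kind", "seq")]
    agg <- as.data.frame(agg[order(agg$scaffold, agg$pos), ])
    agg
}

## mean valid coverage over the reference footprint of an event
localValidCoverage <- function(pileups, scaffold, pos, kind, len) {
    vc <- pileups@scaffolds[[scaffold]]$validCov
    if (kind == "deletion") {
        span <- seq.int(pos + 1L, min(pos + len, length(vc)))
    } else {
        span <- max(pos, 1L)        # left flanking base, 1-based index pos
    }
    mean(vc[span])
}

#' Call small insertions and deletions by valid-read majority
#'
#' An event is called when its distinct-read support reaches half the local
#' valid coverage; for events longer than \code{longIndelLength} the
#' threshold is lowered to \code{longIndelFraction} (longer indels are harder
#' for aligners to represent, so fewer reads show them).
#'
#' @param tally Normalized tally from \code{\link{tallyIndels}}.
#' @param pileups A \linkS4class{PileupTable}.
#' @param config A \linkS4class{PolishConfig}.
#' @return data.frame of calls: scaffold, pos (0-based), kind, ref, alt,
#'   seq, qual, qd.
#' @export
callSmallIndels <- function(tally, pileups, config = polishConfig()) {
    empty <- data.frame(scaffold = character(), pos = integer(),
                        kind = character(), seq = character(),
                        qual = numeric(), qd = numeric(),
                        stringsAsFactors = FALSE)
    if (nrow(tally) == 0) return(empty)
    keep <- logical(nrow(tally))
    qual <- numeric(nrow(tally))
    qd <- numeric(nrow(tally))
    for (i in seq_len(nrow(tally))) {
        ev <- tally[i, ]
        len <- nchar(ev$seq)
        lc <- localValidCoverage(pileups, ev$scaffold, ev$pos, ev$kind, len)
        if (lc <= 0) next
        thr <- if (len <= config@longIndelLength) 0.5 else
            config@longIndelFraction
        frac <- ev$supportCount / lc
        if (frac >= thr) {
            keep[i] <- TRUE
            perRead <- ev$supportWeight / max(1, ev$supportCount)
            opposing <- max(0, (lc - ev$supportCount)) * perRead
            qual[i] <- max(0, min(2000, 10 * log10(
                (1 + ev$supportWeight) / (1 + opposing)) * 10))
            qd[i] <- qual[i] / lc
        }
    }
    out <- tally[keep, c("scaffold", "pos", "kind", "seq"), drop = FALSE]
    out$qual <- qual[keep]
    out$qd <- qd[keep]
    rownames(out) <- NULL
    out
}

#' Turn base classifications into SNP calls and base fixes
#'
#' Every Changed position yields both a fix (applied to the output genome)
#' and a SNP call. Ambiguous positions are reported (with an ambiguity
#' annotation in the VCF) and are fixed to the top-weight allele only when
#' \code{fixAmbiguous} is on.
#'
#' @param genome An \linkS4class{InputGenome}.
#' @param classifications Output of \code{\link{classifyBases}}.
#' @param config A \linkS4class{PolishConfig}.
#' @return list with \code{calls} (data.frame: scaffold, pos, ref, alt, qual,
#'   qd, ambiguous) and \code{fixes} (data.frame: scaffold, pos, ref, alt,
#'   category).
#' @export
callSnps <- function(genome, classifications, config = polishConfig()) {
    calls <- list(); fixes <- list()
    for (scaf in names(classifications)) {
        cl <- classifications[[scaf]]
        gb <- strsplit(scaffoldSeq(genome, scaf), "")[[1]]
        ch <- which(cl$category == "Changed")
        if (length(ch)) {
            calls[[length(calls) + 1L]] <- data.frame(
                scaffold = scaf, pos = ch - 1L, ref = gb[ch],
                alt = cl$allele[ch], qual = cl$qual[ch], qd = cl$qd[ch],
                ambiguous = FALSE, stringsAsFactors = FALSE)
            fixes[[length(fixes) + 1L]] <- data.frame(
                scaffold = scaf, pos = ch - 1L, ref = gb[ch],
                alt = cl$allele[ch], category = "snp",
                stringsAsFactors = FALSE)
        }
        amb <- which(cl$category == "Ambiguous" & !is.na(cl$allele) &
                     cl$allele != gb[seq_len(nrow(cl))])
        if (length(amb)) {
            calls[[length(calls) + 1L]] <- data.frame(
                scaffold = scaf, pos = amb - 1L, ref = gb[amb],
                alt = cl$allele[amb], qual = cl$qual[amb], qd = cl$qd[amb],
                ambiguous = TRUE, stringsAsFactors = FALSE)
            if (config@fixAmbiguous)
                fixes[[length(fixes) + 1L]] <- data.frame(
                    scaffold = scaf, pos = amb - 1L, ref = gb[amb],
                    alt = cl$allele[amb], category = "ambiguous_fix",
                    stringsAsFactors = FALSE)
        }
    }
    emptyCalls <- data.frame(scaffold = character(), pos = integer(),
                             ref = character(), alt = character(),
                             qual = numeric(), qd = numeric(),
                             ambiguous = logical(), stringsAsFactors = FALSE)
    emptyFixes <- data.frame(scaffold = character(), pos = integer(),
                             ref = character(), alt = character(),
                             category = character(), stringsAsFactors = FALSE)
    list(calls = if (length(calls)) do.call(rbind, calls) else emptyCalls,
         fixes = if (length(fixes)) do.call(rbind, fixes) else emptyFixes)
}
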