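## Quality-weighted pileup accumulation and per-base classification.

BASES <- c("A", "C", "G", "T")

#' Evidence weight of one read base
#'
#' Each aligned base contributes its base quality scaled by the probability
#' that the read is correctly mapped: \code{bq * (1 - 10^(-mq/10))}. A read
#' with mapping quality 0 (equally likely to belong elsewhere) contributes
#' nothing; the weight is monotone nondecreasing in both qualities.
#'
#' @param baseQuality Phred base quality (vectorized).
#' @param mappingQuality Phred mapping quality (vectorized).
#' @return Numeric weight(s).
#' @examples
#' readWeight(30, 60)  # 30 * (1 - 1e-6)
#' readWeight(30, 0)   # 0
#' @export
readWeight <- function(baseQuality, mappingQuality) {
    stopifnot(all(baseQuality >= 0), all(mappingQuality >= 0))
    baseQuality * (1 - 10^(-mappingQuality / 10))
}

emptyScaffoldPileup <- function(L) {
    list(weights = matrix(0, L, 4, dimnames = list(NULL, BASES)),
         counts = matrix(0L, L, 4, dimnames = list(NULL, BASES)),
         delWeight = numeric(L), delCount = integer(L),
         validCov = integer(L), fragCov = integer(L),
         totalCov = integer(L), badCov = integer(L),
         clipStarts = integer(L), physCov = integer(L))
}

## add +1 over [start0, end0) half-open 0-based intervals via diff/cumsum
addCoverage <- function(vec, start0, end0) {
    L <- length(vec)
    s <- pmax(start0, 0L); e <- pmin(end0, L)
    ok <- s < e
    if (!any(ok)) return(vec)
    d <- integer(L + 1L)
    ds <- tabulate(s[ok] + 1L, nbins = L + 1L)
    de <- tabulate(e[ok] + 1L, nbins = L + 1L)
    vec + cumsum(ds - de)[seq_len(L)]
}

## scatter-add x into acc at 1-based idx (duplicates accumulate)
scatterAdd <- function(acc, idx, x) {
    rs <- rowsum(x, idx)
    at <- as.integer(rownames(rs))
    acc[at] <- acc[at] + rs[, 1L]
    acc
}

#' Accumulate per-position pileups and raw indel observations
#'
#' For every valid read (proper-paired, or from an unpaired library), each
#' aligned, non-clipped base outside the read-end trim adds its
#' \code{\link{readWeight}} to the allele weights. Reads in non-valid pairs
#' add only to \code{badCov}/\code{totalCov}. Deletion CIGAR ops add weight
#' over the deleted reference span; insertion/deletion events are also
#' recorded per read for the indel caller. Soft-clip boundaries increment
#' \code{clipStarts} at the transition coordinate, and proper-pair templates
#' add physical coverage over their full span.
#'
#' @param genome An \linkS4class{InputGenome}.
#' @param alignments A \linkS4class{PolishAlignments} or list of them.
#' @param config A \linkS4class{PolishConfig}.
#' @return list with elements \code{pileups} (\linkS4class{PileupTable}) and
#'   \code{indels} (data.frame of raw, un-normalized indel observations with
#'   columns scaffold, pos, kind, seq, qname, weight).
#' @export
accumulatePileups <- function(genome, alignments, config = polishConfig()) {
    if (is(alignments, "PolishAlignments")) alignments <- list(alignments)
    lens <- scaffoldLengths(genome)
    sc <- lapply(lens, emptyScaffoldPileup)
    indels <- list()
    trim <- config@flankTrim
    rlModes <- integer()
    for (aln in alignments) {
        rlModes <- c(rlModes, aln@stats@readLengthMode)
        rec <- aln@records
        rec <- rec[!rec$unmapped & !is.na(rec$pos) & !is.na(rec$cigar), ,
                   drop = FALSE]
        if (nrow(rec) == 0) next
        inBounds <- rec$rname %in% names(lens)
        spans <- cigarRefSpanFromOps(rec$cigar, "ref")
        fits <- inBounds & rec$pos >= 0 &
            rec$pos + spans <= lens[rec$rname]
        fits[is.na(fits)] <- FALSE
        if (any(!fits)) {
            warning(sum(!fits), " alignment(s) beyond scaffold bounds skipped")
            rec <- rec[fits, , drop = FALSE]
        }
        if (nrow(rec) == 0) next
        valid <- !rec$paired | rec$proper
        mapTerm <- 1 - 10^(-rec$mapq / 10)
        rl <- nchar(rec$seq)
        dt <- cigarOpTable(rec$cigar)
        qd <- decodeQuals(rec$qual)
        bd <- decodeBases(rec$seq)
        isFrag <- aln@kind != "long_insert"
        for (scaf in unique(rec$rname)) {
            ri <- which(rec$rname == scaf)
            L <- lens[[scaf]]
            P <- sc[[scaf]]
            sub <- dt[dt$rid %in% ri, ]
            pos0 <- rec$pos
            ## --- coverage over aligned (M and D) spans; a deletion op is
            ## part of the alignment, so spanning reads still count as
            ## coverage there (only clipped portions are excluded)
            cOps <- sub[sub$op %in% c("M", "=", "X", "D"), ]
            cst <- pos0[cOps$rid] + cOps$refOff
            cen <- cst + cOps$len
            cvsel <- valid[cOps$rid]
            P$totalCov <- addCoverage(P$totalCov, cst, cen)
            if (any(cvsel)) {
                P$validCov <- addCoverage(P$validCov, cst[cvsel], cen[cvsel])
                if (isFrag)
                    P$fragCov <- addCoverage(P$fragCov, cst[cvsel],
                                             cen[cvsel])
            }
            if (any(!cvsel))
                P$badCov <- addCoverage(P$badCov, cst[!cvsel], cen[!cvsel])
            mOps <- sub[sub$op %in% c("M", "=", "X"), ]
            vsel <- valid[mOps$rid]
            ## --- allele evidence from valid reads
            ev <- mOps[vsel, ]
            if (nrow(ev)) {
                n <- ev$len
                rid2 <- rep.int(ev$rid, n)
                within <- sequence(n)
                refp <- pos0[rid2] + rep.int(ev$refOff, n) + within - 1L
                qpos <- rep.int(ev$qOff, n) + within
                keep <- qpos > trim & qpos <= rl[rid2] - trim
                if (any(keep)) {
                    rid2 <- rid2[keep]; refp <- refp[keep]; qpos <- qpos[keep]
                    g <- qd$off[rid2] + qpos
                    b <- bd$b[g]
                    w <- qd$q[g] * mapTerm[rid2]
                    for (a in 1:4) {
                        s <- b == a
                        if (!any(s)) next
                        idx <- refp[s] + 1L
                        P$counts[, a] <- P$counts[, a] + tabulate(idx, nbins = L)
                        P$weights[, a] <- scatterAdd(P$weights[, a], idx, w[s])
                    }
                }
            }
            ## --- deletions (valid reads): positional + event
            dOps <- sub[sub$op == "D" & valid[sub$rid], ]
            if (nrow(dOps)) {
                dst <- pos0[dOps$rid] + dOps$refOff
                den <- dst + dOps$len
                qAfter <- pmin(pmax(dOps$qOff + 1L, 1L), rl[dOps$rid])
                wdel <- qd$q[qd$off[dOps$rid] + qAfter] * mapTerm[dOps$rid]
                P$delCount <- addCoverage(P$delCount, dst, den)
                n <- dOps$len
                rid2 <- rep.int(seq_len(nrow(dOps)), n)
                posv <- rep.int(dst, n) + sequence(n) - 1L
                P$delWeight <- scatterAdd(P$delWeight, posv + 1L, wdel[rid2])
                ## events away from read ends
                okEv <- dOps$qOff >= trim & dOps$qOff <= rl[dOps$rid] - trim
                if (any(okEv)) {
                    gseq <- scaffoldSeq(genome, scaf)
                    indels[[length(indels) + 1L]] <- data.frame(
                        scaffold = scaf,
                        pos = dst[okEv],
                        kind = "deletion",
                        seq = substring(gseq, dst[okEv] + 1L, den[okEv]),
                        qname = rec$qname[dOps$rid[okEv]],
                        weight = wdel[okEv],
                        stringsAsFactors = FALSE)
                }
            }
            ## --- insertions (valid reads): event only
            iOps <- sub[sub$op == "I" & valid[sub$rid], ]
            if (nrow(iOps)) {
                okEv <- iOps$qOff >= trim & iOps$qOff + iOps$len <= rl[iOps$rid] - trim
                iOps <- iOps[okEv, ]
                if (nrow(iOps)) {
                    wq <- vapply(seq_len(nrow(iOps)), function(j) {
                        g <- qd$off[iOps$rid[j]] + iOps$qOff[j] + seq_len(iOps$len[j])
                        mean(qd$q[g])
                    }, 0)
                    indels[[length(indels) + 1L]] <- data.frame(
                        scaffold = scaf,
                        pos = pos0[iOps$rid] + iOps$refOff,
                        kind = "insertion",
                        seq = substring(rec$seq[iOps$rid], iOps$qOff + 1L,
                                        iOps$qOff + iOps$len),
                        qname = rec$qname[iOps$rid],
                        weight = wq * mapTerm[iOps$rid],
                        stringsAsFactors = FALSE)
                }
            }
            ## --- soft-clip transitions
            sOps <- sub[sub$op == "S", ]
            if (nrow(sOps)) {
                lead <- sOps$qOff == 0L
                at <- ifelse(lead, pos0[sOps$rid],
                             pmin(pos0[sOps$rid] + sOps$refOff, L - 1L))
                at <- pmax(pmin(at, L - 1L), 0L)
                P$clipStarts <- P$clipStarts + tabulate(at + 1L, nbins = L)
            }
            ## --- physical coverage from proper templates (leftmost record)
            ph <- ri[rec$proper[ri] & !is.na(rec$isize[ri]) & rec$isize[ri] > 0]
            if (length(ph))
                P$physCov <- addCoverage(P$physCov, pos0[ph],
                                         pos0[ph] + rec$isize[ph])
            sc[[scaf]] <- P
        }
    }
    indels <- if (length(indels)) do.call(rbind, indels) else
        data.frame(scaffold = character(), pos = integer(), kind = character(),
                   seq = character(), qname = character(), weight = numeric(),
                   stringsAsFactors = FALSE)
    pt <- new("PileupTable", scaffolds = sc,
              readLengthMode = if (length(rlModes))
                  as.integer(stats::median(rlModes)) else 100L)
    list(pileups = pt, indels = indels)
}

#' Classify every genome base from its pileup
#'
#' Each base is Confirmed (the top-weight allele equals the genome base and
#' holds at least \code{changedFraction} of the weight), Changed (a different
#' allele holds that fraction), Ambiguous (a second allele holds at least
#' \code{ambiguousFraction}, or no allele reaches \code{changedFraction}), or
#' Unconfirmed (valid depth below the minimum, or no weighted evidence).
#' QUAL is a bounded log-ratio of top-versus-rest weight; QD is QUAL divided
#' by valid coverage.
#'
#' @param genome An \linkS4class{InputGenome}.
#' @param pileups A \linkS4class{PileupTable}.
#' @param config A \linkS4class{PolishConfig}.
#' @return Named list (per scaffold) of data.frames with columns
#'   \code{category}, \code{allele}, \code{qual}, \code{qd}.
#' @export
classifyBases <- function(genome, pileups, config = polishConfig()) {
    out <- list()
    for (scaf in names(pileups@scaffolds)) {
        P <- pileups@scaffolds[[scaf]]
        L <- length(P$validCov)
        gseq <- scaffoldSeq(genome, scaf)
        gb <- match(strsplit(gseq, "")[[1]], BASES)   # NA for N
        W <- P$weights
        tot <- W[, 1] + W[, 2] + W[, 3] + W[, 4]
        top <- max.col(W, ties.method = "first")
        wt <- W[cbind(seq_len(L), top)]
        ## detect exact top ties (two alleles sharing max weight)
        W2 <- W; W2[cbind(seq_len(L), top)] <- -Inf
        second <- max.col(W2, ties.method = "first")
        ws <- W[cbind(seq_len(L), second)]
        tie <- wt > 0 & ws == wt
        minDepth <- max(config@minDepth, ceiling(0.1 * mean(P$validCov)))
        f1 <- ifelse(tot > 0, wt / tot, 0)
        f2 <- ifelse(tot > 0, ws / tot, 0)
        cat_ <- rep("Ambiguous", L)
        cat_[tot == 0 | P$validCov < minDepth | is.na(gb)] <- "Unconfirmed"
        changed <- tot > 0 & P$validCov >= minDepth & !is.na(gb) &
            top != gb & f1 >= config@changedFraction & !tie
        confirmed <- tot > 0 & P$validCov >= minDepth & !is.na(gb) &
            top == gb & f1 >= config@changedFraction &
            f2 < config@ambiguousFraction
        cat_[changed] <- "Changed"
        cat_[confirmed] <- "Confirmed"
        qual <- pmax(0, pmin(2000, 10 * log10((1 + wt) / (1 + tot - wt)) * 10))
        qual[cat_ == "Unconfirmed"] <- 0
        qd <- ifelse(P$validCov > 0, qual / P$validCov, 0)
        allele <- BASES[top]
        allele[cat_ == "Unconfirmed"] <- NA_character_
        out[[scaf]] <- data.frame(
            category = cat_, allele = allele, qual = qual, qd = qd,
            stringsAsFactors = FALSE)
    }
    out
}
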