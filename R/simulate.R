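## Deterministic synthetic fixtures: genomes with planted features, mutated
## drafts with truth ledgers, simulated paired reads, and truth-projected
## alignments. Together these make the full pipeline testable with no
## external data or aligner. Single-scaffold fixtures (sufficient for every
## defect class the pipeline handles; scaffolds are independent anyway).

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Generate a synthetic genome with planted features
#'
#' I.i.d. uniform ACGT background with optional planted features: tandem
#' arrays (period x copies), dispersed repeat families (length, copies,
#' divergence), adjacent 2-copy duplications (for collapse fixtures), and
#' GC-skewed segments. Deterministic under \code{seed}.
#'
#' @param length Total genome length (>= 1000).
#' @param seed Integer seed.
#' @param repeats list of feature specs, each a list with \code{type}
#'   ("tandem", "dispersed", "duplication", "gc") and type-specific fields:
#'   tandem: \code{period}, \code{copies}, optional \code{at}; dispersed:
#'   \code{length}, \code{copies}, \code{divergence}; duplication:
#'   \code{length}, optional \code{at}; gc: \code{length}, \code{gc}.
#' @param name Scaffold name.
#' @return list(seq = named character, features = data.frame(type, start,
#'   end, period, copies)) with 0-based half-open feature coordinates.
#' @export
generateGenome <- function(length, seed = 1L, repeats = list(),
                           name = "scaffold1") {
    stopifnot(length >= 1000)
    set.seed(seed)
    s <- sample(BASES, length, replace = TRUE)
    feats <- list()
    cursor <- 1000L   # features auto-placed left to right from here
    place <- function(need) {
        at <- cursor
        cursor <<- cursor + need + 1000L
        if (cursor > length - 1000L) stop("features exceed genome length")
        at
    }
    for (rs in repeats) {
        if (rs$type == "tandem") {
            span <- rs$period * rs$copies
            at <- if (!is.null(rs$at)) rs$at else place(span)
            unit <- s[(at + 1L):(at + rs$period)]
            s[(at + 1L):(at + span)] <- rep(unit, rs$copies)
            feats[[length(feats) + 1L]] <- data.frame(
                type = "tandem", start = at, end = at + span,
                period = rs$period, copies = rs$copies)
        } else if (rs$type == "duplication") {
            at <- if (!is.null(rs$at)) rs$at else place(2L * rs$length)
            s[(at + rs$length + 1L):(at + 2L * rs$length)] <-
                s[(at + 1L):(at + rs$length)]
            feats[[length(feats) + 1L]] <- data.frame(
                type = "duplication", start = at, end = at + 2L * rs$length,
                period = rs$length, copies = 2L)
        } else if (rs$type == "dispersed") {
            div <- rs$divergence %||% 0
            at1 <- if (!is.null(rs$at)) rs$at else place(rs$length)
            unit <- s[(at1 + 1L):(at1 + rs$length)]
            feats[[length(feats) + 1L]] <- data.frame(
                type = "dispersed", start = at1, end = at1 + rs$length,
                period = rs$length, copies = rs$copies)
            for (cp in seq_len(rs$copies - 1L)) {
                at <- place(rs$length)
                u <- unit
                if (div > 0) {
                    nmut <- rpois(1, div * rs$length)
                    if (nmut > 0) {
                        at_ <- sample(rs$length, min(nmut, rs$length))
                        u[at_] <- sample(BASES, length(at_), replace = TRUE)
                    }
                }
                s[(at + 1L):(at + rs$length)] <- u
                feats[[length(feats) + 1L]] <- data.frame(
                    type = "dispersed", start = at, end = at + rs$length,
                    period = rs$length, copies = rs$copies)
            }
        } else if (rs$type == "gc") {
            at <- if (!is.null(rs$at)) rs$at else place(rs$length)
            p <- c(rs$gc / 2, rs$gc / 2)
            s[(at + 1L):(at + rs$length)] <- sample(
                BASES, rs$length, replace = TRUE,
                prob = c((1 - rs$gc) / 2, p[1], p[2], (1 - rs$gc) / 2))
            feats[[length(feats) + 1L]] <- data.frame(
                type = "gc", start = at, end = at + rs$length,
                period = NA_integer_, copies = NA_integer_)
        } else stop("unknown feature type: ", rs$type)
    }
    feats <- if (length(feats)) do.call(rbind, feats) else
        data.frame(type = character(), start = integer(), end = integer(),
                   period = integer(), copies = integer())
    list(seq = stats::setNames(paste(s, collapse = ""), name),
         features = feats)
}

#' Plant assembly defects into a genome, producing a draft + truth ledger
#'
#' Defect types (named from the draft's perspective — what polishing should
#' undo): \code{snp} (wrong base), \code{ins} (extra draft bases; fixed by a
#' deletion call), \code{del} (missing truth bases; fixed by an insertion
#' call), \code{gap} (N-run replacing truth sequence), \code{misjoin}
#' (foreign sequence replacing truth sequence), \code{collapse} (a copy of a
#' planted 2-copy duplication dropped from the draft; reads from both truth
#' copies project onto the surviving copy).
#'
#' The returned ledger holds the block-level truth-to-draft liftover used by
#' \code{\link{projectAlignments}} and the expected, left-normalized variant
#' calls used for scoring.
#'
#' @param genome Output of \code{\link{generateGenome}} (or a named
#'   character scalar).
#' @param defects list of lists: \code{type}, \code{at} (0-based truth
#'   position; must be non-overlapping and ascending), \code{len}, optional
#'   \code{seq}.
#' @param seed Integer seed (for generated alternative bases).
#' @return list(draft = named character, ledger). The ledger contains
#'   \code{blocks}, \code{draftOnly}, \code{expected} (snps/indels data
#'   frames in draft coordinates), and \code{regions} (gap/misjoin/collapse
#'   intervals in draft coordinates with their truth sequence).
#' @export
plantDefects <- function(genome, defects = list(), seed = 1L) {
    if (is.list(genome) && !is.null(genome$seq)) genome <- genome$seq
    name <- names(genome)
    truth <- unname(genome)
    set.seed(seed + 7L)
    if (length(defects)) {
        ats <- vapply(defects, `[[`, 0, "at")
        if (is.unsorted(ats, strictly = TRUE))
            stop("defects must be ascending in truth coordinates")
        lens <- vapply(defects, function(d)
            if (d$type %in% c("snp")) 1L
            else if (d$type == "ins") 0L
            else as.integer(d$len), 0L)
        if (any(ats[-1] < (ats + lens)[-length(ats)]))
            stop("overlapping defects")
    }
    blocks <- list(); draftOnly <- list()
    expSnp <- list(); expIndel <- list(); regions <- list()
    pieces <- character(); t <- 0L; d <- 0L
    emitMatch <- function(tEnd) {
        if (tEnd > t) {
            blocks[[length(blocks) + 1L]] <<- data.frame(
                tStart = t, tEnd = tEnd, dStart = d,
                dEnd = d + tEnd - t, kind = "match", dTarget = NA_integer_)
            pieces[[length(pieces) + 1L]] <<- substring(truth, t + 1L, tEnd)
            d <<- d + tEnd - t; t <<- tEnd
        }
    }
    for (df_ in defects) {
        a <- as.integer(df_$at)
        emitMatch(a)
        if (df_$type == "snp") {
            ref <- substring(truth, a + 1L, a + 1L)
            alt <- df_$seq %||% sample(setdiff(BASES, ref), 1L)
            blocks[[length(blocks) + 1L]] <- data.frame(
                tStart = a, tEnd = a + 1L, dStart = d, dEnd = d + 1L,
                kind = "match", dTarget = NA_integer_)
            pieces[[length(pieces) + 1L]] <- alt
            expSnp[[length(expSnp) + 1L]] <- data.frame(
                pos = d, ref = alt, alt = ref, stringsAsFactors = FALSE)
            t <- a + 1L; d <- d + 1L
        } else if (df_$type == "ins") {
            ext <- df_$seq %||% randSeq(df_$len)
            draftOnly[[length(draftOnly) + 1L]] <- data.frame(
                tAt = a, dStart = d, dLen = nchar(ext))
            pieces[[length(pieces) + 1L]] <- ext
            expIndel[[length(expIndel) + 1L]] <- data.frame(
                pos = d, kind = "deletion", seq = ext,
                stringsAsFactors = FALSE)
            d <- d + nchar(ext)
        } else if (df_$type == "del") {
            L <- as.integer(df_$len)
            blocks[[length(blocks) + 1L]] <- data.frame(
                tStart = a, tEnd = a + L, dStart = d, dEnd = d,
                kind = "del", dTarget = NA_integer_)
            expIndel[[length(expIndel) + 1L]] <- data.frame(
                pos = d, kind = "insertion",
                seq = substring(truth, a + 1L, a + L),
                stringsAsFactors = FALSE)
            t <- a + L
        } else if (df_$type %in% c("gap", "misjoin")) {
            L <- as.integer(df_$len)
            rep_ <- if (df_$type == "gap") strrep("N", L) else
                df_$seq %||% randSeq(L)
            blocks[[length(blocks) + 1L]] <- data.frame(
                tStart = a, tEnd = a + L, dStart = d, dEnd = d + nchar(rep_),
                kind = "unalign", dTarget = NA_integer_)
            pieces[[length(pieces) + 1L]] <- rep_
            regions[[length(regions) + 1L]] <- data.frame(
                type = df_$type, dStart = d, dEnd = d + nchar(rep_),
                truthSeq = substring(truth, a + 1L, a + L),
                stringsAsFactors = FALSE)
            t <- a + L; d <- d + nchar(rep_)
        } else if (df_$type == "collapse") {
            L <- as.integer(df_$len)
            if (substring(truth, a - L + 1L, a) !=
                substring(truth, a + 1L, a + L))
                stop("collapse requires identical adjacent copies in truth")
            blocks[[length(blocks) + 1L]] <- data.frame(
                tStart = a, tEnd = a + L, dStart = d, dEnd = d,
                kind = "collapse", dTarget = d - L)
            regions[[length(regions) + 1L]] <- data.frame(
                type = "collapse", dStart = d - L, dEnd = d,
                truthSeq = substring(truth, a + 1L, a + L),
                stringsAsFactors = FALSE)
            t <- a + L
        } else stop("unknown defect type: ", df_$type)
    }
    emitMatch(nchar(truth))
    draft <- paste(pieces, collapse = "")
    blocks <- do.call(rbind, blocks)
    draftOnly <- if (length(draftOnly)) do.call(rbind, draftOnly) else
        data.frame(tAt = integer(), dStart = integer(), dLen = integer())
    ## left-normalize expected indels against the draft
    expIndel <- if (length(expIndel)) do.call(rbind, expIndel) else
        data.frame(pos = integer(), kind = character(), seq = character(),
                   stringsAsFactors = FALSE)
    if (nrow(expIndel)) {
        for (i in seq_len(nrow(expIndel))) {
            nrm <- normalizeIndelLeft(draft, expIndel$pos[i],
                                      expIndel$kind[i], expIndel$seq[i])
            expIndel$pos[i] <- nrm$pos
            expIndel$seq[i] <- nrm$seq
        }
    }
    ledger <- list(
        scaffold = name,
        truthLength = nchar(truth),
        draftLength = nchar(draft),
        blocks = blocks,
        draftOnly = draftOnly,
        expected = list(
            snps = if (length(expSnp)) do.call(rbind, expSnp) else
                data.frame(pos = integer(), ref = character(),
                           alt = character(), stringsAsFactors = FALSE),
            indels = expIndel),
        regions = if (length(regions)) do.call(rbind, regions) else
            data.frame(type = character(), dStart = integer(),
                       dEnd = integer(), truthSeq = character(),
                       stringsAsFactors = FALSE))
    list(draft = stats::setNames(draft, name), ledger = ledger)
}

#' Simulate reads from a (truth) genome
#'
#' Templates are sampled uniformly; paired libraries produce FR-oriented
#' pairs with normally distributed template lengths; qualities are uniform
#' and consistent with the error rate (Q40 for error-free reads); per-base
#' substitution errors occur at \code{errorRate}. Sequences are stored in
#' reference-strand orientation. Deterministic under \code{seed}.
#'
#' @param genomeSeq Character scalar (the truth sequence).
#' @param kind "fragment", "long_insert" or "unpaired".
#' @param insertMean,insertSd Template length distribution (paired kinds).
#' @param readLength Read length in bases (must be < insertMean for paired).
#' @param depth Target mean coverage (> 0).
#' @param errorRate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return data.frame: qname, tStart (0-based truth start), strand, seq,
#'   qual, pair (pair id or NA), mate (1/2/NA).
#' @export
simulateReads <- function(genomeSeq, kind = "fragment", insertMean = 180,
                          insertSd = 18, readLength = 100, depth = 60,
                          errorRate = 0, seed = 1L) {
    stopifnot(depth > 0)
    L <- nchar(genomeSeq)
    set.seed(seed + 13L)
    paired <- kind != "unpaired"
    if (paired) stopifnot(readLength < insertMean)
    q <- if (errorRate > 0) min(40L, round(-10 * log10(errorRate))) else 40L
    qs <- strrep(rawToChar(as.raw(q + 33L)), readLength)
    if (paired) {
        n <- ceiling(depth * L / (2 * readLength))
        tlen <- pmin(pmax(round(stats::rnorm(n, insertMean, insertSd)),
                          readLength), L)
        st <- floor(stats::runif(n, 0, L - tlen + 1))
        reads <- data.frame(
            qname = rep(sprintf("%s_%06d", substr(kind, 1, 4), seq_len(n)),
                        each = 2L),
            tStart = as.vector(rbind(st, st + tlen - readLength)),
            strand = rep(c("+", "-"), n),
            pair = rep(seq_len(n), each = 2L),
            mate = rep(c(1L, 2L), n),
            stringsAsFactors = FALSE)
    } else {
        n <- ceiling(depth * L / readLength)
        st <- floor(stats::runif(n, 0, L - readLength + 1))
        reads <- data.frame(
            qname = sprintf("unp_%06d", seq_len(n)),
            tStart = st, strand = "+",
            pair = NA_integer_, mate = NA_integer_,
            stringsAsFactors = FALSE)
    }
    reads$seq <- substring(genomeSeq, reads$tStart + 1L,
                           reads$tStart + readLength)
    if (errorRate > 0) {
        nb <- nrow(reads) * readLength
        hits <- which(stats::runif(nb) < errorRate)
        if (length(hits)) {
            ri <- (hits - 1L) %/% readLength + 1L
            off <- (hits - 1L) %% readLength + 1L
            for (j in seq_along(hits)) {
                old <- substring(reads$seq[ri[j]], off[j], off[j])
                substring(reads$seq[ri[j]], off[j], off[j]) <-
                    sample(setdiff(BASES, old), 1L)
            }
        }
    }
    reads$qual <- qs
    reads
}

## project one read's truth interval [s,e) through the ledger; returns
## list(pos, cigar) or NULL when unmappable
projectOneRead <- function(s, e, blocks, draftOnly, minAnchor = 20L) {
    ops <- list()   # each: list(op, len, dpos)
    bi <- findInterval(s, blocks$tStart)
    t <- s
    while (t < e && bi <= nrow(blocks)) {
        b <- blocks[bi, ]
        ovE <- min(e, b$tEnd)
        qlen <- ovE - max(t, b$tStart)
        if (qlen > 0) {
            if (b$kind %in% c("match", "collapse")) {
                base <- if (b$kind == "collapse") b$dTarget else b$dStart
                ops[[length(ops) + 1L]] <- list(
                    op = "M", len = qlen, dpos = base + (t - b$tStart))
            } else if (b$kind == "del") {
                ops[[length(ops) + 1L]] <- list(op = "I", len = qlen,
                                                dpos = NA)
            } else {
                ops[[length(ops) + 1L]] <- list(op = "U", len = qlen,
                                                dpos = NA)
            }
            t <- ovE
        }
        ## draft-only sequence at this block boundary?
        if (t < e || (t == e && FALSE)) {
            hit <- draftOnly[draftOnly$tAt == t & t > s & t < e, ]
            if (nrow(hit))
                ops[[length(ops) + 1L]] <- list(op = "D", len = hit$dLen[1],
                                                dpos = NA)
        }
        bi <- bi + 1L
    }
    if (!length(ops)) return(NULL)
    ## split into collinear chunks at U ops, large Ds, or draft-coord jumps
    chunks <- list(); cur <- list(); curD <- NA
    flush <- function() {
        if (length(cur)) chunks[[length(chunks) + 1L]] <<- cur
        cur <<- list(); curD <<- NA
    }
    for (o in ops) {
        if (o$op == "U" || (o$op == "D" && o$len > 20L)) { flush(); next }
        if (o$op == "M") {
            if (!is.na(curD) && o$dpos != curD) flush()
            cur[[length(cur) + 1L]] <- o
            curD <- o$dpos + o$len
        } else {
            cur[[length(cur) + 1L]] <- o
            if (o$op == "D" && !is.na(curD)) curD <- curD + o$len
        }
    }
    flush()
    if (!length(chunks)) return(NULL)
    mScore <- vapply(chunks, function(ch)
        sum(vapply(ch, function(o) if (o$op == "M") o$len else 0, 0)), 0)
    best <- which.max(mScore)
    if (mScore[best] < minAnchor) return(NULL)
    ch <- chunks[[best]]
    ## trim non-M ops at chunk edges (leading/trailing I -> clipped query)
    while (length(ch) && ch[[1]]$op != "M") ch <- ch[-1]
    while (length(ch) && ch[[length(ch)]]$op != "M") ch <- ch[-length(ch)]
    if (!length(ch)) return(NULL)
    ## query consumed before the kept chunk: walk the original op list up to
    ## the first kept M op (identified by its unique draft position)
    qPre <- 0L
    for (o in ops) {
        if (o$op == "M" && !is.na(o$dpos) && o$dpos == ch[[1]]$dpos) break
        if (o$op %in% c("M", "I", "U")) qPre <- qPre + o$len
    }
    qKept <- sum(vapply(ch, function(o)
        if (o$op %in% c("M", "I")) o$len else 0, 0))
    total <- e - s
    qPost <- total - qPre - qKept
    cig <- character()
    if (qPre > 0) cig <- c(cig, sprintf("%dS", qPre))
    for (o in ch) cig <- c(cig, sprintf("%d%s", o$len, o$op))
    if (qPost > 0) cig <- c(cig, sprintf("%dS", qPost))
    list(pos = ch[[1]]$dpos, cigar = paste(cig, collapse = ""))
}

#' Project simulated truth reads onto the draft as alignments
#'
#' Each read is placed at its lifted draft coordinate with a CIGAR derived
#' from the ledger: reads crossing sequence absent from the draft are
#' soft-clipped at the boundary (or emitted unmapped when insufficiently
#' anchored); small draft insertions/deletions become D/I CIGAR ops; pairs
#' are flagged proper when both mates map in FR orientation with a template
#' length within mean + 3 sd. Mapping quality is 60 for uniquely lifted
#' reads and 3 for reads fully inside multi-copy repeat regions
#' (\code{lowMapqRegions}).
#'
#' @param reads From \code{\link{simulateReads}}.
#' @param ledger From \code{\link{plantDefects}}.
#' @param insertMean,insertSd The simulating library's template parameters.
#' @param lowMapqRegions Optional data.frame(start, end) of draft intervals
#'   (0-based) where fully-contained reads get mapping quality 3.
#' @return data.frame of normalized alignment records, coordinate-sorted,
#'   suitable for \code{\link{writeSam}}.
#' @export
projectAlignments <- function(reads, ledger, insertMean = 180,
                              insertSd = 18, lowMapqRegions = NULL) {
    blocks <- ledger$blocks
    draftOnly <- ledger$draftOnly
    rl <- nchar(reads$seq)
    s <- reads$tStart; e <- s + rl
    ## fast path: read within one match/collapse block, no draft-only point
    bs <- findInterval(s, blocks$tStart)
    beI <- findInterval(e - 1L, blocks$tStart)
    kindS <- blocks$kind[bs]
    nIns <- if (nrow(draftOnly))
        findInterval(e - 1L, sort(draftOnly$tAt)) -
        findInterval(s, sort(draftOnly$tAt)) else rep(0L, length(s))
    fast <- bs == beI & kindS %in% c("match", "collapse") & nIns == 0L &
        e <= blocks$tEnd[bs]
    pos <- rep(NA_integer_, length(s))
    cigar <- rep(NA_character_, length(s))
    base <- ifelse(blocks$kind[bs] == "collapse", blocks$dTarget[bs],
                   blocks$dStart[bs])
    pos[fast] <- base[fast] + (s[fast] - blocks$tStart[bs][fast])
    cigar[fast] <- sprintf("%dM", rl[fast])
    for (i in which(!fast)) {
        pr <- projectOneRead(s[i], e[i], blocks, draftOnly)
        if (!is.null(pr)) { pos[i] <- pr$pos; cigar[i] <- pr$cigar }
    }
    mapped <- !is.na(pos)
    mapq <- ifelse(mapped, 60L, 0L)
    if (!is.null(lowMapqRegions) && nrow(lowMapqRegions)) {
        spanEnd <- pos + cigarRefSpanFromOps(cigar, "ref")
        for (j in seq_len(nrow(lowMapqRegions))) {
            inside <- mapped & pos >= lowMapqRegions$start[j] &
                spanEnd <= lowMapqRegions$end[j]
            mapq[inside] <- 3L
        }
    }
    refSpan <- ifelse(mapped, cigarRefSpanFromOps(cigar, "ref"), 0L)
    scaf <- ledger$scaffold
    n <- length(s)
    flag <- integer(n)
    flag[!mapped] <- FLAG_UNMAPPED
    flag[reads$strand == "-" & mapped] <-
        flag[reads$strand == "-" & mapped] + FLAG_REVERSE
    rname <- ifelse(mapped, scaf, NA_character_)
    mrnm <- rep(NA_character_, n); mpos <- rep(NA_integer_, n)
    isize <- rep(NA_integer_, n)
    if (any(!is.na(reads$pair))) {
        ord <- order(reads$pair, reads$mate)
        p1 <- ord[seq(1, n, by = 2L)]; p2 <- ord[seq(2, n, by = 2L)]
        flag[p1] <- flag[p1] + FLAG_PAIRED + FLAG_READ1
        flag[p2] <- flag[p2] + FLAG_PAIRED + FLAG_READ2
        m1 <- mapped[p1]; m2 <- mapped[p2]
        lo <- pmin(pos[p1], pos[p2])
        hi <- pmax(pos[p1] + refSpan[p1], pos[p2] + refSpan[p2])
        tlen <- hi - lo
        fr <- m1 & m2 &
            reads$strand[p1] == "+" & reads$strand[p2] == "-" &
            pos[p1] <= pos[p2]
        proper <- !is.na(fr) & fr & tlen <= insertMean + 3 * insertSd &
            tlen >= 1
        proper[is.na(proper)] <- FALSE
        flag[p1][proper] <- flag[p1][proper] + FLAG_PROPER
        flag[p2][proper] <- flag[p2][proper] + FLAG_PROPER
        flag[p1][!m2] <- flag[p1][!m2] + FLAG_MUNMAPPED
        flag[p2][!m1] <- flag[p2][!m1] + FLAG_MUNMAPPED
        flag[p1][reads$strand[p2] == "-" & m2] <-
            flag[p1][reads$strand[p2] == "-" & m2] + FLAG_MREVERSE
        flag[p2][reads$strand[p1] == "-" & m1] <-
            flag[p2][reads$strand[p1] == "-" & m1] + FLAG_MREVERSE
        ## placed-unmapped convention: unmapped read sits at its mate
        pos[p1][!m1 & m2] <- pos[p2][!m1 & m2]
        rname[p1][!m1 & m2] <- rname[p2][!m1 & m2]
        pos[p2][!m2 & m1] <- pos[p1][!m2 & m1]
        rname[p2][!m2 & m1] <- rname[p1][!m2 & m1]
        mrnm[p1] <- rname[p2]; mrnm[p2] <- rname[p1]
        mpos[p1] <- pos[p2]; mpos[p2] <- pos[p1]
        both <- m1 & m2
        isize[p1][both] <- ifelse(pos[p1][both] <= pos[p2][both],
                                  tlen[both], -tlen[both])
        isize[p2][both] <- -isize[p1][both]
    }
    rec <- data.frame(
        qname = reads$qname, flag = flag, rname = rname, pos = pos,
        mapq = ifelse(mapped, mapq, 0L), cigar = cigar,
        mrnm = mrnm, mpos = mpos, isize = isize,
        seq = reads$seq, qual = reads$qual, stringsAsFactors = FALSE)
    rec[order(is.na(rec$rname), rec$rname, rec$pos), ]
}

#' Write alignment records as a SAM file
#'
#' Coordinate-sorted SAM with @HD/@SQ header; the inverse of what
#' \code{\link{readAlignments}} ingests.
#'
#' @param records Record data.frame (0-based pos/mpos; NA cigar for
#'   unmapped).
#' @param genome The draft \linkS4class{InputGenome} (for the header).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSam <- function(records, genome, path) {
    lens <- scaffoldLengths(genome)
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
    r <- records
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
        r$qname, r$flag,
        ifelse(is.na(r$rname), "*", r$rname),
        ifelse(is.na(r$pos), 0L, r$pos + 1L),
        ifelse(is.na(r$mapq), 0L, r$mapq),
        ifelse(is.na(r$cigar), "*", r$cigar),
        ifelse(is.na(r$mrnm) | is.na(r$mpos), "*",
               ifelse(!is.na(r$rname) & r$mrnm == r$rname, "=", r$mrnm)),
        ifelse(is.na(r$mpos), 0L, r$mpos + 1L),
        ifelse(is.na(r$isize), 0L, r$isize),
        r$seq, r$qual)
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Build the standard benchmark fixture
#'
#' A deterministic end-to-end fixture: a truth genome containing a 2-copy
#' tandem duplication, a 100 kb draft carrying planted single-base errors,
#' small indels, N-run gaps, a mis-join and the collapsed duplication, plus
#' error-free fragment (180 bp insert, 60x) and long-insert (3 kb, 20x)
#' libraries projected onto the draft. Written as FASTA + SAM under
#' \code{dir}.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param draftLength Approximate draft length (default 100 kb).
#' @param nSnps,nIns,nDel,nGaps Planted defect counts.
#' @param gapLen,misjoinLen,dupLen Feature sizes (bases).
#' @param fragDepth,jumpDepth Library depths.
#' @return list(genomeFile, fragSam, jumpSam, draft, truth, ledger,
#'   defects).
#' @export
benchmarkFixture <- function(dir, seed = 1L, draftLength = 100000L,
                             nSnps = 50L, nIns = 10L, nDel = 10L,
                             nGaps = 5L, gapLen = 200L, misjoinLen = 500L,
                             dupLen = 15000L, fragDepth = 60, jumpDepth = 20) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    truthLength <- draftLength + dupLen
    dupAt <- as.integer(draftLength * 0.65)
    gen <- generateGenome(truthLength, seed = seed,
                          repeats = list(list(type = "duplication",
                                              length = dupLen, at = dupAt)))
    ## place small defects in truth space, avoiding the duplication and ends
    set.seed(seed + 101L)
    nSmall <- nSnps + nIns + nDel
    nBig <- nGaps + 1L
    forbidden <- c(dupAt - 1000L, dupAt + 2L * dupLen + 1000L)
    slots <- c()
    candidates <- seq(2000L, truthLength - 2000L, by = 1000L)
    candidates <- candidates[candidates < forbidden[1] |
                             candidates > forbidden[2]]
    if (length(candidates) < nSmall + nBig)
        stop("genome too small for the requested defect counts")
    slots <- sort(sample(candidates, nSmall + nBig))
    jitter <- sample(0:300, length(slots), replace = TRUE)
    slots <- slots + jitter   # spacing stays >= 700 > any defect length
    types <- sample(c(rep("snp", nSnps), rep("ins", nIns), rep("del", nDel),
                      rep("gap", nGaps), "misjoin"))
    defects <- vector("list", length(slots) + 1L)
    set.seed(seed + 202L)
    for (i in seq_along(slots)) {
        ty <- types[i]
        defects[[i]] <- switch(ty,
            snp = list(type = "snp", at = slots[i]),
            ins = list(type = "ins", at = slots[i],
                       len = sample(1:3, 1L)),
            del = list(type = "del", at = slots[i],
                       len = sample(1:3, 1L)),
            gap = list(type = "gap", at = slots[i], len = gapLen),
            misjoin = list(type = "misjoin", at = slots[i],
                           len = misjoinLen))
    }
    defects[[length(defects)]] <- list(type = "collapse",
                                       at = dupAt + dupLen, len = dupLen)
    ord <- order(vapply(defects, `[[`, 0, "at"))
    defects <- defects[ord]
    pd <- plantDefects(gen, defects, seed = seed)
    draftGenome <- newInputGenome(pd$draft)
    genomeFile <- file.path(dir, "draft.fa")
    writeGenomeFasta(draftGenome, genomeFile)
    truthSeq <- unname(gen$seq)
    fragReads <- simulateReads(truthSeq, "fragment", insertMean = 180,
                               insertSd = 18, readLength = 100,
                               depth = fragDepth, errorRate = 0,
                               seed = seed + 1L)
    jumpReads <- simulateReads(truthSeq, "long_insert", insertMean = 3000,
                               insertSd = 300, readLength = 100,
                               depth = jumpDepth, errorRate = 0,
                               seed = seed + 2L)
    fragAln <- projectAlignments(fragReads, pd$ledger, 180, 18)
    jumpAln <- projectAlignments(jumpReads, pd$ledger, 3000, 300)
    fragSam <- file.path(dir, "frag.sam")
    jumpSam <- file.path(dir, "jump.sam")
    writeSam(fragAln, draftGenome, fragSam)
    writeSam(jumpAln, draftGenome, jumpSam)
    list(genomeFile = genomeFile, fragSam = fragSam, jumpSam = jumpSam,
         draft = pd$draft, truth = gen$seq, ledger = pd$ledger,
         defects = defects)
}
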