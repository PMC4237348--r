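## Local reassembly: read collection, pruned De Bruijn graph, flank walks,
## closure, consensus extension, gap filling.

#' Collect reads for local reassembly of a region
#'
#' Reads that might carry the true sequence of an untrusted region are
#' recruited from flanks of width \code{insertMean + 3*insertSd} of the
#' widest paired library: fragment/unpaired reads aligned (fully or
#' partially, i.e. soft-clipped) within the flanks; for pairs with a read
#' anchored in a flank whose mate is unmapped or improperly mapped, both
#' reads (fragment libraries) or only the unanchored mate (long-insert
#' libraries) join the collection.
#'
#' @param scaffold,start,end Region (0-based half-open) on the genome.
#' @param alignments list of \linkS4class{PolishAlignments}.
#' @param genome An \linkS4class{InputGenome}.
#' @param config A \linkS4class{PolishConfig}.
#' @return list(seq, qual): character vectors of recruited reads.
#' @export
collectReadsForRegion <- function(scaffold, start, end, alignments, genome,
                                  config = polishConfig()) {
    if (is(alignments, "PolishAlignments")) alignments <- list(alignments)
    spans <- vapply(alignments, function(a)
        if (a@kind == "unpaired" || is.na(a@stats@insertMean))
            3 * a@stats@readLengthMode
        else a@stats@insertMean + 3 * a@stats@insertSd, 0)
    flank <- as.integer(max(spans, 300))
    lf <- c(start - flank, start)     # [lf1, lf2)
    rf <- c(end, end + flank)
    outSeq <- character(); outQual <- character()
    for (aln in alignments) {
        rec <- aln@records
        onScaf <- !is.na(rec$rname) & rec$rname == scaffold
        mapped <- onScaf & !rec$unmapped & !is.na(rec$pos)
        rl <- nchar(rec$seq)
        aEnd <- rec$pos + rl          # approximate reference end
        inFlank <- mapped &
            ((aEnd > lf[1] & rec$pos < lf[2]) |
             (aEnd > rf[1] & rec$pos < rf[2]))
        anchored <- inFlank & (!rec$paired | rec$proper |
                               grepl("S", rec$cigar))
        if (aln@kind != "long_insert") {
            sel <- which(inFlank)
            outSeq <- c(outSeq, rec$seq[sel])
            outQual <- c(outQual, rec$qual[sel])
        }
        ## recruit unanchored mates of flank-anchored reads
        needMate <- which(inFlank & rec$paired &
                          (rec$mateUnmapped | !rec$proper))
        if (length(needMate)) {
            isR1 <- bitwAnd(rec$flag, FLAG_READ1) > 0L
            keyTab <- data.table::data.table(
                qname = rec$qname, r1 = isR1, idx = seq_len(nrow(rec)))
            data.table::setkey(keyTab, qname, r1)
            query <- data.table::data.table(
                qname = rec$qname[needMate], r1 = !isR1[needMate])
            mate <- keyTab[query]$idx
            mate <- mate[!is.na(mate)]
            mate <- setdiff(mate, which(inFlank & aln@kind != "long_insert"))
            if (length(mate)) {
                outSeq <- c(outSeq, rec$seq[mate])
                outQual <- c(outQual, rec$qual[mate])
            }
        }
    }
    ok <- !is.na(outSeq) & nchar(outSeq) > 0
    list(seq = outSeq[ok], qual = outQual[ok])
}

#' Build a pruned local De Bruijn graph from reads
#'
#' Each read and its reverse complement contribute: for every k-mer, the
#' following base is recorded in a next-base pileup weighted by its base
#' quality. Links supported by fewer than \code{minLinkCoverage} reads are
#' pruned at query time; a node yields a single forward link when one allele
#' dominates, or a branch when two or more alleles each reach the ambiguity
#' fraction.
#'
#' @param reads list(seq, qual) as from \code{\link{collectReadsForRegion}},
#'   or a character vector of sequences (uniform quality 30 assumed).
#' @param config A \linkS4class{PolishConfig}.
#' @return A \linkS4class{KmerGraph} (empty nodes when all reads are shorter
#'   than k+1).
#' @export
buildKmerGraph <- function(reads, config = polishConfig()) {
    if (is.character(reads))
        reads <- list(seq = reads, qual = strrep("?", nchar(reads)))
    k <- config@k
    seqs <- c(reads$seq, revComp(reads$seq))
    quals <- c(reads$qual, vapply(reads$qual, function(q)
        paste(rev(strsplit(q, "")[[1]]), collapse = ""), ""))
    keep <- nchar(seqs) >= k + 1L
    seqs <- seqs[keep]; quals <- quals[keep]
    if (!length(seqs))
        return(new("KmerGraph", k = k, nodes = NULL))
    parts <- lapply(seq_along(seqs), function(i) {
        s <- seqs[i]; q <- quals[i]
        n <- nchar(s) - k
        st <- seq_len(n)
        list(kmer = substring(s, st, st + k - 1L),
             nb = substring(s, st + k, st + k),
             w = as.integer(charToRaw(q))[st + k] - 33L)
    })
    dt <- data.table::data.table(
        kmer = unlist(lapply(parts, `[[`, "kmer"), use.names = FALSE),
        nb = unlist(lapply(parts, `[[`, "nb"), use.names = FALSE),
        w = unlist(lapply(parts, `[[`, "w"), use.names = FALSE))
    dt <- dt[dt$nb %in% BASES & !grepl("N", dt$kmer, fixed = TRUE), ]
    if (!nrow(dt)) return(new("KmerGraph", k = k, nodes = NULL))
    agg <- dt[, list(w = sum(w), n = .N), by = c("kmer", "nb")]
    wide <- data.table::dcast(agg, kmer ~ nb, value.var = c("w", "n"),
                              fill = 0)
    for (b in BASES) {
        for (pfx in c("w_", "n_")) {
            col <- paste0(pfx, b)
            if (!col %in% names(wide)) wide[[col]] <- 0
        }
    }
    m <- as.matrix(wide[, paste0(rep(c("w_", "n_"), each = 4),
                                 rep(BASES, 2)), with = FALSE])
    vals <- asplit(m, 1)
    names(vals) <- wide$kmer
    env <- list2env(as.list(vals), hash = TRUE, size = length(vals) * 2L)
    new("KmerGraph", k = k, nodes = list(env = env, n = length(vals)))
}

#' @describeIn buildKmerGraph number of stored k-mer nodes
#' @param graph A \linkS4class{KmerGraph}.
#' @export
graphSize <- function(graph) {
    if (is.null(graph@nodes)) 0L else graph@nodes$n
}

#' Forward links of one k-mer node
#'
#' @param graph A \linkS4class{KmerGraph}.
#' @param kmer k-mer string.
#' @param config A \linkS4class{PolishConfig}.
#' @return data.frame(base, count, weight) of surviving forward links,
#'   ordered by decreasing weight; zero rows at dead ends or absent nodes.
#' @export
graphLinks <- function(graph, kmer, config = polishConfig()) {
    empty <- data.frame(base = character(), count = integer(),
                        weight = numeric(), stringsAsFactors = FALSE)
    if (is.null(graph@nodes)) return(empty)
    v <- get0(kmer, envir = graph@nodes$env, inherits = FALSE)
    if (is.null(v)) return(empty)
    w <- v[1:4]; n <- v[5:8]
    eligible <- n >= config@minLinkCoverage
    if (!any(eligible)) return(empty)
    tot <- sum(w)
    fr <- if (tot > 0) w / tot else rep(0, 4)
    link <- eligible & fr >= config@ambiguousFraction
    if (!any(link)) link <- eligible & seq_len(4) == which.max(w * eligible)
    ord <- order(w[link], decreasing = TRUE)
    data.frame(base = BASES[link][ord], count = as.integer(n[link][ord]),
               weight = w[link][ord], stringsAsFactors = FALSE)
}

#' Walk extensions into an untrusted region from a trusted flank k-mer
#'
#' Depth-first expansion through the pruned graph, forking at branch nodes.
#' A path ends at a dead end, upon reaching the branch limit (so at most
#' \code{2^branchLimit} extensions are returned), or upon revisiting a k-mer
#' already incorporated on its own walk, which indicates a tandem repeat
#' loop; the loop period is the distance since that k-mer was first seen.
#'
#' @param graph A \linkS4class{KmerGraph}.
#' @param seed Seed k-mer from the trusted flank (walks "rightward"; seed a
#'   reverse-complemented flank k-mer to walk leftward).
#' @param config A \linkS4class{PolishConfig}.
#' @return list of extensions: list(sequence, branchCount, terminatedBy,
#'   loopPeriod); empty when the seed is absent from the graph.
#' @export
walkFromFlank <- function(graph, seed, config = polishConfig()) {
    if (is.null(graph@nodes) ||
        is.null(get0(seed, envir = graph@nodes$env, inherits = FALSE)))
        return(list())
    k <- graph@k
    results <- list()
    stack <- list(list(cur = seed, bases = character(0), branches = 0L,
                       visited = stats::setNames(0L, seed)))
    while (length(stack)) {
        st <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        repeat {
            if (length(st$bases) >= config@maxWalkLength) {
                results[[length(results) + 1L]] <- list(
                    sequence = paste0(seed, paste(st$bases, collapse = "")),
                    branchCount = st$branches, terminatedBy = "limit",
                    loopPeriod = NA_integer_)
                break
            }
            links <- graphLinks(graph, st$cur, config)
            if (nrow(links) == 0) {
                results[[length(results) + 1L]] <- list(
                    sequence = paste0(seed, paste(st$bases, collapse = "")),
                    branchCount = st$branches, terminatedBy = "dead_end",
                    loopPeriod = NA_integer_)
                break
            }
            if (nrow(links) > 1 && st$branches >= config@branchLimit) {
                results[[length(results) + 1L]] <- list(
                    sequence = paste0(seed, paste(st$bases, collapse = "")),
                    branchCount = st$branches, terminatedBy = "branch_limit",
                    loopPeriod = NA_integer_)
                break
            }
            branching <- nrow(links) > 1
            advanced <- FALSE
            for (j in rev(seq_len(nrow(links)))) {
                nk <- paste0(substring(st$cur, 2L, k), links$base[j])
                step <- length(st$bases) + 1L
                prev <- st$visited[nk]
                if (!is.na(prev)) {
                    results[[length(results) + 1L]] <- list(
                        sequence = paste0(seed,
                                          paste(c(st$bases, links$base[j]),
                                                collapse = "")),
                        branchCount = st$branches + if (branching) 1L else 0L,
                        terminatedBy = "loop",
                        loopPeriod = step - unname(prev))
                    next
                }
                nxt <- st
                nxt$cur <- nk
                nxt$bases <- c(st$bases, links$base[j])
                nxt$branches <- st$branches + if (branching) 1L else 0L
                nxt$visited <- c(st$visited, stats::setNames(step, nk))
                if (j == 1L && !advanced) {
                    st <- nxt
                    advanced <- TRUE
                } else {
                    stack[[length(stack) + 1L]] <- nxt
                }
            }
            if (!advanced) break
        }
    }
    results
}

#' Greedy consensus extension from a flank
#'
#' Walks the graph from a seed, at each branch following the highest-weight
#' link; stops at an exact weight tie (conservative: never guess), a dead
#' end, or a revisited k-mer.
#'
#' @param graph A \linkS4class{KmerGraph}.
#' @param seed Seed k-mer.
#' @param config A \linkS4class{PolishConfig}.
#' @return Consensus sequence (starts with the seed); "" if seed absent.
#' @export
consensusExtension <- function(graph, seed, config = polishConfig()) {
    if (is.null(graph@nodes) ||
        is.null(get0(seed, envir = graph@nodes$env, inherits = FALSE)))
        return("")
    k <- graph@k
    cur <- seed
    bases <- character(0)
    visited <- new.env(hash = TRUE)
    assign(seed, TRUE, envir = visited)
    while (length(bases) < config@maxWalkLength) {
        links <- graphLinks(graph, cur, config)
        if (nrow(links) == 0) break
        if (nrow(links) > 1 &&
            links$weight[2] >= links$weight[1] * (1 - 1e-9)) break  # tie
        nk <- paste0(substring(cur, 2L, k), links$base[1])
        if (!is.null(get0(nk, envir = visited, inherits = FALSE))) break
        assign(nk, TRUE, envir = visited)
        bases <- c(bases, links$base[1])
        cur <- nk
    }
    paste0(seed, paste(bases, collapse = ""))
}

#' Longest prefix shared by a set of extensions
#'
#' @param seqs Character vector.
#' @return The longest common prefix ("" for empty input).
#' @export
commonPrefix <- function(seqs) {
    if (!length(seqs)) return("")
    if (length(seqs) == 1) return(seqs)
    n <- min(nchar(seqs))
    lo <- 0L
    for (i in seq_len(n)) {
        if (length(unique(substring(seqs, i, i))) > 1L) break
        lo <- i
    }
    substring(seqs[1], 1L, lo)
}

#' Attempt flank-to-flank closure of a region from walk extensions
#'
#' Right extensions (walked leftward on the reverse complement) are
#' reverse-complemented into left orientation, then all (left, right) pairs
#' are matched for perfect overlaps of at least \code{2k+1} bases. Exactly
#' one distinct flank-to-flank sequence: closed. None or several: extended
#' (consensus extensions are then used by the caller). Any loop-terminated
#' extension forces a tandem-repeat outcome with no closure attempt.
#'
#' @param leftExtensions,rightExtensions lists from
#'   \code{\link{walkFromFlank}} (or character vectors of plain sequences;
#'   right extensions are given as walked, i.e. reverse-complement
#'   orientation).
#' @param config A \linkS4class{PolishConfig}.
#' @return list(outcome = "closed"|"extended"|"tandem_repeat"|"no_solution",
#'   replacement, candidates, tandemPeriod).
#' @export
attemptClosure <- function(leftExtensions, rightExtensions,
                           config = polishConfig()) {
    wrap <- function(x) {
        if (is.character(x))
            x <- lapply(x, function(s) list(sequence = s, branchCount = 0L,
                                            terminatedBy = "dead_end",
                                            loopPeriod = NA_integer_))
        x
    }
    le <- wrap(leftExtensions); re <- wrap(rightExtensions)
    allExt <- c(le, re)
    loops <- vapply(allExt, function(e) identical(e$terminatedBy, "loop"), TRUE)
    if (any(loops)) {
        periods <- vapply(allExt[loops], function(e)
            as.integer(e$loopPeriod), 0L)
        return(list(outcome = "tandem_repeat", replacement = NA_character_,
                    candidates = character(),
                    tandemPeriod = min(periods, na.rm = TRUE)))
    }
    if (!length(le) || !length(re))
        return(list(outcome = "extended", replacement = NA_character_,
                    candidates = character(), tandemPeriod = NA_integer_))
    minOv <- closureOverlap(config)
    lseqs <- vapply(le, `[[`, "", "sequence")
    rseqs <- revComp(vapply(re, `[[`, "", "sequence"))
    ## left extensions are left-anchored, right extensions (after reverse
    ## complement) are right-anchored; slide each right extension along each
    ## left one and accept perfect overlaps of at least 2k+1. The merged
    ## flank-to-flank sequence keeps both anchors.
    cands <- character()
    for (ls in lseqs) {
        nl <- nchar(ls)
        for (rs in rseqs) {
            nr <- nchar(rs)
            if (min(nl, nr) < minOv) next
            for (s in 0:(nl - minOv)) {
                ov <- min(nl - s, nr)
                if (substring(ls, s + 1L, s + ov) == substring(rs, 1L, ov))
                    cands <- c(cands, paste0(substring(ls, 1L, s), rs))
            }
            ## right extension reaching left past the left anchor
            for (m in seq_len(nr - minOv)) {
                ov <- min(nr - m, nl)
                if (substring(rs, m + 1L, m + ov) == substring(ls, 1L, ov))
                    cands <- c(cands, substring(rs, m + 1L, nr))
            }
        }
    }
    cands <- unique(cands)
    if (length(cands) == 1L)
        list(outcome = "closed", replacement = cands,
             candidates = cands, tandemPeriod = NA_integer_)
    else
        list(outcome = "extended", replacement = NA_character_,
             candidates = cands, tandemPeriod = NA_integer_)
}

## find a trusted seed k-mer adjacent to the region; returns list(kmer, at)
## where at is the 0-based genome start of the k-mer, or NULL
findSeed <- function(graph, gseq, k, side, start, end, maxSlide = NULL) {
    if (is.null(maxSlide)) maxSlide <- 2L * k
    L <- nchar(gseq)
    for (o in 0:maxSlide) {
        if (side == "left") {
            at <- start - k - o
            if (at < 0) return(NULL)
            km <- substring(gseq, at + 1L, at + k)
        } else {
            at <- end + o
            if (at + k > L) return(NULL)
            km <- substring(gseq, at + 1L, at + k)
        }
        if (grepl("N", km, fixed = TRUE)) next
        if (!is.null(graph@nodes) &&
            !is.null(get0(km, envir = graph@nodes$env, inherits = FALSE)))
            return(list(kmer = km, at = at))
    }
    NULL
}

trimCommonEnds <- function(src, dst, srcStart) {
    ns <- nchar(src); nd <- nchar(dst)
    p <- 0L
    while (p < min(ns, nd) &&
           substring(src, p + 1L, p + 1L) == substring(dst, p + 1L, p + 1L))
        p <- p + 1L
    s <- 0L
    while (s < min(ns, nd) - p &&
           substring(src, ns - s, ns - s) == substring(dst, nd - s, nd - s))
        s <- s + 1L
    list(srcStart = srcStart + p,
         src = substring(src, p + 1L, ns - s),
         dst = substring(dst, p + 1L, nd - s))
}

#' Locally reassemble one suspicious region or captured gap
#'
#' Runs the full local-reassembly procedure for one target: recruit reads,
#' build the pruned graph, walk extensions from both flanks, and either
#' close the region with a unique flank-to-flank sequence, shrink it with
#' consensus extensions, report a tandem repeat, or give up.
#'
#' @param genome An \linkS4class{InputGenome}.
#' @param scaffold,start,end Target region, 0-based half-open.
#' @param triggers Character, comma-joined trigger set ("gap" marks a
#'   captured-gap target).
#' @param alignments list of \linkS4class{PolishAlignments}.
#' @param config A \linkS4class{PolishConfig}.
#' @return list(status = "fixed"|"confirmed"|"extended"|"no_solution"|
#'   "tandem_repeat", tandemPeriod, change = one-row data.frame or NULL).
#' @export
reassembleRegion <- function(genome, scaffold, start, end, triggers,
                             alignments, config = polishConfig()) {
    isGap <- grepl("\\bgap\\b", triggers)
    gseq <- scaffoldSeq(genome, scaffold)
    k <- config@k
    noChange <- function(status, period = NA_integer_)
        list(status = status, tandemPeriod = period, change = NULL)
    reads <- collectReadsForRegion(scaffold, start, end, alignments, genome,
                                   config)
    if (!length(reads$seq)) return(noChange("no_solution"))
    graph <- buildKmerGraph(reads, config)
    if (graphSize(graph) == 0) return(noChange("no_solution"))
    seedL <- findSeed(graph, gseq, k, "left", start, end)
    seedR <- findSeed(graph, gseq, k, "right", start, end)
    le <- if (!is.null(seedL)) walkFromFlank(graph, seedL$kmer, config)
          else list()
    re <- if (!is.null(seedR)) walkFromFlank(graph, revComp(seedR$kmer),
                                             config) else list()
    if (!length(le) && !length(re)) return(noChange("no_solution"))
    cl <- attemptClosure(le, re, config)
    if (cl$outcome == "tandem_repeat")
        return(noChange("tandem_repeat", cl$tandemPeriod))
    if (cl$outcome == "closed") {
        merged <- cl$replacement
        srcStart <- seedL$at
        srcEnd <- seedR$at + k
        src <- substring(gseq, srcStart + 1L, srcEnd)
        if (grepl("N", merged, fixed = TRUE))
            return(noChange("no_solution"))
        if (identical(merged, src)) return(noChange("confirmed"))
        tr <- trimCommonEnds(src, merged, srcStart)
        chg <- data.frame(scaffold = scaffold, srcStart = tr$srcStart,
                          srcEnd = tr$srcStart + nchar(tr$src),
                          srcSeq = tr$src, destSeq = tr$dst,
                          category = if (isGap) "gap_fill" else "break_fix",
                          stringsAsFactors = FALSE)
        return(list(status = "fixed", tandemPeriod = NA_integer_,
                    change = chg))
    }
    ## extended: consensus from each available flank
    consL <- if (!is.null(seedL)) consensusExtension(graph, seedL$kmer, config)
             else ""
    consR <- if (!is.null(seedR))
        revComp(consensusExtension(graph, revComp(seedR$kmer), config))
        else ""
    leftAdd <- if (!is.null(seedL) && nchar(consL) > (start - seedL$at))
        substring(consL, start - seedL$at + 1L, nchar(consL)) else ""
    rightAdd <- if (!is.null(seedR) && nchar(consR) > (seedR$at + k - end))
        substring(consR, 1L, nchar(consR) - (seedR$at + k - end)) else ""
    la <- nchar(leftAdd); ra <- nchar(rightAdd)
    if (la + ra == 0L) return(noChange("no_solution"))
    gapLen <- end - start
    if (!isGap && !config@openNewGaps) return(noChange("no_solution"))
    ## keep at least one N between the extensions
    if (la + ra >= gapLen) {
        la2 <- min(la, max(0L, (gapLen - 1L) %/% 2L))
        ra2 <- min(ra, max(0L, gapLen - 1L - la2))
        la2 <- min(la, gapLen - 1L - ra2)
        leftAdd <- substring(leftAdd, 1L, la2)
        rightAdd <- substring(rightAdd, ra - ra2 + 1L, ra)
        la <- la2; ra <- ra2
        if (la + ra == 0L) return(noChange("no_solution"))
    }
    dest <- paste0(leftAdd, strrep("N", gapLen - la - ra), rightAdd)
    src <- substring(gseq, start + 1L, end)
    if (identical(dest, src)) return(noChange("no_solution"))
    chg <- data.frame(scaffold = scaffold, srcStart = start, srcEnd = end,
                      srcSeq = src, destSeq = dest,
                      category = if (isGap) "gap_shrink" else "break_fix",
                      stringsAsFactors = FALSE)
    list(status = "extended", tandemPeriod = NA_integer_, change = chg)
}

#' Fill one captured gap by local reassembly
#'
#' Convenience wrapper around \code{\link{reassembleRegion}} treating the
#' N-run itself as the untrusted region. Uncaptured (terminal) N-runs are
#' skipped.
#'
#' @param genome An \linkS4class{InputGenome}.
#' @param scaffold,start,end The N-run, 0-based half-open.
#' @param alignments list of \linkS4class{PolishAlignments}.
#' @param config A \linkS4class{PolishConfig}.
#' @return As \code{\link{reassembleRegion}}.
#' @export
fillCapturedGap <- function(genome, scaffold, start, end, alignments,
                            config = polishConfig()) {
    gt <- gapTable(genome)
    hit <- gt$scaffold == scaffold & gt$start <= start & gt$end >= end
    if (!any(hit & gt$captured))
        return(list(status = "no_solution", tandemPeriod = NA_integer_,
                    change = NULL))
    reassembleRegion(genome, scaffold, start, end, "gap", alignments, config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
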