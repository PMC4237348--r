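## exhaustive path oracle: enumerate all walks through the pruned graph with
## the same termination rules, independently of the DFS implementation
oracleWalk <- function(graph, seed, config) {
    out <- list()
    recurse <- function(cur, bases, branches, visited) {
        if (length(bases) >= config@maxWalkLength) {
            out[[length(out) + 1L]] <<- list(
                sequence = paste0(seed, paste(bases, collapse = "")),
                terminatedBy = "limit")
            return()
        }
        links <- graphLinks(graph, cur, config)
        if (nrow(links) == 0) {
            out[[length(out) + 1L]] <<- list(
                sequence = paste0(seed, paste(bases, collapse = "")),
                terminatedBy = "dead_end")
            return()
        }
        if (nrow(links) > 1 && branches >= config@branchLimit) {
            out[[length(out) + 1L]] <<- list(
                sequence = paste0(seed, paste(bases, collapse = "")),
                terminatedBy = "branch_limit")
            return()
        }
        b2 <- branches + (nrow(links) > 1)
        for (j in seq_len(nrow(links))) {
            nk <- paste0(substring(cur, 2), links$base[j])
            if (nk %in% names(visited)) {
                out[[length(out) + 1L]] <<- list(
                    sequence = paste0(seed, paste(c(bases, links$base[j]),
                                                  collapse = "")),
                    terminatedBy = "loop")
            } else {
                v2 <- c(visited, setNames(length(bases) + 1L, nk))
                recurse(nk, c(bases, links$base[j]), b2, v2)
            }
        }
    }
    recurse(seed, character(0), 0L, setNames(0L, seed))
    out
}

test_that("identical reads build a linear chain with full link support", {
    cfg <- polishConfig(k = 4L)
    s <- "ACGTTGCAAGGTCCATGGAACCTTGGACAATTGGCCAAGGTTCCAAGGTTAACCGGTTAA"
    gr <- buildKmerGraph(rep(s, 10), cfg)
    l <- graphLinks(gr, substring(s, 1, 4), cfg)
    expect_equal(nrow(l), 1L)
    expect_equal(l$count, 10L)
    ## every forward link along the chain has support 10
    for (i in 1:20) {
        l <- graphLinks(gr, substring(s, i, i + 3), cfg)
        expect_true(all(l$count >= 10L))
    }
})

test_that("links below the minimum coverage cutoff are pruned", {
    cfg <- polishConfig(k = 5L)
    s <- "AAGGCTCATGCGTAC"
    gr4 <- buildKmerGraph(rep(s, 4), cfg)
    expect_equal(nrow(graphLinks(gr4, "AAGGC", cfg)), 0L)   # support 4: pruned
    gr5 <- buildKmerGraph(rep(s, 5), cfg)
    l <- graphLinks(gr5, "AAGGC", cfg)
    expect_equal(l$count, 5L)                               # support 5: kept
})

test_that("a 50/50 biallelic site yields exactly one branch node", {
    cfg <- polishConfig(k = 5L)
    h1 <- "AAGGCTCATGCGTACCTTGG"
    h2 <- h1; substring(h2, 10, 10) <- "A"
    gr <- buildKmerGraph(c(rep(h1, 5), rep(h2, 5)), cfg)
    nBranch <- 0L
    for (i in 1:(nchar(h1) - 5)) {
        km <- substring(h1, i, i + 4)
        l <- graphLinks(gr, km, cfg)
        if (nrow(l) > 1) nBranch <- nBranch + 1L
    }
    expect_equal(nBranch, 1L)
})

test_that("a linear graph walks to a single full-length extension", {
    cfg <- polishConfig(k = 12L)
    set.seed(15)
    s <- paste(sample(c("A","C","G","T"), 80, replace = TRUE), collapse = "")
    gr <- buildKmerGraph(rep(s, 6), cfg)
    ex <- walkFromFlank(gr, substring(s, 1, 12), cfg)
    expect_length(ex, 1L)
    expect_equal(ex[[1]]$sequence, s)
    expect_equal(ex[[1]]$terminatedBy, "dead_end")
    expect_length(walkFromFlank(gr, strrep("G", 12), cfg), 0L)
})

test_that("walk enumeration matches the exhaustive path oracle", {
    set.seed(17)
    cfg <- polishConfig(k = 6L, maxWalkLength = 300L)
    for (rep_ in 1:6) {
        base <- paste(sample(c("A","C","G","T"), 120, replace = TRUE),
                      collapse = "")
        nvar <- sample(2:4, 1)
        at <- sort(sample(seq(15, 100, by = 15), nvar))
        h2 <- base
        for (p in at) {
            old <- substring(h2, p, p)
            substring(h2, p, p) <- sample(setdiff(c("A","C","G","T"), old), 1)
        }
        gr <- buildKmerGraph(c(rep(base, 6), rep(h2, 6)), cfg)
        seed <- substring(base, 1, 6)
        got <- walkFromFlank(gr, seed, cfg)
        want <- oracleWalk(gr, seed, cfg)
        expect_setequal(
            vapply(got, function(e) paste(e$sequence, e$terminatedBy), ""),
            vapply(want, function(e) paste(e$sequence, e$terminatedBy), ""))
    }
})

test_that("tandem repeats longer than k terminate walks as loops with the period", {
    cfg <- polishConfig(k = 47L)
    set.seed(23)
    unit <- paste(sample(c("A","C","G","T"), 57, replace = TRUE), collapse = "")
    pre <- paste(sample(c("A","C","G","T"), 80, replace = TRUE), collapse = "")
    post <- paste(sample(c("A","C","G","T"), 80, replace = TRUE), collapse = "")
    s <- paste0(pre, strrep(unit, 5), post)
    gr <- buildKmerGraph(rep(s, 8), cfg)
    ex <- walkFromFlank(gr, substring(s, 1, 47), cfg)
    loops <- Filter(function(e) e$terminatedBy == "loop", ex)
    expect_gte(length(loops), 1L)
    expect_true(any(vapply(loops, `[[`, 0L, "loopPeriod") == 57L))
    ## closure refuses to bridge a detected tandem
    cl <- attemptClosure(ex, list(), polishConfig())
    expect_equal(cl$outcome, "tandem_repeat")
    expect_equal(cl$tandemPeriod, 57L)
})

test_that("closure requires a unique perfect overlap of at least 2k+1", {
    set.seed(29)
    cfg <- polishConfig()          # k = 47, overlap 95
    rnd <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                             collapse = "")
    mkPair <- function(ov) {
        ovs <- rnd(ov)
        left <- paste0(rnd(150), ovs)
        rightLeftOriented <- paste0(ovs, rnd(150))
        list(left = left, right = as.character(
            Biostrings::reverseComplement(
                Biostrings::DNAString(rightLeftOriented))))
    }
    p95 <- mkPair(95)
    cl <- attemptClosure(p95$left, p95$right, cfg)
    expect_equal(cl$outcome, "closed")
    p94 <- mkPair(94)
    expect_equal(attemptClosure(p94$left, p94$right, cfg)$outcome, "extended")
    ## two distinct valid pairings: ambiguous, not closed
    q <- mkPair(100)
    q2 <- mkPair(100)
    cl2 <- attemptClosure(c(p95$left, q$left, q2$left),
                          c(p95$right, q$right, q2$right), cfg)
    expect_equal(cl2$outcome, "extended")
    expect_gt(length(cl2$candidates), 1L)
})

test_that("closure is symmetric under reverse complement", {
    set.seed(31)
    cfg <- polishConfig()
    rnd <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                             collapse = "")
    ovs <- rnd(100)
    left <- paste0(rnd(120), ovs)
    rightLO <- paste0(ovs, rnd(120))
    rightWalked <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rightLO)))
    cl <- attemptClosure(left, rightWalked, cfg)
    ## mirror the locus: the former right walk becomes the new left
    ## mirrored locus: former right walk becomes the left extension and the
    ## former left extension, reverse-complemented twice, is passed as-walked
    clRC <- attemptClosure(rightWalked, left, cfg)
    expect_equal(cl$outcome, "closed")
    expect_equal(clRC$outcome, "closed")
    expect_equal(clRC$replacement,
                 as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(cl$replacement))))
})

test_that("consensus extension follows weight and stops at ties", {
    cfg <- polishConfig(k = 5L)
    h1 <- "AAGGCTCATGCGTACCTTGGAACC"
    h2 <- h1; substring(h2, 12, 12) <- "T"
    gr <- buildKmerGraph(c(rep(h1, 10), rep(h2, 5)), cfg)
    cons <- consensusExtension(gr, substring(h1, 1, 5), cfg)
    expect_equal(cons, h1)            # majority haplotype followed to its end
    grTie <- buildKmerGraph(c(rep(h1, 5), rep(h2, 5)), cfg)
    consTie <- consensusExtension(grTie, substring(h1, 1, 5), cfg)
    expect_equal(consTie, substring(h1, 1, 11))   # stops before the split
    expect_equal(consensusExtension(gr, "GGGGG", cfg), "")
    expect_equal(commonPrefix(c("ACGTAA", "ACGTTT")), "ACGT")
})

test_that("captured gaps close exactly over unique sequence", {
    fx <- tinyFixture(len = 9000,
                      defects = list(list(type = "gap", at = 4000,
                                          len = 200)),
                      seed = 51, depth = 60)
    res <- fillCapturedGap(fx$draft, "scaffold1", 4000, 4200,
                           fx$alignments)
    expect_equal(res$status, "fixed")
    expect_equal(res$change$category, "gap_fill")
    expect_false(grepl("N", res$change$destSeq))
    expect_equal(res$change$destSeq,
                 substring(fx$truth, res$change$srcStart + 1,
                           res$change$srcEnd))
    ## uncaptured runs are skipped
    expect_equal(fillCapturedGap(fx$draft, "scaffold1", 0, 10,
                                 fx$alignments)$status, "no_solution")
})

test_that("a gap over a long-period tandem is reported, not closed", {
    fx <- tinyFixture(len = 9000,
                      repeats = list(list(type = "tandem", period = 60,
                                          copies = 6, at = 4000)),
                      defects = list(list(type = "gap", at = 4060,
                                          len = 240)),
                      seed = 53, depth = 60)
    res <- fillCapturedGap(fx$draft, "scaffold1", 4060, 4300,
                           fx$alignments)
    expect_equal(res$status, "tandem_repeat")
    expect_equal(res$tandemPeriod, 60L)
    expect_null(res$change)    # gap untouched
})

test_that("a gap with one covered flank extends from that side only", {
    fx <- tinyFixture(len = 9000,
                      defects = list(list(type = "gap", at = 4000,
                                          len = 400)),
                      seed = 55, depth = 60)
    aln <- fx$alignments[[1]]
    rec <- aln@records
    keep <- !is.na(rec$pos) & rec$pos >= 4000
    oneSided <- new("PolishAlignments", records = rec[keep, ],
                    kind = aln@kind, stats = aln@stats)
    res <- fillCapturedGap(fx$draft, "scaffold1", 4000, 4400,
                           list(oneSided))
    expect_equal(res$status, "extended")
    ch <- res$change
    expect_equal(ch$category, "gap_shrink")
    expect_true(grepl("^N+", ch$destSeq))        # left side stays N
    expect_true(grepl("[ACGT]+$", ch$destSeq))   # right side extended
})
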