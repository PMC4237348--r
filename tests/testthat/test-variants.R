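## brute-force oracle: minimal coordinate among all equivalent edits
oracleNormalize <- function(genome, pos, kind, seq) {
    apply1 <- function(p, s) {
        if (kind == "deletion")
            paste0(substring(genome, 1, p), substring(genome, p + nchar(s) + 1))
        else
            paste0(substring(genome, 1, p), s, substring(genome, p + 1))
    }
    target <- apply1(pos, seq)
    n <- nchar(seq)
    best <- NULL
    limit <- if (kind == "deletion") nchar(genome) - n else nchar(genome)
    for (p in 0:limit) {
        if (kind == "deletion") {
            s <- substring(genome, p + 1, p + n)
            if (apply1(p, s) == target) { best <- list(pos = p, seq = s); break }
        } else {
            for (s in apply(expand.grid(rep(list(c("A","C","G","T")), n)),
                            1, paste, collapse = "")) {
                if (apply1(p, s) == target) { best <- list(pos = p, seq = s);
                    break }
            }
            if (!is.null(best)) break
        }
    }
    best
}

test_that("homopolymer indels normalize to their leftmost placement", {
    for (off in 1:4)
        expect_equal(normalizeIndelLeft("ACCCCT", off, "deletion", "C")$pos, 1L)
    r <- normalizeIndelLeft("AAAT", 3, "insertion", "A")
    expect_equal(r$pos, 0L)
    expect_equal(r$seq, "A")
    r <- normalizeIndelLeft("ACGT", 1, "deletion", "C")
    expect_equal(r$pos, 1L)
    expect_error(normalizeIndelLeft("ACGT", 3, "deletion", "TT"), "past")
})

test_that("left normalization equals the brute-force oracle and is idempotent", {
    set.seed(3)
    genomes <- c(
        apply(expand.grid(rep(list(c("A","C")), 5)), 1, paste, collapse = ""),
        replicate(40, paste(sample(c("A","C","G","T"), 8, replace = TRUE),
                            collapse = "")))
    for (g in genomes) {
        L <- nchar(g)
        for (p in 0:(L - 1)) {
            ## all 1 bp deletions
            got <- normalizeIndelLeft(g, p, "deletion",
                                      substring(g, p + 1, p + 1))
            exp_ <- oracleNormalize(g, p, "deletion",
                                    substring(g, p + 1, p + 1))
            expect_equal(got$pos, exp_$pos)
            expect_equal(got$seq, exp_$seq)
            again <- normalizeIndelLeft(g, got$pos, "deletion", got$seq)
            expect_equal(again, got)
            ## 1 bp insertions of each base
            for (b in c("A", "T")) {
                got <- normalizeIndelLeft(g, p, "insertion", b)
                exp_ <- oracleNormalize(g, p, "insertion", b)
                ## oracle returns lexicographically-first equivalent seq at
                ## min pos; positions must agree, edited strings must agree
                expect_equal(got$pos, exp_$pos)
                apply1 <- function(pp, ss) paste0(substring(g, 1, pp), ss,
                                                  substring(g, pp + 1))
                expect_equal(apply1(got$pos, got$seq), apply1(p, b))
            }
        }
        ## a few 2 bp deletions
        for (p in 0:(L - 2)) {
            got <- normalizeIndelLeft(g, p, "deletion",
                                      substring(g, p + 1, p + 2))
            exp_ <- oracleNormalize(g, p, "deletion",
                                    substring(g, p + 1, p + 2))
            expect_equal(got$pos, exp_$pos)
        }
    }
})

test_that("equivalent indel observations merge into one tallied event", {
    g <- newInputGenome(c(s1 = "ACCCCTGGGG"))
    obs <- data.frame(scaffold = "s1", pos = c(1L, 2L, 3L, 4L),
                      kind = "deletion", seq = "C",
                      qname = paste0("r", 1:4), weight = 25,
                      stringsAsFactors = FALSE)
    tal <- tallyIndels(obs, g)
    expect_equal(nrow(tal), 1L)
    expect_equal(tal$pos, 1L)
    expect_equal(tal$supportCount, 4L)
    expect_equal(tal$supportWeight, 100)

    obs2 <- rbind(obs[1, ],
                  data.frame(scaffold = "s1", pos = 1L, kind = "deletion",
                             seq = "CC", qname = "r9", weight = 25,
                             stringsAsFactors = FALSE))
    expect_equal(nrow(tallyIndels(obs2, g)), 2L)
    empty <- obs[0, ]
    expect_equal(nrow(tallyIndels(empty, g)), 0L)
})

test_that("indel calls need a majority, relaxed for long events", {
    g <- newInputGenome(c(s1 = strrep("ACGTG", 20)))
    pu <- makePileupTable(100, validCov = rep(10L, 100))
    mkTally <- function(support, len) data.frame(
        scaffold = "s1", pos = 40L, kind = "deletion",
        seq = substring(strrep("ACGTG", 20), 41, 40 + len),
        supportCount = support, supportWeight = support * 28,
        stringsAsFactors = FALSE)
    expect_equal(nrow(callSmallIndels(mkTally(8, 1), pu)), 1L)   # 0.8 >= 0.5
    expect_equal(nrow(callSmallIndels(mkTally(3, 1), pu)), 0L)   # 0.3 < 0.5
    expect_equal(nrow(callSmallIndels(mkTally(4, 15), pu)), 1L)  # 0.4 >= 0.35
    expect_equal(nrow(callSmallIndels(mkTally(4, 10), pu)), 0L)  # len 10 still 0.5
})

test_that("changed bases yield fixes; ambiguous bases only when enabled", {
    g1 <- newInputGenome(c(s1 = "AAA"))
    cls <- list(s1 = data.frame(
        category = c("Confirmed", "Changed", "Ambiguous"),
        allele = c("A", "C", "G"), qual = c(900, 500, 100),
        qd = c(30, 25, 5), stringsAsFactors = FALSE))
    r <- callSnps(g1, cls, polishConfig())
    expect_equal(nrow(r$fixes), 1L)
    expect_equal(r$fixes$category, "snp")
    expect_equal(r$fixes$pos, 1L)
    expect_equal(sum(r$calls$ambiguous), 1L)   # reported, not fixed
    r2 <- callSnps(g1, cls, polishConfig(fixAmbiguous = TRUE))
    expect_equal(nrow(r2$fixes), 2L)
    expect_setequal(r2$fixes$category, c("snp", "ambiguous_fix"))
})
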