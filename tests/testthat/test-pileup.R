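test_that("read weight combines base quality with mapping confidence", {
    expect_equal(readWeight(30, 0), 0)
    expect_equal(readWeight(0, 60), 0)
    expect_equal(readWeight(30, 60), 30 * (1 - 1e-6))
    ## monotone nondecreasing in both arguments
    bq <- sample(0:40, 30, replace = TRUE)
    mq <- sample(0:60, 30, replace = TRUE)
    expect_true(all(readWeight(bq + 1, mq) >= readWeight(bq, mq)))
    expect_true(all(readWeight(bq, mq + 5) >= readWeight(bq, mq)))
})

test_that("a valid perfect-match read contributes weighted evidence", {
    g <- newInputGenome(c(s1 = "ACGTACGTACGTACGTACGT"))
    rec <- samRecord("r1", 5L, substring("ACGTACGTACGTACGTACGT", 6, 15),
                     qual = strrep("?", 10))   # '?' = Q30
    cfg <- polishConfig(flankTrim = 0L)
    acc <- accumulatePileups(g, ingestRecords(rec, g, "unpaired"), cfg)
    P <- acc$pileups@scaffolds$s1
    covered <- 6:15
    expect_equal(P$validCov[covered], rep(1L, 10))
    w <- rowSums(P$weights)[covered]
    expect_equal(w, rep(30 * (1 - 1e-6), 10))
    ## each base credited to the genome allele
    gb <- strsplit("ACGTACGTACGTACGTACGT", "")[[1]][covered]
    expect_equal(P$weights[cbind(covered, match(gb, c("A","C","G","T")))],
                 rep(30 * (1 - 1e-6), 10))
})

test_that("non-proper paired reads count only as bad coverage", {
    g <- newInputGenome(c(s1 = "ACGTACGTACGTACGTACGT"))
    bad <- samRecord("r1", 5L, "ACGTACGTAC", flag = 1L,   # paired, not proper
                     mrnm = "s1", mpos = 0L)
    ## one proper pair elsewhere so library statistics are computable
    anchor <- rbind(
        samRecord("p1", 0L, "ACGTA", flag = 1L + 2L + 64L, mrnm = "s1",
                  mpos = 0L, isize = 5L),
        samRecord("p1", 0L, "ACGTA", flag = 1L + 2L + 16L + 128L,
                  mrnm = "s1", mpos = 0L, isize = -5L))
    acc <- accumulatePileups(g, ingestRecords(rbind(bad, anchor), g,
                                              "fragment"),
                             polishConfig(flankTrim = 0L))
    P <- acc$pileups@scaffolds$s1
    expect_equal(P$badCov[6:15], rep(1L, 10))
    expect_equal(sum(P$weights[6:15, ]), 0)
    expect_equal(P$validCov[6:15], rep(0L, 10))
})

test_that("soft clips mark the transition and are excluded from coverage", {
    g <- newInputGenome(c(s1 = strrep("ACGT", 10)))
    rec <- samRecord("r1", 10L, strrep("A", 15), cigar = "5S10M",
                     qual = strrep("?", 15))
    acc <- accumulatePileups(g, ingestRecords(rec, g, "unpaired"),
                             polishConfig(flankTrim = 0L))
    P <- acc$pileups@scaffolds$s1
    expect_equal(P$clipStarts[11], 1L)     # transition at match start (0-based 10)
    expect_equal(sum(P$validCov), 10L)     # clipped bases not counted
})

test_that("base classification follows the four-category rules", {
    cfg <- polishConfig()
    mkW <- function(a, c, g = 0, t = 0) {
        w <- matrix(0, 1, 4, dimnames = list(NULL, c("A","C","G","T")))
        w[1, ] <- c(a, c, g, t); w
    }
    g1 <- newInputGenome(c(s1 = "A"))
    cl <- function(w, vc) classifyBases(
        g1, makePileupTable(1, validCov = vc, weights = w), cfg)$s1
    expect_equal(cl(mkW(300, 0), 10)$category, "Confirmed")
    r <- cl(mkW(10, 290), 10)
    expect_equal(r$category, "Changed")
    expect_equal(r$allele, "C")
    expect_equal(cl(mkW(140, 160), 10)$category, "Ambiguous")
    expect_equal(cl(mkW(300, 0), 0)$category, "Unconfirmed")
    expect_equal(cl(mkW(0, 0), 10)$category, "Unconfirmed")
    ## an exact top tie is never called Changed
    expect_equal(cl(mkW(0, 150, 150), 10)$category, "Ambiguous")
})

test_that("classification is invariant to uniform weight scaling", {
    cfg <- polishConfig()
    g1 <- newInputGenome(c(s1 = "A"))
    set.seed(11)
    for (i in 1:40) {
        w <- matrix(runif(4) * 100, 1, 4,
                    dimnames = list(NULL, c("A","C","G","T")))
        c1 <- classifyBases(g1, makePileupTable(1, 20, weights = w),
                            cfg)$s1$category
        c2 <- classifyBases(g1, makePileupTable(1, 20, weights = w * 37.5),
                            cfg)$s1$category
        expect_identical(c1, c2)
    }
})

test_that("error-free coverage confirms every covered position", {
    fx <- tinyFixture(len = 6000, defects = list(), seed = 5, depth = 60)
    acc <- accumulatePileups(fx$draft, fx$alignments)
    cls <- classifyBases(fx$draft, acc$pileups)
    cat_ <- cls[[1]]$category
    covered <- cat_ != "Unconfirmed"
    expect_gt(mean(covered), 0.95)
    expect_true(all(cat_[covered] == "Confirmed"))
    ## weight conservation: on this defect-free fixture every alignment is a
    ## pure match, so allele counts must equal valid reads x trimmed length
    P <- acc$pileups@scaffolds[[1]]
    rec <- fx$alignments[[1]]@records
    valid <- !rec$unmapped & rec$proper
    expect_true(all(grepl("^\\d+M$", rec$cigar[valid])))
    expect_equal(sum(P$counts), sum(nchar(rec$seq[valid]) - 2L * 5L))
})

test_that("high-mapping-quality reads dominate a repeat-haplotype call", {
    ## two-copy repeat scenario: MQ60 long-insert-anchored reads support the
    ## genome-true allele C, MQ2 intra-repeat fragment reads support T
    g <- newInputGenome(c(s1 = strrep("ACGTG", 8)))
    base <- strrep("ACGTG", 8)
    alt <- base; substring(alt, 11, 11) <- "T"
    recs <- rbind(
        do.call(rbind, lapply(1:6, function(i)
            samRecord(sprintf("hi%d", i), 0L, substring(base, 1, 20),
                      qual = strrep("?", 20), mapq = 60L))),
        do.call(rbind, lapply(1:12, function(i)
            samRecord(sprintf("lo%d", i), 0L, substring(alt, 1, 20),
                      qual = strrep("?", 20), mapq = 2L))))
    acc <- accumulatePileups(g, ingestRecords(recs, g, "unpaired"),
                             polishConfig(flankTrim = 0L))
    cls <- classifyBases(g, acc$pileups)
    expect_equal(cls$s1$allele[11], substring(base, 11, 11))
})
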