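## naive oracle: apply edits right-to-left on a plain string
oracleApply <- function(s, changes) {
    ch <- changes[order(-changes$srcStart), , drop = FALSE]
    for (i in seq_len(nrow(ch)))
        s <- paste0(substring(s, 1, ch$srcStart[i]), ch$destSeq[i],
                    substring(s, ch$srcEnd[i] + 1))
    s
}

mkChange <- function(scaffold, srcStart, srcEnd, srcSeq, destSeq, category) {
    data.frame(scaffold = scaffold, srcStart = srcStart, srcEnd = srcEnd,
               srcSeq = srcSeq, destSeq = destSeq, category = category,
               stringsAsFactors = FALSE)
}

test_that("applying changes tracks destination coordinates exactly", {
    s <- strrep("ACGTG", 40)
    g <- newInputGenome(c(s1 = s))
    none <- applyChanges(g, mkChange(character(), integer(), integer(),
                                     character(), character(), character()))
    expect_identical(as.character(genomeSequences(none$genome)[[1]]), s)

    one <- applyChanges(g, mkChange("s1", 10L, 11L,
                                    substring(s, 11, 11), "T", "snp"))
    out <- as.character(genomeSequences(one$genome)[[1]])
    expect_equal(sum(strsplit(out, "")[[1]] != strsplit(s, "")[[1]]), 1L)

    two <- applyChanges(g, rbind(
        mkChange("s1", 10L, 11L, substring(s, 11, 11), "T", "snp"),
        mkChange("s1", 100L, 100L, "", "AACCG", "small_insertion")))
    expect_equal(two$changes$destStart, c(10L, 100L))
    expect_equal(two$changes$destEnd, c(11L, 105L))
    expect_identical(as.character(genomeSequences(two$genome)[[1]]),
                     oracleApply(s, two$changes))
    expect_error(applyChanges(g, rbind(
        mkChange("s1", 10L, 20L, substring(s, 11, 20), "", "small_deletion"),
        mkChange("s1", 15L, 16L, substring(s, 16, 16), "A", "snp"))),
        "overlapping")
})

test_that("random change sets match the string-edit oracle", {
    set.seed(41)
    s <- paste(sample(c("A","C","G","T"), 600, replace = TRUE), collapse = "")
    g <- newInputGenome(c(s1 = s))
    for (rep_ in 1:10) {
        starts <- sort(sample(seq(10, 550, by = 30), 6))
        rows <- lapply(starts, function(p) {
            ty <- sample(c("snp", "ins", "del"), 1)
            if (ty == "snp") mkChange("s1", p, p + 1L,
                                      substring(s, p + 1, p + 1),
                                      sample(c("A","C","G","T"), 1), "snp")
            else if (ty == "ins") mkChange("s1", p, p, "",
                paste(sample(c("A","C","G","T"), 3, replace = TRUE),
                      collapse = ""), "small_insertion")
            else mkChange("s1", p, p + 4L, substring(s, p + 1, p + 4),
                          "", "small_deletion")
        })
        ch <- do.call(rbind, rows)
        got <- applyChanges(g, ch)
        expect_identical(as.character(genomeSequences(got$genome)[[1]]),
                         oracleApply(s, ch))
    }
})

test_that("VCF records follow the anchor-base and SV conventions", {
    set.seed(43)
    s <- paste(sample(c("A","C","G","T"), 300, replace = TRUE), collapse = "")
    substring(s, 10, 10) <- "A"
    g <- newInputGenome(c(s1 = s))
    variants <- data.frame(
        scaffold = "s1",
        pos = c(9L, 50L, 100L),
        ref = c("A", NA, substring(s, 101, 150)),
        alt = c("C", NA, ""),
        kind = c("snp", "insertion", "sv"),
        seq = c(NA, "GGT", NA),
        qual = c(500, 300, 0), qd = c(25, 10, 0),
        ambiguous = FALSE, stringsAsFactors = FALSE)
    f <- tempfile(fileext = ".vcf")
    writeVcf(g, variants, f)
    lines <- grep("^[^#]", readLines(f), value = TRUE)
    parts <- strsplit(lines, "\t")
    ## SNP at 0-based 9 -> POS 10, REF A, ALT C
    expect_equal(parts[[1]][2], "10")
    expect_equal(parts[[1]][4], "A")
    expect_equal(parts[[1]][5], "C")
    ## insertion before 0-based 50 -> anchored at POS 50
    expect_equal(parts[[2]][2], "50")
    expect_equal(nchar(parts[[2]][5]), 4L)
    expect_equal(substring(parts[[2]][5], 2), "GGT")
    ## 50 bp deletion [100,150): POS 100, REF 51 bases, SVLEN -50
    expect_equal(parts[[3]][2], "100")
    expect_equal(nchar(parts[[3]][4]), 51L)
    expect_match(parts[[3]][8], "SVTYPE=DEL")
    expect_match(parts[[3]][8], "SVLEN=-50")
    ## structural validity + REF matches the genome (independent parser)
    vcf <- VariantAnnotation::readVcf(f, genome = "test")
    expect_equal(length(vcf), 3L)
    refs <- as.character(VariantAnnotation::ref(vcf))
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))
    for (i in seq_along(refs))
        expect_equal(refs[i],
                     substring(s, pos[i], pos[i] + nchar(refs[i]) - 1L))
})

test_that("the changes file replays to the output genome bit-exactly", {
    fx <- tinyFixture(len = 9000,
                      defects = list(list(type = "snp", at = 2000),
                                     list(type = "del", at = 3000, len = 2),
                                     list(type = "gap", at = 5000, len = 200)),
                      seed = 61, depth = 60)
    dir <- tempfile(); dir.create(dir)
    fa <- file.path(dir, "d.fa"); writeGenomeFasta(fx$draft, fa)
    sam <- file.path(dir, "f.sam")
    writeSam(fx$alignments[[1]]@records, fx$draft, sam)
    res <- runPolish(fa, frags = sam, quiet = TRUE,
                     output = file.path(dir, "out"))
    chf <- file.path(dir, "out.changes")
    expect_true(file.exists(chf))
    replay <- applyChanges(readInputGenome(fa), readChangesFile(chf))
    f1 <- file.path(dir, "replay.fa")
    writeGenomeFasta(replay$genome, f1)
    expect_identical(readLines(f1), readLines(file.path(dir, "out.fasta")))
})

test_that("wiggle tracks serialize arrays byte-for-byte", {
    vc <- sample(0:50, 100, replace = TRUE)
    pt <- makePileupTable(100, validCov = vc, totalCov = rep(10L, 100))
    pre <- tempfile()
    files <- writeTracks(pt, prefix = pre)
    wig <- readLines(paste0(pre, "ValidCoverage.wig"))
    expect_equal(wig[2], "fixedStep chrom=s1 start=1 step=1")
    expect_identical(wig[3:102], as.character(vc))
    pct <- readLines(paste0(pre, "PctBadAlignments.wig"))
    vals <- as.integer(pct[3:102])
    expect_true(all(vals >= 0 & vals <= 100))
})

test_that("the summary reports confirmation, changes and tandem periods", {
    fx <- tinyFixture(len = 5000, defects = list(), seed = 63, depth = 60)
    dir <- tempfile(); dir.create(dir)
    fa <- file.path(dir, "d.fa"); writeGenomeFasta(fx$draft, fa)
    sam <- file.path(dir, "f.sam")
    writeSam(fx$alignments[[1]]@records, fx$draft, sam)
    res <- runPolish(fa, frags = sam, quiet = TRUE)
    lines <- writeSummary(res, con = nullfile())
    expect_true(any(grepl("Confirmed", lines)))
    expect_true(any(grepl("Changes applied: none", lines)))
    ## tandem period reporting path
    reg <- GenomicRanges::GRanges("scaffold1", IRanges::IRanges(100, 200),
                                  triggers = "clip", status = "tandem_repeat",
                                  tandemPeriod = 57L)
    res2 <- res; res2@regions <- reg
    lines2 <- writeSummary(res2, con = nullfile())
    expect_true(any(grepl("period 57", lines2)))
})
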