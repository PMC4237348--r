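## Shared fixture builders: everything is generated in code at test time.

## A PileupTable with one scaffold built from explicit arrays (defaults: no
## evidence). Used to exercise classifiers/detectors without simulation.
makePileupTable <- function(L, validCov = NULL, fragCov = NULL,
                            totalCov = NULL, badCov = NULL,
                            clipStarts = NULL, weights = NULL,
                            readLengthMode = 100L) {
    P <- burnish:::emptyScaffoldPileup(L)
    if (!is.null(validCov)) P$validCov <- as.integer(validCov)
    if (!is.null(fragCov)) P$fragCov <- as.integer(fragCov)
    if (!is.null(totalCov)) P$totalCov <- as.integer(totalCov)
    if (!is.null(badCov)) P$badCov <- as.integer(badCov)
    if (!is.null(clipStarts)) P$clipStarts <- as.integer(clipStarts)
    if (!is.null(weights)) P$weights <- weights
    new("PileupTable", scaffolds = list(s1 = P),
        readLengthMode = as.integer(readLengthMode))
}

## Write records to SAM and read them back through the normal ingest path.
ingestRecords <- function(records, genome, kind = "fragment") {
    f <- tempfile(fileext = ".sam")
    writeSam(records, genome, f)
    readAlignments(f, kind, genome)
}

## One perfect-match alignment record (0-based pos).
samRecord <- function(qname, pos, seq, qual = strrep("I", nchar(seq)),
                      flag = 0L, mapq = 60L, cigar = NULL, rname = "s1",
                      mrnm = NA_character_, mpos = NA_integer_,
                      isize = NA_integer_) {
    data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
               mapq = mapq,
               cigar = if (is.null(cigar)) sprintf("%dM", nchar(seq))
                       else cigar,
               mrnm = mrnm, mpos = mpos, isize = isize,
               seq = seq, qual = qual, stringsAsFactors = FALSE)
}

## Simulated end-to-end mini-fixture: truth genome + defects -> draft, reads,
## projected SAM, ingested alignments. Error-free fragment library unless
## stated otherwise.
tinyFixture <- function(len = 8000, defects = list(), seed = 42,
                        depth = 60, jumpDepth = 0, repeats = list()) {
    gen <- generateGenome(len, seed = seed, repeats = repeats)
    pd <- plantDefects(gen, defects, seed = seed)
    draft <- newInputGenome(pd$draft)
    truth <- unname(gen$seq)
    alns <- list()
    fr <- simulateReads(truth, "fragment", 180, 18, 100, depth, 0,
                        seed = seed + 1)
    fsam <- tempfile(fileext = ".sam")
    writeSam(projectAlignments(fr, pd$ledger, 180, 18), draft, fsam)
    alns$frag <- readAlignments(fsam, "fragment", draft)
    if (jumpDepth > 0) {
        ju <- simulateReads(truth, "long_insert", 3000, 300, 100, jumpDepth,
                            0, seed = seed + 2)
        jsam <- tempfile(fileext = ".sam")
        writeSam(projectAlignments(ju, pd$ledger, 3000, 300), draft, jsam)
        alns$jump <- readAlignments(jsam, "long_insert", draft)
    }
    list(truth = truth, draft = draft, ledger = pd$ledger,
         alignments = unname(alns), gen = gen)
}

## Cache the expensive benchmark run once per test session.
.benchEnv <- new.env()
benchmarkRun <- function() {
    if (is.null(.benchEnv$res)) {
        dir <- file.path(tempdir(), "benchfix")
        fx <- benchmarkFixture(dir, seed = 1)
        res <- runPolish(fx$genomeFile, frags = fx$fragSam,
                         jumps = fx$jumpSam, quiet = TRUE)
        .benchEnv$fx <- fx
        .benchEnv$res <- res
    }
    list(fx = .benchEnv$fx, res = .benchEnv$res)
}
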