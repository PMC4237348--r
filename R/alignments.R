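## Alignment ingest: SAM/BAM -> flat record table + per-library statistics.

FLAG_PAIRED <- 0x1L; FLAG_PROPER <- 0x2L; FLAG_UNMAPPED <- 0x4L
FLAG_MUNMAPPED <- 0x8L; FLAG_REVERSE <- 0x10L; FLAG_MREVERSE <- 0x20L
FLAG_READ1 <- 0x40L; FLAG_READ2 <- 0x80L; FLAG_SECONDARY <- 0x100L
FLAG_QCFAIL <- 0x200L; FLAG_DUP <- 0x400L; FLAG_SUPPL <- 0x800L

#' Read one alignment library (SAM or BAM)
#'
#' Loads a coordinate-sorted SAM/BAM into a flat record table, dropping
#' secondary, supplementary, duplicate-flagged and QC-fail records entirely.
#' Unmapped records (placed mates) are kept: local reassembly recruits them
#' through their anchored mates. Library statistics (insert size distribution
#' over proper pairs, modal read length, mean coverage) are computed on load.
#'
#' @param path SAM or BAM file. SAM is converted (sorted + indexed) on the fly.
#' @param kind Library kind: "fragment", "long_insert" or "unpaired".
#' @param genome The \linkS4class{InputGenome} the reads were aligned to.
#' @return A \linkS4class{PolishAlignments}.
#' @export
readAlignments <- function(path, kind = c("fragment", "long_insert", "unpaired"),
                           genome) {
    kind <- match.arg(kind)
    if (!file.exists(path)) stop("alignment file not found: ", path)
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile()
        path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                                 indexDestination = TRUE)
    }
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "mrnm", "mpos", "isize", "seq", "qual"))
    res <- Rsamtools::scanBam(path, param = p)[[1]]
    flag <- res$flag
    keep <- bitwAnd(flag, FLAG_SECONDARY + FLAG_QCFAIL + FLAG_DUP + FLAG_SUPPL) == 0L
    rec <- data.frame(
        qname = res$qname[keep],
        flag = flag[keep],
        rname = as.character(res$rname)[keep],
        pos = res$pos[keep] - 1L,             # 0-based
        mapq = res$mapq[keep],
        cigar = res$cigar[keep],
        mrnm = as.character(res$mrnm)[keep],
        mpos = res$mpos[keep] - 1L,
        isize = res$isize[keep],
        seq = as.character(res$seq)[keep],
        qual = as.character(res$qual)[keep],
        stringsAsFactors = FALSE)
    fl <- rec$flag
    rec$paired <- bitwAnd(fl, FLAG_PAIRED) > 0L
    rec$proper <- bitwAnd(fl, FLAG_PROPER) > 0L
    rec$unmapped <- bitwAnd(fl, FLAG_UNMAPPED) > 0L
    rec$mateUnmapped <- bitwAnd(fl, FLAG_MUNMAPPED) > 0L
    rec$reverse <- bitwAnd(fl, FLAG_REVERSE) > 0L
    stats <- scanLibraryStats(rec, genome, kind)
    new("PolishAlignments", records = rec, kind = kind, stats = stats)
}

#' Compute library statistics from normalized records
#'
#' Insert mean/sd are computed over proper pairs only, using the absolute
#' template length of leftmost-read records (population sd); mean coverage is
#' total aligned (M-op) bases over the non-N genome length.
#'
#' @param records Normalized record data.frame (see \code{readAlignments}).
#' @param genome The \linkS4class{InputGenome}.
#' @param kind Library kind.
#' @return A \linkS4class{LibraryStats}.
#' @export
scanLibraryStats <- function(records, genome,
                             kind = c("fragment", "long_insert", "unpaired")) {
    kind <- match.arg(kind)
    mapped <- records[!records$unmapped & !is.na(records$pos), , drop = FALSE]
    if (nrow(mapped) == 0) stop("no mapped records in library")
    rl <- nchar(mapped$seq)
    rlMode <- as.integer(names(sort(table(rl), decreasing = TRUE))[1])
    nonN <- sum(scaffoldLengths(genome)) -
        sum(gapTable(genome)$end - gapTable(genome)$start)
    alignedBases <- sum(cigarRefSpanFromOps(mapped$cigar, "M"))
    meanCov <- alignedBases / max(1, nonN)
    if (kind == "unpaired") {
        im <- NA_real_; isd <- NA_real_
    } else {
        tl <- mapped$isize[mapped$proper & !is.na(mapped$isize) & mapped$isize > 0]
        if (length(tl) == 0)
            stop("paired library '", kind, "' has no proper pairs; ",
                 "check that the aligner set the PROPER_PAIR flag")
        im <- mean(tl)
        isd <- sqrt(mean((tl - im)^2))   # population sd, deterministic
    }
    new("LibraryStats", kind = kind, insertMean = im, insertSd = isd,
        readLengthMode = rlMode, meanCoverage = meanCov)
}

#' Warn about inputs below the recommended operating point
#'
#' The pipeline is tuned for reads of 75 bases or longer and total coverage
#' of 50x or greater; inputs below that produce warnings, not errors.
#'
#' @param stats A \linkS4class{LibraryStats} or list of them.
#' @return Character vector of warnings (empty when none).
#' @export
validateInputs <- function(stats) {
    if (is(stats, "LibraryStats")) stats <- list(stats)
    w <- character()
    for (s in stats)
        if (s@readLengthMode < 75L)
            w <- c(w, sprintf(
                "library '%s': modal read length %d is below the recommended 75 bases",
                s@kind, s@readLengthMode))
    total <- sum(vapply(stats, function(s) s@meanCoverage, 0))
    if (total < 50)
        w <- c(w, sprintf(
            "total coverage %.1fx is below the recommended 50x", total))
    w
}

## ---- CIGAR utilities (vectorized) ----------------------------------------

## Expand CIGAR strings into a per-op table with 0-based reference and query
## offsets of each op within its alignment.
## Returns data.table: rid, op, len, refOff, qOff
cigarOpTable <- function(cigars) {
    m <- gregexpr("\\d+[MIDNSHP=X]", cigars)
    toks <- regmatches(cigars, m)
    nOps <- lengths(toks)
    toks <- unlist(toks, use.names = FALSE)
    dt <- data.table::data.table(
        rid = rep.int(seq_along(cigars), nOps),
        len = as.integer(sub("[A-Z=]$", "", toks)),
        op = substring(toks, nchar(toks), nchar(toks)))
    refc <- dt$op %in% c("M", "D", "N", "=", "X")
    qc <- dt$op %in% c("M", "I", "S", "=", "X")
    dt[, `:=`(refStep = len * refc, qStep = len * qc)]
    dt[, `:=`(refOff = cumsum(refStep) - refStep,
              qOff = cumsum(qStep) - qStep), by = "rid"]
    dt[, c("refStep", "qStep") := NULL]
    dt
}

## Total reference span (or aligned-base count for op="M") per CIGAR.
cigarRefSpanFromOps <- function(cigars, which = c("ref", "M")) {
    which <- match.arg(which)
    ok <- !is.na(cigars)
    out <- numeric(length(cigars))
    if (!any(ok)) return(out)
    dt <- cigarOpTable(cigars[ok])
    sel <- if (which == "M") dt$op %in% c("M", "=", "X")
           else dt$op %in% c("M", "D", "N", "=", "X")
    agg <- dt[sel, list(n = sum(len)), by = "rid"]
    tmp <- numeric(sum(ok))
    tmp[agg$rid] <- agg$n
    out[ok] <- tmp
    out
}

## Decode Phred qualities of many reads into one integer vector, with the
## per-read offsets needed to index it: list(q = int vector, off = start-1).
decodeQuals <- function(qual) {
    big <- paste(qual, collapse = "")
    q <- as.integer(charToRaw(big)) - 33L
    off <- cumsum(c(0L, nchar(qual)))[seq_along(qual)]
    list(q = q, off = off)
}

## Encode read bases as integers 1..4 (A,C,G,T), 0 otherwise; same layout.
decodeBases <- function(seqs) {
    big <- paste(seqs, collapse = "")
    r <- charToRaw(big)
    lut <- integer(256)
    lut[as.integer(charToRaw("A")) + 1L] <- 1L
    lut[as.integer(charToRaw("C")) + 1L] <- 2L
    lut[as.integer(charToRaw("G")) + 1L] <- 3L
    lut[as.integer(charToRaw("T")) + 1L] <- 4L
    b <- lut[as.integer(r) + 1L]
    off <- cumsum(c(0L, nchar(seqs)))[seq_along(seqs)]
    list(b = b, off = off)
}
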