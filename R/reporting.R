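## Output generation: apply edits, emit FASTA/VCF/changes/tracks/summary.
## Internal coordinates are 0-based half-open; this module is the single
## conversion point to the 1-based conventions of VCF and the changes file.

#' Apply accepted changes to the genome
#'
#' Changes must be non-overlapping in source coordinates. They are applied
#' in ascending coordinate order per scaffold; destination coordinates are
#' tracked through the cumulative length shift so that replaying the changes
#' ledger transforms the input genome into the output genome exactly.
#'
#' @param genome An \linkS4class{InputGenome}.
#' @param changes data.frame with columns scaffold, srcStart, srcEnd
#'   (0-based half-open), srcSeq, destSeq, category.
#' @return list(genome = polished \linkS4class{InputGenome},
#'   changes = input changes augmented with destStart/destEnd).
#' @export
applyChanges <- function(genome, changes) {
    seqs <- stats::setNames(as.character(genome@sequences),
                            names(genome@sequences))
    if (nrow(changes) == 0) {
        changes$destStart <- integer(0); changes$destEnd <- integer(0)
        return(list(genome = newInputGenome(seqs), changes = changes))
    }
    changes <- changes[order(changes$scaffold, changes$srcStart,
                             changes$srcEnd), , drop = FALSE]
    changes$destStart <- NA_integer_
    changes$destEnd <- NA_integer_
    for (scaf in unique(changes$scaffold)) {
        idx <- which(changes$scaffold == scaf)
        ch <- changes[idx, ]
        if (any(ch$srcStart[-1] < ch$srcEnd[-nrow(ch)]))
            stop("overlapping changes on scaffold ", scaf,
                 " (internal logic error)")
        s <- seqs[[scaf]]
        obs <- substring(s, ch$srcStart + 1L, ch$srcEnd)
        if (!all(obs == ch$srcSeq))
            stop("change source sequence does not match genome on ", scaf)
        pieces <- character(2L * nrow(ch) + 1L)
        cursor <- 0L; off <- 0L
        for (j in seq_len(nrow(ch))) {
            pieces[2L * j - 1L] <- substring(s, cursor + 1L, ch$srcStart[j])
            pieces[2L * j] <- ch$destSeq[j]
            changes$destStart[idx[j]] <- ch$srcStart[j] + off
            changes$destEnd[idx[j]] <- ch$srcStart[j] + off +
                nchar(ch$destSeq[j])
            off <- off + nchar(ch$destSeq[j]) - (ch$srcEnd[j] - ch$srcStart[j])
            cursor <- ch$srcEnd[j]
        }
        pieces[2L * nrow(ch) + 1L] <- substring(s, cursor + 1L, nchar(s))
        seqs[[scaf]] <- paste(pieces, collapse = "")
    }
    list(genome = newInputGenome(seqs), changes = changes)
}

vcfAnchored <- function(gseq, pos, srcSeq, destSeq) {
    ## anchor-base convention: returns list(pos1, ref, alt)
    if (pos > 0) {
        anchor <- substring(gseq, pos, pos)
        list(pos1 = pos, ref = paste0(anchor, srcSeq),
             alt = paste0(anchor, destSeq))
    } else {
        after <- substring(gseq, nchar(srcSeq) + 1L, nchar(srcSeq) + 1L)
        list(pos1 = 1L, ref = paste0(srcSeq, after),
             alt = paste0(destSeq, after))
    }
}

#' Write variant calls as VCF 4.2
#'
#' In "variants_only" mode one record per call is emitted; in "all_sites"
#' mode every reference position additionally gets a record carrying its
#' pileup evidence. Indels use the anchor-base convention; large events
#' from local reassembly carry SVTYPE/SVLEN and the full assembled ALT
#' sequence when closed. Ambiguous sites are annotated with FILTER=Amb.
#'
#' @param genome An \linkS4class{InputGenome}.
#' @param variants Unified variant data.frame (see \code{\link{runPolish}}).
#' @param path Output path.
#' @param mode "variants_only" or "all_sites".
#' @param pileups,classifications Required for "all_sites" mode.
#' @return Invisibly, \code{path}.
#' @export
writeVcf <- function(genome, variants, path,
                     mode = c("variants_only", "all_sites"),
                     pileups = NULL, classifications = NULL) {
    mode <- match.arg(mode)
    lens <- scaffoldLengths(genome)
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##source=burnish",
        sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
        "##INFO=<ID=VC,Number=1,Type=Integer,Description=\"Valid-pair coverage\">",
        "##INFO=<ID=BC,Number=1,Type=Integer,Description=\"Non-valid (bad) coverage\">",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Depth-normalized call quality (QUAL/VC)\">",
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
        "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length difference of ALT versus REF\">",
        "##FILTER=<ID=Amb,Description=\"Evidence supports more than one allele\">",
        "##FILTER=<ID=LowCov,Description=\"Insufficient valid coverage\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              sep = "\t"))
    lines <- character()
    fmtInfo <- function(scaf, pos0, extra = character()) {
        info <- extra
        if (!is.null(pileups)) {
            P <- pileups@scaffolds[[scaf]]
            i <- pos0 + 1L
            info <- c(sprintf("DP=%d", P$totalCov[i]),
                      sprintf("VC=%d", P$validCov[i]),
                      sprintf("BC=%d", P$badCov[i]), extra)
        }
        if (!length(info)) "." else paste(info, collapse = ";")
    }
    if (nrow(variants)) {
        v <- variants[order(variants$scaffold, variants$pos), , drop = FALSE]
        for (i in seq_len(nrow(v))) {
            r <- v[i, ]
            gseq <- scaffoldSeq(genome, r$scaffold)
            qd <- sprintf("QD=%.2f", r$qd)
            if (r$kind == "snp") {
                pos1 <- r$pos + 1L; ref <- r$ref; alt <- r$alt
                extra <- qd
            } else if (r$kind == "insertion") {
                a <- vcfAnchored(gseq, r$pos, "", r$seq)
                pos1 <- a$pos1; ref <- a$ref; alt <- a$alt
                extra <- qd
            } else if (r$kind == "deletion") {
                a <- vcfAnchored(gseq, r$pos, r$seq, "")
                pos1 <- a$pos1; ref <- a$ref; alt <- a$alt
                extra <- qd
            } else {  # sv: block substitution from reassembly
                a <- vcfAnchored(gseq, r$pos, r$ref, r$alt)
                pos1 <- a$pos1; ref <- a$ref; alt <- a$alt
                svlen <- nchar(r$alt) - nchar(r$ref)
                extra <- c(qd, sprintf("SVTYPE=%s",
                                       if (svlen >= 0) "INS" else "DEL"),
                           sprintf("SVLEN=%d", svlen))
            }
            filt <- if (isTRUE(r$ambiguous)) "Amb" else "PASS"
            lines <- c(lines, paste(
                r$scaffold, pos1, ".", ref, alt,
                sprintf("%.1f", r$qual), filt,
                fmtInfo(r$scaffold, r$pos, extra), sep = "\t"))
        }
    }
    if (mode == "all_sites" && !is.null(pileups) &&
        !is.null(classifications)) {
        siteLines <- character()
        callPos <- paste(variants$scaffold, variants$pos)
        for (scaf in names(pileups@scaffolds)) {
            P <- pileups@scaffolds[[scaf]]
            cl <- classifications[[scaf]]
            gb <- strsplit(scaffoldSeq(genome, scaf), "")[[1]]
            L <- length(gb)
            skip <- paste(scaf, seq_len(L) - 1L) %in% callPos
            for (i in which(!skip & gb != "N")) {
                filt <- switch(cl$category[i], Unconfirmed = "LowCov",
                               Ambiguous = "Amb", "PASS")
                siteLines <- c(siteLines, paste(
                    scaf, i, ".", gb[i], ".",
                    sprintf("%.1f", cl$qual[i]), filt,
                    fmtInfo(scaf, i - 1L, sprintf("QD=%.2f", cl$qd[i])),
                    sep = "\t"))
            }
        }
        lines <- c(lines, siteLines)
        ## keep records sorted by CHROM, POS
        if (length(lines)) {
            key <- do.call(rbind, strsplit(lines, "\t"))
            lines <- lines[order(key[, 1], as.integer(key[, 2]))]
        }
    }
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Write the changes ledger as TSV
#'
#' One row per edit with 1-based fully-closed source and destination
#' coordinates (for a pure insertion the interval is written as
#' \code{start-(start-1)}, i.e. empty) and the source/destination sequences
#' ("." when empty). Columns: sourceCoords, destCoords, sourceSeq, destSeq,
#' category.
#'
#' @param changes Augmented changes data.frame from
#'   \code{\link{applyChanges}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeChangesFile <- function(changes, path) {
    fmt <- function(scaf, st0, en0)
        sprintf("%s:%d-%d", scaf, st0 + 1L, en0)
    df <- data.frame(
        sourceCoords = fmt(changes$scaffold, changes$srcStart, changes$srcEnd),
        destCoords = fmt(changes$scaffold, changes$destStart, changes$destEnd),
        sourceSeq = ifelse(nchar(changes$srcSeq) == 0, ".", changes$srcSeq),
        destSeq = ifelse(nchar(changes$destSeq) == 0, ".", changes$destSeq),
        category = changes$category,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Parse a changes ledger written by \code{\link{writeChangesFile}}
#'
#' @param path Changes TSV path.
#' @return data.frame with 0-based srcStart/srcEnd and sequences.
#' @export
readChangesFile <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    parse1 <- function(x) {
        m <- regmatches(x, regexec("^(.*):(\\d+)-(\\d+)$", x))[[1]]
        list(scaffold = m[2], start = as.integer(m[3]) - 1L,
             end = as.integer(m[4]))
    }
    src <- lapply(df$sourceCoords, parse1)
    data.frame(
        scaffold = vapply(src, `[[`, "", "scaffold"),
        srcStart = vapply(src, `[[`, 0L, "start"),
        srcEnd = vapply(src, `[[`, 0L, "end"),
        srcSeq = ifelse(df$sourceSeq == ".", "", df$sourceSeq),
        destSeq = ifelse(df$destSeq == ".", "", df$destSeq),
        category = df$category,
        stringsAsFactors = FALSE)
}

#' Write genome-browser tracks
#'
#' Four fixedStep wiggle tracks (valid coverage, physical coverage, clipped
#' alignments, percent bad alignments) and one BED features track
#' (suspicious regions with status, duplications tagged DUP, applied
#' changes). Wiggle is 1-based; BED intervals are 0-based half-open.
#'
#' @param pileups A \linkS4class{PileupTable}.
#' @param regions Suspicious-region \link[GenomicRanges]{GRanges} (with
#'   status) or NULL.
#' @param duplications Duplication data.frame or NULL.
#' @param changes Augmented changes data.frame or NULL.
#' @param prefix Output path prefix.
#' @return Invisibly, character vector of files written.
#' @export
writeTracks <- function(pileups, regions = NULL, duplications = NULL,
                        changes = NULL, prefix = "burnish") {
    wig <- function(name, get) {
        f <- paste0(prefix, name, ".wig")
        con <- file(f, "w")
        on.exit(close(con))
        writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
        for (scaf in names(pileups@scaffolds)) {
            writeLines(sprintf("fixedStep chrom=%s start=1 step=1", scaf),
                       con)
            writeLines(format(get(pileups@scaffolds[[scaf]]),
                              scientific = FALSE, trim = TRUE), con)
        }
        f
    }
    files <- c(
        wig("ValidCoverage", function(P) P$validCov),
        wig("PhysicalCoverage", function(P) P$physCov),
        wig("ClippedAlignments", function(P) P$clipStarts),
        wig("PctBadAlignments", function(P)
            round(100 * P$badCov / pmax(1L, P$totalCov))))
    bed <- paste0(prefix, "Features.bed")
    rows <- character()
    if (!is.null(regions) && length(regions))
        rows <- c(rows, sprintf("%s\t%d\t%d\t%s",
                                as.character(seqnames(regions)),
                                start(regions) - 1L, end(regions),
                                paste0("SUSPICIOUS:",
                                       mcols(regions)$status)))
    if (!is.null(duplications) && nrow(duplications))
        rows <- c(rows, sprintf("%s\t%d\t%d\tDUP", duplications$scaffold,
                                duplications$start, duplications$end))
    if (!is.null(changes) && nrow(changes))
        rows <- c(rows, sprintf("%s\t%d\t%d\t%s", changes$scaffold,
                                changes$srcStart,
                                pmax(changes$srcEnd, changes$srcStart + 1L),
                                toupper(changes$category)))
    writeLines(rows, bed)
    invisible(c(files, bed))
}

#' Write the run summary
#'
#' Mean coverage per library, percentage of the input genome confirmed,
#' counts of applied changes per category, unresolved regions (with tandem
#' periods where detected) and flagged duplications.
#'
#' @param result A \linkS4class{PolishResult}.
#' @param con Connection or path (default stdout).
#' @return Invisibly, the summary lines.
#' @export
writeSummary <- function(result, con = stdout()) {
    lines <- character()
    for (s in result@stats)
        lines <- c(lines, sprintf(
            "Library %s: mean coverage %.1fx, read length %d",
            s@kind, s@meanCoverage, s@readLengthMode))
    nonN <- 0L; conf <- 0L
    for (scaf in names(result@classifications)) {
        cl <- result@classifications[[scaf]]
        gb <- strsplit(scaffoldSeq(result@inputGenome, scaf), "")[[1]]
        nonN <- nonN + sum(gb != "N")
        conf <- conf + sum(cl$category == "Confirmed")
    }
    lines <- c(lines, sprintf("Confirmed %d of %d bases (%.2f%%)",
                              conf, nonN, 100 * conf / max(1L, nonN)))
    if (nrow(result@changes)) {
        tab <- table(result@changes$category)
        lines <- c(lines, sprintf("Changes applied: %s",
                                  paste(sprintf("%s=%d", names(tab),
                                                as.integer(tab)),
                                        collapse = ", ")))
    } else lines <- c(lines, "Changes applied: none")
    reg <- result@regions
    unres <- reg[mcols(reg)$status %in% c("no_solution", "tandem_repeat")]
    for (i in seq_along(unres)) {
        per <- mcols(unres)$tandemPeriod[i]
        lines <- c(lines, sprintf(
            "Unresolved region %s:%d-%d (%s)%s",
            as.character(seqnames(unres))[i], start(unres)[i] - 1L,
            end(unres)[i], mcols(unres)$status[i],
            if (!is.na(per)) sprintf(": tandem repeat of period %d", per)
            else ""))
    }
    d <- result@duplications
    for (i in seq_len(nrow(d)))
        lines <- c(lines, sprintf(
            "Possible collapsed repeat/duplication %s:%d-%d (%.1fx)",
            d$scaffold[i], d$start[i], d$end[i], d$meanRatio[i]))
    writeLines(lines, con)
    invisible(lines)
}
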