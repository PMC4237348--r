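## Pipeline orchestration: the single entry point tying every stage
## together, in assembly-improvement or variant-detection mode.

#' Polish a genome / call variants from aligned short reads
#'
#' Runs the full pipeline: ingest alignments, accumulate quality-weighted
#' pileups, classify every base, call SNPs and small indels, scan for
#' discontiguities, locally reassemble suspicious regions and captured
#' gaps, flag large duplications, apply accepted changes and (optionally)
#' serialize all outputs.
#'
#' @param genome Path to a FASTA file or an \linkS4class{InputGenome}.
#' @param frags,jumps,unpaired Character vectors of SAM/BAM paths for
#'   fragment, long-insert and unpaired libraries (at least one file
#'   total).
#' @param config A \linkS4class{PolishConfig}.
#' @param fix Subset of c("bases", "gaps", "local") (or "all"): which change
#'   categories are applied to the output genome.
#' @param variantMode Variant-detection mode: VCF emission defaults on and
#'   all-sites records are written.
#' @param output Output path prefix; when NULL nothing is written and only
#'   the \linkS4class{PolishResult} is returned.
#' @param vcf,tracks,changes Which optional outputs to write (with
#'   \code{output}).
#' @param quiet Suppress progress messages.
#' @return A \linkS4class{PolishResult}.
#' @export
runPolish <- function(genome, frags = character(), jumps = character(),
                      unpaired = character(), config = polishConfig(),
                      fix = "all", variantMode = FALSE, output = NULL,
                      vcf = variantMode, tracks = FALSE, changes = TRUE,
                      quiet = FALSE) {
    say <- function(...) if (!quiet) message(...)
    if (is.character(genome)) genome <- readInputGenome(genome)
    if ("all" %in% fix) fix <- c("bases", "gaps", "local")
    stopifnot(all(fix %in% c("bases", "gaps", "local")))
    nIn <- length(frags) + length(jumps) + length(unpaired)
    if (nIn == 0) stop("at least one alignment file is required")
    say("Reading ", nIn, " alignment file(s)")
    alns <- c(lapply(frags, readAlignments, kind = "fragment",
                     genome = genome),
              lapply(jumps, readAlignments, kind = "long_insert",
                     genome = genome),
              lapply(unpaired, readAlignments, kind = "unpaired",
                     genome = genome))
    statsList <- lapply(alns, function(a) a@stats)
    for (w in validateInputs(statsList)) warning(w, call. = FALSE)
    say("Accumulating pileups")
    acc <- accumulatePileups(genome, alns, config)
    say("Classifying bases")
    cls <- classifyBases(genome, acc$pileups, config)
    snps <- callSnps(genome, cls, config)
    tally <- tallyIndels(acc$indels, genome)
    indelCalls <- callSmallIndels(tally, acc$pileups, config)
    say("Scanning for discontiguities")
    regions <- flagSuspiciousRegions(acc$pileups, genome, config, cls,
                                     statsList)
    targets <- enumerateReassemblyTargets(regions, genome)
    dups <- detectLargeDuplications(acc$pileups, config)

    ## --- local reassembly over the work list
    doLocal <- "local" %in% fix || variantMode
    doGaps <- "gaps" %in% fix
    stat <- rep("pending", length(targets))
    period <- rep(NA_integer_, length(targets))
    reChanges <- list()
    if (length(targets) && (doLocal || doGaps)) {
        say("Reassembling ", length(targets), " target region(s)")
        for (i in seq_along(targets)) {
            scaf <- as.character(seqnames(targets))[i]
            st <- start(targets)[i] - 1L
            en <- end(targets)[i]
            trg <- mcols(targets)$triggers[i]
            isGap <- grepl("\\bgap\\b", trg)
            if ((isGap && !doGaps) || (!isGap && !doLocal)) {
                stat[i] <- "skipped"; next
            }
            res <- reassembleRegion(genome, scaf, st, en, trg, alns, config)
            stat[i] <- res$status
            period[i] <- res$tandemPeriod
            if (!is.null(res$change))
                reChanges[[length(reChanges) + 1L]] <- res$change
        }
    } else if (length(targets)) stat <- rep("skipped", length(targets))
    mcols(targets)$status <- stat
    mcols(targets)$tandemPeriod <- period
    reChanges <- if (length(reChanges)) do.call(rbind, reChanges) else NULL

    ## --- assemble the change set
    chg <- list()
    if ("bases" %in% fix && nrow(snps$fixes))
        chg[[length(chg) + 1L]] <- data.frame(
            scaffold = snps$fixes$scaffold, srcStart = snps$fixes$pos,
            srcEnd = snps$fixes$pos + 1L, srcSeq = snps$fixes$ref,
            destSeq = snps$fixes$alt, category = snps$fixes$category,
            stringsAsFactors = FALSE)
    if ("bases" %in% fix && nrow(indelCalls)) {
        isDel <- indelCalls$kind == "deletion"
        chg[[length(chg) + 1L]] <- data.frame(
            scaffold = indelCalls$scaffold,
            srcStart = indelCalls$pos,
            srcEnd = indelCalls$pos + ifelse(isDel, nchar(indelCalls$seq), 0L),
            srcSeq = ifelse(isDel, indelCalls$seq, ""),
            destSeq = ifelse(isDel, "", indelCalls$seq),
            category = ifelse(isDel, "small_deletion", "small_insertion"),
            stringsAsFactors = FALSE)
    }
    small <- if (length(chg)) do.call(rbind, chg) else NULL
    if (!is.null(small) && !is.null(reChanges)) {
        drop <- rep(FALSE, nrow(small))
        for (j in seq_len(nrow(reChanges)))
            drop <- drop | (small$scaffold == reChanges$scaffold[j] &
                            small$srcEnd > reChanges$srcStart[j] &
                            small$srcStart < reChanges$srcEnd[j])
        small <- small[!drop, , drop = FALSE]
    }
    allChanges <- rbind(small, reChanges)
    if (is.null(allChanges))
        allChanges <- data.frame(scaffold = character(),
                                 srcStart = integer(), srcEnd = integer(),
                                 srcSeq = character(), destSeq = character(),
                                 category = character(),
                                 stringsAsFactors = FALSE)
    ## drop any change overlapping an earlier one (reassembly spans can
    ## collide when two targets sit close together)
    allChanges <- allChanges[order(allChanges$scaffold,
                                   allChanges$srcStart,
                                   allChanges$srcEnd), , drop = FALSE]
    if (nrow(allChanges) > 1) {
        keep <- rep(TRUE, nrow(allChanges))
        lastEnd <- -1L; lastScaf <- ""
        for (i in seq_len(nrow(allChanges))) {
            if (allChanges$scaffold[i] == lastScaf &&
                allChanges$srcStart[i] < lastEnd) {
                keep[i] <- FALSE
            } else {
                lastEnd <- allChanges$srcEnd[i]
                lastScaf <- allChanges$scaffold[i]
            }
        }
        allChanges <- allChanges[keep, , drop = FALSE]
    }
    say("Applying ", nrow(allChanges), " change(s)")
    applied <- applyChanges(genome, allChanges)

    ## --- unified variant table
    vlist <- list()
    if (nrow(snps$calls))
        vlist[[length(vlist) + 1L]] <- data.frame(
            scaffold = snps$calls$scaffold, pos = snps$calls$pos,
            ref = snps$calls$ref, alt = snps$calls$alt, kind = "snp",
            seq = NA_character_, qual = snps$calls$qual, qd = snps$calls$qd,
            ambiguous = snps$calls$ambiguous, stringsAsFactors = FALSE)
    if (nrow(indelCalls))
        vlist[[length(vlist) + 1L]] <- data.frame(
            scaffold = indelCalls$scaffold, pos = indelCalls$pos,
            ref = NA_character_, alt = NA_character_,
            kind = indelCalls$kind, seq = indelCalls$seq,
            qual = indelCalls$qual, qd = indelCalls$qd, ambiguous = FALSE,
            stringsAsFactors = FALSE)
    sv <- applied$changes[applied$changes$category %in%
                          c("gap_fill", "break_fix"), , drop = FALSE]
    if (nrow(sv))
        vlist[[length(vlist) + 1L]] <- data.frame(
            scaffold = sv$scaffold, pos = sv$srcStart, ref = sv$srcSeq,
            alt = sv$destSeq, kind = "sv", seq = NA_character_,
            qual = 0, qd = 0, ambiguous = FALSE, stringsAsFactors = FALSE)
    variants <- if (length(vlist)) do.call(rbind, vlist) else
        data.frame(scaffold = character(), pos = integer(),
                   ref = character(), alt = character(), kind = character(),
                   seq = character(), qual = numeric(), qd = numeric(),
                   ambiguous = logical(), stringsAsFactors = FALSE)
    variants <- variants[order(variants$scaffold, variants$pos), ,
                         drop = FALSE]
    rownames(variants) <- NULL

    result <- new("PolishResult",
                  inputGenome = genome, polishedGenome = applied$genome,
                  changes = applied$changes, variants = variants,
                  classifications = cls, regions = targets,
                  duplications = dups, pileups = acc$pileups,
                  stats = statsList, config = config)
    if (!is.null(output)) {
        writeGenomeFasta(applied$genome, paste0(output, ".fasta"))
        if (changes)
            writeChangesFile(applied$changes, paste0(output, ".changes"))
        if (vcf)
            writeVcf(genome, variants, paste0(output, ".vcf"),
                     mode = if (variantMode) "all_sites" else
                         "variants_only",
                     pileups = acc$pileups, classifications = cls)
        if (tracks)
            writeTracks(acc$pileups, targets, dups, applied$changes,
                        prefix = output)
        writeSummary(result)
    }
    result
}
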