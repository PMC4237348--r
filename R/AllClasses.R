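#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width ranges
#' @importFrom IRanges IRanges reduce findOverlaps
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement DNAString
NULL

#' Tunable parameters for the polishing pipeline
#'
#' All heuristic thresholds used by the pipeline live in one object so a run
#' is fully described by (inputs, config). Defaults are chosen for >=50x
#' short-read coverage of haploid genomes.
#'
#' @slot k k-mer size for local reassembly (bases). The closure overlap
#'   requirement is derived from it as \code{2k+1}.
#' @slot minLinkCoverage minimum read support for a forward link in the
#'   reassembly graph; weaker links are pruned.
#' @slot branchLimit maximum number of branch points a single flank walk may
#'   traverse (at most \code{2^branchLimit} extensions per flank).
#' @slot flankTrim bases ignored at each end of a read when accumulating
#'   allele evidence (alignments are least trustworthy near read ends).
#' @slot minDepth minimum valid-read depth to classify a base; the effective
#'   floor is \code{max(minDepth, 0.1 * mean coverage)}.
#' @slot changedFraction weight fraction the top allele must reach for a
#'   Confirmed or Changed call ("vast majority").
#' @slot ambiguousFraction weight fraction at which a second allele makes a
#'   site Ambiguous.
#' @slot longIndelFraction valid-read support fraction required to call an
#'   indel longer than \code{longIndelLength} (shorter events need a strict
#'   majority, 0.5).
#' @slot longIndelLength event length (bases) above which the lowered indel
#'   threshold applies.
#' @slot clipFractionThreshold fraction of covering reads soft-clipped at a
#'   position that seeds a suspicious region.
#' @slot invalidRatioThreshold ratio of invalid to valid reads covering a
#'   position that seeds a suspicious region.
#' @slot lowCoverageFraction fraction of the scaffold mean below which valid
#'   coverage counts as "extremely low".
#' @slot coverageDropFraction relative coverage drop within one read length
#'   that seeds a suspicious region.
#' @slot dupMinLength minimum length (bases) for a reported collapsed
#'   repeat / duplication.
#' @slot dupCoverageRatio coverage ratio over the scaffold baseline at which
#'   a window counts as duplicated.
#' @slot dupWindow window size (bases) for duplication scanning.
#' @slot fixAmbiguous change Ambiguous bases to their top-weight allele
#'   (off by default).
#' @slot openNewGaps allow replacing an unresolved suspicious region with
#'   flank extensions separated by a new gap (off by default).
#' @slot maxWalkLength safety cap on a single flank-walk length (bases).
#' @export
setClass("PolishConfig", representation(
    k = "integer",
    minLinkCoverage = "integer",
    branchLimit = "integer",
    flankTrim = "integer",
    minDepth = "integer",
    changedFraction = "numeric",
    ambiguousFraction = "numeric",
    longIndelFraction = "numeric",
    longIndelLength = "integer",
    clipFractionThreshold = "numeric",
    invalidRatioThreshold = "numeric",
    lowCoverageFraction = "numeric",
    coverageDropFraction = "numeric",
    dupMinLength = "integer",
    dupCoverageRatio = "numeric",
    dupWindow = "integer",
    fixAmbiguous = "logical",
    openNewGaps = "logical",
    maxWalkLength = "integer"
))

#' Construct a PolishConfig
#'
#' @param k k-mer size for local reassembly.
#' @param minLinkCoverage minimum forward-link support.
#' @param branchLimit maximum branch points per flank walk.
#' @param flankTrim bases ignored at read ends for allele evidence.
#' @param minDepth minimum valid depth for base classification.
#' @param changedFraction top-allele weight fraction for Confirmed/Changed.
#' @param ambiguousFraction second-allele weight fraction for Ambiguous.
#' @param longIndelFraction support fraction for long indels.
#' @param longIndelLength length at which the long-indel threshold starts.
#' @param clipFractionThreshold clip-fraction region seed threshold.
#' @param invalidRatioThreshold invalid/valid ratio region seed threshold.
#' @param lowCoverageFraction low-coverage region seed threshold.
#' @param coverageDropFraction coverage-drop region seed threshold.
#' @param dupMinLength minimum reported duplication length.
#' @param dupCoverageRatio duplication coverage ratio.
#' @param dupWindow duplication scan window.
#' @param fixAmbiguous also fix Ambiguous bases.
#' @param openNewGaps allow opening new gaps at unresolved regions.
#' @param maxWalkLength cap on flank-walk length.
#' @return A \linkS4class{PolishConfig} object.
#' @examples
#' cfg <- polishConfig()
#' closureOverlap(cfg)  # 2k + 1 = 95 at the default k = 47
#' @export
polishConfig <- function(k = 47L, minLinkCoverage = 5L, branchLimit = 5L,
                         flankTrim = 5L, minDepth = 5L,
                         changedFraction = 0.75, ambiguousFraction = 0.25,
                         longIndelFraction = 0.35, longIndelLength = 10L,
                         clipFractionThreshold = 0.33,
                         invalidRatioThreshold = 1.0,
                         lowCoverageFraction = 0.20,
                         coverageDropFraction = 0.50,
                         dupMinLength = 10000L, dupCoverageRatio = 1.8,
                         dupWindow = 1000L,
                         fixAmbiguous = FALSE, openNewGaps = FALSE,
                         maxWalkLength = 20000L) {
    new("PolishConfig",
        k = as.integer(k), minLinkCoverage = as.integer(minLinkCoverage),
        branchLimit = as.integer(branchLimit), flankTrim = as.integer(flankTrim),
        minDepth = as.integer(minDepth),
        changedFraction = changedFraction, ambiguousFraction = ambiguousFraction,
        longIndelFraction = longIndelFraction,
        longIndelLength = as.integer(longIndelLength),
        clipFractionThreshold = clipFractionThreshold,
        invalidRatioThreshold = invalidRatioThreshold,
        lowCoverageFraction = lowCoverageFraction,
        coverageDropFraction = coverageDropFraction,
        dupMinLength = as.integer(dupMinLength),
        dupCoverageRatio = dupCoverageRatio, dupWindow = as.integer(dupWindow),
        fixAmbiguous = fixAmbiguous, openNewGaps = openNewGaps,
        maxWalkLength = as.integer(maxWalkLength))
}

setValidity("PolishConfig", function(object) {
    msg <- character()
    fr <- c(changed = object@changedFraction, ambiguous = object@ambiguousFraction,
            longIndel = object@longIndelFraction,
            clip = object@clipFractionThreshold,
            lowCov = object@lowCoverageFraction,
            drop = object@coverageDropFraction)
    if (any(fr <= 0 | fr > 1))
        msg <- c(msg, "all fraction thresholds must lie in (0, 1]")
    if (object@k < 3L) msg <- c(msg, "k must be >= 3")
    if (object@branchLimit < 0L) msg <- c(msg, "branchLimit must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Closure overlap required by the local reassembler
#'
#' The minimum perfect overlap (bases) between flank extensions for a region
#' or gap to be closed: \code{2k + 1}.
#'
#' @param config A \linkS4class{PolishConfig}.
#' @return Integer overlap length in bases.
#' @export
closureOverlap <- function(config) 2L * config@k + 1L

#' An input genome with derived gap annotation
#'
#' Scaffold sequences over \{A,C,G,T,N\} plus the intervals of maximal N-runs
#' (candidate captured gaps). Gaps with assembled sequence on both sides are
#' "captured" and eligible for gap filling; leading/trailing N-runs are not.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} of scaffolds, unique names.
#' @slot gaps A \link[GenomicRanges]{GRanges} of maximal N-runs with a logical
#'   metadata column \code{captured}.
#' @export
setClass("InputGenome", representation(
    sequences = "DNAStringSet",
    gaps = "GRanges"
))

setValidity("InputGenome", function(object) {
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm))
        return("scaffold names must be present and unique")
    af <- Biostrings::alphabetFrequency(object@sequences, baseOnly = FALSE)
    used <- colnames(af)[colSums(af) > 0]
    if (!all(used %in% c("A", "C", "G", "T", "N")))
        return("sequences must contain only A, C, G, T, N")
    TRUE
})

#' Per-position weighted evidence for every scaffold
#'
#' For each scaffold, per-position quality-weighted allele evidence plus the
#' coverage, clipping and pair-validity counters every downstream step feeds
#' on. Built by \code{\link{accumulatePileups}}.
#'
#' @slot scaffolds Named list; each element holds the matrices/vectors
#'   \code{weights} (L x 4), \code{counts} (L x 4), \code{delWeight},
#'   \code{delCount}, \code{validCov}, \code{fragCov}, \code{totalCov},
#'   \code{badCov}, \code{clipStarts}, \code{physCov}.
#' @slot readLengthMode Modal read length over contributing libraries.
#' @export
setClass("PileupTable", representation(
    scaffolds = "list",
    readLengthMode = "integer"
))

#' A local De Bruijn reassembly graph
#'
#' Nodes are k-mers; each node carries a next-base pileup (base-quality
#' weights and read counts per A/C/G/T). Forward links with support below
#' \code{minLinkCoverage} are pruned at query time.
#'
#' @slot k k-mer size.
#' @slot nodes data.table keyed by k-mer with per-base weight/count columns.
#' @export
setClass("KmerGraph", representation(k = "integer", nodes = "ANY"))

#' Statistics of one alignment library
#'
#' @slot kind "fragment", "long_insert" or "unpaired".
#' @slot insertMean,insertSd Insert-size mean/sd over proper pairs (NA for
#'   unpaired libraries); population sd.
#' @slot readLengthMode Modal read length.
#' @slot meanCoverage Total aligned bases over non-N genome length.
#' @export
setClass("LibraryStats", representation(
    kind = "character",
    insertMean = "numeric",
    insertSd = "numeric",
    readLengthMode = "integer",
    meanCoverage = "numeric"
))

#' Normalized alignments of one library
#'
#' One coordinate-sorted SAM/BAM, ingested into a flat record table with
#' validity and clipping flags, plus its \linkS4class{LibraryStats}.
#'
#' @slot records data.frame of normalized alignment records.
#' @slot kind library kind ("fragment", "long_insert", "unpaired").
#' @slot stats \linkS4class{LibraryStats}.
#' @export
setClass("PolishAlignments", representation(
    records = "data.frame",
    kind = "character",
    stats = "LibraryStats"
))

#' Result of a polishing / variant-calling run
#'
#' @slot inputGenome the \linkS4class{InputGenome} that was analyzed.
#' @slot polishedGenome the corrected \linkS4class{InputGenome}.
#' @slot changes data.frame of applied edits (the changes ledger).
#' @slot variants data.frame of VCF-representable calls.
#' @slot classifications per-scaffold base classification list.
#' @slot regions \link[GenomicRanges]{GRanges} of suspicious regions with
#'   resolution status.
#' @slot duplications data.frame of flagged collapsed repeats.
#' @slot pileups the \linkS4class{PileupTable}.
#' @slot stats list of \linkS4class{LibraryStats} per input library.
#' @slot config the \linkS4class{PolishConfig} used.
#' @export
setClass("PolishResult", representation(
    inputGenome = "InputGenome",
    polishedGenome = "InputGenome",
    changes = "data.frame",
    variants = "data.frame",
    classifications = "list",
    regions = "GRanges",
    duplications = "data.frame",
    pileups = "PileupTable",
    stats = "list",
    config = "PolishConfig"
))

setMethod("show", "PolishConfig", function(object) {
    cat("PolishConfig: k=", object@k,
        " (closure overlap ", closureOverlap(object), ")",
        ", minLinkCoverage=", object@minLinkCoverage,
        ", branchLimit=", object@branchLimit,
        ", flankTrim=", object@flankTrim, "\n",
        "  changedFraction=", object@changedFraction,
        ", ambiguousFraction=", object@ambiguousFraction,
        ", longIndelFraction=", object@longIndelFraction,
        " (length>", object@longIndelLength, ")\n",
        "  fixAmbiguous=", object@fixAmbiguous,
        ", openNewGaps=", object@openNewGaps, "\n", sep = "")
})

setMethod("show", "InputGenome", function(object) {
    n <- length(object@sequences)
    cat("InputGenome:", n, "scaffold(s),",
        sum(Biostrings::width(object@sequences)), "bp,",
        length(object@gaps), "N-run(s) (",
        sum(mcols(object@gaps)$captured), "captured )\n")
})

setMethod("show", "LibraryStats", function(object) {
    cat("LibraryStats[", object@kind, "]: insert ",
        round(object@insertMean, 1), " +/- ", round(object@insertSd, 1),
        ", read length ", object@readLengthMode,
        ", coverage ", round(object@meanCoverage, 1), "x\n", sep = "")
})

setMethod("show", "PolishAlignments", function(object) {
    cat("PolishAlignments[", object@kind, "]: ",
        nrow(object@records), " records\n", sep = "")
    show(object@stats)
})

setMethod("show", "PileupTable", function(object) {
    cat("PileupTable:", length(object@scaffolds), "scaffold(s)\n")
    for (nm in names(object@scaffolds)) {
        sc <- object@scaffolds[[nm]]
        cat("  ", nm, ": ", length(sc$validCov), " bp, mean valid coverage ",
            round(mean(sc$validCov), 1), "\n", sep = "")
    }
})

setMethod("show", "KmerGraph", function(object) {
    cat("KmerGraph: k=", object@k, ", ",
        if (is.null(object@nodes)) 0L else nrow(object@nodes),
        " node(s)\n", sep = "")
})

setMethod("show", "PolishResult", function(object) {
    cat("PolishResult:", nrow(object@changes), "change(s),",
        nrow(object@variants), "variant record(s),",
        length(object@regions), "suspicious region(s),",
        nrow(object@duplications), "duplication(s)\n")
})

#' @describeIn InputGenome-class scaffold sequences as a DNAStringSet
#' @param x An \code{InputGenome}.
#' @export
genomeSequences <- function(x) x@sequences

#' @describeIn InputGenome-class N-run (gap) intervals as a GRanges
#' @export
genomeGaps <- function(x) x@gaps

#' @describeIn PolishResult-class the applied-edit ledger
#' @param x A \code{PolishResult}.
#' @export
polishChanges <- function(x) x@changes

#' @describeIn PolishResult-class the variant calls
#' @export
polishVariants <- function(x) x@variants

#' @describeIn PolishResult-class the polished genome
#' @export
polishedGenome <- function(x) x@polishedGenome
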