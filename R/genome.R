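## Genome loading and gap derivation.
## Coordinates are 0-based half-open everywhere inside the package; 1-based
## conventions appear only at VCF/changes/track serialization.

#' Load an input genome from FASTA
#'
#' Sequences are uppercased; characters other than A/C/G/T/N (including IUPAC
#' ambiguity codes) are mapped to N with a warning. Maximal N-runs are derived
#' as gap intervals; a gap is "captured" when assembled sequence flanks it on
#' both sides.
#'
#' @param path Path to a FASTA file (any line width).
#' @return An \linkS4class{InputGenome}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACNNNGT"), fa)
#' g <- readInputGenome(fa)
#' genomeGaps(g)   # one captured gap [2,5) in 0-based coordinates
#' @export
readInputGenome <- function(path) {
    if (!file.exists(path) || file.size(path) == 0)
        stop("genome FASTA is missing or empty: ", path)
    seqs <- readDNAStringSet(path)
    if (length(seqs) == 0) stop("no sequences in genome FASTA: ", path)
    ## FASTA descriptions: keep the first word as the scaffold name
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("duplicate scaffold names in genome FASTA")
    newInputGenome(setNames(toupper(as.character(seqs)), names(seqs)))
}

#' Construct an InputGenome from named character sequences
#'
#' @param seqs Named character vector of scaffold sequences.
#' @return An \linkS4class{InputGenome}.
#' @export
newInputGenome <- function(seqs) {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("scaffold names must be present and unique")
    seqs <- toupper(seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
        warning("non-ACGTN characters found in ",
                sum(bad), " scaffold(s); mapped to N")
        seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
    }
    dna <- DNAStringSet(seqs)
    new("InputGenome", sequences = dna, gaps = deriveGaps(seqs))
}

#' Derive maximal N-run intervals from sequences
#'
#' @param seqs Named character vector (uppercase ACGTN).
#' @return A \link[GenomicRanges]{GRanges} in 1-based coordinates (standard for
#'   GRanges) with metadata column \code{captured}; use \code{start(gr) - 1L}
#'   for the package-internal 0-based start.
#' @export
deriveGaps <- function(seqs) {
    out <- lapply(names(seqs), function(nm) {
        m <- gregexpr("N+", seqs[[nm]])[[1]]
        if (m[1] == -1) return(NULL)
        st <- as.integer(m)
        w <- attr(m, "match.length")
        L <- nchar(seqs[[nm]])
        data.frame(scaffold = nm, start = st, width = w,
                   captured = st > 1L & (st + w - 1L) < L)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        return(GRanges(character(), IRanges(integer(), width = integer()),
                       captured = logical()))
    GRanges(out$scaffold, IRanges(out$start, width = out$width),
            captured = out$captured)
}

#' Write a genome as FASTA
#'
#' Fixed 70-column line width, uppercase; this is the package's canonical
#' FASTA serialization so round-trips are byte-exact.
#'
#' @param genome An \linkS4class{InputGenome}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(genome, path) {
    writeXStringSet(genome@sequences, path, width = 70L)
    invisible(path)
}

## 0-based gap table for internal use: scaffold, start, end, captured
gapTable <- function(genome) {
    g <- genome@gaps
    data.frame(scaffold = as.character(seqnames(g)),
               start = start(g) - 1L, end = end(g),
               captured = mcols(g)$captured,
               stringsAsFactors = FALSE)
}

scaffoldLengths <- function(genome) {
    setNames(Biostrings::width(genome@sequences), names(genome@sequences))
}

scaffoldSeq <- function(genome, name) {
    as.character(genome@sequences[[name]])
}

revComp <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}
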