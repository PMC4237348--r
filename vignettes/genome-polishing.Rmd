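---
title: "Genome polishing and variant detection with burnish"
author: "burnish authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome polishing and variant detection with burnish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnish)
```

## The problem

Draft microbial assemblies built from short reads carry residual single-base
errors, small indels, uncaptured or partially captured gaps (N-runs between
contigs of a scaffold), local mis-assemblies, and collapsed repeats. The same
evidence that reveals these defects — short reads aligned back to the draft —
can also be read against a finished reference to call the variants of a
sequenced isolate, from SNPs up to multi-kilobase insertions and deletions.
`burnish` does both with one machinery: quality-weighted pileup consensus for
local accuracy, and local De Bruijn reassembly for events larger than a read.

The pipeline (`runPolish()`) takes a FASTA genome and one or more
coordinate-sorted SAM/BAM files, designated per library as *fragment* (short
insert, FR orientation), *long insert* (> 1 kb, FR after any reorientation of
mate-pair data), or *unpaired*. It emits a corrected FASTA, an optional VCF,
a tabular changes ledger, genome-browser tracks, and a text summary.

## Pileups and base classification

For every genome position a pileup records, per allele, a count and a
weighted evidence mass. An aligned base contributes

$$ w = q_b \left(1 - 10^{-q_m/10}\right), $$

its Phred base quality $q_b$ scaled by the probability that the read is
correctly placed (mapping quality $q_m$). A read with $q_m = 0$ — placeable
in several locations equally well — contributes nothing, which is what lets
high-$q_m$ long-insert reads anchored in unique flanking sequence outvote
misplaced intra-repeat fragment reads over collapsed repeats. Only reads in
*valid* pairs (the aligner's proper-pair flag, taken as authoritative) or
from unpaired libraries contribute allele evidence; other reads are tallied
as *bad* coverage. Alignments are least trustworthy near read ends,
especially for distinguishing indels from substitutions, so the
`flankTrim` (default 5) terminal bases of each read are excluded from allele
evidence (they still count as coverage). Soft-clip transition points and
per-template physical coverage are tallied alongside.

Each base is then classified:

* **Confirmed** — the top-weight allele equals the genome base and holds at
  least `changedFraction` (default 0.75) of the weight;
* **Changed** — a different allele holds that fraction (an exact top-weight
  tie is never Changed);
* **Ambiguous** — a second allele holds at least `ambiguousFraction`
  (default 0.25), or no allele reaches the Changed threshold;
* **Unconfirmed** — valid depth below `max(minDepth, 0.1 x mean coverage)`,
  or no weighted evidence.

The per-site QUAL is a bounded, monotone log-ratio of top-versus-rest
weight, `min(2000, 10 * log10((1 + w_top) / (1 + w_rest)) * 10)`, and QD is
QUAL over valid depth. These orderings are what matters; the absolute scale
is a convention. Changed bases are fixed and reported; Ambiguous bases are
reported and fixed only under `fixAmbiguous` (off by default — on real data
most such changes are not reliable).

## Small indels

Indel observations from alignments are shifted to their leftmost equivalent
edit (in `ACCCCT`, a single-C deletion aligns equally at four coordinates)
so that support for one event accumulates at one locus; the implementation
is checked against a brute-force enumeration oracle in the test suite. An
event is called when distinct-read support reaches half the local valid
coverage — the mean over a deletion's footprint, or the left flanking base
for an insertion — relaxed to `longIndelFraction` (default 0.35) for events
longer than `longIndelLength` (default 10), since aligners represent long
indels in fewer of the reads that actually span them. Coverage counts reads
*spanning* a position, including those whose alignments delete it: a
deletion op is part of the alignment, and counting it avoids spuriously
flagging confident deletions as coverage holes.

## Discontiguity scanning and local reassembly

Four heuristics seed suspicious regions: a high fraction of reads
soft-clipped at a position (`clipFractionThreshold`, 0.33, with at least 5
clipped reads), a high invalid-to-valid ratio (`invalidRatioThreshold`, 1.0,
with at least 5 invalid reads), extremely low valid coverage
(`lowCoverageFraction`, 0.20 of the scaffold mean), and a rapid coverage
drop within about a read length (`coverageDropFraction`, 0.50). The
qualitative signals are standard; these particular numbers are this
package's own calibration, chosen so that clean 60x error-free simulations
produce zero false flags, and all are exposed as tunables. Coverage
necessarily ramps near scaffold ends and gap edges — over a template
length, not a read length, for paired data — so the two coverage heuristics
ignore a margin equal to the smallest paired-library insert span (at least
two read lengths). Clusters of three or more Ambiguous bases within 50 bp
also seed a region, which is how block substitutions surface. Seeds within
one modal read length merge; captured gaps join the work list with their own
trigger.

Each target region is treated as untrusted and locally reassembled:

1. **Read collection.** Flanks of width `insertMean + 3 sd` of the widest
   paired library supply reads: fragment/unpaired reads aligned fully or
   partially (soft-clipped) in the flanks, plus, for pairs with a read
   anchored in a flank and a mate unmapped or improperly mapped, both reads
   (fragment) or only the unanchored mate (long insert). Fully
   flank-contained reads are included deliberately — they supply the trusted
   seed k-mers. Both strands of every collected read go into the graph,
   which makes mate-orientation bookkeeping unnecessary.
2. **Graph.** For each k-mer (default `k = 47`) the following base is
   recorded in a base-quality-weighted pileup. Forward links need
   `minLinkCoverage` (5) supporting reads; a node forks when two alleles
   each reach the ambiguity fraction. This prunes almost all
   sequencing-error branches.
3. **Walks.** Depth-first extension from trusted flank k-mers on both sides
   (the right flank walks on the reverse complement), forking at branches up
   to `branchLimit` (5) times per path, so at most $2^5$ extensions per
   flank. Revisiting a k-mer already incorporated on the same walk means a
   tandem repeat with period longer than k: the walk stops, the period (the
   distance since that k-mer was first seen) is reported, and no closure is
   attempted for the region. Loop detection is per-walk, not global —
   sibling paths may legitimately reconverge.
4. **Closure.** Extensions are combinatorially matched for perfect (exact)
   overlaps of at least $2k + 1$ bases — 95 at the default k, so spurious
   joins need 95 exact matching bases. Extensions may overrun each other's
   anchors, so the match slides each right-anchored extension along each
   left-anchored one rather than testing only suffix-prefix pairs. Exactly
   one distinct flank-to-flank sequence: the region (or gap) is replaced by
   it, never introducing Ns. None, or several: a greedy max-weight consensus
   extension from each flank shrinks a gap from both sides (the remainder
   stays N), while a non-gap region is left reported as unresolved unless
   `openNewGaps` is set. Consensus extension stops at exact weight ties
   rather than guessing — when the evidence is split, extending would be
   invention.

Replacement intervals are anchored at the seed k-mers and trimmed to the
minimal differing span before entering the changes ledger.

## Collapsed repeats / segmental duplications

Windows of `dupWindow` (1 kb) of fragment+unpaired valid coverage are
compared with the per-scaffold median; runs of windows at or above
`dupCoverageRatio` (1.8, rather than exactly 2.0, to tolerate sampling
noise) longer than `dupMinLength` (10 kb) are reported with their mean
ratio. Long-insert coverage is excluded — it is far more variable across
genomes. Nothing is modified: in an assembly these regions are candidate
collapsed repeats, in variant calling candidate segmental duplications, and
either way they deserve a human. A true duplication interrupted by a
short element at different copy number is reported as two runs; that is the
expected behavior of a ratio detector, not a defect, and it is pinned down
as a property test.

## Outputs and coordinate conventions

Internally every coordinate is 0-based half-open; conversion to 1-based
conventions happens exactly once, at serialization. The FASTA writer uses a
fixed 70-column width so round-trips are byte-exact. The VCF (4.2) uses the
anchor-base convention for indels, carries DP/VC/BC/QD INFO fields, marks
ambiguous sites with `FILTER=Amb`, and represents reassembly events as
sequence-resolved SVTYPE=INS/DEL records. The changes file lists every edit
with 1-based closed source and destination coordinates (a pure insertion
point is written as the empty interval `start-(start-1)`); replaying it
against the input FASTA must reproduce the output FASTA bit-exactly, and the
test suite enforces that. Tracks are fixedStep wiggle (valid coverage,
physical coverage, clipped alignments, percent bad alignments) and a BED
features track (suspicious regions with resolution status, duplications,
changes).

## The synthetic-fixture generator

`generateGenome()`, `plantDefects()`, `simulateReads()` and
`projectAlignments()` make the whole pipeline testable with no external
data or aligner. A truth genome (i.i.d. uniform ACGT background, optionally
with tandem arrays, dispersed repeat families, 2-copy duplications and
GC-skewed segments) is mutated into a draft carrying ledgered defects:
single-base errors, extra/missing small sequence, N-run gaps over real
sequence, equal-length foreign-sequence mis-joins, and collapsed
duplications (the second copy deleted, with reads from both truth copies
projected onto the survivor). Reads are simulated from the truth and
*projected* onto the draft through the ledger's block liftover: reads
crossing draft-absent sequence are soft-clipped or emitted as placed
unmapped records, small draft indels become CIGAR I/D ops, template lengths
are recomputed in draft coordinates so discordant pairs arise exactly where
they should, and mapping quality is 60 for uniquely lifted reads versus 3
inside multi-copy repeats.

Projection replaces a real aligner deliberately: it is deterministic,
dependency-free, and gives tests exact control over which discordance
signals exist. The cost is realism — uniform base qualities consistent with
a single error rate, substitution-only errors, no quality-by-cycle decay, no
chimeric or duplicate reads, and alignment decisions that are always
"correct" given the ledger. Passing the recovery suites therefore shows the
algorithms do the right thing with the evidence they are given; it does not
bound error rates on real libraries, where aligner artifacts and error
correlation matter.

The standard benchmark (`benchmarkFixture()`) is a 100 kb draft with 50
SNPs, 10 extra-sequence and 10 missing-sequence indels of 1–3 bp, five
200 bp gaps, one 500 bp mis-join and one collapsed 15 kb duplication,
covered by an error-free 180 bp-insert fragment library at 60x and a 3 kb
long-insert library at 20x — library geometries chosen to mirror common
bacterial resequencing designs, and sizes chosen so the full run takes
about a minute on one core. On it the pipeline achieves 100% recall and
precision for SNPs and small indels, closes 5/5 gaps with zero incorrect
closures, repairs the mis-join exactly, and reports the duplication; the
acceptance script recomputes all of this from scratch.

## Numerical and degenerate-input choices

* Non-ACGTN genome characters become N with a warning; IUPAC codes are not
  interpreted.
* Insert-size sd is the population sd over proper pairs — immaterial at
  realistic n, fixed for determinism.
* A paired library with zero proper pairs is a fatal error (the proper-pair
  flag is load-bearing); read length below 75 or total coverage below 50x
  only warns.
* Leading/trailing N-runs are recorded but not fillable (no second flank).
* Ties: an exact top-weight tie at a Changed candidate is classified
  Ambiguous; an exact branch-weight tie stops consensus extension; multiple
  distinct closures refuse to close.
* Walks carry a safety cap (`maxWalkLength`, 20 kb) against pathological
  graphs; capped walks are treated like dead ends.
* Overlapping change records (possible when two reassembly targets sit
  closer than a flank) keep the first in coordinate order; small fixes
  inside a reassembled span are superseded by the replacement.
* Tandem copy number is never estimated — only the period is reported.

## Known limitations

Haploid model only: no diploid genotype likelihoods, no heterozygous indel
calling. Scaffolds are never joined or broken. Closure requires exact
overlap, so two flank extensions that meet with even one mismatch (e.g.
within an imperfect repeat) will shrink rather than close a gap. The
duplication detector flags but neither fixes nor sizes copy number. A
single polishing pass is performed; on heavily damaged drafts, realigning
reads to the polished output and re-running can recover more.
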