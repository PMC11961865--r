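---
title: "Calling T-DNA integration sites from tagmentation bridge-PCR libraries"
author: "tagtis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling T-DNA integration sites from tagmentation bridge-PCR libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagtis)
```

# The assay, as the caller models it

A Tn5 transposome fragments genomic DNA of a transgenic plant at effectively
random positions and tags the fragment ends. A PCR with a *bridge primer*
specific to the left-border (LB) or right-border (RB) region of the T-DNA —
annealing, by the usual design rule, 150–200 bp interior of the border repeat
and extending toward it — amplifies only fragments containing a T-DNA end and
whatever genome it integrated into. Paired-end sequencing (PE150 by default)
of the pooled LB- and RB-PCRs gives, for each amplicon:

* **read 2**, starting at the bridge site and reading toward the border, and
* **read 1**, starting at the Tn5 cut in the flanking genome and reading
  inward.

Because the bridge site sits ~180–200 bp from the junction, read 2 usually
ends *before* crossing it; base-resolution evidence comes mostly from read 1
entering the T-DNA from the genome side. Both situations are informative:

* a **split** read covers the junction and aligns in two segments, one on a
  genome contig and one on the construct contig;
* a **discordant** pair has one mate wholly on the genome and the other
  wholly on the construct.

Alignment is against a *merged reference*: the genome plus one contig named
`tDNA` carrying the construct sequence from the start of the LB repeat to the
end of the RB repeat. The border repeats themselves are included in that
contig — junction-spanning reads must be able to align across a repeat, and
excluding them would push every breakpoint ~25 bp into the flank. Vector
backbone outside LB–RB is deliberately absent, so backbone-only integrations
are invisible by design.

## Junction typing

All internal coordinates are 0-based half-open; everything user-facing is
1-based. The construct's upper strand from LB to RB is the **forward** strand.
For a split read whose genome segment occupies \[g1, g2) on strand *s*:

* the junction adjoins the segment's high-coordinate end — `RefSide = Left`,
  breakpoint `g2` — when (*s* = `+` and the tDNA part follows the genome part
  in read order) or (*s* = `-` and it precedes it); otherwise
  `RefSide = Right` with breakpoint `g1 + 1`;
* `Direction = Forward` iff the genome and tDNA segment strands agree
  (i.e. the integrated forward strand is co-linear with the genome);
* the border (`tDNA = LB` or `RB`) is whichever repeat lies nearer the
  junction-adjacent construct coordinate; exactly equidistant evidence is
  discarded and counted.

This gives eight labels, `Left/Right & LB/RB & Forward/Reverse`, and the
label is invariant to which mate carries the split, to read layout, and to
strand flips — a property the acceptance tests sweep exhaustively. For
discordant pairs the same triple is inferred from mate orientation alone:
the genome mate's strand fixes RefSide (mates face each other), strand
*disagreement* between the mates means Forward (they sit on opposite strands
of one fragment), and the border comes from the tDNA mate's position. For
concatemers with truncated outer units the mate-adjacent T-DNA need not be
the junction-adjacent unit, so discordant border/direction are treated as
corroborative rather than definitive (see *Clustering*).

The breakpoint convention — Left = last genome base before the insertion,
Right = first genome base after it — makes
`target_deletion_bp = right − left − 1` read directly as the number of target
bases lost (0 for a clean junction, negative for junction overlap).

## From evidence to calls

1. **Classification.** A valid split mate has exactly two segments, one
   genome / one `tDNA`, each covering ≥ 20 bp of the read exclusive of their
   overlap; reads fragmenting into three or more segments contribute no split
   evidence. These two constants mirror the extraction settings of the
   published pipeline this assay family uses (`minNonOverlap 20`,
   `maxSplitCount 2`).
2. **Deduplication.** Junction evidence is collapsed to one record per
   *fragment signature* — (chromosome, outermost genome coordinate = the Tn5
   cut, junction side). Distinct cut sites are independent molecules;
   identical signatures are PCR duplicates. Ties keep the record with fewest
   mismatches, then the lexicographically smallest read id, so support counts
   are invariant under duplicating the input.
3. **Clustering.** Split evidence is grouped by (chrom, RefSide, border,
   Direction) and clustered around modal breakpoints within `tol = 5` bp
   (absorbing microhomology ambiguity in real data); the reported breakpoint
   is the mode, ties to the smallest. A cluster is kept with
   `split_supportN ≥ 2`, or `≥ 1` split plus `≥ 3` discordant mates. The
   source assay publishes no numeric thresholds, so these are this package's
   defaults, all config-exposed. Discordant evidence attaches to the nearest
   cluster on the same (chrom, RefSide) within the maximum fragment length
   (900 bp default), preferring clusters that also match its inferred
   border/direction; unattached discordant evidence forms support-only
   clusters that are reported but flagged *imprecise* rather than suppressed.
4. **Control subtraction.** Any call within 10 bp of a call from the
   wild-type control library (processed identically) is removed and logged.
5. **Multi-mapping.** Evidence whose genome segment has equally-scoring
   alternative loci keeps a deterministic primary site (lexicographically
   smallest contig/position), is flagged ambiguous, and lists every candidate
   site for PCR disambiguation — the repeat-rich polyploid case. Mapping
   quality is not modeled; ambiguity is carried explicitly instead.
6. **Full-TIS pairing.** Left and Right calls on one chromosome pair
   greedily by nearest gap within a 100 bp window; leftovers are the half-TIS
   case (e.g. one border's bridge site truncated away).

# The built-in aligner

Real datasets are expected to arrive as SAM/BAM from a production aligner
(bwa-mem) via `read_alignment_file()`; the internal seed-and-extend aligner
exists so simulated fixtures run with no external binaries, and both paths
must produce identical calls on error-free data (an acceptance property).

Design: an exact k-mer index (`k = 21`, both query orientations against the
forward reference), best diagonal by seed votes, then *ungapped* x-drop
extension — match +1, mismatch −6, drop threshold 30, trimmed back to the
first maximum-scoring prefix. The harsh mismatch penalty means extension past
a true junction would need a 7-base chance-match run (probability ≈ 4⁻⁷ per
junction read), so segment boundaries stay put for breakpoint work, while
isolated sequencing errors (score dip 6, recovered after 7 matches) are still
crossed. If ≥ 20 bp of the read remains unaligned at either end, the
remainder is aligned in a second pass seeded at k = 13 (so a 20 bp remainder
— the split-validity floor — is still seedable); resulting segments shorter
than 20 bp are not emitted, keeping the aligner path and the SAM extraction
path classification-equivalent. At most two segments are returned per read.
No gapped alignment and no base-quality model: the simulator introduces no
indels, and indel-bearing real data belongs to the external-aligner path.

# What the simulator emulates — and what it does not

`simulate_scenario()` builds a random genome (2 × 100 kb by default,
GC 0.36), a 5 kb toy construct with 25 bp border repeats and bridge sites
180 bp from each end, and insertion events drawn from an archetype catalogue:
ideal single-copy insertions in both orientations, border-truncated variants,
head-to-head and tail-to-tail concatemers, and concatemers whose heavily
truncated outer unit exposes, e.g., a reversed LB fragment at the junction.
The last group matters: with an intact adjacent border, the bridge chemistry
can only ever observe four of the eight insertion types (exactly the types
that dominate published surveys); the other four arise when a junction is
reached *through* a truncated outer unit from a bridge site in a deeper unit.
Detectability is therefore modeled generally: a junction is detectable iff
some surviving bridge site reads toward it within amplicon range
(`fragment_max − 30` bp), which reduces to "the bridge site was not truncated
away" for single units.

Events replace a 0–50 bp deleted target interval with
`filler(0–20 bp) + payload + filler(0–20 bp)`. Amplicons per detectable
junction span from the nearest inward-reading bridge site to a uniform Tn5
cut beyond the junction, with fragment length uniform on 150–900 bp, PE150
reads, constant `I` quality, optional uniform substitution errors, PCR
duplicates re-emitted at rate 0.1, and uniform background pairs from the
sample genome (which may legitimately fall inside, or across the edges of,
integrated T-DNA). A truth SAM of oracle alignments (primary + supplementary,
segments ≥ 20 bp, capped at two) and a truth table accompany every library.

**Junctions are implanted without terminal microhomology**: when a drawn
filler or payload boundary base happens to equal the reference continuation
base, that filler base is redrawn (or the deletion/truncation extended by
1 bp). Real junctions do carry microhomology — but then the breakpoint itself
is ill-defined at the homology width for *any* caller, and reported
coordinates shift within it. Excluding it from the generator is what makes
"every breakpoint equals truth exactly" a meaningful target; on real data the
5 bp cluster tolerance absorbs the same ambiguity. Other simplifications: no
Tn5 insertion bias (irrelevant to breakpoint correctness), no indel or
quality-dependent error model, no chimeric PCR artifacts, no barcode
demultiplexing (facilities deliver demultiplexed FASTQ), and filler is
uniform-random rather than microhomology-mediated. Passing round-trip tests
therefore demonstrates correctness of the calling logic under the assay's
fragment geometry — not robustness to indels, adapters or chimeras, which the
external-aligner path and control subtraction handle in practice.

## Validation problem sizes

The round-trip acceptance test runs 20 seeded scenarios (2 × 100 kb contigs,
1–3 insertions each, all eight junction types across the sweep, truncations,
deletions, duplicates) and requires 100 % recall of detectable junctions,
100 % precision after control subtraction, exact breakpoints, and exact
target-deletion readout. These scenarios use 80 capturable fragments per
junction rather than the `library_params()` default of 8. That is a
realistic depth — a pooled library yields on the order of 10⁵–10⁶ pairs per
sample, i.e. hundreds of distinct cut sites per junction — and it is chosen
from a power calculation, not tuned: a fragment crosses the junction within
read reach with p ≈ 0.15 under the 150–900 bp fragment distribution, so at
depth 8 a junction lacks split evidence with probability ≈ 0.25, while at 80
the expected number of split-less junctions across the whole suite is ≪ 1.
Noise robustness is checked at a 0.5 % substitution rate (recall and
breakpoint exactness ≥ 95 %), and SAM-path/aligner-path equivalence is
asserted byte-for-byte on summaries.

# Reporting, annotation, safe harbors

`write_summary()` emits the tab-separated call table with fixed columns
`Sample, Ref:Breakpoint, RefSide, tDNA, Direction, Split_supportN,
Discort_supportN` (the conventional filename is `<sample>.tDNA.summary`;
separator and coordinate sort are this package's choices, as the original
format documents neither). Supported reads are exported as FASTA together
with a re-alignment TSV produced by the internal aligner — a blast-tabular
stand-in that serves the same manual-checking purpose without an external
binary. `extract_flanks()` returns the 2,000 bp on each side of a breakpoint
for primer design; `recommend_primers()` places the site-specific primer
window 300–700 bp into the flank (sense for Left calls, antisense for Right)
so expected products fall in the 350–700 bp Sanger-friendly range.

`annotate_tis()` classifies each TIS with precedence
exon > intron > promoter (≤ 1 kb, 1–2 kb, 2–3 kb upstream of the nearest
transcription start site, measured on the gene's strand — the TSS, not the
gene-record start, since promoter bins are conventionally TSS-anchored) >
downstream ≤ 300 bp of a gene 3′ end > distal (> 3 kb). The published bins
leave a gap (301 bp–3 kb downstream of a gene, yet > 3 kb from every TSS);
such positions are distal here, and a position downstream of one gene but
within a promoter bin of another goes to the promoter bin — the precedence
resolves the overlap deterministically, and a per-base brute-force oracle
checks the partition in the tests.

`predict_gsh()` expands every annotation interval by its class buffer
(gene and centromere 10 kb, lncRNA and tRNA 20 kb, miRNA 30 kb — "away from"
meaning exclusive edge distance), subtracts the union from each chromosome,
and keeps complements ≥ `min_length`. The 1 kb default minimum is this
package's reporting floor — the source criteria state none — and is
config-exposed, as is every buffer. Equivalence with a per-base scan and
buffer monotonicity are test properties.

# Degenerate inputs and tie-breaks, collected

* Construct configs drawn in the opposite plasmid orientation are normalized
  by reverse-complementing (features keep their identity; coordinates flip).
  Bridge primers given as sequences must match exactly once, else error.
* The contig name `tDNA` is reserved; a genome already containing it is
  rejected, as are empty genomes.
* Equally-best alignment loci: primary = lexicographically smallest
  (contig, position); the rest become cohits → ambiguous-site reports.
* Breakpoint mode ties in a cluster → smallest coordinate. Discordant-only
  cluster breakpoints are the outermost (most junction-proximal) estimate and
  are flagged imprecise.
* Border assignment uses construct-coordinate proximity to the two repeats,
  never the PCR of origin — pooled libraries carry no reliable primer
  identity, and read names are not trusted.
* Zero calls is a success (wild-type input produces a header-only summary).

# Known limitations

* Copy number, full concatemer architecture and backbone presence are out of
  reach of junction enrichment; whole-genome approaches cover that niche.
* Junctions whose bridge site was truncated away are undetectable by
  construction (the half-TIS case); the tool reports the surviving side.
* The internal aligner is deliberately small: ungapped, no quality awareness,
  two segments — use a production aligner for real libraries.
* Discordant-only (imprecise) calls carry no base-resolution breakpoint and
  should be PCR-validated from the recommended windows.
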