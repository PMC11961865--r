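# tagtis

Locates **T-DNA integration sites (TISs)** in transgenic plant genomes from
paired-end sequencing of **Tn5 tagmentation / bridge-primer enrichment
libraries**, and ships everything needed to validate the caller end-to-end
without external data.

## The problem and the method

Agrobacterium-mediated transformation inserts the T-DNA segment of a binary
vector (delimited by ~25 bp left/right border repeats, LB and RB) at
quasi-random genomic positions. Knowing where it landed matters for selecting
transgenic lines, for safety assessment, and for choosing genomic safe
harbors. Whole-genome sequencing finds TISs but its cost scales with genome
size; the assay this package supports instead enriches junction fragments:
Tn5 transposase cuts genomic DNA at random positions and tags the ends, and a
*bridge primer* annealing ~150–200 bp inside the LB (or RB) region amplifies
only fragments that contain a T-DNA end plus its flanking genome.

Reads are aligned to a **merged reference** — the plant genome plus one extra
contig named `tDNA` holding the LB-to-RB construct sequence. Each read pair
then falls into one of four classes:

* **split**: one mate aligns partly to a genome contig and partly to `tDNA`
  (each segment ≥ 20 bp exclusive of overlap, at most 2 segments per read) —
  it sequences through the junction and pins the breakpoint to the base;
* **discordant**: one mate on the genome, the other on `tDNA` — the pair
  straddles the junction without crossing it and corroborates the site;
* **invalid** (genome-only or tDNA-only): uninformative.

Split evidence is typed into one of **8 insertion types**
`RefSide&tDNA&Direction` — whether the genome flank lies Left or Right of the
junction, whether the adjoining T-DNA is the LB or RB region, and whether the
integrated T-DNA forward strand (LB→RB) is co-linear with the genome
(`Forward`) or inverted (`Reverse`). Evidence is de-duplicated per Tn5
fragment (distinct cut sites = independent molecules), clustered around modal
breakpoints, filtered by support (≥ 2 split reads, or 1 split + ≥ 3
discordant), control-subtracted against a wild-type library, and paired into
**full TISs**: a Left and a Right call whose distance reads out the bases
deleted at the target site (`right − left − 1`).

The package also recommends PCR validation primer windows (a site-specific
genomic primer 300–700 bp out, paired with an LB/RB common primer), annotates
TISs against gene models (exon / intron / promoter bins / downstream /
distal), and predicts **genomic safe harbors** as the intervals further than
10 kb from genes and centromeres, 20 kb from lncRNAs and tRNAs, and 30 kb
from miRNAs.

## Worked example

Simulate a transgenic line with two insertions, call TISs with the built-in
aligner, and compare with ground truth:

```r
library(tagtis)

sc <- simulate_scenario(seed = 3, n_events = 2,
                        archetypes = c("ideal_F", "ideal_R"),
                        params = library_params(n_capturable = 30, seed = 3))
idx   <- build_index(sc$merged_ref)
pairs <- align_read_pairs(sc$lib$r1, sc$lib$r2, idx)
calls <- call_tis(pairs, sc$construct, sample = "S1")
calls
#> 4 TIS call(s)
#>  sample       site             type split discordant flags
#>      S1 chr1:54824  Left&RB&Reverse     3         24
#>      S1 chr1:54827 Right&LB&Reverse     7         23
#>      S1 chr2:76426  Left&LB&Forward     4         27
#>      S1 chr2:76446 Right&RB&Forward     8         20

pair_full_tis(calls)$full[, 1:5]
#>   sample chrom left_breakpoint right_breakpoint target_deletion_bp
#> 1     S1  chr1           54824            54827                  2
#> 2     S1  chr2           76426            76446                 19
```

The first event is a reverse-oriented single-copy insertion on chr1 (RB faces
the left flank, hence `Left&RB&Reverse` + `Right&LB&Reverse`) that deleted
2 bp of target sequence; the second is an ideal forward insertion on chr2
with a 19 bp target deletion. Both breakpoint pairs match the simulator's
truth table (`sc$implant$truth`) exactly, with 3–8 non-redundant split reads
and ~20–27 discordant pairs supporting each junction.

A shell entry point with `simulate`, `call`, `annotate`, `gsh` and `flanks`
subcommands is installed as `exec/tagtis`; `run_call()` writes the standard
output set (`<sample>.tDNA.summary`, supported-read FASTA + re-alignment
table, 2 kb flanks, full-TIS table, run log) from a YAML config.

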