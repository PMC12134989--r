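---
title: "Assembly evaluation and sex-chromosome divergence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly evaluation and sex-chromosome divergence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(killistat)
```

`killistat` packages a set of genome-assembly evaluation analyses — the
kind run on a new long-read killifish assembly — as tested functions plus a
seeded synthetic generator that supplies every input with a truth table.
This vignette explains the models and procedures, the parameters that
matter, and the design decisions taken where conventions genuinely differ.

## Coordinates, case and containers

All internal coordinates are 0-based half-open; conversion to and from the
1-based inclusive conventions of GFF3 and RepeatMasker `.out` happens only
in the readers and writers. One convention throughout eliminates off-by-one
drift between modules. Sequence case is preserved on I/O (soft-masked
lowercase survives a round trip) but every analysis is case-insensitive, so
masking state never changes a result. Assemblies are ordered sets of named
sequences (`genome_assembly`); gene models keep per-transcript exon and CDS
interval sets, and gene-level queries use the union across transcripts —
the analyses operate per gene, not per isoform.

## Contiguity and gap statistics

A gap is a maximal run of `N` (case-insensitive), minimum length one; other
IUPAC ambiguity codes are *not* gaps. The one-character minimum follows the
convention of counting every N-run, and a `min_gap_length` argument is
exposed for sensitivity checks. The Nx statistic sorts lengths descending
and reports the first length at which the cumulative sum reaches x% of the
total, together with its 1-based rank — the "n = 13"-style count of
sequences at least that long. Placed/unplaced accounting takes an explicit
chromosome id list and an explicit exclusion list (e.g. the mitochondrial
record): explicit lists are safer than name-sniffing record headers.

## Gene-proximal gap context

For each protein-coding gene the scanner flags whether at least one gap
base overlaps (i) the flank within `flank_size` (default 10,000 bp)
upstream, (ii) the downstream flank, (iii) the coding sequence, and (iv)
any intron (gene span minus exon union). Three conventions were genuinely
open and are all selectable:

* **Strand awareness** (default on): upstream means 5′ of the gene in
  transcription direction. That is the biologically standard reading;
  `strand_aware = FALSE` gives the purely positional variant.
* **CDS vs exon** (default CDS): the coding-sequence flag is computed
  against CDS interval unions, which matches what a "Ns in coding
  sequence" column means for a gene whose terminal exons carry UTRs;
  `cds_mode = "exon"` tests whole exons instead.
* Flank windows are clipped at scaffold ends but **not truncated at
  neighboring genes**, and genes on unplaced scaffolds are included — the
  gene universe is the full protein-coding set.

## Homology, reciprocal best hits and chromosome matching

At synthetic scale, protein similarity comes from global Needleman–Wunsch
alignment (BLOSUM62, affine gaps 11/1) of translated gene CDSs; at real
scale the same downstream code consumes a BLAST `-outfmt 6` table
(`read_blast_tab`), since reimplementing a protein search engine is not the
point. Identity is matches over aligned columns including gap columns. A
reciprocal best hit keeps pair (a, b) iff b is a's highest-scoring partner
and vice versa; ties break by higher identity, then lexicographically
smaller partner id, making results order-independent.

Chromosome homology pools RBH genes into shared-gene counts per chromosome
pair and assigns homologs greedily in descending count order, skipping
chromosomes already taken. Greedy matches the informal "most shared genes"
rule used in practice; on realistic count tables (a dominant true pairing
plus sparse noise) it attains the brute-force optimum, and the test suite
verifies that equivalence exhaustively on instances up to 6 chromosomes per
side.

Dot plots are exact shared k-mer anchors (default k = 15) on both strands,
with two suppression rules: k-mers containing N never anchor, and k-mers
occurring more than `max_occurrences` (default 10) times in either sequence
are dropped. The cap is what keeps satellite blocks from saturating the
plot; k = 15 is small enough to anchor diverged homologous chromosomes and
large enough that random 15-mer collisions are negligible at the megabase
scale.

## Repeat landscape

RepeatMasker `.out` rows map to report categories through an editable
regular-expression table (`repeat_category_map()`), because class/family
naming varies across repeat libraries. Element counts count annotation
rows, but masked bases are per-category interval unions, so overlapping
annotations within a category are not double-counted; the overall masked
percentage is the union across all categories and is therefore bounded
above by the per-category sum. The percentage denominator defaults to the
assembly's non-N length — the convention under which "masked percent of
the assembly" is usually quoted — with total length available by passing it
instead. Whether a published RepeatMasker table double-counts overlaps
depends on that tool's precedence rules; the union convention here is
declared, not asserted to match any specific table.

## Sex-chromosome fragments

`locate_marker` is seed-and-extend: exact 15-mer seeds are clustered by
alignment diagonal (bandwidth 400 bp, at least the largest expected indel),
and each cluster is extended by aligning the whole marker into a padded
window (nucleotide scores +2/−3, gaps 5/2 — BLAST-like defaults, all
configurable). Hit identity is computed over aligned non-gap columns so
that a genuine copy of the locus carrying a long deletion is not rejected
on gap columns alone. Overlapping hits keep the best score.

X/Y classification globally aligns the hit region to the X-linked reference
and scores each diagnostic feature. A deletion is "present" when the net
number of reference bases absent from the region near the feature's
coordinates matches the feature length within ±1 bp; the "near" window
extends 10 bp because affine-gap aligners occasionally split a long gap
around a chance match, which changes the run structure but not the net
deleted length. A region that does not cover a feature's coordinates scores
it "untestable". The call is Y iff every diagnostic is present, X iff every
one is absent, otherwise ambiguous — partial evidence never produces a
confident call.

Gametolog divergence aligns the two CDSs globally; nucleotide divergence is
substitutions over aligned non-gap columns. Excluding indel columns from
the denominator means a 9-bp deletion does not inflate the substitution
rate; the alignment-length denominator is available via
`denominator = "alignment"`. Both inputs are then translated in frame 1
with the standard genetic code (no ORF search — inputs are annotated CDSs;
trailing partial codons are dropped) and the proteins aligned the same way
for amino-acid divergence. A synonymous third-position change therefore
yields zero amino-acid divergence, which the tests assert.

Pseudogene scanning aligns each reference exon into the target on both
strands; an exon is missing below 80% identity, and the start codon is read
from the target residues homologous to the first three reference bases. A
locus is flagged when the start codon is lost or any exon is missing.
Exons are aligned directly against the target rather than through the
seeded search, because reference exons can be shorter than a sensible
seeded-marker minimum; at the fragment scales this scan targets, direct
alignment is exact and fast enough.

## The synthetic study system

The generator emulates the statistical structure the analyses assume — not
real killifish sequence. Defaults: 4 chromosomes of 20–30 kb, 8 multi-exon
protein-coding genes per chromosome on random strands (2–5 exons of
90–240 bp, introns 80–400 bp, intergenic 300–1,200 bp, GC 0.42 as in a
fish genome), ~8 classified repeat insertions per chromosome from a small
library spanning LINE/LTR/DNA/satellite/simple/rolling-circle/unknown
families, and N-runs of 50–300 bp at 1.5 × 10⁻⁴ per bp. The diploid sex
region carries 20 genes of 900–1,800 bp CDS; the Y haplotype differs by
per-gene substitutions (default 0.5%, the scale of observed X–Y gametolog
divergence), a 1.6% substitution rate on the marker locus, a 9-bp CDS
deletion plus a 241-bp 3′-UTR deletion (the published diagnostic features
of the Y-linked marker), and a 3-kb terminal satellite expansion.
Fragmentation breaks the genome into contigs (12 breaks, ≥2 kb contigs)
and rejoins them with 50–300 bp N-runs, so scaffolded length = contig
length + gap length by construction.

Every entry point seeds R's stream once from `config$seed` and draws in a
fixed order, so identical configurations reproduce artifacts
byte-for-byte. Nucleotide composition is i.i.d. with configured GC — no
higher-order chain — which is sufficient for interval, counting and
divergence analyses but means the synthetic data do not reproduce real
codon usage, isochores, or repeat-family sequence structure. Passing tests
therefore demonstrate algorithmic correctness against planted truth, not
robustness to every artifact of real data (alignment ambiguity in highly
repetitive regions being the main caveat).

Problem sizes in the test-suite loops (tens-of-kb genomes, 50 genome
replicates for gap-context truth, 100 diploid replicates for haplotype
calling, 5 genes per rate for substitution-rate recovery) were chosen so
the full suite runs in a few minutes while every property is still
exercised across independent seeds.

## Degenerate inputs and numerical choices

Empty sequences, empty hit lists, markers shorter than the seed size,
deletion coordinates outside the marker, chromosome ids absent from the
assembly, repeat hits beyond a supplied sequence length, and GFF3 children
with unresolvable parents all raise immediate errors rather than
propagating. Rate estimates divide by aligned non-gap columns, so
zero-length denominators cannot arise from valid alignments. Greedy
homology ties break lexicographically, and RBH ties break by identity then
id, so every result is deterministic given its inputs.

## Known limitations

* The internal aligner is quadratic; marker and gene searches target
  fragments up to a few Mb, not whole-genome alignment (use minimap2-class
  tools there and feed the coordinates in).
* Chromosome homology is greedy, not optimal matching; pathological count
  tables with no dominant pairing can differ from the maximum-weight
  assignment (the tests bound this on small instances).
* The gap-context scanner assumes the annotation's seq_ids resolve in the
  assembly being scanned — lift-over between assemblies is out of scope.
* `classify_haplotype` tests only the configured diagnostics; it does not
  discover novel X/Y differences.
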