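---
title: "Methods: splice-mode discovery, isoform enumeration and expression analysis for fungal SOD genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-mode discovery, isoform enumeration and expression analysis for fungal SOD genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodsplice)
```

`sodsplice` implements a desk-scale pipeline for studying a small gene
family -- superoxide dismutases (SODs) in a fungal genome -- whose members
show complicated alternative splicing: intron retention, alternative 5' and
3' splice sites, and, in the extracellular Cu-Zn SOD gene, an initiation
codon located *inside* a retainable intron, so that only retention of that
intron yields a translatable, domain-complete enzyme. This vignette records
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic data do and do not emulate.

## The gene model and coordinate conventions

A `gene_model` is a transcribed region held on the coding strand with
0-based half-open coordinates throughout the package; everything written to
disk (GFF3) is converted to 1-based inclusive coordinates, and minus-strand
genes are reverse-complemented at load time so that all downstream logic
sees the coding strand. Exons and introns alternate and tile the interval
between the transcription start site (TSS) and termination site (TES), and
every intron must begin `GT` and end `AG` on the coding strand -- the GT-AG
rule is enforced by the class validator, by the junction caller, and by the
synthetic-gene builder.

Per-intron splicing states are written `canonical`, `retained`,
`alt5(+k)`, and `alt3(-k)`. Alternative-site offsets are signed and
relative to the canonical intron boundary: `alt3(-6)` means the acceptor
moves 6 bases upstream (the transcript keeps the last 6 intron bases). Both
shifted ends must still present `GT` (for `alt5`) or `AG` (for `alt3`).

## Synthetic fixture genes

The three default fixtures reproduce the studied intron layouts:

* Cu-Zn SOD gene: introns of 52, 76, 80, 125, 57, 58, 54, 55 bp; retention
  capability on I1, I3, I4, I7, I8; an alternative 3' site on I2 (offset
  -6) and on I3 (offset -9); the functional initiation codon inside I4.
* Mn SOD gene 1: introns of 154, 57, 56 bp; I1 retained or alternatively
  donated (`alt5(+9)`), I2 retained.
* Mn SOD gene 2: introns of 47, 72, 126, 119, 88, 61, 87 bp; retention on
  I1, I3, I4, I5, I7.

The builder works backwards from the functional mRNA: an ATG-free 5' UTR, a
coding sequence that encodes a protein carrying the family's conserved
residues, and a 3' UTR. Ordinary introns are inserted into this mRNA as
fresh `GT..AG` sequences; the initiation-codon intron is instead *carved
out* of the mRNA, so that the mature transcript retaining it is exactly the
functional mRNA, while canonically spliced transcripts lose the start codon
and the first ~38 codons. Alternative-site offsets were chosen as multiples
of 3 so that some variant combinations remain frame-intact.

Several sequence-hygiene rules keep the combinatorics interpretable:

* the 5' UTR and all intron interiors are generated free of `ATG`
  trinucleotides, and insertions that would create one at a boundary are
  repaired, so the only upstream start codon any transcript can carry is
  the designed initiator;
* free protein positions never use methionine, so the reading frame
  contains no internal in-frame start before the first required residue;
* stray `GT`/`AG` dinucleotides within 12 bases of donors/acceptors are
  rewritten (designed alternative sites excepted), so junction calls are
  not ambiguous at the 1-2 bp level.

The builder finally *checks its own contract*: the functional transcript's
best open reading frame must translate to the designed protein, and when
the start codon is intronic the canonical transcript must not encode a
domain-complete protein. Violations are errors at build time, not silent
fixtures.

Exon sizes in the fixtures stay at or above 40 bp. This is a deliberate
desk-scale choice: the coding sequences (~520-620 bp) are long enough for
ORF logic and short enough that the exhaustive 96-transcript screen of the
Cu-Zn fixture runs in seconds.

## Read simulation

`simulate_read_pairs()` samples fragments per isoform in proportion to
`coverage x proportion x length`. Fragment sizes are Normal(300, 50)
truncated to `[2 x read length, 1000]`: the mapper's 1-2000 bp pair-span
window is a mapping tolerance, not a library geometry, so a realistic
insert model is used instead. Mate 1 is the fragment's 5' end, mate 2 the
reverse complement of its 3' end; errors are substitutions only (no
indels), qualities are constant Phred+33 `I`, and provenance (isoform,
fragment start) is recorded so closed-loop tests can compare calls with
truth. Every generator in the package is a pure function of its
configuration and seed.

The default isoform mixture gives the canonical transcript 70% and splits
the remaining 30% equally over single-event variants. With the Cu-Zn
fixture's seven variants this puts each event at ~4% of transcripts --
deliberately minor isoforms, as retained-intron transcripts typically are.

## Junction-aware mapping

`map_reads()` is a seed-and-extend spliced mapper specialised to short
references (a gene plus flanks). Exact 16-mers tiled every 4 bases across
the mate are looked up in a reference k-mer index; each hit implies a
candidate origin. Contiguous placements are scored by mismatch count, and
every ordered pair of origins whose distance lies in [4, 2000] bp defines a
candidate reference skip, for which the breakpoint is chosen to satisfy
`GT..AG` at the skip ends and minimise total mismatches (ties: leftmost
donor). A mate may split across at most one junction; its blocks must keep
at least 8 aligned bases on each side. Transcriptome mode tolerates 2
substitutions per mate, genome mode none and no splits. Pairs are retained
only when both mates map and their span is 1-2000 bp. Equal-score
alternative placements make a mate ambiguous and it is dropped --
conservative junction evidence over mapping yield.

Two consequences are worth knowing. First, a read whose junction lies
within 16 bases of either end cannot anchor both blocks and is lost;
second, reads crossing two junctions (possible over the Cu-Zn fixture's
small 5' UTR exons) are lost too. Neither biases *which* junctions are
called; both reduce support counts, which is why the event-recovery
experiments below use deeper coverage.

TSS/TES determination is the paired-end rule: the smallest and largest
reference coordinates covered by any mapped mate. Because fragment starts
are uniform, coverage decays linearly over the outermost read-length of the
transcript, so bounds converge to the truth only within about one read
length at moderate depth; closed-loop tests assert exactly that.
`coverage_profile()` reports per-base depth over aligned blocks only, the
minimum depth, and any uncovered gaps; a region is *verified* when no gap
remains.

## Splice calling

`call_introns()` tallies distinct (donor, acceptor) skips, enforces GT-AG
against the reference, and applies a support floor of 2 unique junction
reads (the default everywhere a support threshold appears). The canonical
intron set is chosen greedily by support (ties: shorter intron, then
smaller donor coordinate) among non-overlapping junctions.
`classify_events()` then accumulates per-intron states: a junction sharing
the acceptor but shifting the donor is `alt5`; sharing the donor but
shifting the acceptor is `alt3`; retention requires at least 2 reads whose
*contiguous aligned block* crosses each exon-intron boundary with >= 8
bases on both sides. Counting any qualifying aligned block (not only
single-block mates) matters for retained introns flanked by short exons,
where retention-supporting reads often also span a neighbouring junction.
Junctions sharing neither end with a canonical intron are reported as
novel rather than classified.

Event-recovery experiments run at 300x total coverage. This is a
support-arithmetic choice made when the experiment was designed: with the
default 70/30 mixture a single Cu-Zn variant receives about 4% of
transcripts, i.e. ~13x; after junction-proximal read losses its junction or
boundary support lands near 6-10 reads, safely above the floor of 2, so
that >= 95% of simulated events are recovered across 20 seeds with no
spurious alternative-site calls. At 30x -- used for canonical-structure
recovery, where the canonical isoform holds 70% of the mixture -- variant
support would sit at the floor and recovery would be a coin flip.

## Isoform enumeration and the intronic start codon

`enumerate_transcripts()` forms the exact Cartesian product of per-intron
state sets in lexicographic order (8 introns with 2/2/3/2/1/1/2/2 states
give 96 Cu-Zn transcripts; 3/2/1 give 6; five binary retentions give 32).
`find_orf()` returns the longest ATG-initiated ORF ending at an in-frame
stop, ties resolved 5'-most, with a configurable floor of 50 codons (the
floor is lowered only in unit tests of hand-sized examples). Translations
are screened against the family's residue profile; reports keep
ORF-disrupted transcripts with verdict `absent`, and distinct proteins are
grouped by exact string identity with the lexicographically smallest state
vector as representative.

On the Cu-Zn fixture this machinery exhibits the central mechanism: every
domain-complete isoform retains I4, and no I4-spliced isoform is
domain-complete, verified exhaustively over all 96 state vectors.

## Homology screening

`local_align()` is an exact Smith-Waterman with affine gaps (BLOSUM62,
open 11, extend 1; a gap of length L costs `11 + L`). The DP is vectorised
one row at a time; the within-row gap state needs only a running maximum
over pre-gap scores, because opening a second gap immediately after another
can never beat the single merged gap. Scores were cross-checked against an
independent scalar DP oracle and against a second implementation on random
pairs. E-values use the Karlin-Altschul form `E = K m n exp(-lambda S)`
with lambda = 0.267 and K = 0.041, the standard gapped BLOSUM62/11,1
constants; the retention threshold defaults to E <= 1e-2.

An e-value threshold alone retains occasional random decoys (that is what
an e-value of 0.01 means); family membership is therefore *confirmed* by
conserved residues. The Cu-Zn profile uses the canonical numbering --
Cu-binding H97/H99/H114/H171, Zn-binding H114/H122/H131/D134, the C108/C147
disulfide, and the N137 glycosylation site -- on a synthetic 173-residue
reference. For the Mn family the ligand positions are configurable, with a
default of H27/H82 plus the C-terminal D-x-W-E-H signature (D168, W170,
E171, H172) on a 205-residue reference; Fe-family proteins share this fold,
so Fe vs Mn discrimination is by reference label only. A verdict is
`complete` when all required residues are matched through the optimal
alignment, `partial` at half or more, `absent` otherwise. Family members
are modelled as mutated copies of the profile reference (default 25%
substitution at free positions), which keeps them alignable while distinct;
decoys are uniform random sequences, rejection-sampled to verdict `absent`.

## Phylogeny

`pdistance_partial_deletion()` removes alignment columns whose non-gap
fraction falls below the site-coverage threshold (default 0.70) *globally*,
before any pairwise comparison -- the interpretation chosen for the named
"partial deletion" option; pairwise-deletion semantics would differ.
Distances are then mismatch proportions over sites where both rows are
non-gap, with an explicit error naming any pair left without comparable
sites. `nj_tree()` delegates to the standard neighbor-joining
implementation in `ape` (exact on additive matrices, verified against
random additive trees) and clamps negative branch-length estimates to zero
with a warning. `bootstrap_support()` resamples the filtered columns with
replacement, rebuilds the tree per replicate, and reports for each internal
branch the percentage of replicates containing the same bipartition
(branch lengths ignored, trees treated as unrooted); supports are attached
as integer node labels and survive Newick round trips. Replicates whose
resampled columns leave a pair without comparable sites are skipped and the
percentage is taken over the replicates actually built.

## Expression

`ddct_fold_change()` implements relative quantification with an assumed
amplification efficiency of exactly 2. Technical replicates sharing a
replicate id are averaged within sample first; dCt = target Ct - reference
Ct per biological replicate; ddCt subtracts the calibrator's mean dCt; the
reported fold is `2^-ddCt` of the condition mean, which makes the
calibrator's fold *identically* 1 for any noise realisation. Standard
errors are delta-method propagated to the linear scale
(`se = fold x ln 2 x se(dCt)`), from each condition's own replicate spread.
The generator inverts the statistic -- target Ct = baseline - log2(fold) +
Gaussian noise -- so closed-loop recovery is a genuine test of the
estimator; with noise sd 0.05 cycles, 4 replicates and a constant reference
gene, recovered folds sit within a few percent of truth, and the log-scale
estimator is unbiased.

`lsd_letters()` runs one-way ANOVA for the pooled error and all pairwise
least-significant-difference t-tests at alpha (default 0.05). The compact
letter display assigns letters as the maximal cliques of the
non-significance graph, ordered by decreasing group mean: two groups share
a letter exactly when their difference is not significant, and the display
is transitive-consistent by construction. A pooled mean square of zero
(all groups constant) is a degenerate-variance error, not a letter
assignment. Correlations are plain Pearson r, with explicit errors for
zero-variance input; `karyogamy_correlation()` correlates stage-wise
expression against the recorded karyogamy efficiencies (37.5%, 30%, 0.1%
at the egg, elongation and maturation stages).

## What the synthetic data do not emulate

The simulators aim at logical correctness of the pipeline, not platform
realism: no indel errors, no quality-score decay along reads, no
GC-coverage bias, no positional fragmentation bias, uniform decoy
amino-acid composition, and intron interiors with uniform base composition
rather than branch-point or polypyrimidine structure. Passing closed-loop
tests therefore demonstrates that the algorithms recover what they are
defined to recover under clean, known-truth conditions; they do not
demonstrate robustness to real library artefacts. Likewise the isoform
mixture is a design default (70/30), not an estimate: relative transcript
abundances of the real genes are unknown to the package.

## Problem sizes

The shipped experiments are sized for a desk: canonical-structure recovery
simulates 2x75 bp pairs at 30x per gene; event-mode recovery runs 20 seeds
x 3 genes at 300x (~10^5 mates in total); the proteome screen uses 200
decoys plus two embedded family members against two references; bootstrap
analyses use 1000 replicates on 8-taxon alignments of ~126 columns. The
full test suite completes in under two minutes on a single core.
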