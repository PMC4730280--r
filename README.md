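# sodsplice

Alternative splicing, isoform enumeration and expression analysis for
fungal superoxide dismutase (SOD) genes.

Small gene families with complicated splicing are awkward to analyse with
genome-scale tools: the interesting structure is per-intron (which introns
can be retained, which donors/acceptors shift), the isoform space is small
enough to enumerate exhaustively, and the biological question is often a
single mechanism — here, an extracellular Cu-Zn SOD gene whose initiation
codon lies *inside* a retainable intron, so that intron retention, usually
a way to break a transcript, is the only way to make the functional enzyme.
`sodsplice` is a desk-scale pipeline for exactly this setting, aimed at
researchers studying small families (SODs in basidiomycete fungi being the
motivating case) who want every step testable end-to-end against synthetic
data with known truth.

The pipeline covers:

* **Homology screening** — exact Smith–Waterman local alignment
  (BLOSUM62, affine gaps 11/1) against labeled reference SODs with
  Karlin–Altschul e-values, `E = K·m·n·e^{−λS}` (λ = 0.267, K = 0.041),
  threshold `E ≤ 10⁻²`, confirmed by conserved metal-binding residue
  profiles (Cu: H97/H99/H114/H171; Zn: H114/H122/H131/D134; the C108/C147
  disulfide; N137 glycosylation).
* **Junction-aware read mapping** — paired-end 2×75 bp reads mapped to a
  gene region with spliced alignments under the GT-AG rule, paired-end
  TSS/TES determination, and per-base coverage verification.
* **Splice calling** — per-intron state catalogs: `canonical`,
  `retained`, `alt5(+k)`, `alt3(−k)`, with read-support thresholds.
* **Isoform enumeration** — the Cartesian product of per-intron states,
  ORF/UTR annotation (longest ATG→stop, ties 5′-most), translation,
  domain screening, and distinct-protein counting.
* **Distance phylogeny** — p-distances under partial deletion (70% site
  coverage), neighbor joining, bootstrap supports from resampled columns.
* **RT-qPCR expression** — 2^−ΔΔCt relative quantification against a
  reference gene and calibrator, Fisher's LSD compact letter displays,
  Pearson correlations including stage-wise karyogamy efficiency.
* **Synthetic data** — fixture genes with configurable GT-AG intron
  layouts (defaults reproduce the three studied *sod* genes), isoform
  mixtures, paired-end read simulation, Ct tables with known fold-change
  effects, and decoy proteomes. Everything is a pure function of
  (config, seed).

## Worked example

Build the Cu-Zn SOD fixture gene, sequence it in silico, and recover its
splicing modes:

```r
library(sodsplice)

g <- cuzn_sod1_fixture()
g
#> <gene_model> CuZnsod1 (+) region 1224 bp, transcribed [0, 1224), 8 intron(s)
#>   intron lengths: 52, 76, 80, 125, 57, 58, 54, 55 bp
#>   splice states: I1:{canonical,retained} I2:{canonical,alt3(-6)}
#>   I3:{canonical,retained,alt3(-9)} I4:{canonical,retained} I5:{canonical}
#>   I6:{canonical} I7:{canonical,retained} I8:{canonical,retained}

reads  <- simulate_read_pairs(g, config = sim_config(coverage = 300,
                                                     error_rate = 0.005,
                                                     seed = 1))
aln    <- map_reads(reads, g$seq)
jx     <- call_introns(aln, g$seq, min_support = 2)
events <- classify_events(jx, aln, g)
events[events$type != "canonical", ]
#>   intron start   end type     offset support
#> 1 I1        50   102 retained      0       2
#> 2 I2       147   223 alt3         -6       4
#> 3 I3       268   348 alt3         -9       5
#> 4 I3       268   348 retained      0       3
#> 5 I4       388   513 retained      0       3
#> 6 I7       923   977 retained      0       7
#> 7 I8      1097  1152 retained      0       7
```

All seven simulated non-canonical events come back with the correct type
and offset. Enumerating the 2⁴·2·3 = 96 transcripts and screening their
translations shows the initiation-codon mechanism — domain-complete
proteins arise *only* from I4-retained transcripts:

```r
tx  <- enumerate_transcripts(g)     # 96 transcripts
rep <- screen_isoforms(tx, g$meta$profile)
table(i4 = vapply(rep$states, `[`, "", 4), verdict = rep$verdict)
#>            verdict
#> i4          complete partial
#>   canonical        0       0
#>   retained        24      24
```

(The 48 I4-canonical transcripts have no qualifying ORF at all.) A
closed-loop qPCR experiment with a known 5.1-fold cold-stress induction:

```r
des <- ct_design(genes = "CuZnsod1", conditions = c("control", "cold"),
                 folds = tibble::tibble(gene = "CuZnsod1",
                                        condition = "cold", fold = 5.1),
                 replicates = 4, sd = 0.05, reference_sd = 0, seed = 1)
fit <- ddct_fold_change(generate_ct_table(des), "gapdh", "control")
tidy(fit)
#>   gene     condition   dct  ddct  fold     se     n
#> 1 CuZnsod1 cold       3.66 -2.35  5.08 0.0608     4
#> 2 CuZnsod1 control    6.00  0     1    0.0191     4
```

The estimator recovers 5.08× against a truth of 5.1×; the calibrator is
pinned at exactly 1 by construction. `autoplot()` methods draw gene
structures and expression bar charts; `tidy()`/`glance()` expose fitted
results as tibbles.

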