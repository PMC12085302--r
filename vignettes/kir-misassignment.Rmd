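---
title: "Modelling KIR read misassignment in 5' single-cell RNA-seq"
author: "kirsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling KIR read misassignment in 5' single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirsim)
```

## The problem

The killer immunoglobulin-like receptor (KIR) genes are a cluster of
~16 highly homologous loci on chromosome 19. Their gene content varies
between people: the A haplotype carries a fixed, largely inhibitory set
(KIR2DL1/L3/L4, KIR2DS4, KIR3DL1-3 plus the framework pseudogenes),
while B haplotypes add activating genes (KIR2DS1/S2/S3/S5, KIR3DS1,
KIR2DL2, KIR2DL5). The human reference assemblies carry only one
haplotype's worth of KIR sequence — seven genes — so standard
single-cell RNA-seq pipelines cannot report the missing activating
genes at all. Worse, because the family is so homologous, reads from a
gene that is absent from the reference do not disappear: they are
captured by the nearest homolog that *is* in the reference (an
activating transcript silently inflating an inhibitory gene's counts),
or — if no homolog is close enough — they are dropped as unmapped. A
second, independent loss mechanism is annotation biotype filtering:
KIR2DS4 is present in the assembly but annotated as a "polymorphic
pseudogene", so pseudogene-excluding default annotations silently
suppress its counts.

`kirsim` reproduces this whole chain of effects at desk scale with a
synthetic, fully-controlled KIR-like family, so that every stage —
simulation truth, alignment decision, UMI count, diagnostic
classification — is verifiable exactly.

## The synthetic family

A family is generated on a shared 9-exon plan (`kir_exon_plan()`,
1281 nt, exon lengths approximating a three-domain KIR cDNA).
Divergence is realized by substitutions only, at uniformly random
positions per exon, so all sequences stay coordinate-aligned;
position-wise identity and diagnostic-position extraction are then
exact, and the mapper never needs gapped alignment. Coordinates are
0-based and half-open everywhere internally; GTF output converts to the
standard 1-based inclusive convention.

Pairwise identity between two genes drawn independently from the
ancestor at per-site rate $d$ is $q = (1-d)^2 + d^2/3$ (both unchanged,
or both mutated to the same alternative out of three). The generator
inverts this to hit a target per-exon identity profile; the default
profile is 0.97 at the short conserved exons 1/2/6/7/8 and 0.90 at the
Ig-domain exons 3/4/5. The spec of the family states no value for exon
9; we group it with the variable exons at 0.90, since 3' ends of the
cDNAs are not part of the conserved receptor core.

Two structural features are laid on top of this backbone, because a
flat homology profile alone cannot produce the misassignment pattern
seen in real data (under a flat profile every absent gene is
equidistant from all references, and its reads scatter or multimap
rather than sinking into one locus):

* **Sister genes.** Each activating analog is derived from its
  inhibitory partner directly (KIR3DS1 from KIR3DL1, KIR2DS1/2DS5 from
  KIR2DL1, KIR2DL2 from KIR2DL3 with KIR2DS2/2DS3 stacked on KIR2DL2),
  *identical at the conserved exons 1/2/6/7/8* and carrying a defined
  1-1.5% per-site substitution load in the variable exons 3/4/5/9.
  Lineage loads are exact (`round(rate * exon length)` substitutions),
  not binomial draws: how many paralog-defining sites a pair shares is
  a structural property of the family we want reproduced at every
  seed, whereas backbone identity is a statistical target where
  binomial variation is appropriate.
* **Anchor polymorphisms.** Each sister gene is guaranteed one
  defining SNP inside transcript positions 190-250 (mid exon 3, within
  reach of 5' reads). Without this guarantee a random draw
  occasionally produces a paralog with no read-accessible diagnostic
  site at all, whose reads are unattributable under *any* reference —
  contradicting the observed behaviour of the real family, where
  locus-assigned reads demonstrably expose gene-specific polymorphisms
  (that observation is precisely what makes read-level diagnostic
  classification possible). The anchor makes "every paralog is
  distinguishable somewhere a read can see" a property of the family
  rather than an accident of the seed.
* **A distant gene.** The KIR2DL5 analog is generated at 25% flat
  divergence, below the mapper's acceptance floor against every other
  gene, so under the restricted reference its reads are lost unmapped
  rather than misassigned — the one family member whose absence
  produces no artefactual signal elsewhere.

`kir_fixture()` carries the non-synthetic facts the presets encode:
which seven genes are in GRCh38, the 14-functional + 2-pseudogene
composition of the complete family, and KIR2DS4's polymorphic-
pseudogene biotype. KIR2DL5A/B is one merged entry for these counts; a
split view exists because genotyping panels display both loci
separately, and the literature counts either way.

## Simulation

A donor genotype fixes per-gene presence (all A-fixed/framework genes
always present; B-associated genes present with probability
$1-(1-p)^{n_B}$) and an allele pair per present gene. Expression truth
draws, per cell and present gene, positivity at frequency 0.25 and
$1 + \mathrm{Poisson}(\mu - 1)$ molecules ($\mu = 3$). Each molecule
receives a globally unique 10-nt UMI and two 90-nt reads; cell barcodes
are 16-nt, drawn without replacement (10x v2-style 5' chemistry), and
travel in the read name (`r<n>:<barcode>:<umi>`), making the FASTQ
lossless without index files. Read starts follow a truncated geometric
5' model. The simulator's default is `p = 0.05`; the preset experiment
uses `p = 0.02` (mean offset ~50 nt) so that reads sample the whole
first Ig-domain exon — under the steeper default, variable-exon
diagnostic SNPs beyond position ~200 would be invisible to every read
and sister genes would be unrecoverable under any reference, which is
not what real 5' libraries (insert spread of a few hundred bases) do.
Substitution errors are i.i.d. per base (preset rate 0.005; recovery
experiments run error-free); realized error counts are recorded in the
truth table. There are no indels, no barcode collisions, no chimeras
and no quality model (all Q37): each is a fixed, documented assumption,
chosen because the phenomena under study are driven by substitution-
level homology, not by library artefacts.

## The mapper and its oracle

The bespoke transcriptome mapper is deliberately minimal so that it is
*exactly* analyzable: exact k-mer seeds (default k = 21) propose
(transcript, diagonal) candidates; each candidate is scored by ungapped
extension of the full read (+1 match, -1 mismatch); hits below 0.8 of
the perfect score are discarded (this acceptance floor is what turns a
sufficiently diverged gene's reads into unmapped ones instead of
letting them mismap). Assignment follows default single-cell counting
semantics: hits confined to one gene (alleles of a gene count as that
gene) are unique; a top score tied across two or more genes is
multimapped and discarded from counting — ties are never broken,
because the tie *is* the multi-mapping signal; no hits is unmapped.
Gapped alignment is unnecessary by construction (substitution-only
simulator) and omitted; strand search is sense-only, matching the
simulation.

The oracle (`oracle_align()`) is an independent pure-R exhaustive scan:
for every read and transcript it scores *all* diagonals on which the
read fits and returns the optimum. The seed-and-extend path provably
equals the oracle wherever the oracle-optimal diagonal carries at
least one exact k-mer seed; a read can score above threshold on a
seedless diagonal (mismatches spaced closer than k), and such reads
are counted as seed-sensitivity losses rather than asserted equal —
asserting raw equality there would test a property seed-based mappers
do not have. The oracle itself is cross-checked against
`Biostrings::pairwiseAlignment` with gaps forbidden.

## Quantification and comparison

UMI counting collapses unique-status reads by exact
(barcode, UMI, gene) triple; no UMI error correction is attempted
because the simulator emits error-free barcodes and UMIs, and UMI
correction is orthogonal to the questions here. The restricted arm
aligns against all seven GRCh38-analog transcripts but counts only the
six genes surviving the biotype filter — reproducing the
assembly-versus-annotation distinction through which KIR2DS4 is
aligned but never quantified.

`compare_references()` cross-tabulates each read's label under the two
references (the reassignment flow; both marginals must equal the read
total, asserted on every run) and reports the signed unique-count
change $(u_B - u_A)/u_A$. In the preset this is negative (typically
-10% to -40% of unique reads): the full reference introduces each
sunk gene's near-identical partner, converting confidently-wrong
unique assignments into discarded multi-mapping ties. The real-data
analog of this statistic is a percent-level reduction; the synthetic
magnitude is larger because the preset family is deliberately small
and sister-dense, so only the *sign* is a claim the simulation makes.
Whether such a reduction should be measured on reads or UMIs is
genuinely ambiguous; flows are computed on reads by default ("
proportion of reads per locus"), with a `umi = TRUE` option.

Co-expression patterns (per-cell expressed gene sets at a UMI
threshold, default 1) and genotype recovery (gene present iff >=
`min_cells` cells carry >= `min_umis` UMIs; defaults 2 and 1) complete
the quantifier. With error-free reads and reference alleles, false
positives are impossible by construction — a read cannot score
strictly higher on a gene it did not come from than on its own gene —
so recovery accuracy is governed entirely by whether each present gene
retains enough unique reads, which the anchor design guarantees.

## Diagnostics

`exon_identity()` gives the per-exon pairwise identity landscape (the
conserved-exon blocks are where misassignment and multi-mapping
concentrate). `find_diagnostic_positions()` returns exactly the
non-unanimous columns of a locus group with their base-support maps;
`classify_locus_reads()` applies them to locus-assigned reads the way
one inspects polymorphisms in a pileup: a source supports a read if it
agrees at every covered diagnostic position (at least
`min_informative`, default 1 — a single covered diagnostic base
classifies); unique support classifies the read, empty support is a
conflict (impossible for error-free reads, so any conflict measures
the error process), ambiguous support is uninformative.

`predict_sink()` predicts where an absent gene's reads will land:
the reference gene with the highest read-length-windowed identity, if
it clears the identity threshold (0.9, the mapper's 0.8 score floor
translated through +1/-1 scoring), else UNMAPPED. Windowed ties are
broken by whole-transcript mean identity, since several genes can
share one perfect conserved window while only one is the genuine
nearest homolog. Predictions also carry a `decisive` flag: when an
absent gene is near-equidistant from several references (the framework
pseudogene analogs under the flat backbone), its simulated majority
fate is multi-mapping, not a single sink, and the argmax prediction is
reported but not expected to match a majority — a documented
limitation of the windowed-identity model rather than of the mapper.

## Problem sizes and numerical choices

The preset experiment uses 800 cells, positive-cell frequency 0.25,
mean 3 molecules, 2 reads per molecule: ~1.9 x 10^4 reads, which keeps
a full two-arm run in a few seconds while leaving >1000 truth reads
per gene. Recovery experiments run the preset error-free over 10
seeds; oracle-equivalence checks use 200 random instances of up to 8
transcripts x 25 reads with k = 11 (smaller k stresses the seeding
logic harder than the preset's 21). Stage seeds derive
deterministically from one master seed (`derive_seed()`), so any stage
can be reproduced alone; identical configurations are byte-identical,
which the suite asserts on written FASTQ.

## What passing does and does not show

The generator emulates controlled homology structure, presence/absence
genotypes, 5' tag chemistry and substitution error. It does not
emulate indel polymorphism, copy-number variation within a haplotype,
recombination, ambient RNA, doublets, or real IPD-KIR allele
nomenclature; the mapper does not model spliced genomic alignment,
base-quality weighting, or EM rescue of multi-mapped reads (the
modelled pipeline discards them, which is the behaviour under study).
Consequently, passing results demonstrate the *mechanisms* —
reference-content-driven sinks, biotype-filter losses, multi-mapping
trade-offs, diagnostic-SNP attribution — and their directions, not the
numeric rates any particular real dataset would show. Real-data rates
depend on the actual allele sequences, library insert distribution and
the production aligner, none of which are in scope here; the optional
real-sequence mode (`load_family_from_fasta()`) accepts pre-aligned
equal-length KIR sequences but building multiple-sequence alignments
is out of scope.
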