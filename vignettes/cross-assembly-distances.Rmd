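---
title: "Comparing metagenomes by cross-assembly accounting"
author: "xadist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing metagenomes by cross-assembly accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xadist)
```

## The problem

Metagenomic samples — especially viral ones — are dominated by sequences
with no homolog in any reference database, so comparative analyses that
map reads to references silently discard most of the data.  A
reference-independent alternative is to pool the reads of all samples into
one de novo assembly (a *cross-assembly*) and let the assembler itself
decide which reads belong to the same biological entity.  A contig that
contains reads from two samples (a *cross-contig*) is direct evidence that
those samples share an entity, whether or not anything about that entity
is known.

`xadist` consumes the two artifacts of such an experiment — one read file
per sample (FASTA/FASTQ; sequences may be stripped, since only identifiers
are needed) and the ACE file describing the assembly — and produces
per-contig read accounting, pairwise distance matrices, and BioNJ
cladograms or contig scatter plots.

## The accounting model

Index contigs by $k = 1, \dots, n$ and let $r_{ki}$ be the number of reads
of sample $i$ in contig $k$.  Reads assembled into no contig (singletons)
are listed in the output but excluded from every distance.  From the
count matrix come:

* $c_i = |\{k : r_{ki} > 0\}|$ — contigs containing sample $i$;
* $c_{ij}$ — cross-contigs containing both $i$ and $j$;
* $r_i = \sum_k r_{ki}$ — assembled reads of $i$;
* $r_{ij}$ — reads of $i$ inside the shared cross-contigs;
* $p_{ki} = r_{ki} / r_i$ — a probability vector over contigs that
  characterises sample $i$.

## The four distance formulas

Two formulas are presence/absence based — a contig either contains a
sample's reads or not — and two treat read counts as abundances.

**shot** normalises the shared-contig signal by a size-corrected mean of
$c_i$ and $c_j$ (the squared geometric mean over the root mean square), a
correction with a history in gene-content phylogenetics:
$$d = 1 - c_{ij}\sqrt{\frac{c_i^2 + c_j^2}{2\,c_i^2 c_j^2}}
    = 1 - \sqrt{\tfrac12\left[(c_{ij}/c_i)^2 + (c_{ij}/c_j)^2\right]}.$$
Because that mean never falls below $\min(c_i, c_j)$, the **minimum**
formula
$$d = 1 - \frac{c_{ij}}{\min(c_i, c_j)}$$
is a lower bound: $d_{\mathrm{shot}} \ge d_{\mathrm{minimum}}$ always,
strictly whenever $c_i \ne c_j$ and $c_{ij} > 0$.

**wootters** is the statistical distance between the contig distributions:
$$d = \frac{2}{\pi}\arccos\!\Big(\sum_k \sqrt{p_{ki}\,p_{kj}}\Big),$$
the angle between the square-root embeddings of the two probability
vectors, interpretable as the number of statistically distinguishable
intermediates between the two distributions.  The $2/\pi$ scaling makes
disjoint support give exactly 1, commensurate with the other formulas (the
raw angle in radians is available via `scale = "radians"`).  Numerically
the angle is evaluated in its chordal form
$2\arcsin(\lVert\sqrt{p} - \sqrt{q}\rVert / 2)$, which is exact at zero
where $\arccos$ near 1 loses half its digits.

**reads** mirrors the shot formula with read fractions instead of contig
fractions, damping the bias of long contigs catching stray reads:
$$d = 1 - \sqrt{\tfrac12\left[(r_{ij}/r_i)^2 + (r_{ji}/r_j)^2\right]}.$$

All four distances live in $[0, 1]$, are symmetric and have zero
diagonal; `wootters` additionally satisfies the triangle inequality.
The distance-versus-similarity convention here is $d = 1 - s$ throughout,
chosen for the documented $[0,1]$ range and for direct use in cladograms.

As a reference-independent baseline of a different kind, the package also
computes dinucleotide odds-ratio signatures
$\rho^*_{XY} = f^*_{XY} / (f^*_X f^*_Y)$ (counted strand-symmetrically per
read, windows with ambiguous bases skipped; ratios with zero expected
frequency are reported as 0) and the mean absolute signature difference
$d_{ij} = \frac{1}{16}\sum_{XY} |\rho^*_{i,XY} - \rho^*_{j,XY}|$.  The
$1/16$ averaging follows the usual genomic-signature convention; any fixed
scaling rescales all distances uniformly and cannot change a clustering.
Profiles are computed on raw reads by default (contig consensus sequences
can be profiled by passing them explicitly).

## Trees

For more than three samples each distance matrix is summarised as a
cladogram built with BioNJ — neighbor joining with variance-weighted
reduction, exact on additive matrices.  The agglomeration is implemented
in the package in double precision (the classical C implementation uses
single precision, which costs six digits of the additive-recovery
guarantee); ties in the Q-criterion break towards the lexicographically
smallest label pair so results are platform-independent.  Each tree is
serialised to Newick twice: with branch lengths, and topology-only for
the common situation where between-sample differences dwarf the
similarities and internal branches become invisibly short.  Negative
branch lengths, which NJ-family methods can produce on non-additive
input, are kept in the tree object but clamped to zero at serialisation
(default on).  Two- and three-sample analyses are shown instead as XY/XYZ
scatter plots of per-contig counts (zeros drawn at 0.9 on the log axes so
sample-specific contigs stay visible) and as a barycentric triangle plot.

## The synthetic-data module

Nothing above can be tested end to end without an assembler and genomes,
so the package generates its own:

* **Genome pools** (`make_genome_pool`): iid sequences with controlled GC,
  optionally (i) derived from a common pool ancestor by per-site
  substitution (`divergence`), so that different "species" of one pool
  share exact k-mers the way real within-phylum homologs do, and/or (ii)
  first-order Markov chains sharing a pool-wide dinucleotide signature
  (`dinuc_bias`), because iid sequences have $\rho^* \approx 1$ everywhere
  and would make the signature baseline blind.  Genome lengths are
  desk-scale (tens to hundreds of kb rather than Mb).
* **Communities and reads** (`community_spec`, `sample_reads`):
  relative abundances uniform or logarithmic (geometric rank-decay),
  contamination as a fraction of reads drawn uniformly from a separate
  pool, and pyrosequencing-like reads: length $\mathcal{N}(450, 100)$
  truncated below at 50 nt, uniform position and strand, 2% per-base
  errors split 85% substitutions / 15% indels, with the error rate
  inflated threefold inside homopolymer runs of 3 nt or more — a
  deliberately simple stand-in for flowgram-resolution homopolymer error
  models; the distances depend only weakly on the error microstructure.
  Every read records its true origin, so downstream assertions are exact.
* **A toy cross-assembler** (`toy_cross_assemble`): single-linkage
  clustering of reads sharing at least `min_shared = 2` exact canonical
  21-mers.  It builds no consensus and is not a sequence assembler; it
  reproduces the one property the accounting needs — reads from the same
  or homologous region end in the same contig.  `min_shared = 2` is
  deliberately conservative: one chance k-mer collision between unrelated
  loci would otherwise merge two whole coverage islands into a chimeric
  contig (with multi-Mb total genome space such collisions do occur),
  while two independent collisions between one read pair are vanishingly
  unlikely.  The ground-truth contig composition is returned alongside
  the ACE output.

## The three simulation experiments

The package re-creates, at reduced scale, three classic benchmark designs;
their defaults are the package's study conditions and are used by the
test suite and the acceptance script.

**Species overlap** (`experiment_overlap`): a reference community of 10
low-GC genomes (20 kb each, 2,000 reads/sample) is compared against a
series of 11 samples in which 0, 1, ..., 10 members are replaced by
genomes from a high-GC pool.  Each step is cross-assembled pairwise with
the reference; all four cross-assembly distances and the dinucleotide
baseline must decrease as true species overlap increases.

**Abundance permutation** (`experiment_abundance`): four pairs of samples
over one shared set of 10 genomes (400 kb each), with logarithmic
abundances (decay 0.65/rank) assigned to genomes differently per pair,
identically within a pair; 1,500 reads/sample.  Pair members should
appear as sisters in every formula's cladogram.  Two design points
matter here:

* *Coverage.*  Per-sample coverage is well below 1x while the joint
  assembly reaches ~1.2x, so the assembly fragments into thousands of
  contigs whose per-sample presence is informative.  This is the regime
  of the original experiments (tens of thousands of reads against
  communities of 2–6 Mb genomes); with saturated presence the
  presence/absence formulas lose their signal.
* *Balanced assignments.*  The per-pair rank permutations are not drawn
  at random but constructed greedily so every genome receives a nearly
  equal abundance total across pairs.  Random permutations can
  concentrate several pairs' mass on the same genomes; those genomes'
  joint coverage then merges them into few contigs, the affected samples'
  presence vectors become nested inside denser ones, and the
  minimum-normalised formula in particular misclusters — an artifact of
  the desk-scale genome count, not of the method.  The genomes' GC range
  is kept narrow (0.38–0.48) for the same exchangeability reason:
  strongly AT-rich sequence carries more homopolymer runs and therefore
  assembles systematically worse under the inflated-error model.

**Noise contamination** (`experiment_noise`): three samples of different
species from a high-GC pool and six from a low-GC pool (pool members
diverge 2% from a pool ancestor of 800 kb, so within-group homology is
real), all contaminated with 0–100% reads from a shared third pool.  The
internal cladogram branch separating the two groups must shrink
monotonically with contamination and vanish at 100%.

What passing these experiments does **not** show: the generator has no
strain-level variation, no conserved genes shared *across* pools, no GC
or length heterogeneity within a pool beyond the divergence model, no
chimeric assembly artifacts, and the toy assembler has no consensus or
quality model.  Real cross-assemblies will show weaker and noisier
versions of these signals, and the choice of assembler and its
stringency measurably changes the response curve shape.

## Numerical and interface choices

* Sample order everywhere is the input order of the read files.
* ACE `AF` placement lines are authoritative for membership; `RD` blocks
  are a fallback.  A read listed twice in one contig counts once.
* ACE read identifiers are matched to inventory identifiers exactly
  first, then retried with one trailing `.<digits>` suffix stripped
  (454/consed fragment suffixes); anything still unmatched is a hard
  error, because a silent mismatch would corrupt every count.
* Denominators use assembled reads only, so $p_{\cdot i}$ is a genuine
  probability vector; singletons never enter any distance.
* All generator functions are bit-reproducible given `(seed, parameters)`.
* Experiment problem sizes (10–12 samples, 20–800 kb genomes, 700–2,000
  reads per sample) are chosen so each experiment completes in about one
  to two minutes; they are the package's study conditions, stated above.

## A worked example

```{r example, eval = FALSE}
pool <- make_genome_pool(5, c(20000, 20000), c(0.40, 0.50), seed = 1)
reads <- lapply(1:3, function(s) {
  sample_reads(community_spec(paste0("s", s), names(pool$genomes),
                              n_reads = 500),
               pool, seed = s)
})
asm <- toy_cross_assemble(reads)
inv <- readsets_inventory(reads)
profile <- build_profile(inv, asm$membership)
distance_matrix(profile, "wootters")
```

For real data, replace the generator calls with `read_sample_reads()` on
the per-sample FASTQ files and `parse_ace()` on the assembler's ACE file
— or run everything at once with `run_crossassembly()`, which also writes
the accounting table, all matrices, trees and plots to an output
directory.
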