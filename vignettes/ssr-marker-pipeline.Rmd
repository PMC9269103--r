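---
title: "Developing SSR markers for large repetitive genomes with ssrforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing SSR markers for large repetitive genomes with ssrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrforge)
```

## The problem

Microsatellites (SSRs) are the workhorse codominant marker for population
genetics of non-model plants, but in species with very large, highly
repetitive genomes the naive route — mine repeats, design primers — mostly
yields markers that sit inside transposable elements, amplify several loci
at once, or fail PCR. `ssrforge` implements the desk side of a marker
development campaign for exactly this situation: it reconstructs short
contig fragments from paired-end reads, mines perfect repeats, pushes
SSR-bearing contigs through a cascade of repetitiveness filters *before*
primer design, and then characterizes the genotyped survivors with the
standard codominant-locus statistics and an individual-level distance
analysis.

## Contig fragments from read pairs

For a standard FR library whose fragments are shorter than twice the read
length, the two mates overlap and the fragment can be reconstructed
without assembly. `merge_pair()` aligns the 3' end of read 1 against the
reverse-complemented read 2 and accepts the longest overlap of at least
`min_overlap` (default 30 nt) whose mismatch fraction does not exceed
`max_mismatch_rate` (default 0.1). Within the overlap the base with the
higher Phred quality wins; read 1 wins ties. Two safeguards keep merging
conservative: a pair with no admissible overlap, or with two distinct
admissible overlaps tying on length, is rejected rather than guessed at.
With the suffix-against-prefix overlap model the tie case cannot actually
arise — the guard documents the contract rather than a reachable branch.
Merged fragments are deduplicated (`dedupe_sequences()`), where a sequence
and its reverse complement count as the same molecule and the first
occurrence is kept.

Coverage annotation does not require an aligner at this scale.
`estimate_coverage()` assigns each read to every contig sharing at least
one exact 31-mer (either strand); mean coverage is assigned read bases
over contig length, and the multi-mapping fraction — the share of a
contig's reads that also hit another contig — is a cheap proxy for
repetitiveness. The defaults (k = 31, multi-mapping threshold 0.5) are
deliberately blunt: the filter only needs to separate clearly single-copy
contigs from clearly collapsed ones, and users with a real alignment can
substitute an external coverage table.

## Mining perfect repeats

`find_ssrs()` reports maximal perfect tandem repeats with unit sizes 2–6
nt, at minimum repeat numbers 8, 6, 5, 4 and 4 respectively — the common
MISA-style thresholds for genomic SSR surveys — and never reports
mononucleotide runs, which are unusable as markers. Three conventions
remove ambiguity:

* a run is reported under its smallest true unit (`ACACACAC` is an
  `(AC)4`-type run, never `(ACAC)2`), at its leftmost phase only;
* a trailing partial unit is excluded, so the repeat count is the number
  of complete units;
* runs containing `N` are skipped.

Because motifs that differ by rotation or by strand describe the same
tract, frequency reporting uses canonical classes: the label `"X/Y"` takes
`X` as the lexicographically smallest member of the rotation ∪
reverse-complement class and `Y` as the smallest rotation of `X`'s
reverse complement. Exhaustive enumeration over all primitive motifs shows
exactly 4 dinucleotide and 10 trinucleotide classes, which the test suite
asserts. One subtlety: under this definition the two halves of a label are
always rotation/reverse-complement equivalent, so a label pairing two
inequivalent motifs (occasionally seen in the literature, e.g. an
"AGT/ATC" class) cannot be produced; `AGT` canonicalizes to `"ACT/AGT"`
and `ATC` to `"ATC/ATG"`.

Neighboring SSRs separated by at most `max_interrupt` bases (default 100,
the conventional compound-SSR distance) merge into a single compound
locus, with chaining, via `mark_compound()`. Compound loci are retained
for reporting but are the first thing the filter discards: their complex
allele ladders make fragment-size genotyping unreliable.

## The filter cascade

`apply_filters()` evaluates seven criteria in a fixed order, and a failing
candidate records the *first* violated criterion, so attrition reports are
deterministic and independent of input order:

1. no compound repeats;
2. no repeat-element annotation (RepeatMasker `.out`) overlapping the SSR;
3. multi-mapping read fraction at most 0.5;
4. mean coverage within 0.5–2× the expected single-copy depth (default
   12.5×), contig length above 130 nt, and at least 30 nt of flank on each
   side of the SSR;
5. one or two BLAST occurrences in a draft genome — zero occurrences also
   fails, since a genuine single-copy contig must at least find itself;
6. di- or trinucleotide motif;
7. GC content within 0.43 ± 0.10.

Several knobs deserve comment. The coverage window [0.5×, 2×] is
symmetric on a log scale: contigs well above the expected depth are
collapsed repeats, those well below are likely chimeric or contaminant
fragments. The 30 nt flank floor is not part of the coverage/length
criterion conceptually but is folded into criterion 4 as a designability
extension — a primer cannot be placed on a 5 nt flank regardless of how
clean the contig is. The BLAST occurrence counter treats hits at ≥ 90 %
identity covering ≥ 80 % of the query as occurrences and collapses hits
to the same subject interval (≥ 50 % reciprocal overlap), so a split
alignment is not double-counted. Repeat length and GC proximity, the two
"preference" criteria, become the ranking key for survivors
(`rank_candidates()`: more repeats first, then GC closest to center, then
contig id), and the ranked list exports directly as Primer3 Boulder-IO
records (`write_boulder_io()`), one primer pair requested per locus.

The GC center deserves a note: it is exposed as a parameter
(`gc_center = 0.43` by default) because the appropriate center is the
genome's own GC content, which varies by species; users should set it to
their assembly's measured value.

## Marker statistics

`locus_stats()` computes, per locus, from a diploid genotype matrix:
allele counts and frequencies over typed gene copies; observed
heterozygosity; unbiased expected heterozygosity
$\hat H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$ (the biased form
is available by flag); the heterozygote-deficit inbreeding coefficient
$F_{IS} = 1 - H_O/H_E$ (undefined and reported `NA` for monomorphic
loci); Botstein's polymorphic information content
$PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$; and the probability
of identity $PI = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2$, with the
panel-level combined PI being the product over loci. The
heterozygote-deficit $F_{IS}$ form is used (rather than the Weir &
Cockerham variance-component estimator) because it is what diversity
tables of this kind conventionally print and what the bundled marker
panel's values follow.

Hardy–Weinberg deviation is tested with the exact probability test on
Levene's conditional distribution: given the observed allele counts, a
genotype table with $h$ heterozygotes has probability
$P = \frac{n!\, 2^h \prod_a c_a!}{\prod_g n_g!\,(2n)!}$, and the p-value
sums the probabilities of all tables no more probable than the observed
one. Tables are fully enumerated when feasible (two-allele loci always
are; for richer loci a cheap product-of-caps bound decides); otherwise a
Monte-Carlo sample is drawn by re-pairing the observed gene copies
uniformly at random, which samples exactly the Levene distribution, with
a fixed seed for reproducibility. The test suite checks the enumerated
p against an independent brute-force enumeration of all pairings, and the
Monte-Carlo p against enumeration within two Monte-Carlo standard errors.
Significance across a panel is assessed with the sequential Bonferroni
(Holm) step-down rule.

Null alleles — alleles that fail to amplify and inflate apparent
homozygosity — are estimated with two standard heterozygote-deficit
estimators, Chakraborty's $(H_E-H_O)/(H_E+H_O)$ and Brookfield's first
$(H_E-H_O)/(1+H_E)$, both floored at zero and both always reported,
since published panels rarely state which one they used and the two
bracket most published values.

The package bundles `tcin_marker_panel()`, the per-locus characterization
table of 17 genomic SSR markers developed for Dalmatian pyrethrum
(*Tanacetum cinerariifolium*, an outcrossing Asteraceae with a ~10 Gbp
highly repetitive genome) on 20 individuals of one natural population.
`summarize_panel()` on that table reproduces its published aggregates: 94
alleles, 5.53 per locus, mean $H_E$ 0.545, mean PIC 0.492, combined PI
1.9 × 10⁻¹¹, two highly (PIC > 0.70), eight moderately (PIC > 0.44) and
four weakly (PIC < 0.29) polymorphic loci. One caveat worth recording:
the arithmetic mean of the panel's printed $H_O$ column is 0.438, and
that column mean is what `summarize_panel()` reports.

## Distances and trees

The proportion-of-shared-alleles distance between two diploid individuals
is $D_{PSA} = 1 - \frac{\sum_l s_l}{2 L}$, where $s_l \in \{0,1,2\}$
counts allele matches at locus $l$ (each allele matched at most once
between the two unordered genotypes) and $L$ is the number of loci typed
in *both* individuals — pairwise-complete normalization, the convention
of the classic MICROSAT tool. Over 12 complete loci every distance is a
multiple of 1/24.

`neighbor_joining()` is the canonical Saitou–Nei agglomeration on the
Q-criterion, written in-package so that two reproducibility guarantees
can be made that generic implementations do not: ties in Q are broken by
the lexicographically smallest pair of node labels, making output
bit-identical across runs and platforms, and negative branch lengths are
clamped to zero for display with the raw lengths preserved in
`attr(tree, "raw_edge_length")`. On additive matrices the tree reproduces
all pairwise distances; the test suite cross-checks topologies against
`ape::nj` and against an exhaustive least-squares search over all
topologies (for 6 taxa), and verifies exact recovery of randomly
generated additive trees.

`bootstrap_tree()` resamples loci with replacement, recomputes
$D_{PSA}$ and the NJ tree per replicate, and annotates each internal edge
of the full-data tree with the percentage of replicates containing the
same bipartition; a majority-rule consensus is returned alongside,
since either tree may be the one a study displays. A replicate whose
locus draw leaves some pair of individuals with no co-typed locus is
dropped (the support denominator shrinks accordingly); with realistic
missingness this is vanishingly rare.

## The simulators, and what passing tests do and do not show

`simulate_contigs()` plants perfect repeats at known positions in i.i.d.
background sequence (optionally at a GC target) and adjusts the two
boundary bases so the planted tract cannot extend into the background —
the truth table is therefore exact, and the miner is required to recover
it at 100 % recall *and* precision. Background SSRs arising by chance are
not screened out; at the mining thresholds (a ≥ 16 nt perfect
dinucleotide run, etc.) their probability at the simulated contig sizes
is of order 10⁻⁶ per contig, and screening with the miner itself would
make the precision check circular.

`simulate_read_pairs()` draws fragments uniformly (contigs weighted by
length), reads the two ends in FR orientation, and applies i.i.d.
substitution errors with quality strings at the Phred value implied by
the error rate, constant per run — sufficient because the merger consumes
only relative qualities. `simulate_genotypes()` draws diploid calls under
Hardy–Weinberg proportions within each population from supplied
allele-frequency vectors; a null allele segregates as one hidden allele
per locus at the stated rate (null homozygotes become missing, null
heterozygotes appear homozygous), matching the model underlying the
implemented estimators.

Simulation scales are chosen to keep the full suite under half a minute
while leaving no estimate borderline: 20–40 contigs of 300–600 nt for
mining, 100 read pairs for merging, 200 diploids for parameter recovery
(He recovered within ±0.05 and mean $F_{IS}$ within ±0.05 of zero), 50
replicates for the null-allele study, and 200–1000 bootstrap replicates
on 30 individuals in three populations with disjoint allele pools, where
each population's bipartition reaches ≥ 95 % support.

These are deliberately idealized conditions. The generators emulate the
*shapes* of real data, not its pathologies: no stutter or allele-binning
error in genotypes, no indel sequencing errors, no transposon families
with internal structure, uniform fragment sampling. Passing tests
demonstrate the algorithms are implemented correctly, not that a real
campaign will achieve these rates — on real data the filter cascade
typically discards well over 90 % of mined loci, and of primer pairs
actually synthesized only a minority prove polymorphic and well-behaved.

## Numerical and degenerate-input conventions

* All coordinates are 1-based inclusive, matching RepeatMasker/BLAST
  output and Primer3 input.
* A genotype call is complete or missing; a half-missing call in an input
  table is coerced to missing with a warning.
* GC fraction excludes `N` from the denominator and is undefined (an
  error) on all-`N` sequence.
* Monomorphic loci: $H_E = 0$, $F_{IS}$ and the HWE p-value are `NA`,
  PIC = 0, PI = 1.
* Holm flags treat `NA` p-values as untestable: excluded from the family
  size, never rejected.
* Filter evaluation order is fixed 1→7; re-filtering a PASS set is a
  no-op.
* Identical individuals produce zero $D_{PSA}$ and zero-length NJ edges;
  equidistant (ultrametric-tie) matrices resolve deterministically via
  the label-pair tie-break.

## Limitations

Imperfect (interrupted) repeats are not mined; coverage is k-mer
approximate rather than alignment-based; the Weir & Cockerham $F$
estimators, linkage disequilibrium tests, and the Oosterhout null-allele
estimator are out of scope, as are population-level distances and
likelihood trees. RepeatMasker, BLAST and Primer3 are consumed/fed via
their standard file formats but never executed by the package.
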