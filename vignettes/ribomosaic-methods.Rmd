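---
title: "Methods: block-allele ribotyping of rDNA clone libraries"
author: "ribomosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-allele ribotyping of rDNA clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomosaic)
```

## The model

`ribomosaic` analyses intra-genomic ribosomal polymorphism in clone
libraries: several clones of a marker gene (typically a partial SSU
rDNA fragment of roughly 800 bp) are sequenced per specimen, and the
clones differ at a small number of fixed hypervariable loci located in
expansion segments.  The data model discretizes each clone to a tuple
of **block alleles** — at every variable locus the clone carries
exactly one member of a small set of discrete, internally homogeneous
block sequences, usually distinguishable by length alone.  The tuple is
the clone's **ribotype**.

Three quantities structure everything downstream.  The theoretical
ribotype space is $S = \prod_l a_l$ for $a_l$ alleles at locus $l$.
The tree-compatibility bound for a pair of loci is
$k_{\max} = a_i + a_j - 1$: on a single genealogy without recurrent
change at these loci, at most that many distinct allele pairs can
coexist (the multi-allelic generalisation of the four-gamete test), so
observing more is a heuristic recombination signal.  And because a
non-recombinant parental haplotype contributes one allele per locus,
$\max_l a_l$ lower-bounds the number of parental ribosomal gene
clusters (e.g. from hybridizing populations) needed to explain the
observations.

Two artifact processes are modelled explicitly.  PCR template switching
creates **chimeras**: mosaic amplicons whose alleles left of an
inter-locus breakpoint come from one template and right of it from
another, indistinguishable in kind from genuine recombinants but
expected to be minority products.  Uniform **SNP noise** from
polymerase and sequencing error perturbs blocks by single
substitutions.

## Pipeline stages and their parameters

**Locus detection** (`detectVariableLoci`).  Per alignment column,
variability is one minus the modal-symbol frequency over `A C G T -`.
Gaps count as a fifth symbol because length-variable blocks express
themselves as gap columns; `N` is excluded so base-calling ambiguity
cannot create variability.  Runs of at least `flankLen` (default 10)
columns at variability `<= 1 - flankConservation` (default 0.05) are
conserved anchors; each region strictly between two anchors containing
at least `minBlockCols` (default 4) columns at variability
`>= varThreshold` (default 0.15) becomes one locus.  We segment by
anchors rather than by literal runs of variable columns because alleles
of a genuine block coincide by chance at roughly a quarter of its
interior columns, which would fragment a run-based scan; inter-anchor
segmentation keeps the block whole.  Detection is purely
sequence-based; confirming that loci sit at stem–loop ends of the rRNA
secondary structure is out of scope.  Raising `varThreshold` can only
remove loci, never add them, which makes threshold sensitivity easy to
explore.

**Anchored extraction** (`anchorBlocks`) locates each flank in an
unaligned clone by minimum-Hamming search (no indels) with at most
`maxFlankMismatch` (default 1) substitutions, leftmost on ties; the
block is the substring strictly between the flanks.  Unlocatable or
misordered flanks leave the locus unassigned rather than guessing.  On
noise-free data this path provably returns the same blocks as aligned
extraction, which the tests check.

**Allele calling** (`callAlleles`).  Identical blocks are grouped; a
group below `minAlleleCount` (default 2) that lies within Hamming
distance `snpTolerance` (default 1) of an equal-length group at or
above the threshold is absorbed into the nearest such group (ties:
larger group, then lexicographically smaller sequence).  The rationale:
block variants behave as homogeneous sequences and SNPs are a separate
phenomenon, so a singleton one substitution from a common allele is
most parsimoniously an error.  Length differences are never absorbed —
block alleles are primarily length variants, and a length difference
cannot arise from substitution error.  Labels `a, b, c, ...` follow
descending abundance with a lexicographic tie-break, making calling
deterministic; published label orders can be restored with
`relabelAlleles`.  Note the absorption threshold is deliberately
minimal: two clones that independently acquire the same substitution at
the same site form a legitimate doubleton allele (at typical error
rates and library sizes this birthday collision occurs in a sizeable
minority of libraries, and the simulator reproduces it).

**Assignment and tabulation**.  Assignment mirrors calling (exact
match, else nearest equal-length allele within tolerance, else
unassigned).  Clones with any unassigned locus are excluded from the
ribotype table but reported (`incompleteClones`); the observed-clone
table covers the *entire* combination space with explicit zero rows,
ordered by descending abundance with a lexicographic tie-break so that
output is reproducible where abundances tie.

**Statistics** (`esp_stats`).  The clones-vs-ribotypes Spearman
correlation uses average ranks and a one-sided permutation test
(positive association: the mechanistic prediction is undersampling).
All $n!$ permutations are enumerated when $n \le 8$; otherwise Monte
Carlo with an explicit seed and the add-one estimator
$(1+\#)/(1+B)$; the asymptotic $t$ approximation is reported for
reference, since no distributional assumption is safe at $n = 25$.
Allele prevalence is reported two ways on purpose: a pooled chi-square
against uniformity (df $= k-1$), and a specimen-level cluster bootstrap
(resample specimens with replacement; recompute the max-minus-min
allele frequency difference $D$; p is the fraction of null-shifted
replicates $D^\ast - D_{obs} \ge D_{obs}$).  Pooling treats clones as
independent although clones within a specimen sample the same genome,
so the pooled test is anticonservative for clustered data — for pooled
counts such as 24/13/33 over 70 clones it rejects uniformity
($\chi^2 = 8.6$, df 2) even though the imbalance may not survive
clustering.  Both are printed; the cluster bootstrap is the defensible
one.  Rarefaction of ribotype richness is the analytic hypergeometric
expectation (delegated to `vegan::rarefy`) at every depth, with a
clone-resampling bootstrap band; the curve is monotone and concave by
construction, and the tests verify it against exhaustive subset
enumeration at small $n$.

**Recombination screens**.  `flagPutativeChimeras` enumerates, for
every observed ribotype, all (parent1, parent2, breakpoint)
explanations with both parents observed at `minParentRatio` (default 3)
times its abundance — chimeras are minority products, and 3 is
deliberately permissive since the output is a screen, not a verdict.
Breakpoints live only *between* loci: the tuple representation cannot
resolve intra-block mosaics, which are indistinguishable from new
alleles.  `pairwiseCompatibility` and `minParents` implement the bounds
above; both are labelled heuristics in the output, since recurrent
mutation can mimic recombination signal and no likelihood model is
fitted.

## The simulator, and what passing tests do and do not show

`generateLibrary` emulates the survey design the pipeline assumes: 25
specimens with 1–7 clones each (uniform), an 800 bp uniform-random
conserved backbone, three embedded block loci with allele-length sets
{6, 8, 10}, {32, 34} and {11, 14} bp at positions 200/400/600, SNP rate
0.002 per site and chimera rate 0.05 per clone by default.  Default
ribotype weights put all mass on three parental clusters (`a|a|a` 0.45,
`b|b|b` 0.35, `c|a|b` 0.20) that jointly carry every allele — the
hybridization scenario under study, in which minority mosaics arise
through the chimera process; `dirichletRibotypeWeights` provides a
random spread over the whole space for users who want many genuine
ribotypes instead.  Fixed (rather than drawn) default weights make
every allele observable at essentially any seed and library size, as in
the surveys being emulated.

Design choices worth knowing: allele sequences are random but
length-distinct; if all alleles at a locus happen to share their first
base, one is rotated so both block boundaries stay polymorphic and
planted spans remain identifiable.  SNPs never land in the 2 bp of
backbone adjacent to a block, so flank anchoring can be tested
independently of its mismatch tolerance (configurable off by editing
the mask).  Chimera breakpoints are restricted to inter-locus
boundaries, matching the resolution of the downstream screens.  A
chimera whose realized tuple equals one of its parents is recorded but
marked undetectable (`detectable_chimera = FALSE`): no tuple-level
method can see it, so sensitivity is measured over detectable mosaics
only.  A single RNG stream ordered (specimen, clone, site) makes
identical seeds give byte-identical FASTA and truth tables.

What the simulator does *not* model: indel evolution outside the
blocks, alignment error (its "aligned" output is the true alignment),
non-uniform PCR error profiles, chromatogram quality, intra-block
chimera breakpoints, and copy-number structure of the rDNA arrays.
Passing the recovery tests therefore shows the pipeline is correct
*given* a clean alignment and the block-allele model; it does not show
robustness to alignment artifacts or to polymorphism that violates the
discrete-block assumption.

## Numerical and coordinate conventions

All alignment spans are IRanges-style 1-based closed intervals, the
Bioconductor convention, and the TSV interfaces write 1-based inclusive
`start`/`end`; chimera breakpoints are reported as "after locus $b$".
Permutation p-values use a $10^{-12}$ slack when comparing correlations
to avoid floating-point ties.  Degenerate inputs fail loudly and
early: constant rank vectors, all-unassigned loci, empty libraries and
out-of-range spans are errors, while an empty detection result, a
monomorphic prevalence locus and an unexplainable rare ribotype are
ordinary (empty or annotated) results.

## Problem sizes used in validation

The validation suite runs the full pipeline on single simulated
libraries (~70–175 clones) for exactness checks, 200 replicate
libraries for the noisy recovery and chimera-sensitivity measurements,
and 200 replicates of a 70-clone, 30%-crossover positive control for
recombination-signal power; exhaustive oracles (all 720 permutations at
$n = 6$, all subsets at $n \le 8$, brute-force chimera enumeration) pin
the statistics.  These sizes keep a full run in the tens of seconds on
one CPU while leaving the Monte Carlo standard errors far from the
asserted margins.

## Known limitations

The compatibility statistic is a screen, not a test with a null
distribution; the chimera flagger cannot see a chimera that lands on an
abundant genuine ribotype (its sensitivity is defined over detectable
mosaics); absorption cannot distinguish a genuine rare allele one
substitution from a common one from recurrent error (it errs on the
side of parsimony); and ribotype richness estimates inherit all the
usual caveats of rarefaction under non-independent sampling of rDNA
copies within specimens.
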