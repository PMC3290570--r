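# ribomosaic

Intra-genomic ribosomal polymorphism analysis for clone libraries of
marker genes.

Some organisms — benthic foraminifera are the motivating case — carry
multiple divergent copies of their rDNA within a single genome.  In
SSU rDNA clone libraries this shows up not as scattered SNPs but as
**expansion segment polymorphism (ESP)**: at a few fixed hypervariable
loci inside expansion segments, each clone carries one of a small set of
discrete, internally homogeneous sequence blocks ("block alleles"),
often of different lengths.  The combination of alleles a clone carries
across all loci is its **ribotype**.  Several ribotypes can co-occur in
one specimen, and their mosaic distribution across loci is the signature
of recombination between two or more parental ribosomal gene clusters —
for example after hybridization — overlaid with PCR chimera artifacts.

`ribomosaic` turns that analysis into a tested pipeline for anyone
working with clone libraries of a marker gene:

* **Locus detection** — find hypervariable block loci in a gapped MSA
  from per-column variability (gaps count as a symbol, `N` does not),
  with conserved flanking anchors; or extract declared loci from
  unaligned clones by fuzzy flank matching.
* **Allele calling and ribotyping** — collapse blocks into discrete
  alleles (near-miss singletons are absorbed as sequencing/PCR error;
  length variants are never merged) and assign each clone an allele
  tuple.
* **Quantification** — the theoretical combination space
  `S = prod_l a_l` (with `a_l` alleles at locus `l`; 3 x 2 x 2 = 12),
  observed abundances over all of it, per-specimen richness,
  chi-square and cluster-bootstrap allele prevalence tests, Spearman
  correlation between clones sequenced and ribotypes found (exact or
  Monte Carlo permutation p), and hypergeometric rarefaction of ribotype
  richness.
* **Recombination screens** — flag ribotypes explainable as PCR
  chimeras of two more-abundant parents; test locus pairs against the
  tree-compatibility bound `k_max = a_i + a_j - 1` (the multi-allelic
  four-gamete bound); lower-bound the number of parental haplotypes by
  `max_l a_l`.
* **Simulation** — a truth-tracked generator of clone libraries
  (parental ribotype clusters, SNP noise, PCR template-switch chimeras)
  that validates every stage.

## Worked example

Simulate a survey-style library (25 specimens, 1–7 clones each, ~800 bp
fragments, three block loci, SNP and chimera noise) and analyse it:

```r
library(ribomosaic)

cfg    <- espSimulationConfig(seed = 4)
sim    <- generateLibrary(cfg)
report <- runPipeline(sim$aligned, seed = 4)
report
```

```
ESP pipeline report
CloneLibrary: 96 clone(s) from 25 specimen(s), aligned (858 columns)
LocusSet: 3 variable block locus/loci
  label start end left_flank right_flank
1    L1   201 210 GATTGAGGTC  GTAGCATTCT
2    L2   411 444 GCACTGGTCC  AAGTACTGGA
3    L3   645 658 TCCCTCCCAA  ATGGGTTAAT
RibotypeTable: 7 of 16 possible ribotype(s) observed (96 clone(s))
   L1 L2 L3 abundance
1   a  b  a        44
2   b  a  b        31
3   c  a  a        16
4   d  b  a         2
...
minimum parental haplotypes: 4
Spearman rho = 0.801 (n = 25)
one-sided p = 9.999e-05 [monte_carlo, 10000 permutations]; asymptotic p = 7.643e-07
chimera explanations: 4; locus pairs with recombination signal: 2/3
```

Reading the output: detection recovered the three planted loci (spans
`201–210`, `411–444`, `645–658`) with their conserved flanks.  The three
parental ribotypes dominate (44, 31, 16 of 96 clones).  The `d` allele
at L1 is instructive — two independent clones hit the same SNP at the
same site, producing an identical doubleton block that legitimately
stands as an allele (singletons would have been absorbed); it inflates
the theoretical space to 16 and the parental lower bound to 4.  Rare
mosaics such as `a|a|b` (abundance 1) are flagged as putative chimeras
of the two top ribotypes:

```r
head(report$chimeraCalls, 2)
```

```
  ribotype parent1 parent2 breakpoint abundance parent1_abundance parent2_abundance abundance_ratio
1    a|a|b   a|b|a   b|a|b          1         1                44                31              31
2    a|b|b   a|b|a   b|a|b          2         1                44                31              31
```

The strong clone-vs-ribotype correlation (rho = 0.80) says richness is
still undersampled at this depth — exactly what `ribotypeSaturation()`
shows as a still-rising rarefaction curve.  With noise switched off
(`snpRate = 0, chimeraRate = 0`) the pipeline recovers every clone's
true ribotype, the exact allele catalogs and the 12-combination space.

All tables can be written to disk (`runPipeline(..., outDir = "out")`)
as TSV plus a JSON report carrying parameters and the seed.

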