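# olfactoR

Fine-scale evolutionary analysis of a single olfactory receptor (OR) gene
family from amplicon sequencing.

OR genes encode the 7-transmembrane receptors of vertebrate olfaction and
evolve by birth and death: duplication, diversification, pseudogenization,
loss. A common design for studying one OR family amplifies a TM2–TM7
fragment (~645 bp) across related species, clones and sequences the
products, and then has to answer, from sequence alone: which amplicons are
functional genes and which are pseudogenes; how many unique genes the
read pool represents once sequencing variants and alleles are merged;
where amino-acid variability sits on the receptor (especially the
odorant-binding pocket spanning TM3–TM6); which well-supported clades the
gene tree contains and what selection acts on them; and whether pseudogene
proportions differ between ecological groups of species. `olfactoR`
implements that entire workflow, developed around the African mole-rat
(Bathyergidae) OR7 family design with 14 species in six genera.

## The methods in brief

* **Functional classification** — a sequence is a pseudogene if it has a
  premature stop codon or a frameshift indel relative to a functional
  reference row; in-frame length variants stay functional only if the
  MAYDRFVAIC (TM3) and KAFSTCASH (TM6) motifs are present within a
  mismatch budget and no indel hits a binding position.
* **Allele merging** — reads within 2 bp collapse as sequencing variants;
  unique sequences cluster into genes at ≥99% identity within species,
  ≥98% within genera, ≥96% across genera (single linkage), with tree-based
  resolution of status mixtures, non-transitive components and duplicate
  copies; genes are reported as majority-rule consensus sequences.
* **Variability mapping** — per-column distinct-residue counts over
  functional genes, binned 1 / 2 / 3–4 / ≥5; binding-pocket polymorphism
  (count ≥2) over the 26 binding positions and the TM3–TM6 core;
  hydrophobic composition; cross-clade conserved versus clade-specific
  binding motifs.
* **Selection statistics** — Nei–Gojobori counting with uniform averaging
  over minimal mutational pathways (stop pathways excluded) and
  Jukes–Cantor correction; a codon-based Z test (dS − dN, bootstrap over
  codon columns) for purifying or positive selection; a per-codon
  counting scan; the ZZ linkage-disequilibrium statistic (Za − ZnS) as a
  recombination check; Benjamini–Hochberg and Storey q-value corrections.
* **Phylogeny** — TN93 distances (pairwise deletion), neighbor joining
  with bootstrap support, outgroup or midpoint rooting, extraction of
  maximal clades at ≥97% support, per-clade functional composition, and
  CodeML-style `#1` foreground labelling of terminal branches by species
  trait.
* **Ecogroups** — per-species pseudogene percentages, group means ± SE,
  pairwise Wilcoxon rank-sum tests (exact for small tie-free groups) with
  BH adjustment.
* **Simulator** — a birth-and-death repertoire generator with full truth
  tables (gene identity, functional status, planted lesions, clade, per-
  codon ω), plus a codon-alignment generator for calibrating the
  statistics and an ecogroup-table generator.

## Worked example

Simulate a repertoire under the default study conditions and run the full
pipeline:

```r
library(olfactoR)

sim <- simulate_repertoire(simulation_config(seed = 1))
sim
#> <or_simulation> 603 reads, 76 true genes (37% pseudogene reads), seed 1

res <- run_pipeline(pipeline_config(
  input = sim$alignment, outdir = "run1",
  n_boot = 200, z_boot = 1000, outgroups = sim$outgroups, seed = 2))
res
#> <pipeline_result> 603 reads -> 144 unique -> 78 genes (47 functional); 4 clades
```

603 cloned reads collapse to 144 unique sequences, which merge into 78
genes (47 putatively functional, 31 pseudogenes — close to the 76 loci
the generator actually planted). The gene tree contains exactly the four
simulated founder clades, all at full bootstrap support:

```r
res$clades
#> <clade_assignment> 141 leaves: A=55 (100%), B=28 (100%), C=36 (100%), D=22 (100%)
res$clade_summary
#>   clade n_functional n_pseudogene n_total percent_functional percent_pseudogene
#> 1     A           19           10      29           65.51724           34.48276
#> 2     B           13            3      16           81.25000           18.75000
#> 3     C           11            8      19           57.89474           42.10526
#> 4     D            4           10      14           28.57143           71.42857
```

Selection and recombination summaries on the same run:

```r
res$zz
#> ZnS = 0.0388, Za = 0.0230, ZZ = -0.0157 (132 segregating sites)
do.call(rbind, res$ztests)
#>   clade n_genes        Z            p
#> A     A      19 6.281983 1.671403e-10
#> B     B      13 7.559654 2.020716e-14
#> C     C      11 6.226191 2.389559e-10
#> D     D       4 4.096513 2.097096e-05
```

ZZ near zero means linkage disequilibrium shows no decay with distance —
no recombination signal, so variability reflects substitution and
duplication, not PCR chimeras. Every clade's functional genes show highly
significant purifying selection (dS > dN), as expected under the
generator's predominantly purifying ω classes. The binding pocket behaves
like a real OR family: 23 of the 26 binding positions are variable, 87%
of the TM3–TM6 binding sites are polymorphic, and 89% of binding-site
residue observations are hydrophobic.

Every stage is also callable on its own (`classify_alignment()`,
`dedupe_identical()`, `merge_alleles()`, `site_variability()`,
`codon_z_test()`, `zz_statistic()`, `bootstrap_support()`,
`extract_clades()`, `pairwise_wilcoxon()`, ...), reading and writing plain
FASTA/TSV/newick/JSON.

## Methods documentation

The full account of the models, conventions, default parameters and their
rationale, the simulator's scope, and known limitations is in the methods
vignette: `vignettes/or7-repertoire-methods.Rmd`.
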