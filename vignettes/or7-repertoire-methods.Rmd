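---
title: "Methods: fine-scale analysis of an olfactory receptor gene repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale analysis of an olfactory receptor gene repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfactoR)
```

## The analysis problem

Olfactory receptors (ORs) are seven-transmembrane (7TM) G-protein-coupled
receptors encoded by the largest gene family in vertebrate genomes. The
family evolves by birth and death: genes duplicate, diversify under
selection, decay into pseudogenes, or are lost. A common experimental
design for studying a single OR family amplifies a fragment spanning TM2
through TM7 (about 645 bp) from many individuals across related species,
clones and sequences the amplicons, and then asks:

1. Which amplicons encode putatively functional receptors and which are
   pseudogenes?
2. How do sequencing reads, alleles and genes relate — how many *unique
   genes* does the amplicon pool represent?
3. Where is amino-acid variability concentrated on the receptor, and in
   particular how variable are the residues lining the odorant-binding
   pocket (TM3–TM6)?
4. Which well-supported clades exist in the gene tree, and what selective
   regimes (purifying, neutral, positive) act on them?
5. Do pseudogene proportions differ between ecological groups of species?

`olfactoR` implements this workflow end to end for within-family OR
amplicon studies, together with a ground-truthed simulator so every stage
can be validated without any external data. The packaged species table and
14-taxon tree mirror an African mole-rat (Bathyergidae) study design —
two *Bathyergus*, three *Cryptomys*, six *Fukomys*, and *Georychus*,
*Heliophobius* and *Heterocephalus* — but every input (species metadata,
receptor topology, thresholds) is data, not code.

## Functional classification

A sequence is called a **pseudogene** when it carries an ORF disruption:

* a premature stop codon (TAA/TAG/TGA) in the reading frame anchored by a
  designated functional reference row — by default the longest gap-free
  sequence in the run whose own translation is stop-free; the terminal
  codon is never counted;
* an insertion or deletion run, relative to that reference, whose length
  is not a multiple of three (a frameshift).

Length variants — sequences whose only indels are in-frame — remain
functional only if both diagnostic receptor motifs (MAYDRFVAIC at the end
of TM3 and KAFSTCASH at the start of TM6) are found within a configurable
mismatch budget and none of the indels falls on a ligand-binding position.
The motif budget defaults to 2 mismatches per motif: receptor motifs are
polymorphic in functional genes, so requiring exact matches would
misclassify them, while decayed pseudogene motifs typically exceed two
differences. Whether both motifs or either one is required is a config
switch (`require_all_motifs`, default both). Codons containing ambiguity
codes are flagged rather than classified, and do not by themselves make a
sequence a pseudogene.

These rules are deliberately one-sided: disruptions outside the amplified
fragment or in regulatory sequence are invisible, so pseudogene counts
from amplicon data are lower bounds. Nothing in the package attempts to
model the unamplified regions.

## From reads to genes

Merging proceeds in two stages.

**Collapse of sequencing variants.** Reads within 2 differing sites of
each other (transitive closure) are treated as one molecule; the
differences are attributed to PCR or sequencing error. A base-versus-gap
column counts as a difference here, so 1–2 bp indel artifacts also
collapse. The surviving representative is the lexicographically first id,
which makes the whole pipeline reproducible under input reordering.

**Hierarchical identity clustering.** Identity is nucleotide identity
over pairwise-deleted columns (gaps and N excluded — the convention of
the standard distance software this mirrors; whether gaps count as
differences is not observable at these thresholds anyway, and the choice
is documented here). Two unique sequences are provisionally alleles of
the same gene when their identity reaches the threshold for their
taxonomic relation: 99% within a species, 98% between congeneric species,
96% across genera. Clusters are connected components (single linkage),
which is what makes non-transitivity (A=B, B=C, A≠C) possible in the
first place. Three resolution rules then produce the final genes:

* clusters mixing functional and pseudogene members are split by status
  (interpreted as a duplication followed by pseudogenization);
* components in which some pair fails its threshold are re-partitioned
  against the bootstrap NJ tree: members merge only when they form a
  tree-contiguous group (a subtree containing no non-member leaf) in
  which every pair satisfies its threshold; fully transitive clusters are
  never re-partitioned;
* when one individual contributes more than two members to a gene, two
  gene copies must be present; the gene is split along the deepest split
  of its members' subtree, recursively if needed.

Each final gene is summarised by a per-column majority-rule consensus
(gap treated as a residue; ties broken alphabetically, so the consensus
is deterministic).

## Receptor topology and variability mapping

The 7TM topology — domain boundaries and the ligand-binding alignment
positions — is a configuration input, because binding-site coordinates
come from an external receptor model, not from the data. The packaged
fixture (`topology_synthetic.tsv/.json`, labelled synthetic) defines a
215-residue TM2–TM7 amplicon with 26 binding positions of which 23 lie in
TM3–TM6, mirroring the layout of published odorant-binding-site models.

Per-column variability is the number of distinct residues among
functional genes (gaps and X excluded), binned as highly conserved (1),
conserved (2), variable (3–4) and highly variable (≥5). Two conventions
coexist deliberately: the category plot uses those bins, while the
binding-pocket statistic counts a position as polymorphic at ≥2 distinct
residues, because any variation at a binding residue is functionally
relevant. The TM3–TM6 fraction excludes the binding residues in TM2 and
TM7. The hydrophobic fraction is computed over residue *observations*
(every row × binding column), with the standard hydropathy set
{A,V,L,I,M,F,W,C,Y} as a configurable default, since "hydrophobic" has no
single canonical definition. Cross-clade motif comparison asks, for each
TM3–TM6 binding position, whether one residue is fixed in every clade;
all other positions carry clade-specific motifs.

## Counting-based selection statistics

The package authors its own counting machinery rather than wrapping a
distance library, because these statistics are the analysis core:

* **Per-codon site counts** follow the classic convention: at each codon
  position the synonymous fraction is synonymous changes over non-stop
  changes, so sites still sum to 3 per codon. Disregarding mutations to
  stops matters: counting them as nonsynonymous deflates dN and makes a
  neutral alignment look purifying (we measured type-I error of 0.20
  instead of 0.03 at ω = 1 with the naive variant).
* **Pairwise differences** average synonymous/nonsynonymous steps over
  all minimal mutational pathways between codons, with uniform pathway
  weights and pathways through stop codons excluded (restored only if
  every pathway is blocked). Gap- or N-containing codons drop pairwise.
  Proportions are Jukes–Cantor corrected; p ≥ 3/4 yields NaN and a
  saturation flag.
* The **codon Z test** uses the mean over sequence pairs of dS − dN
  (purifying alternative; dN − dS for positive selection), with the
  standard error obtained by bootstrap over codon columns (the resampling
  unit that respects within-codon dependence), Z = mean/SE and a
  one-tailed normal p-value. The seed is a required argument. Identical
  sequences give zero bootstrap variance and p = 1 with a warning.
* The **per-codon scan** pools path-averaged differences over all pairs
  per codon column and classes codons by comparing the synonymous and
  nonsynonymous proportions per site. It is a descriptive counting
  stand-in for likelihood site models, documented as such; the q-value
  machinery accepts externally computed likelihood-ratio p-values so that
  branch-site results can be post-processed identically.
* **ZZ** quantifies intragenic recombination: r² over all pairs of
  retained segregating sites (biallelic, gap- and N-free), ZnS the mean
  over all pairs, Za the mean over adjacent retained sites, ZZ = Za −
  ZnS. Values near zero mean no distance decay of LD, i.e. no
  recombination signal (and no PCR-recombination artifact).
* **Multiple testing**: Benjamini–Hochberg step-up adjustment, and Storey
  q-values with π0 estimated by the mean over a λ grid (0.05–0.90 step
  0.05) of #{p>λ}/(m(1−λ)) — the mean-of-estimates smoother, simpler than
  the spline and adequate at these m; π0 = 1 reduces exactly to BH.

## Trees, clades and trait labels

Distances are Tamura–Nei (TN93) with empirical base frequencies and
pairwise deletion; saturated pairs are flagged as NaN. Trees are built by
neighbor joining with negative branch-length artifacts clamped to zero
and the deficit shifted to the sibling branch. This distance approach is
a deliberate stand-in for a full maximum-likelihood search: clade
*membership* of borderline leaves may differ from an ML tree, so all
clade-dependent conclusions are tied to bootstrap support rather than to
exact leaf lists. Support is the percentage of column-resampled replicate
trees containing each bipartition; supports are attached to the reference
tree *after* rooting (outgroup rooting when outgroup tips are present,
midpoint otherwise with a warning), because re-rooting a node-labelled
tree scrambles the label-to-node mapping.

Clades are the maximal non-nested supported subtrees: support ≥ 97% (the
configurable default), at least 2 leaves, no outgroup tips, and a proper
subset of the ingroup (otherwise the rooting split itself would count as
a clade). Labels A, B, C… follow tree order; unplaced leaves are
UNASSIGNED. Per-clade functional composition and a codon Z test for
purifying selection on each clade's functional genes summarise the
selective regimes. For branch-site analyses in external codon-model
software, terminal branches can be labelled by a species trait
(sociality), producing the `#1` foreground newick dialect in both
polarities.

## Ecogroup comparison

Per-species pseudogene percentages are aggregated into ecogroup means
with SE = sd/√k over the k species of a group (NA for singleton groups).
Every ecogroup pair is compared by a Wilcoxon rank-sum test — exact when
both groups have fewer than 50 observations and no ties, otherwise the
normal approximation with tie and continuity correction, mirroring
standard statistical-package semantics so published tables computed that
way are matchable — with BH adjustment across all pairs. Both raw and
adjusted matrices are reported, because published tables are not always
explicit about which is shown. An external cross-mammal count table with
schema `species ecogroup n_functional n_pseudogene` can be supplied to
place a new clade in the mammal-wide context; it is a documented optional
input and is never bundled.

## The synthetic-data generator

`simulate_repertoire()` emulates the statistical structure the analysis
assumes: four deeply diverged founder gene lineages (the clade structure)
evolve along the fixed 14-taxon species tree by duplication (Poisson,
0.05 per gene per unit branch), pseudogenization (probability 0.15 per
unit branch; a planted premature stop with probability 0.6, otherwise a
1–2 base deletion), and codon substitution by rejection sampling in which
the relative nonsynonymous:synonymous acceptance rate equals the codon's
ω class (defaults: ω = 0.1 for 60% of codons, 0.5 for 30%, 2 for 10%;
motif codons pinned at ω = 0). At each tip, two individuals are sampled
with two alleles per gene copy (0–2 private substitutions each), two
clones per allele, and up to one PCR error base per read. Three related,
deeply divergent GPCR-like outgroup sequences are emitted for rooting,
mirroring the use of non-OR GPCRs as outgroups in OR studies. Deletions
stand in for all pseudogenizing indels so that the emitted FASTA stays in
one coordinate system.

The default rates were chosen from the identity-threshold geometry, not
fitted: within-species reads of one gene differ by at most ~6 bp (≥99.07%
identity, above the 99% species threshold), while orthologous copies in
different species and duplicate copies within a species diverge beyond
their merge thresholds (≥2% within genera, ≥4% between). The observable
gene entities of the truth table are therefore species-local loci. This
is one deliberate regime of the paper-style design space: it does *not*
emulate alleles shared identically across species (ancient trans-species
polymorphism), nor transition/transversion bias (proposals are uniform,
matching the unweighted pathway assumption of the counting statistics),
nor insertion-type frameshifts, nor chimeric PCR recombinants. Passing
tests on this generator therefore demonstrate correctness of the
machinery under the stated model, not robustness to every artifact of
real amplicon data.

`simulate_codon_alignment()` is the light-weight star-phylogeny variant
used to calibrate the counting statistics, and `make_ecogroup_fixture()`
draws per-species pseudogene proportions around group truths (Gaussian
noise, optional binomial count realization; with zero noise and
deterministic counts the group means equal the truths exactly).

## Validation and problem sizes

The test-suite calibration runs use 20 sequences × 200 codons with 15–20
replicates for dN/dS recovery (mean estimate within ±0.15 of the planted
ω at 0.1 and 1.0), 100 replicates with 200 bootstrap resamples for the
Z-test operating characteristics (power 1.0 at ω = 0.1; type-I error
0.03–0.05 at ω = 1), bootstrap trees with 100–200 replicates, and full
pipeline runs of ~450–600 reads. These sizes are the package's chosen
validation scale; all stages accept larger inputs. Against the simulator
truth, the default study conditions give classification agreement ≥ 0.95
(the gap being PCR-error artifacts, which the collapse stage is designed
to absorb), allele-clustering adjusted Rand index ≥ 0.9, and exact
recovery of the four planted clades at ≥97% bootstrap support.

## Numerical and degenerate-input conventions

Ties in consensus calling and representative choice are broken
lexicographically. Empty clusters, empty binding sets, alignments with
fewer than two usable segregating sites, unrooted trees passed to clade
extraction, and ids missing from metadata or tree all raise immediate,
named errors rather than propagating NA. Saturated distance pairs are
flagged; bootstrap replicates that saturate fall back to the raw
p-distance for that replicate. All stochastic entry points require an
explicit seed, and rerunning any pipeline configuration reproduces every
output checksum.

## Known limitations

* The per-codon selection scan is counting-based; it has no power model
  and is not a substitute for likelihood site or branch-site tests.
* NJ/TN93 is a stand-in for ML tree search; only support-qualified clade
  statements should be trusted.
* Pseudogene calls are lower bounds (amplicon-limited).
* The identity-threshold rules inherit the published cut-offs; in data
  where allele and paralog divergence overlap these thresholds, gene
  counts are threshold-dependent by construction.
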