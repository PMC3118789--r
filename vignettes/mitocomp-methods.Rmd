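---
title: "Methods: comparative analysis of ciliate mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of ciliate mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope and data model

`mitocomp` analyses small, linear, densely gene-packed mitochondrial genomes of
the kind found in ciliates (40–47 kb, ~50 genes, no introns, very short
intergenic spacers) and compares them between species. The pipeline covers:
composition by region class and codon position, codon-usage bias (relative
synonymous codon frequencies, rare codons, Wright's effective number of
codons), Nei–Gojobori Ka/Ks with a gene-class contrast, neighbor-joining trees
with bootstrap support and placement of a GC3 compositional shift, and
detection of intragenic minisatellites.

Internally all coordinates are 0-based half-open; the GenBank reader/writer
converts from the flat file's 1-based inclusive convention at the boundary.
This keeps interval arithmetic (merging, gap-finding, tiling checks) free of
off-by-one cases. Only the LOCUS/FEATURES/ORIGIN blocks of a GenBank file are
required, with `join`/`complement` locations resolved; of the qualifiers only
`/gene` and `/product` are used. Ambiguity characters other than `N` are
rejected on read; `N` is tolerated but excluded from composition denominators
and codon tallies.

Every feature carries a `gene_class`: `known` (annotated gene of known
function), `orf` (unknown reading frame; ymf-style names), `rna` (rRNA/tRNA),
or `noncoding`. The class drives the gene-class contrast of the divergence
stage and the region classes of the composition stage.

## Genetic code

The default translation table is NCBI code 4 (mold/protozoan mitochondrial:
TGA = Trp; stops TAA/TAG), the code of ciliate mitochondria; the code id is a
parameter everywhere and never hard-coded in a computation. All degeneracy
structure is derived from the code at run time. Under code 4 the Trp family is
{TGA, TGG}, so the code has 62 sense codons in families of sizes 1 (Met),
2 (×10, including Trp), 3 (Ile), 4 (×5) and 6 (×3).

## Open reading frames and coding density

The ORF scanner works on all six frames. The default mode is `stop_to_stop`: a
call is a maximal run of stop-free codons, with no start-codon requirement,
because ciliate mitochondrial start codons are nonstandard and unreliable to
model. A `start_required` mode (configurable start set `ATG, ATA, ATT, TTG,
GTG`) is provided for sensitivity analysis. The default length threshold is 60
aa, reading the conventional "longer than 60 aa" filter inclusively; the
strict reading is one configuration flip. Codons containing `N` break runs
conservatively.

Intergenic spacers are the maximal gaps between annotated gene intervals after
merging overlaps (a spacer is non-genic DNA); gaps flanking the first and last
gene of the linear molecule are included, so merged genes plus spacers tile
the genome exactly — a conservation property the tests assert. Coding density
is reported both for all annotated genes (including RNA genes) and for the
protein-coding subset.

## Composition

Base composition excludes `N` from denominators and errors on all-`N` input.
Positional G+C (GC1/GC2/GC3) is pooled over the codons of a gene set;
stop codons are excluded by default, the usual convention for GC3 over sense
codons, with a flag to include them. Report-level rounding is one decimal
place, half away from zero, as in comparative composition tables; raw doubles
are kept internally and used in all computations.

## Codon usage and the effective number of codons

Within each amino-acid family of the active code (stop codons forming their
own family), the relative frequency of a codon is its count over the family
total; families with zero total are flagged undefined rather than zeroed.

A codon is *rare* when its within-family relative frequency falls below a
threshold, stop codons included. The default threshold is 0.085 on the
unrounded frequency — i.e. everything that prints as ≤ 0.08 at two decimals.
This is a calibrated stand-in for the rare-codon convention of the comparative
literature (the original counting rule is not restated in the sources this
package follows); it is exposed as a configuration value, and the bundled
three-species reference columns reproduce the published counts 28/23/5 under
it exactly.

Wright's effective number of codons summarises usage bias on an absolute
scale: per family the codon homozygosity is estimated as
F = (n·Σp² − 1)/(n − 1), and Nc sums N_k / mean(F_k) over the degeneracy
classes k of the code's census, with single-codon families added directly.
Under code 4 the census is N1=1, N2=10, N3=1, N4=5, N6=3, so Nc runs from 20
(one codon per amino acid) to 62 (uniform synonymous usage) rather than the
standard-code 61. Families with n ≤ 1 or F ≤ 0 fall back to their class mean;
a fully absent 3-fold class borrows the mean of the 2- and 4-fold classes
(Wright's interpolation), and any other absent class rescales the total by the
class's census share, with a warning — short genes thus yield a flagged value
rather than an error. The final value is capped at the sense-codon count, the
convention of the classical implementations, so the uniform extreme attains
the maximum exactly. For published frequency columns the large-n limit
F = Σp² is used, with frequencies renormalised within each family to absorb
table rounding.

## Divergence: identity, NG86 Ka/Ks, gene-class contrast

Protein identity is identical columns over columns with residues in both
sequences (gap columns excluded). Unaligned inputs are aligned globally with
match 1 / mismatch −1 / gap −2 (configurable). Codon alignments are obtained
by aligning the proteins and back-threading the nucleotides, dropping
gap-containing codon columns pairwise.

Ka/Ks uses the Nei–Gojobori (1986) counting method under the active genetic
code: per codon and position, the synonymous site fraction counts the
single-nucleotide changes that preserve the amino acid among those that do not
create a stop; sites are averaged across the two sequences. Codons differing
at several positions average the synonymous/nonsynonymous split over all
substitution orderings with equal weights, excluding paths through stop
codons (falling back to all paths when every ordering is blocked). Both
proportions receive the Jukes–Cantor correction d = −(3/4)·ln(1 − 4p/3);
p ≥ 3/4 is a saturation error. A ratio with Ks = 0 is flagged infinite
(Ka > 0) or undefined (both zero) rather than silently dropped. NG86 with
equal path weights was chosen because the published per-gene values this
package is checked against came from a tool whose exact estimator is
unstated; class means and tolerance bands, not per-gene equality, are the
reproduction target.

The gene-class contrast uses the Mann–Whitney U test with midranks,
tie-corrected normal approximation and no continuity correction; the sign
convention follows the first group (known genes), so known genes ranking
lower gives negative z. An exact permutation p-value is enumerated for
combined samples of at most 20.

## Phylogeny and the GC3 shift

Distances default to Kimura's two-parameter model with pairwise deletion
(gap/`N` sites dropped per pair), the common default of the distance-era
tools; JC and p-distance are options. Trees are built with Saitou–Nei
neighbor joining (exact on additive matrices — asserted against brute-force
reconstructions in the tests); negative branch lengths are clamped to zero
with the clamped total recorded. Bootstrap support resamples alignment
columns with replacement and reports, for each internal bipartition of the
full-data tree (not a consensus), the percentage of replicates containing it;
runs are seed-reproducible.

The compositional shift is placed by thresholding per-taxon GC3: taxa at or
above the cut form the high set, and if that set is exactly one side of a
single edge, that edge is the placement; otherwise a non-monophyly flag is
returned. Placement is deliberately the only tree-level quantity treated as a
reproduction target, because it is robust to the (unstated) distance model
behind published figures.

## Minisatellite detection

The detector is seed-and-extend: exact lag-d match runs (seed length chosen by
pigeonhole so that any adjacent unit pair at the identity threshold must
contain one) anchor candidate arrays, which grow unit-by-unit while adjacent
full units keep ungapped Hamming identity ≥ 0.8 (default), with fractional
head/tail copies extended on exact matches. Identity between adjacent units is
ungapped because the target repeat class is length-conserved per unit; an
indel-tolerant mode is out of scope. Calls are reduced to their primitive
period; arrays reducible below `min_unit` (homopolymer/microsatellite runs)
are suppressed — the unit range is a contract on the reported unit, so
detecting a 3-bp repeat requires `min_unit = 3`. Overlapping calls keep the
smaller period. Defaults (unit 6–100 bp, ≥3 copies, identity ≥ 0.8) detect an
imperfect 18-bp × 9 array reliably while keeping calls on random AT-rich
sequence rare; note that such sequence does occasionally contain genuine
qualifying arrays, so the tested property is agreement with an exhaustive
all-(period, offset) scanner, not absence of calls. Frame preservation is
simply unit length ≡ 0 (mod 3): copy-number variation in such an array cannot
cause a frameshift.

## Synthetic data: what it emulates and what it does not

Every stage is testable offline against seeded generators that emit
machine-readable truth ledgers:

* `simulate_genome()` builds a linear genome: ~20 protein-coding genes (a
  quarter ymf-style ORFs, lengths 60–600 aa), two rRNA genes, spacers of
  0–85 bp, AT-rich noncoding composition (G+C ≈ 15%), codons sampled from an
  AT-ending usage profile (the bundled *P. caudatum*-like column), all genes
  terminated by TAA, and one ORF carrying an imperfect 18-bp × 9 in-frame
  repeat array near its middle. These defaults are the study conditions of
  the comparative setting the package addresses, not tuning knobs.
* `evolve_pair()` evolves two lineages from an ancestor with uniform
  single-nucleotide proposals, accepting synonymous changes always and
  nonsynonymous ones with probability ω (stop-creating changes rejected), so
  the realised rate ratio equals ω by construction; proposal counts are
  Poisson with expectation t_syn/2 per site per lineage.
* `simulate_alignment()` evolves in-frame codons down a tree under JC, with
  third positions drawing replacements from biased equilibrium frequencies; on
  the designated clade's stem edge all third positions are redrawn from the
  high-GC equilibrium, modelling a compositional shift on that edge.
* `simulate_strain_set()` varies the copy number of a shared repeat locus
  across strains (default copy numbers 18, 11, 11, 9, 9, 14, 10).

The generators do not emulate indel processes, rRNA secondary structure,
within-genome rate heterogeneity beyond the third-position bias, or
annotation error; passing recovery tests therefore demonstrates correctness
of the estimators under their own model assumptions, not robustness to real
data pathologies. Generated genomes are linear, matching the biology.

All generator randomness flows through one seeded local RNG stream per
invocation; the caller's RNG state is untouched and equal seeds give
byte-identical output.

## Numerical choices and problem sizes

Degenerate inputs raise errors or flags rather than silent fixes: CDS lengths
off the codon grid (unless marked partial), internal stop codons (wrong frame
or code), saturated distances, empty groups, undefined ratios. Neighbor
joining breaks ties deterministically and clamps negative edges. The test
suite and the acceptance script use deliberately modest problem sizes — 5,000
codons × 10 replicates for the ω-recovery study, 20 random trees of 4–6 taxa
for NJ exactness, 50 random 2-kb sequences for the repeat-detector/brute-force
agreement, 200–500 bootstrap replicates on 6-taxon alignments — chosen so the
sampling error of each check sits well inside its stated tolerance.

## Known limitations

* The GenBank dialect is minimal (no EMBL/GFF3, no rich qualifiers).
* Ka/Ks is NG86 only; ML codon models and sliding windows are out of scope.
* The repeat detector has no indel-tolerant mode.
* The published per-gene Ka/Ks values are reproduced as class means and
  tolerance bands, not per-gene equalities, because the original estimator is
  under-specified.
* Network fetching of accessions lives in an optional helper script; the
  package itself never downloads, so accession-based checks require the
  records to be fetched once by the user.
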