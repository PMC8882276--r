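---
title: "Parent-aware mutation analysis of evolved diploid genomes"
author: "alemut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-aware mutation analysis of evolved diploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alemut)
```

## Why parent-aware comparison

Resequencing single clones after adaptive laboratory evolution (ALE) of a
heterozygous diploid strain yields two very different kinds of genetic
change. *De novo* mutation introduces an allele absent from both parental
haplotypes. *Loss of heterozygosity* (LOH) homozygoses a tract of an
existing heterozygous chromosome pair, typically by mitotic recombination
or gene conversion; no new sequence arises, but long stretches of the
genome switch from `ref/alt` to `alt/alt` or to `ref/ref`.

The `ref/ref` case — a *reversion* — is the methodological crux. A
reverted site is indistinguishable from wild type in the evolved strain's
own variant calls: it simply stops being called. Any analysis that only
looks at the evolved strain's variant list therefore undercounts LOH by
roughly a factor of two. `alemut` instead takes the union of parent and
evolved variable sites as the comparison universe and imputes
homozygous-reference genotypes for sites absent from either table
(`diff_sites()`). Classification is then a total function of the compared
genotypes (`classify_site()`):

1. any evolved allele absent from the parent's genotype → `new_variant`
   (zygosity read off the evolved genotype itself);
2. otherwise a heterozygous parent became homozygous → `loh`, a
   `reversion` when the retained allele equals the reference.

A deliberate boundary decision: LOH requires a *heterozygous* parent
site. A homozygous parent site changing to a different homozygous allele
(even back to the reference) is a homozygous new variant — that is what
"loss of heterozygosity" means genetically. Zygosity of a new variant is
defined by whether the two evolved alleles are equal, which stays
well-defined when both copies are novel but different (e.g. parent `A/A`,
evolved `G/T`).

One site counts as one mutation regardless of how many alleles it
involves; indel alleles are left-normalized on VCF read (common suffix
then prefix trimmed, position advanced) so that parent and evolved
representations of the same event cannot produce spurious differences.

## Effect annotation

Effects are evaluated on the strand-corrected coding sequence. All of a
strain's edits within one CDS are applied jointly (right-to-left in
genomic coordinates so positions never shift under the edit), because
evolved clones do carry co-occurring edits in one gene; a per-variant mode
exists and is what the cohort accounting uses for its per-call
amino-acid-change flag, so that each counted mutation carries its own
effect. Translation uses the standard nuclear code and stops at the first
stop codon.

The protein diff distinguishes synonymous, missense (notation
`H2Q` at the first differing residue), nonsense (`W3*`, with the count of
truncated residues), stop-lost, in-frame indels, and frameshifts. A
frameshift (net in-CDS indel length not divisible by 3) is reported the
way geneticists describe it: position of the first altered residue, the
number of altered residues until the shifted frame reaches a stop, and
the number of wild-type residues truncated; if the shifted frame reaches
the end of the CDS without a stop the record is flagged
`stop_not_found`. Substitutions are labelled conservative when their
BLOSUM62 score is positive — an explicit convention, since the
conservative/non-conservative vocabulary is standard but rarely given a
criterion (H→Q scores 0 and P→T scores −1, both non-conservative; I→V
scores 3, conservative).

LOH reversions carry the reference allele, so against the reference CDS
they produce no protein change; they are annotated effect-neutral
(`synonymous` with empty notation) and never enter amino-acid-change
counts. Variants that straddle a CDS boundary have the edit clipped to
the CDS and the record flagged rather than rejected.

The test suite holds this module to an independent oracle: a brute-force
implementation that rebuilds the whole mutant contig by plain string
editing, re-extracts the (shifted) CDS span, translates with `seqinr`,
and diffs the proteins. Implementation and oracle agree on effect,
notation and frameshift tail counts over hundreds of random CDS/variant
combinations per seed, including minus-strand features.

## LOH segmentation

Per strain and contig, a single linear scan joins consecutive LOH calls
separated by at most `max_gap` bp; clusters with at least `min_sites`
supporting calls become segments whose bounds are the outermost
supporting calls — deliberately conservative, with no extension to
midpoints between flanking heterozygous sites. Defaults `max_gap = 25000`
and `min_sites = 3` are chosen so that at the default heterozygosity
density of 1/300 a 10 kb tract is comfortably detectable, while the
probability of a >25 kb gap between het sites inside a real tract is
negligible; both are exposed because any real dataset should tune them to
its het density. Reversion calls count as supporting sites — they are LOH
evidence recovered by the parent comparison. Segments shared between
strains are connected components under reciprocal overlap ≥ 0.5, reported
with the intersection interval; new variants inside a strain's segments
get a positional flag (inside a selected tract, most mutations are
passengers inherited with the rearrangement).

No statistical changepoint model (HMM/CBS) is attempted: at ALE depths
and noiseless genotype input, run-joining recovers planted tracts
exactly, and the parameters are transparent.

## Copy number from depth

Depth is converted to approximate copy number by
`c_i = 2 d_i / m`, with `m` the genome-wide median depth of the sample —
the genome-wide median of `c` is therefore exactly 2 by construction, and
the profile is invariant to rescaling all depths. A per-contig median
mode exists behind a flag but is not the default, since whole-chromosome
aneuploidy would defeat a per-contig baseline. Optional smoothing applies
non-overlapping window medians (default window 1000 bp) after
normalization.

Gene-level copy number is the median of `c` over the gene span, rounded
half-up; calls are loss/neutral/gain against baseline ploidy 2. A
whole-contig event requires ≥ 80% of the contig's genes (min 5 genes) to
share a non-neutral call; otherwise maximal runs of ≥ 3 consecutive
same-call genes are reported as partial events. These thresholds are
package conventions, config-exposed; gene-level aggregation by median
makes reproducible what is often done by eye on coverage plots. Genes
straddling a planted-event boundary have no single true copy number, so
recovery metrics exclude them. GC bias and mappability correction are out
of scope — the depth model here is per-base Poisson, not read-level.

Sites inside CNV regions are still classified under the diploid genotype
model; ploidy-aware genotyping is out of scope.

## The synthetic generator

`sim_config()` defaults encode the study regime the package targets:

| parameter | default | meaning |
|---|---|---|
| `contig_lengths` | 3 × 100 kb | desk-scale stand-in for a 12 Mb genome |
| `gc_fraction` | 0.38 | yeast-like base composition |
| `het_density` | 1/300 | parent heterozygous sites per bp (industrial-isolate scale) |
| `n_loh_tracts` | 4 | LOH tracts per evolved lineage |
| `tract_mean_length` | 15 kb | geometric tract-length mean |
| `p_retain_reference` | 0.5 | probability a tract homozygoses to the reference homolog |
| `n_de_novo` | 18 (Poisson mean) | de novo events per lineage |
| `snv_fraction` | 0.9 | SNV : indel ratio among de novo events |
| `mean_depth` | 50 | Poisson depth at copy 2 |

With these values a lineage carries on the order of 200 LOH sites against
18 de novo events, i.e. ~8% new variants — the LOH-dominated regime, with
about half of the LOH sites reverting to reference. The tract-length
distribution is geometric as a modelling choice (no empirical
distribution is available for ALE tracts); each tract homozygoses to a
single homolog, modelling the parent as reference-homolog ×
divergent-homolog, which is what makes the per-tract reversion
probability a single Bernoulli draw. LOH is gene-conversion-like (no copy
change); a chromosome-loss LOH can be emulated by co-locating a terminal
tract with a −1 CNV event. Depth is per-base Poisson; real coverage is
overdispersed and GC-biased, so passing recovery tests here demonstrates
correctness of the estimators under the stated model, not robustness to
library artefacts. Reads, selection dynamics and transposition are not
simulated.

Everything is a pure function of `(config, seed)`; `generate_cohort()`
writes FASTA/GFF3/VCF/TSV/WIG plus a truth JSON (copy profiles run-length
encoded) and an md5 manifest.

## Cohort accounting

Cross-strain identity of a mutation is site + resulting genotype
(`mutation_key()`), so "the same heterozygous SNP in seven strains" is
distinguishable from different mutations in the same gene; gene-level
sharing uses `gene_id` only. Group rows count the *union* of member
strains' keys and the shared row the intersection across groups — the
only convention under which the inclusion–exclusion identity
`overall = group A + group B − shared` can hold, and it is
property-tested on random cohorts. Contig-class column blocks
(host reference / inserted pathway / strain-specific) are treated as
disjoint, with classes supplied by a side manifest since they are
metadata, not inferable from sequence. Printed-style percentages round
half-away-from-zero, matching how results text typically reports `8.3%`
or `55%`.

## Problem sizes and determinism

The test suite and the acceptance script run on desk-scale cohorts chosen
to keep the full run in tens of seconds while leaving every estimator in
its operating regime: 11-lineage cohorts on 3 × 100 kb genomes for
classification recovery (a few thousand calls), 500 random CDS/variant
cases for the effect oracle, 20 seeded replicates of 3 × 40 kb genomes
with planted ±1 segments (25 kb and 20 kb at depth 50) for CNV recovery,
and 200 single-tract lineages for segmentation and the reversion
fraction. All randomness flows from explicit integer seeds; reruns are
byte-identical, which the tests assert via file checksums.

## Known limitations

- Genotype input is assumed clean; caller quality/rank filtering happens
  upstream and false positives in the input propagate.
- Multi-allelic sites count as one mutation (per-site counting); the
  evolved genotype records exactly the two called alleles.
- Effect annotation covers CDS only — no splice, UTR or regulatory
  effects, and no protein-structure interpretation.
- The diploid model is global: segmental aneuploidy does not alter
  genotype interpretation, only the copy-number track.
- Shared-segment detection is positional; it does not test whether
  sharing exceeds chance.
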