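---
title: "Methods: contrasting selfing-line genomes against a reference"
author: "vircontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting selfing-line genomes against a reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`vircontrast` implements the downstream half of a two-selfing-line
resequencing contrast. The biological premise: repeated self-pollination
fixes chromosome segments to homozygosity through recombination, and two
sibling lines fix *different* segments. If a trait (here,
self-incompatibility strength read out as fruit-set rate) differs
between the lines, genes carrying protein-altering variants inside the
differentially homozygous segments are candidate modifiers. The package
therefore chains: variant ingest and normalization, per-variant
consequence annotation, per-locus two-sample contrast, windowed
homozygosity mapping, descriptive variation statistics, Pfam-domain
nonsyn/syn enrichment, and a candidate-gene filter.

## Coordinate convention

All internal coordinates are 1-based inclusive, the native convention of
GRanges/IRanges on which the package is built; conversion happens only
at format boundaries (BED output is converted to 0-based half-open on
write; GFF3 and VCF are already 1-based). A single convention with
conversions confined to the readers and writers is what eliminates
off-by-one bugs; adopting the host ecosystem's convention rather than a
zero-based one means every intermediate object can be inspected with
standard Bioconductor tooling.

## Variant normalization

VCF records are left-normalized: context shared by REF and *all* ALT
alleles is trimmed, prefix first (the record position advancing past
it), then suffix. After trimming, an indel's length is
`|nchar(ref) - nchar(alt)|` and a pure deletion/insertion may have an
empty allele string. This makes a `CAC -> C` record a 2-bp deletion of
`AC`, matching how deletion sizes are conventionally reported.
Multi-allelic records are kept as single records because the two-sample
consistency logic compares joint allele multisets; splitting would lose
the pairing. Records whose requested samples are all missing are
dropped with a log message. Indels are *defined* as net changes of
1–30 bp: anything larger is routed to the structural-variant class at
ingest.

## Consequence engine

The engine is codon-local for SNPs: the affected codon is located via
the spliced CDS coordinate (strand-aware), mutated, and translated.
Classification: unchanged amino acid → synonymous (this includes
stop→stop); a mutated initiator codon → start_lost; non-stop→stop →
stopgain; stop→non-stop → stop_lost; otherwise nonsynonymous. Indels
are classified by net length (`net %% 3 != 0` → frameshift; otherwise
codon_deletion / codon_insertion), and frameshifts are re-translated so
the truncation (reference protein length minus mutant protein length)
is attached — this is what lets a frameshift be reported as "the
protein lacks 77 residues". Structural variants touching any CDS
segment are `sv_cds_overlap`; translocation records (ITX/CTX) are
tested at their two breakpoints only, since the span between
breakpoints is not physically affected sequence.

Policy decisions worth stating explicitly:

* Multi-allelic records are labelled with the most severe consequence
  across alternate alleles (severity: stopgain > stop_lost >
  start_lost > frameshift > in-frame indel > nonsynonymous >
  synonymous), because downstream counting is per record.
* An indel spanning an exon/intron boundary is called frameshift with a
  `boundary` flag rather than given a splice-site class of its own; the
  consequence vocabulary deliberately stays closed.
* Genes with a malformed CDS (length not divisible by three, or not
  starting with ATG) are still classified, with a `model_warning`
  attached, rather than dropped — real annotations contain such models.

The engine is validated against an independently written
*translate-and-diff* oracle that rebuilds the entire mutant chromosome
segment, re-splices with shifted exon coordinates, translates both
proteins with Biostrings and derives the class from the protein diff.
The test suite requires the confusion matrix between engine and oracle
to be exactly diagonal over ≥1000 planted variants per class, and a
strand-symmetry property (mirroring the locus and flipping the strand
preserves every call).

## Two-sample contrast

Zygosity per sample: `0/0` hom-ref, `k/k` hom-alt, two distinct allele
indices het, uncalled missing; phase separators are ignored because the
calls are unphased. Two samples are *consistent* at a locus when their
allele multisets are equal; a locus is a *between-sample variant* when
the multisets differ and at least one sample carries a non-reference
allele the other lacks. Loci with a missing genotype in either sample
are excluded from the between-sample set and tallied as unresolvable —
the conservative choice, since an unobserved genotype can neither
support nor refute a difference. Between-sample counts are counts of
loci, not alleles.

## Homozygosity scan

Windows of `window_size` (default 100 kb) tile each chromosome
(`step = window_size` by default). Per window and sample, the scan
counts the sample's variant calls — records where the sample carries at
least one alternate allele — and the heterozygous calls among them.
Heterozygosity is the *fraction of heterozygous calls among called
variants*, not per-bp heterozygosity: that is the only reading under
which a "<10%" threshold applies to variant calls. A window is
homozygous when it has at least `min_variants` calls (default 10; a
floor prevents variant-poor windows from being trivially homozygous)
and a heterozygous fraction strictly below `het_threshold` (default
0.10). Consecutive homozygous windows merge into maximal regions;
`no_call` windows break runs unless bridging is enabled. Tiling rather
than overlapping steps makes the per-chromosome conservation invariant
(window counts sum to the chromosome's call count) exact, and Mb-scale
region reporting does not need sub-window resolution; a smaller `step`
remains available. Differential regions are the interval difference of
the two samples' region sets, with slivers shorter than one window
discarded. Region calling defaults to SNP calls only; indels can be
included via the `classes` argument.

## Variation statistics

Transitions are A↔G and C↔T; everything else is a transversion;
multi-allelic SNPs contribute one observation per alternate allele
(the convention has to be fixed somewhere; per-alt counting keeps the
ratio well-defined for joint records). The indel spectrum is a signed
histogram over ±1..30 bp. For region densities the genome is
partitioned exactly: flattened gene spans split the genome into genic
and intergenic; within genic, the union of exon features (CDS when no
exon features exist) versus the rest gives exon and intron, so
`intergenic + genic = genome` and `exon + intron = genic` hold as
identities and overlapping genes never double-count a base. Each
variant is assigned one region by its most specific class. SV
validation keeps records with depth in [2, 100] and quality > 20;
rejections are logged with machine-readable reasons.

## Pfam enrichment

A coding SNP maps to residue `cds_pos %/% 3 + 1`; it hits a family when
that residue lies in any of the family's intervals on that gene
(several overlapping intervals of one family still count once). Each
family's nonsyn/syn split is tested against the rest of the genome-wide
CDS background in a 2×2 chi-squared with 1 df and no continuity
correction — the family-vs-rest layout is a documented choice, as is
reading "more than 30 nonsyn and syn SNPs" as a combined count (a
strict per-count mode exists). No multiple-testing correction is
applied by default, matching the single p < 0.001 threshold convention;
a Bonferroni option exists. Flagging (count and ratio thresholds) is
deliberately independent of the p-value.

## Candidate genes

A gene qualifies when it carries ≥1 variant with a protein-altering
consequence in ≥1 sample; `require_difference` additionally demands
that the qualifying variant sets of the two samples differ, which is
the operational reading of "genes differing between the samples" for a
two-line design. Prior-knowledge matching is by exact id or
case-insensitive keyword against a user-supplied list; the package does
not bundle any curated list, so candidate counts from real studies
(which fold in literature curation) are out of reach by design — the
mechanical filter is the reproducible part.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions the analysis assumes: seven 2-Mb chromosomes (a
~15-fold scale-down of the ~230-Mb, seven-chromosome reference genome),
SNPs at 12,900/Mb and indels at 1,940/Mb in intergenic sequence with
region-dependent rate multipliers chosen to reproduce the observed
density orderings (SNPs: intergenic > exon > intron; indels:
intergenic > intron > exon), a transition probability tuned to
Ts/Tv = 1.57, 84% of carried calls homozygous outside blocks, indel
lengths 1–30 bp with the mass concentrated in 1–4 bp, and 30
sample-specific homozygous blocks aligned to the 100-kb window grid.
Blocks default to 2–4 windows (200–400 kb): on 2-Mb chromosomes this is
the proportional counterpart of the Mb-scale regions seen on real
20–30-Mb chromosomes, and it leaves enough free windows for 30 disjoint
blocks to be placeable. Genes are 80–320 codons with 1–4 CDS exons on
both strands, constructed as valid ATG…stop frames with no internal
stop; every planted CDS variant is verified at generation time by the
re-translation route and recorded in the truth table with its verified
class, which is what makes the engine-vs-truth confusion matrix a
meaningful test. Candidate genes receive qualifying variants in exactly
one sample; decoys receive only synonymous variants. Homozygous blocks
are planted directly rather than simulated through
recombination-and-selfing generations: the analysis consumes the block
structure, not the breeding process.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: read-level errors and caller artifacts
(genotypes are exact), linkage disequilibrium and recombination
gradients, repeat-induced mis-mapping, UTR annotation (exons equal CDS
in generated models, so the exon-UTR region class is exercised only via
hand-built fixtures), and reference bias. Results on real callsets will
be noisier than the planted-truth recovery suggests, particularly for
the scan near block boundaries.

Determinism: every stochastic draw flows from a single integer seed
through fixed sub-seeds per stage (all below 2^31), so any run is
byte-reproducible.

## Validation problem sizes

The shipped validation uses: 8,000 planted CDS variants (1,000 per
consequence class) for the engine/oracle confusion matrix; the full
7 × 2-Mb genome with ~190,000 calls for block recovery; ~15,000 calls
for recovering the planted homozygote fraction (within three binomial
standard deviations of 0.84) and Ts/Tv (within three binomial SDs of
the transition fraction implied by 1.57); and 20 planted candidate
genes against 30 synonymous-only decoys for filter soundness. These
sizes were chosen so the whole validation recomputes in a few minutes
on one core while every stochastic tolerance is still set by the
statistics (3-SD binomial bands), not by runtime.

## Known limitations

* Consequence calls are made per variant against the reference; the
  engine does not compose multiple variants on one haplotype (two
  frameshifts that jointly restore the frame are reported separately).
* No splice-donor/acceptor classes; boundary-spanning indels are
  frameshift-with-flag.
* The genetic code is fixed to the standard table.
* `genic_exon_utr` requires exon features in the GFF3; with CDS-only
  annotations the non-CDS genic space is all intron.
* The candidate filter reproduces the mechanical variant-based
  selection only; curation against external gene lists is the user's
  input via `prior_genes`.
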