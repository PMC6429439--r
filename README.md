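# vircontrast

Downstream genome-contrast analysis for resequenced selfing lines.

When two inbred (selfing) lines derived from one parent differ sharply in
a phenotype — here, the fruit-set rate that separates self-incompatible
from self-compatible strawberry lines — their variant calls against a
shared reference genome carry the signal: chromosome segments fixed
homozygous by selfing differ between the lines, and protein-altering
variants inside those segments are candidate modifiers of the trait.
`vircontrast` implements the downstream analysis of that design, taking
a reference FASTA, gene models (GFF3) and joint variant calls (VCF) for
two samples, and producing:

- **Variant effect annotation.** Every variant is classed by region
  (intergenic / intron / exon-UTR / CDS) and, for coding variants, by
  amino-acid consequence: synonymous, nonsynonymous, stopgain,
  stop_lost, start_lost, frameshift, in-frame codon deletion/insertion,
  and structural-variant CDS overlap. Frameshifts are re-translated so
  the protein truncation (e.g. "lacks 77 residues") is reported.
- **Two-sample contrast.** Per-locus zygosity (hom-ref / het / hom-alt
  / missing) and allele-multiset comparison between the lines; loci
  where the lines carry different alleles form the between-sample
  variant set.
- **Homozygosity mapping.** A sliding-window scan (default 100-kb
  windows, heterozygous-call fraction < 10%) maps runs of homozygous
  variation per sample, merges them into regions, and reports the
  regions homozygous in exactly one line.
- **Summary statistics.** Transition/transversion ratio (Ts =
  A&harr;G, C&harr;T), signed indel length spectrum over 1&ndash;30 bp,
  per-region variant densities on the intergenic/genic/exon/intron
  partition, and the nonsynonymous/synonymous ratio per sample.
- **Pfam enrichment.** Per domain family, nonsynonymous and synonymous
  CDS SNPs falling inside the family's protein-coordinate intervals are
  counted and tested against the genome-wide CDS background with a 2x2
  chi-squared statistic (1 df, no continuity correction); families with
  more than 30 SNPs combined and nonsyn/syn ratio above 0.6 are
  flagged.
- **Candidate genes.** Genes carrying at least one protein-altering
  variant, optionally restricted to genes whose qualifying variant
  sets differ between the two lines, with a per-chromosome physical-map
  table.
- **A synthetic-data generator** that emits a reference genome, gene
  models, domain tables and a two-sample VCF with a complete truth
  table (planted consequence classes verified by an independent
  re-translation route, planted homozygous blocks, planted candidate
  genes), so every stage is validated against known truth.

Post-call filters follow the study design: indels are defined as net
length changes of 1&ndash;30 bp (larger events are routed to the SV
class), and SV records are retained only with coverage depth in
2&times;&ndash;100&times; and quality above 20.

## Worked example

```r
library(vircontrast)

cfg <- simulationConfig(seed = 42, n_chroms = 2, chrom_length = 500000,
                        n_genes_per_chrom = 20, n_blocks = 4,
                        block_windows_range = c(1, 2),
                        n_candidate_genes = 5, n_decoy_genes = 5,
                        n_sv_per_chrom = 4)
sim <- simulateStudy(cfg, dir = "demo")   # writes ref.fa, genes.gff3,
                                          # domains.tsv, calls.vcf, truth_*
sim$variants
#> VariantSet with 14922 records ( INDEL 1972, SNP 12940, SV 10 )
#>   for samples: lineA, lineB

eff <- annotateEffects(sim$variants, sim$models, sim$genome)
contrastSummary(sim$variants, "lineA", "lineB")$hom_fraction
#> lineA lineB
#> 0.897 0.904
tsTvRatio(sim$variants)$ratio
#> [1] 1.569

w <- scanHeterozygosity(sim$variants, chromLengths(sim$genome),
                        "lineA", scanParams())
mergeHomozygousRegions(w)
#>   chrom  start    end
#> 1  chr2 100001 400000
```

The recovered region is the union of the two blocks planted for lineA
(chr2 100&ndash;300 kb and 300&ndash;400 kb). The homozygote fractions
sit above the planted 0.84 because calls inside a sample's own blocks
are all homozygous. Candidate selection restricted to genes whose
protein-altering variants differ between the lines:

```r
selectCandidates(eff, sim$variants, sim$models, require_difference = TRUE)
#>     gene_id chrom pos_mb n_evidence                  consequences
#> 1 gene00002  chr1  0.044          6 nonsynonymous,stopgain,sv_cds_overlap
#> 2 gene00004  chr1  0.097          5                 nonsynonymous
#> ...
```

The same stages run end to end over files with
`runPipeline(pipelineConfig(...))`, which writes per-stage TSV/BED
tables, `summary.json` and `report.md`.

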