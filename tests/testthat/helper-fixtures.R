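# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small two-chromosome study with blocks, candidates and decoys.
small_sim <- function() cached("small_sim", {
  cfg <- simulationConfig(
    seed = 7L, n_chroms = 2L, chrom_length = 500000L,
    n_genes_per_chrom = 20L, n_blocks = 4L,
    block_windows_range = c(1L, 2L), n_candidate_genes = 5L,
    n_decoy_genes = 5L, n_sv_per_chrom = 4L)
  simulateStudy(cfg)
})

# Same study written to disk (for IO round-trips and the pipeline).
small_sim_dir <- function() cached("small_sim_dir", {
  dir <- file.path(tempdir(), "vircontrast-small-sim")
  cfg <- simulationConfig(
    seed = 7L, n_chroms = 2L, chrom_length = 500000L,
    n_genes_per_chrom = 20L, n_blocks = 4L,
    block_windows_range = c(1L, 2L), n_candidate_genes = 5L,
    n_decoy_genes = 5L, n_sv_per_chrom = 4L)
  simulateStudy(cfg, dir = dir)
})

# Candidate-filter study: no background noise, planted genes only.
candidate_sim <- function() cached("candidate_sim", {
  cfg <- simulationConfig(
    seed = 13L, n_chroms = 2L, chrom_length = 400000L,
    n_genes_per_chrom = 30L, n_blocks = 0L,
    snp_rate = 0, indel_rate = 0, n_sv_per_chrom = 0L,
    effect_counts = c(synonymous = 0),
    n_candidate_genes = 20L, n_decoy_genes = 30L)
  simulateStudy(cfg)
})

# Write a VCF from header + body lines; returns the path.
write_vcf_text <- function(body, samples = c("S1", "S2"),
                           contigs = c(chr1 = 100000L)) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"t\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"t\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}

# A single-gene genome built from explicit CDS segments; cds_segments is
# a data.frame(start, end) on a supplied chromosome sequence.
toy_gene <- function(chrom_seq, cds_segments, strand = "+",
                     gene_id = "g1", chrom = "chr1",
                     gene_span = NULL) {
  genome <- Biostrings::DNAStringSet(stats::setNames(chrom_seq, chrom))
  if (is.null(gene_span))
    gene_span <- c(min(cds_segments$start), max(cds_segments$end))
  genes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(gene_span[1], gene_span[2]), strand = strand,
    gene_id = gene_id, biotype = "protein_coding")
  cds <- GenomicRanges::GRangesList(stats::setNames(list(
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(cds_segments$start,
                                            cds_segments$end),
                           strand = strand)), gene_id))
  list(genome = genome, models = GeneModels(genes, cds))
}

# A VariantSet built directly from a record table (already normalized).
toy_variants <- function(tab, gt, samples = c("S1", "S2"), depth = NULL) {
  defaults <- data.frame(id = ".", sv_type = NA_character_,
                         sv_end = NA_integer_, qual = 100)
  for (col in names(defaults))
    if (is.null(tab[[col]])) tab[[col]] <- defaults[[col]]
  VariantSet(tab[c("chrom", "pos", "id", "ref", "alt", "var_class",
                   "sv_type", "sv_end", "qual")],
             gt, samples, depth)
}

# Random open reading frame of n_codons codons (incl. start and stop).
random_orf <- function(n_codons, seed = 1L) {
  set.seed(seed)
  tab <- Biostrings::GENETIC_CODE
  nonstop <- names(tab)[tab != "*"]
  paste0("ATG", paste(sample(nonstop, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}
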