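test_that("Ts/Tv counts transitions A<->G and C<->T", {
  mk <- function(ref, alt) toy_variants(
    data.frame(chrom = "chr1", pos = seq_along(ref) * 10L, ref = ref,
               alt = alt, var_class = "SNP"),
    matrix("1/1", length(ref), 2))
  expect_equal(tsTvRatio(mk(c("A", "A"), c("G", "T")))$ratio, 1.0)
  # all-transition set: Tv = 0 leaves the ratio undefined
  expect_true(is.na(tsTvRatio(mk(c("A", "C"), c("G", "T")))$ratio))
})

test_that("Ts/Tv arithmetic on a mixed set", {
  # A>G (ts), C>T (ts), A>T (tv), G>C (tv), T>C (ts) -> 3/2
  vs <- toy_variants(
    data.frame(chrom = "chr1", pos = 1:5 * 10L,
               ref = c("A", "C", "A", "G", "T"),
               alt = c("G", "T", "T", "C", "C"), var_class = "SNP"),
    matrix("1/1", 5, 2))
  r <- tsTvRatio(vs)
  expect_equal(c(r$ts, r$tv), c(3L, 2L))
  expect_equal(r$ratio, 1.5)
  # multi-allelic record contributes per alt: A>G (ts) + A>T (tv)
  vs2 <- toy_variants(
    data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G,T",
               var_class = "SNP"), matrix("1/2", 1, 2))
  r2 <- tsTvRatio(vs2)
  expect_equal(c(r2$ts, r2$tv), c(1L, 1L))
})

test_that("planted Ts/Tv is recovered within binomial error", {
  sim <- small_sim()
  r <- tsTvRatio(sim$variants)
  n <- r$ts + r$tv
  expect_gt(n, 10000L)
  p_hat <- r$ts / n
  p0 <- 1.57 / 2.57
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("indel spectrum is signed, bounded and mode is 1-4 bp", {
  vs <- toy_variants(
    data.frame(chrom = "chr1", pos = c(101L, 200L),
               ref = c("AC", ""), alt = c("", "CGT"),
               var_class = "INDEL"),
    matrix("1/1", 2, 2))
  sp <- indelSpectrum(vs)
  expect_equal(sp$count[sp$length == -2], 1L)   # the CAC->A deletion
  expect_equal(sp$count[sp$length == 3], 1L)    # A->ACGT insertion
  expect_equal(sum(sp$count), 2L)
  expect_equal(range(sp$length), c(-30L, 30L))

  sim <- small_sim()
  sp2 <- indelSpectrum(sim$variants)
  mode_len <- abs(sp2$length[which.max(sp2$count)])
  expect_lte(mode_len, 4L)
  # majority of indels in 1-4 bp
  expect_gt(sum(sp2$count[abs(sp2$length) <= 4]) / sum(sp2$count), 0.5)

  bad <- toy_variants(
    data.frame(chrom = "chr1", pos = 1L, ref = "AA", alt = "GG,A",
               var_class = "INDEL"), matrix("1/1", 1, 2))
  # the alt with no length change is ignored; the 1-bp one counts
  expect_equal(sum(indelSpectrum(bad)$count), 1L)
})

test_that("region composition partitions the genome exactly", {
  sim <- small_sim()
  comp <- regionComposition(sim$models, chromLengths(sim$genome))
  get <- function(r) comp$span_bp[comp$region == r]
  expect_equal(get("intergenic") + get("genic"), get("genome"))
  expect_equal(get("exon") + get("intron"), get("genic"))
  expect_gt(get("genome"), 0)

  # a genome with no genes is all intergenic
  empty <- GeneModels(
    GenomicRanges::GRanges(gene_id = character(0), biotype = character(0)),
    GenomicRanges::GRangesList())
  comp0 <- regionComposition(empty, c(chr1 = 2000000L))
  expect_equal(comp0$span_bp[comp0$region == "intergenic"], 2000000)
  expect_equal(comp0$span_bp[comp0$region == "genic"], 0)
})

test_that("variant densities recover the planted region ordering", {
  # background-only study so densities reflect the region weights alone
  cfg <- simulationConfig(seed = 31L, n_chroms = 2L,
                          chrom_length = 600000L,
                          n_genes_per_chrom = 40L, n_blocks = 0L,
                          n_candidate_genes = 0L, n_decoy_genes = 0L,
                          n_sv_per_chrom = 0L,
                          effect_counts = c(synonymous = 0),
                          classify_background = FALSE)
  sim <- cached("density_sim", simulateStudy(cfg))
  eff <- annotateEffects(sim$variants, sim$models, sim$genome)
  comp <- regionComposition(sim$models, chromLengths(sim$genome))
  dens <- regionDensity(eff, comp)
  d <- function(cls, r) dens[dens$region == r, paste0(cls, "_per_mb")]
  # planted SNP rates: intergenic > exon > intron, with genic in between
  expect_gt(d("snp", "intergenic"), d("snp", "exon"))
  expect_gt(d("snp", "exon"), d("snp", "genic"))
  expect_gt(d("snp", "genic"), d("snp", "intron"))
  # planted indel rates: intergenic > intron > genic > exon
  expect_gt(d("indel", "intergenic"), d("indel", "intron"))
  expect_gt(d("indel", "intron"), d("indel", "genic"))
  expect_gt(d("indel", "genic"), d("indel", "exon"))
})

test_that("every variant lands in exactly one region bin", {
  sim <- small_sim()
  eff <- annotateEffects(sim$variants, sim$models, sim$genome)
  comp <- regionComposition(sim$models, chromLengths(sim$genome))
  dens <- regionDensity(eff, comp)
  tb <- variantTable(sim$variants)
  expect_equal(
    sum(dens[dens$region %in% c("intergenic", "genic"), "n_snp"]),
    sum(tb$var_class == "SNP"))
  expect_equal(
    sum(dens[dens$region %in% c("intergenic", "genic"), "n_indel"]),
    sum(tb$var_class == "INDEL"))
})

test_that("SV validation filter enforces depth and quality bounds", {
  tab <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = "A", alt = c(rep("<DEL>", 5), "G"),
    var_class = c(rep("SV", 5), "SNP"),
    sv_type = c(rep("DEL", 5), NA), sv_end = c(1:5 * 1000L, NA),
    qual = c(30, 30, 15, 30, 21, 99))
  depth <- cbind(c(50, 150, 50, NA, 2, 60), c(40, 140, 40, NA, 1, 55))
  vs <- toy_variants(tab, matrix("1/1", 6, 2), depth = depth)
  expect_message(fl <- filterSV(vs), "rejected 3 SV")
  kept <- variantTable(fl$retained)
  expect_equal(kept$pos, c(100L, 500L, 600L))   # depth 2 is within 2-100
  expect_equal(fl$rejected$reason, c("depth", "quality", "no_depth"))
  # the SNP record passes through untouched
  expect_true("SNP" %in% kept$var_class)
})

test_that("variation summary aggregates per sample", {
  sim <- small_sim()
  eff <- annotateEffects(sim$variants, sim$models, sim$genome)
  vsum <- variationSummary(sim$variants, chromLengths(sim$genome), eff,
                           sim$models)
  for (s in c("lineA", "lineB")) {
    expect_gt(vsum$per_sample[[s]]$n[["SNP"]], 1000L)
    expect_gt(vsum$per_sample[[s]]$hom_fraction[["SNP"]], 0.8)
    expect_gt(vsum$nonsyn_syn[[s]][["ratio"]], 0)
  }
  expect_equal(sum(vsum$indel_spectrum$count),
               sum(variantTable(sim$variants)$var_class == "INDEL"))
})
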