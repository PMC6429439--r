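test_that("readFasta loads, uppercases and validates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", ">chr2", "NNAC"), fa)
  g <- readFasta(fa)
  expect_equal(names(g), c("chr1", "chr2"))
  expect_equal(as.character(g[["chr1"]]), "ACGT")
  expect_equal(as.character(g[["chr2"]]), "NNAC")
  expect_equal(unname(chromLengths(g)), c(4L, 4L))

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(readFasta(empty), "empty file")
  bad <- tempfile(fileext = ".fa")
  writeLines("ACGT", bad)
  expect_error(readFasta(bad), "line 1")
})

test_that("GFF3 reading keeps 1-based coordinates, strand and isoform policy", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\tsrc\tCDS\t101\t160\t.\t+\t0\tID=c1;Parent=gA.t1",
    "chr1\tsrc\tCDS\t201\t260\t.\t+\t0\tID=c2;Parent=gA.t1",
    "chr1\tsrc\tCDS\t301\t340\t.\t+\t0\tID=c3;Parent=gA.t2",
    "chr2\tsrc\tgene\t51\t350\t.\t-\t.\tID=gB",
    "chr2\tsrc\tmRNA\t51\t350\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr2\tsrc\tCDS\t201\t350\t.\t-\t0\tID=c4;Parent=gB.t1",
    "chr2\tsrc\tCDS\t51\t110\t.\t-\t2\tID=c5;Parent=gB.t1"), gff)
  expect_message(m <- readGeneModels(gff), "first isoform")
  expect_equal(length(m), 2L)
  segA <- cdsByGene(m)[["gA"]]
  expect_equal(GenomicRanges::start(segA), c(101L, 201L))   # t2 dropped
  segB <- cdsByGene(m)[["gB"]]
  # minus-strand segments stored in genomic order
  expect_equal(GenomicRanges::start(segB), c(51L, 201L))
  expect_equal(as.character(GenomicRanges::strand(segB)), c("-", "-"))

  orphan <- tempfile(fileext = ".gff3")
  writeLines(c("chr1\ts\tgene\t1\t50\t.\t+\t.\tID=g",
               "chr1\ts\tCDS\t10\t20\t.\t+\t0\tID=c;Parent=missing"),
             orphan)
  expect_warning(m2 <- readGeneModels(orphan), "without resolvable Parent")
  expect_equal(length(cdsByGene(m2)), 0L)

  rev <- tempfile(fileext = ".gff3")
  writeLines("chr1\ts\tgene\t50\t10\t.\t+\t.\tID=g", rev)
  expect_error(readGeneModels(rev), "end < start")
})

test_that("VCF records are left-normalized and classed", {
  vcf <- write_vcf_text(c(
    "chr1\t50\t.\tA\tG\t99\tPASS\t.\tGT:DP\t1/1:30\t0/1:28",
    "chr1\t101\t.\tCAC\tA\t99\tPASS\t.\tGT:DP\t0/1:30\t0/0:30",
    "chr1\t201\t.\tCAC\tC\t99\tPASS\t.\tGT:DP\t1/1:30\t1/1:30",
    "chr1\t300\t.\tA\t<DEL>\t45\tPASS\tSVTYPE=DEL;END=900\tGT:DP\t1/1:40\t1/1:41",
    "chr1\t400\t.\tG\tT,C\t99\tPASS\t.\tGT:DP\t1/2:30\t0/1:30",
    "chr1\t500\t.\tA\tG\t99\tPASS\t.\tGT:DP\t./.:.\t./.:."))
  expect_message(vs <- readVariants(vcf, c("S1", "S2")), "all-missing")
  tb <- variantTable(vs)
  expect_equal(nrow(tb), 5L)        # fully missing record dropped

  expect_equal(tb$var_class[tb$pos == 50], "SNP")
  expect_equal(classifyZygosity(vs, "S1")[tb$pos == 50], "hom_alt")

  # REF=CAC ALT=A shares no context: stays put, net 2-bp deletion
  r2 <- tb[tb$pos == 101, ]
  expect_equal(r2$var_class, "INDEL")
  expect_equal(nchar(r2$ref) - nchar(r2$alt), 2L)

  # REF=CAC ALT=C: anchor stripped, pos advanced, deletion of "AC"
  r3 <- tb[tb$ref == "AC", ]
  expect_equal(r3$pos, 202L)
  expect_equal(r3$alt, "")
  expect_equal(r3$var_class, "INDEL")

  r4 <- tb[tb$var_class == "SV", ]
  expect_equal(r4$sv_type, "DEL")
  expect_equal(r4$sv_end, 900L)

  r5 <- tb[tb$pos == 400, ]         # multi-allelic kept as one record
  expect_equal(r5$alt, "T,C")

  expect_error(readVariants(vcf, c("S1", "nope")), "configuration error")
})

test_that("indels longer than 30 bp are routed to SV", {
  long_del <- paste(rep("A", 32), collapse = "")
  vcf <- write_vcf_text(sprintf(
    "chr1\t10\t.\tG%s\tG\t99\tPASS\t.\tGT:DP\t1/1:30\t1/1:30", long_del))
  vs <- readVariants(vcf, c("S1", "S2"))
  expect_equal(variantTable(vs)$var_class, "SV")
  expect_equal(variantTable(vs)$sv_type, "DEL")
})

test_that("BED output is 0-based half-open and sorted", {
  bed <- tempfile(fileext = ".bed")
  writeBed(data.frame(chrom = c("chr2", "chr1"),
                      start = c(101, 101), end = c(200, 200)), bed)
  expect_equal(readLines(bed),
               c("chr1\t100\t200", "chr2\t100\t200"))
  writeBed(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)), bed)
  expect_equal(length(readLines(bed)), 0L)
})

test_that("TSV output has a header and deterministic order", {
  tsv <- tempfile(fileext = ".tsv")
  writeTsv(data.frame(chrom = c("chr2", "chr1"), pos = c(5L, 9L),
                      x = c("b", "a")), tsv)
  got <- read.delim(tsv)
  expect_equal(got$chrom, c("chr1", "chr2"))
  expect_equal(names(got), c("chrom", "pos", "x"))
})

test_that("generated FASTA/GFF3/VCF round-trip through the readers", {
  sim <- small_sim_dir()
  g2 <- readFasta(sim$paths$fasta)
  expect_identical(as.character(g2), as.character(sim$genome))

  m2 <- readGeneModels(sim$paths$gff3)
  expect_equal(length(m2), length(sim$models))
  for (gid in names(cdsByGene(sim$models))) {
    a <- as.data.frame(cdsByGene(sim$models)[[gid]])
    b <- as.data.frame(cdsByGene(m2)[[gid]])
    expect_equal(a[c("start", "end", "strand")],
                 b[c("start", "end", "strand")])
  }

  vs2 <- readVariants(sim$paths$vcf, sampleNames(sim$variants))
  t_mem <- variantTable(sim$variants); t_file <- variantTable(vs2)
  rownames(t_mem) <- rownames(t_file) <- NULL
  expect_equal(t_mem, t_file, ignore_attr = TRUE)
  expect_identical(unname(genotypes(sim$variants)),
                   unname(genotypes(vs2)))
})

test_that("GFF3 reader agrees with an independent GFF3 parser", {
  skip_if_not_installed("rtracklayer")
  sim <- small_sim_dir()
  ours <- readGeneModels(sim$paths$gff3)
  ref <- rtracklayer::import(sim$paths$gff3)
  ref_cds <- ref[ref$type == "CDS"]
  ours_cds <- unlist(cdsByGene(ours), use.names = FALSE)
  expect_equal(length(ref_cds), length(ours_cds))
  key <- function(gr) sort(paste(GenomeInfoDb::seqnames(gr),
                                 GenomicRanges::start(gr),
                                 GenomicRanges::end(gr),
                                 GenomicRanges::strand(gr)))
  expect_identical(key(ref_cds), key(ours_cds))
  ref_genes <- ref[ref$type == "gene"]
  gt <- geneTable(ours)
  expect_setequal(gt$gene_id, ref_genes$ID)
  m <- match(gt$gene_id, ref_genes$ID)
  expect_equal(gt$start, GenomicRanges::start(ref_genes)[m])
  expect_equal(gt$end, GenomicRanges::end(ref_genes)[m])
})

test_that("SNP records agree with the reference genome they were drawn from", {
  sim <- small_sim()
  chk <- checkReferenceAgreement(sim$variants, sim$genome)
  expect_gt(chk$n_checked, 1000L)
  expect_equal(chk$n_mismatch, 0L)

  # a corrupted record is counted and reported
  vs <- sim$variants
  tb <- variantTable(vs)
  i <- which(tb$var_class == "SNP")[1]
  tb$ref[i] <- setdiff(c("A", "C", "G", "T"), tb$ref[i])[1]
  bad <- VariantSet(tb, genotypes(vs), sampleNames(vs))
  expect_warning(chk2 <- checkReferenceAgreement(bad, sim$genome),
                 "disagree")
  expect_equal(chk2$n_mismatch, 1L)
  expect_equal(chk2$mismatch_rows, i)
})
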