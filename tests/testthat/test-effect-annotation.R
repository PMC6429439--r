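test_that("spliceCds concatenates segments in transcription order", {
  tg <- toy_gene("ATGCCCAAA", data.frame(start = c(1, 7), end = c(3, 9)))
  expect_equal(spliceCds("g1", tg$models, tg$genome), "ATGAAA")

  # palindromic control: reverse complement of ATGCAT is ATGCAT
  tgm <- toy_gene("ATGCAT", data.frame(start = 1, end = 6), strand = "-")
  expect_equal(spliceCds("g1", tgm$models, tgm$genome), "ATGCAT")

  # a genuinely asymmetric minus-strand gene
  tgm2 <- toy_gene("TTACAT", data.frame(start = 1, end = 6), strand = "-")
  expect_equal(spliceCds("g1", tgm2$models, tgm2$genome), "ATGTAA")

  tg3 <- toy_gene("ATGCC", data.frame(start = 1, end = 5))
  expect_warning(cds <- spliceCds("g1", tg3$models, tg3$genome),
                 "not divisible by 3")
  expect_true(attr(cds, "frame_warning"))

  tg4 <- toy_gene("ATGCCC", data.frame(start = 1, end = 9),
                  gene_span = c(1, 9))
  expect_error(spliceCds("g1", tg4$models, tg4$genome), "coordinate error")
})

test_that("translation uses the standard code and stops at the first stop", {
  expect_equal(translateCds("ATGTAA"), "M")
  expect_equal(translateCds("ATGGCCTAA"), "MA")
  expect_equal(translateCds("ATGTAAGGG"), "M")      # internal stop wins
  expect_equal(translateCds("ATGANGTAA"), "MX")     # N codon -> X
  expect_error(translateCds("AT"), "shorter")
})

test_that("a 1098-nt open reading frame translates to 365 residues", {
  orf <- random_orf(366L, seed = 3L)
  expect_equal(nchar(orf), 1098L)
  prot <- translateCds(orf)
  expect_equal(nchar(prot), 365L)
  expect_equal(nchar(prot), 1098L / 3L - 1L)
})

test_that("region classification distinguishes intergenic, intron, CDS", {
  # gene span 101-400 with CDS 101-160 and 201-260
  seq <- paste(rep("A", 500), collapse = "")
  tg <- toy_gene(seq, data.frame(start = c(101, 201), end = c(160, 260)),
                 gene_span = c(101, 400))
  vs <- toy_variants(
    data.frame(chrom = "chr1", pos = c(50L, 150L, 180L, 350L),
               ref = "A", alt = "G", var_class = "SNP"),
    matrix("0/1", 4, 2))
  reg <- classifyRegion(vs, tg$models)
  expect_equal(reg$region_class[reg$variant == 1], "intergenic")
  expect_equal(reg$region_class[reg$variant == 2], "genic_cds")
  expect_equal(reg$region_class[reg$variant == 3], "genic_intron")
  expect_equal(reg$region_class[reg$variant == 4], "genic_intron")
})

test_that("SNP consequences follow the genetic code, codon-locally", {
  # ATG GCC TAC TGG TAA ; protein M A Y W
  tg <- toy_gene("ATGGCCTACTGGTAA", data.frame(start = 1, end = 15))
  snp <- function(pos, ref, alt) toy_variants(
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               var_class = "SNP"), matrix("1/1", 1, 2))
  cons <- function(pos, ref, alt) {
    e <- annotateEffects(snp(pos, ref, alt), tg$models, tg$genome)
    e[e$region_class == "genic_cds", c("consequence", "aa_change")]
  }
  expect_equal(cons(6, "C", "T")$consequence, "synonymous")   # GCC->GCT
  r <- cons(4, "G", "A")                                      # GCC->ACC
  expect_equal(r$consequence, "nonsynonymous")
  expect_equal(r$aa_change, "p.Ala2Thr")
  expect_equal(cons(9, "C", "A")$consequence, "stopgain")     # TAC->TAA
  expect_equal(cons(13, "T", "C")$consequence, "stop_lost")   # TAA->CAA
  expect_equal(cons(15, "A", "G")$consequence, "synonymous")  # TAA->TAG
  expect_equal(cons(2, "T", "C")$consequence, "start_lost")   # ATG->ACG
  # reference mismatch is an integrity error naming the position
  expect_error(cons(6, "G", "T"), "integrity error.*chr1:6")
})

test_that("multi-allelic records take the most severe consequence", {
  tg <- toy_gene("ATGGCCTACTGGTAA", data.frame(start = 1, end = 15))
  vs <- toy_variants(
    data.frame(chrom = "chr1", pos = 9L, ref = "C", alt = "T,A",
               var_class = "SNP"), matrix("1/2", 1, 2))
  e <- annotateEffects(vs, tg$models, tg$genome)
  # TAC->TAT synonymous, TAC->TAA stopgain; stopgain wins
  expect_equal(e$consequence[e$region_class == "genic_cds"], "stopgain")
})

test_that("indel consequences: frameshift, in-frame, boundary flag", {
  orf <- random_orf(40L, seed = 9L)            # 120 nt, one exon
  tg <- toy_gene(orf, data.frame(start = 1, end = 120))
  indel <- function(pos, ref, alt) toy_variants(
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               var_class = "INDEL"), matrix("1/1", 1, 2))
  eff <- function(pos, ref, alt) {
    e <- annotateEffects(indel(pos, ref, alt), tg$models, tg$genome)
    e[e$region_class == "genic_cds", ]
  }
  del2 <- substr(orf, 10, 11)
  e1 <- eff(10L, del2, "")
  expect_equal(e1$consequence, "frameshift")
  expect_equal(e1$net_len, -2L)
  e2 <- eff(10L, substr(orf, 10, 12), "")
  expect_equal(e2$consequence, "codon_deletion")
  e3 <- eff(10L, "", "GGG")
  expect_equal(e3$consequence, "codon_insertion")

  # two-exon gene: deletion across the splice boundary
  seq2 <- paste0(substr(orf, 1, 60),
                 "GTAAGTCCCTTTAG",                # fake intron
                 substr(orf, 61, 120))
  tg2 <- toy_gene(seq2, data.frame(start = c(1, 75), end = c(60, 134)))
  vs <- toy_variants(
    data.frame(chrom = "chr1", pos = 58L,
               ref = substr(seq2, 58, 63), alt = "",
               var_class = "INDEL"), matrix("1/1", 1, 2))
  e4 <- annotateEffects(vs, tg2$models, tg2$genome)
  e4 <- e4[e4$region_class == "genic_cds", ]
  expect_equal(e4$consequence, "frameshift")
  expect_true(e4$boundary)
})

test_that("frameshift truncation is reported from re-translation", {
  # 366-codon ORF engineered so deleting the first base of codon 289
  # (CTA AAA -> TAA ...) truncates the 365-residue protein by 77
  orf <- random_orf(366L, seed = 42L)
  substr(orf, 865, 870) <- "CTAAAA"
  tg <- toy_gene(orf, data.frame(start = 1, end = 1098))
  expect_equal(nchar(translateCds(orf)), 365L)

  chk <- oracle_for_gene(list(genome = tg$genome, models = tg$models),
                         "g1", 865L, "C", "")
  expect_equal(chk$consequence, "frameshift")
  expect_equal(chk$truncation, 77L)

  vs <- toy_variants(
    data.frame(chrom = "chr1", pos = 865L, ref = "C", alt = "",
               var_class = "INDEL"), matrix("1/1", 1, 2))
  e <- annotateEffects(vs, tg$models, tg$genome)
  e <- e[e$region_class == "genic_cds", ]
  expect_equal(e$consequence, "frameshift")
  expect_equal(e$truncation, 77L)
  expect_equal(e$new_protein_len, 288L)
})

test_that("SV consequences require CDS contact", {
  seq <- paste(rep("ACGT", 250), collapse = "")
  tg <- toy_gene(seq, data.frame(start = c(201, 301), end = c(260, 330)),
                 gene_span = c(150, 400))
  sv <- function(pos, end, type) toy_variants(
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "<DEL>",
               var_class = "SV", sv_type = type, sv_end = end),
    matrix("1/1", 1, 2))
  res <- function(pos, end, type) {
    e <- annotateEffects(sv(pos, end, type), tg$models, tg$genome)
    e[!is.na(e$gene_id), "consequence"]
  }
  expect_equal(res(100, 500, "DEL"), "sv_cds_overlap")
  expect_equal(res(262, 298, "INV"), "none")        # intron only
  # translocation: only breakpoints count, span in between does not
  expect_equal(res(220, 700, "CTX"), "sv_cds_overlap")
  expect_equal(res(270, 290, "CTX"), "none")
})

test_that("engine agrees with the re-translation oracle on planted variants", {
  sim <- small_sim()
  eff <- annotateEffects(sim$variants, sim$models, sim$genome)
  tv <- sim$truth$variants
  planted <- which(tv$origin %in% c("candidate", "decoy", "effect_mix") &
                     tv$var_class != "SV")
  expect_gt(length(planted), 250L)
  ekey <- paste(eff$chrom, eff$pos, eff$alt)
  m <- match(paste(tv$chrom, tv$pos, tv$alt)[planted], ekey)
  expect_false(anyNA(m))
  for (k in seq_along(planted)) {
    i <- planted[k]
    orc <- oracle_for_gene(sim, tv$gene_id[i], tv$pos[i], tv$ref[i],
                           tv$alt[i])
    expect_equal(eff$consequence[m[k]], orc$consequence,
                 info = sprintf("%s:%d %s>%s", tv$chrom[i], tv$pos[i],
                                tv$ref[i], tv$alt[i]))
  }
})

test_that("classification is strand-symmetric", {
  # the same locus rebuilt on the opposite strand yields the same calls
  orf <- random_orf(60L, seed = 5L)            # 180 nt
  pad <- paste(rep("T", 20), collapse = "")
  fwd_seq <- paste0(pad, orf, pad)
  rev_seq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd_seq)))
  tg_f <- toy_gene(fwd_seq, data.frame(start = 21, end = 200))
  tg_r <- toy_gene(rev_seq, data.frame(start = 21, end = 200),
                   strand = "-")
  expect_equal(spliceCds("g1", tg_f$models, tg_f$genome),
               spliceCds("g1", tg_r$models, tg_r$genome))
  L <- nchar(fwd_seq)
  for (pos in c(30L, 55L, 103L, 188L)) {
    ref_f <- substr(fwd_seq, pos, pos)
    alt_f <- setdiff(c("A", "C", "G", "T"), ref_f)[1]
    vf <- toy_variants(data.frame(chrom = "chr1", pos = pos, ref = ref_f,
                                  alt = alt_f, var_class = "SNP"),
                       matrix("1/1", 1, 2))
    pos_r <- L - pos + 1L
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    vr <- toy_variants(data.frame(chrom = "chr1", pos = pos_r,
                                  ref = unname(comp[ref_f]),
                                  alt = unname(comp[alt_f]),
                                  var_class = "SNP"),
                       matrix("1/1", 1, 2))
    ef <- annotateEffects(vf, tg_f$models, tg_f$genome)
    er <- annotateEffects(vr, tg_r$models, tg_r$genome)
    expect_equal(ef$consequence[ef$region_class == "genic_cds"],
                 er$consequence[er$region_class == "genic_cds"],
                 info = paste("pos", pos))
  }
})
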