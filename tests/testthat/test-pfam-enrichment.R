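# direct-formula 2x2 chi-squared oracle: sum (O - E)^2 / E
chi2_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2 <- sum((m - E)^2 / E)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

test_that("SNP-to-domain mapping uses integer residue arithmetic", {
  eff <- data.frame(variant = 1:3, gene_id = "g1",
                    region_class = "genic_cds", var_class = "SNP",
                    cds_pos = c(0L, 35L, 15L),
                    consequence = c("nonsynonymous", "synonymous",
                                    "nonsynonymous"))
  dom <- data.frame(gene_id = "g1",
                    family = c("FamA", "FamB"),
                    aa_start = c(1L, 10L), aa_end = c(5L, 20L))
  hits <- mapSnpToDomains(eff, dom)
  # cds_pos 0 -> residue 1 (FamA); 35 -> residue 12 (FamB);
  # 15 -> residue 6, outside both FamA (1-5) and ... inside FamB? no (10-20)
  expect_equal(hits$residue[hits$variant == 1], 1L)
  expect_equal(hits$family[hits$variant == 1], "FamA")
  expect_equal(hits$residue[hits$variant == 2], 12L)
  expect_equal(hits$family[hits$variant == 2], "FamB")
  expect_false(3 %in% hits$variant)   # residue 6 hits no interval

  # overlapping intervals of one family count once
  dom2 <- data.frame(gene_id = "g1", family = "FamA",
                     aa_start = c(1L, 1L), aa_end = c(5L, 8L))
  hits2 <- mapSnpToDomains(eff[1, ], dom2)
  expect_equal(nrow(hits2), 1L)
})

test_that("chi-squared matches the closed-form oracle", {
  m <- rbind(c(40, 20), c(73735, 86005))
  orc <- chi2_oracle(m)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(unname(ct$statistic), orc$chi2, tolerance = 1e-9)
  expect_equal(unname(ct$p.value), orc$p, tolerance = 1e-9)

  # through the enrichment surface: one family with exactly these counts
  # rest-of-genome row of the 2x2 is exactly [73735, 86005]
  n_rest <- 73735 + 86005
  eff <- data.frame(
    variant = seq_len(60 + n_rest),
    gene_id = c(rep("gFam", 60), rep("gBg", n_rest)),
    region_class = "genic_cds", var_class = "SNP",
    cds_pos = c(rep(3L, 60), rep(3000L, n_rest)),
    consequence = c(rep("nonsynonymous", 40), rep("synonymous", 20),
                    rep("nonsynonymous", 73735),
                    rep("synonymous", 86005)))
  dom <- data.frame(gene_id = "gFam", family = "FamX",
                    aa_start = 1L, aa_end = 10L)
  enr <- domainEnrichment(eff, dom)
  expect_equal(enr$n_nonsyn, 40L)
  expect_equal(enr$n_syn, 20L)
  expect_equal(enr$chi2, orc$chi2, tolerance = 1e-9)
  expect_equal(enr$p_value, orc$p, tolerance = 1e-9)
  expect_true(enr$flagged)          # 60 > 30 and ratio 2 > 0.6
  # p ~ 0.0014: above the 0.001 default, below a 0.01 level
  expect_false(enr$significant)
  expect_true(domainEnrichment(eff, dom, alpha = 0.01)$significant)
})

test_that("a family proportional to background is not enriched", {
  # family nonsyn/syn 10/20 equals background 100/200
  eff <- data.frame(
    variant = 1:300, gene_id = c(rep("gA", 30), rep("gB", 270)),
    region_class = "genic_cds", var_class = "SNP",
    cds_pos = c(rep(3L, 30), rep(3000L, 270)),
    consequence = c(rep("nonsynonymous", 10), rep("synonymous", 20),
                    rep("nonsynonymous", 90), rep("synonymous", 180)))
  dom <- data.frame(gene_id = "gA", family = "Fam",
                    aa_start = 1L, aa_end = 10L)
  enr <- domainEnrichment(eff, dom)
  expect_lt(enr$chi2, 1e-9)
  expect_gt(enr$p_value, 0.999)
  expect_false(enr$flagged)   # ratio 0.5 < 0.6
})

test_that("flagging thresholds and sentinels behave at the edges", {
  mk_eff <- function(n_non, n_syn, bg_non = 500, bg_syn = 500) {
    data.frame(
      variant = seq_len(n_non + n_syn + bg_non + bg_syn),
      gene_id = c(rep("gA", n_non + n_syn), rep("gB", bg_non + bg_syn)),
      region_class = "genic_cds", var_class = "SNP",
      cds_pos = c(rep(3L, n_non + n_syn), rep(3000L, bg_non + bg_syn)),
      consequence = c(rep("nonsynonymous", n_non), rep("synonymous", n_syn),
                      rep("nonsynonymous", bg_non), rep("synonymous", bg_syn)))
  }
  dom <- data.frame(gene_id = "gA", family = "Fam", aa_start = 1L,
                    aa_end = 10L)
  # 31 + 1 = 32 > 30 and ratio 31 > 0.6: flagged
  expect_true(domainEnrichment(mk_eff(31, 1), dom)$flagged)
  # combined 30 is not > 30
  expect_false(domainEnrichment(mk_eff(29, 1), dom)$flagged)
  # strict mode needs each count above the threshold
  expect_false(domainEnrichment(mk_eff(31, 1), dom, strict = TRUE)$flagged)
  expect_true(domainEnrichment(mk_eff(40, 31), dom, strict = TRUE)$flagged)
  # zero margin: chi2/p undefined, never flagged as significant
  e0 <- mk_eff(0, 0)
  enr0 <- domainEnrichment(e0, dom)
  expect_true(is.na(enr0$chi2) || enr0$n_nonsyn + enr0$n_syn == 0)
  expect_false(enr0$significant)
  # Bonferroni multiplies p across families
  dom2 <- rbind(dom, data.frame(gene_id = "gA", family = "Fam2",
                                aa_start = 11L, aa_end = 20L))
  enr_b <- domainEnrichment(mk_eff(31, 1), dom2, bonferroni = TRUE)
  raw <- domainEnrichment(mk_eff(31, 1), dom2)
  f <- enr_b$family == "Fam"
  expect_equal(enr_b$significant[f],
               raw$p_value[f] * 2 < 0.001)
})

test_that("enrichment runs end to end on the simulated study", {
  sim <- small_sim()
  eff <- annotateEffects(sim$variants, sim$models, sim$genome)
  enr <- domainEnrichment(eff, sim$domains)
  expect_true(all(enr$n_nonsyn >= 0 & enr$n_syn >= 0))
  expect_setequal(enr$family, unique(sim$domains$family))
  # ranked by ratio then chi2
  r <- ifelse(is.na(enr$ratio), -Inf, enr$ratio)
  expect_true(all(diff(r) <= 1e-12, na.rm = TRUE))
})
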