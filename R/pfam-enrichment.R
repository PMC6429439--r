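#' Read a protein-domain annotation table
#'
#' @param path TSV with columns `gene_id`, `family`, `aa_start`,
#'   `aa_end` (1-based inclusive protein coordinates)
#' @return data.frame
#' @export
readDomainTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "family", "aa_start", "aa_end")
  if (!all(need %in% names(tab)))
    .stopf("domain table must have columns %s", paste(need, collapse = ", "))
  if (any(tab$aa_start < 1L | tab$aa_end < tab$aa_start))
    .stopf("domain table format error: invalid protein interval")
  tab
}

#' Map coding SNPs to protein-domain families
#'
#' The affected residue of a CDS SNP is `cds_pos %/% 3 + 1` (1-based);
#' a SNP hits a family when the residue lies inside any of the family's
#' intervals on that gene. SNPs hitting several intervals of one family
#' count once per family.
#'
#' @param effects result of [annotateEffects()]
#' @param domains data.frame from [readDomainTable()]
#' @param protein_lengths optional named vector of protein lengths used
#'   to warn when a residue index exceeds the protein
#' @return data.frame with columns `variant`, `gene_id`, `family`,
#'   `residue`, `consequence`
#' @export
mapSnpToDomains <- function(effects, domains, protein_lengths = NULL) {
  cds <- effects[effects$region_class == "genic_cds" &
                   effects$var_class == "SNP" &
                   !is.na(effects$cds_pos), , drop = FALSE]
  if (nrow(cds) == 0L)
    return(data.frame(variant = integer(0), gene_id = character(0),
                      family = character(0), residue = integer(0),
                      consequence = character(0)))
  cds$residue <- cds$cds_pos %/% 3L + 1L
  if (!is.null(protein_lengths)) {
    pl <- protein_lengths[cds$gene_id]
    over <- !is.na(pl) & cds$residue > pl
    if (any(over))
      .warnf("%d SNP residue(s) beyond annotated protein length", sum(over))
  }
  hit <- merge(cds[, c("variant", "gene_id", "residue", "consequence")],
               domains, by = "gene_id")
  hit <- hit[hit$residue >= hit$aa_start & hit$residue <= hit$aa_end, ,
             drop = FALSE]
  unique(hit[, c("variant", "gene_id", "family", "residue", "consequence")])
}

# closed-form 2x2 chi-squared without continuity correction (also used
# as sentinel source when a margin is zero)
.chi2_2x2 <- function(m) {
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(chi2 = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Per-family nonsynonymous/synonymous SNP enrichment
#'
#' For every domain family, counts nonsynonymous and synonymous CDS
#' SNPs whose affected residue lies inside the family's intervals, and
#' tests the family's nonsyn/syn split against the rest of the
#' genome-wide CDS background with a 2x2 chi-squared statistic (1 df,
#' no continuity correction). A family is `flagged` when its combined
#' SNP count exceeds `min_total` and its nonsyn/syn ratio exceeds
#' `min_ratio` (with `strict = TRUE`, each count must exceed
#' `min_total` instead). `significant` marks p < `alpha`
#' (Bonferroni-adjusted when `bonferroni = TRUE`).
#'
#' @param effects result of [annotateEffects()]
#' @param domains data.frame from [readDomainTable()]
#' @param min_total combined-count threshold (exclusive)
#' @param min_ratio nonsyn/syn ratio threshold (exclusive)
#' @param strict require each count, not the sum, to exceed `min_total`
#' @param alpha significance level for `significant`
#' @param bonferroni apply Bonferroni correction across families
#' @return data.frame ranked by ratio then chi-squared, with columns
#'   `family`, `n_nonsyn`, `n_syn`, `ratio`, `chi2`, `p_value`,
#'   `flagged`, `significant`
#' @export
domainEnrichment <- function(effects, domains, min_total = 30L,
                             min_ratio = 0.6, strict = FALSE,
                             alpha = 0.001, bonferroni = FALSE) {
  cds <- effects[effects$region_class == "genic_cds" &
                   effects$var_class == "SNP", , drop = FALSE]
  bg_nonsyn <- sum(cds$consequence == "nonsynonymous")
  bg_syn <- sum(cds$consequence == "synonymous")
  hits <- mapSnpToDomains(effects, domains)
  fams <- sort(unique(domains$family))
  rows <- lapply(fams, function(fam) {
    h <- hits[hits$family == fam, , drop = FALSE]
    n_non <- sum(h$consequence == "nonsynonymous")
    n_syn <- sum(h$consequence == "synonymous")
    m <- rbind(c(n_non, n_syn),
               c(bg_nonsyn - n_non, bg_syn - n_syn))
    ch <- .chi2_2x2(m)
    ratio <- if (n_syn > 0) n_non / n_syn
      else if (n_non > 0) Inf else NA_real_
    flagged <- if (strict) n_non > min_total && n_syn > min_total
      else (n_non + n_syn) > min_total
    flagged <- flagged && !is.na(ratio) && ratio > min_ratio
    data.frame(family = fam, n_nonsyn = n_non, n_syn = n_syn,
               ratio = ratio,
               chi2 = ch$chi2, p_value = ch$p, flagged = flagged)
  })
  out <- do.call(rbind, rows)
  p_adj <- if (bonferroni) pmin(1, out$p_value * nrow(out)) else out$p_value
  out$significant <- !is.na(p_adj) & p_adj < alpha
  out[order(-ifelse(is.na(out$ratio), -Inf, out$ratio),
            -ifelse(is.na(out$chi2), -Inf, out$chi2)), , drop = FALSE]
}
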