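#' Consequence classes that qualify a gene as a candidate
#'
#' Protein-altering classes: nonsynonymous, stop gain/loss, start loss,
#' frameshift, in-frame codon deletion/insertion and structural-variant
#' CDS overlap. Synonymous and non-coding calls never qualify.
#'
#' @return character vector of consequence names
#' @export
qualifyingConsequences <- function() {
  c("nonsynonymous", "stopgain", "stop_lost", "start_lost", "frameshift",
    "codon_deletion", "codon_insertion", "sv_cds_overlap")
}

#' Select candidate genes carrying protein-altering variants
#'
#' A gene is a candidate when it carries at least one qualifying
#' consequence (see [qualifyingConsequences()]) in at least one sample
#' (a sample carries a variant when its genotype includes an alternate
#' allele). With `require_difference = TRUE` the gene's qualifying
#' variant sets must additionally differ between the two samples.
#' `prior_match` marks candidates found in a user-supplied
#' prior-knowledge list, matched by exact gene id or case-insensitive
#' keyword against the gene id.
#'
#' @param effects result of [annotateEffects()]
#' @param vs the `VariantSet` the effects were computed from
#' @param models a `GeneModels` (for positions)
#' @param prior_list optional character vector of gene ids/keywords
#' @param require_difference keep only genes whose qualifying variant
#'   sets differ between the two samples
#' @return data.frame ordered by (chrom, position): `gene_id`, `chrom`,
#'   `start`, `pos_mb`, `n_evidence`, `consequences`,
#'   `differs_between_samples`, `prior_match`, and per-sample
#'   hom/het evidence counts
#' @export
selectCandidates <- function(effects, vs, models, prior_list = NULL,
                             require_difference = FALSE) {
  if (is.null(prior_list) || length(prior_list) == 0L) {
    if (!is.null(prior_list))
      .warnf("empty prior gene list: prior_match will be FALSE throughout")
    prior_list <- character(0)
  }
  samples <- sampleNames(vs)
  stopifnot(length(samples) == 2L)
  qual <- effects[!is.na(effects$gene_id) &
                    effects$consequence %in% qualifyingConsequences(), ,
                  drop = FALSE]
  zyg <- vapply(samples, function(s) classifyZygosity(vs, s),
                character(nVariants(vs)))
  zyg <- matrix(zyg, nrow = nVariants(vs), ncol = 2L)
  carries <- matrix(zyg %in% c("hom_alt", "het"), nrow = nrow(zyg))
  gt <- geneTable(models)
  out <- list()
  for (gid in unique(qual$gene_id)) {
    ev <- qual[qual$gene_id == gid, , drop = FALSE]
    in_a <- carries[ev$variant, 1L]
    in_b <- carries[ev$variant, 2L]
    if (!any(in_a | in_b)) next
    key <- paste(ev$chrom, ev$pos, ev$alt)
    set_a <- sort(key[in_a]); set_b <- sort(key[in_b])
    differs <- !identical(set_a, set_b)
    if (require_difference && !differs) next
    g <- gt[gt$gene_id == gid, ]
    zyg_counts <- vapply(seq_along(samples), function(j) {
      z <- zyg[ev$variant, j]
      c(sum(z == "hom_alt"), sum(z == "het"))
    }, numeric(2))
    row <- data.frame(
      gene_id = gid, chrom = g$chrom, start = g$start,
      pos_mb = round(g$start / 1e6, 3),
      n_evidence = sum(in_a | in_b),
      consequences = paste(sort(unique(ev$consequence)), collapse = ","),
      differs_between_samples = differs,
      prior_match = gid %in% prior_list ||
        any(vapply(prior_list, function(k)
          grepl(k, gid, ignore.case = TRUE, fixed = FALSE), logical(1))))
    row[[paste0("hom_", samples[1])]] <- zyg_counts[1, 1]
    row[[paste0("het_", samples[1])]] <- zyg_counts[2, 1]
    row[[paste0("hom_", samples[2])]] <- zyg_counts[1, 2]
    row[[paste0("het_", samples[2])]] <- zyg_counts[2, 2]
    out[[gid]] <- row
  }
  if (!length(out)) {
    res <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), pos_mb = numeric(0),
                      n_evidence = integer(0), consequences = character(0),
                      differs_between_samples = logical(0),
                      prior_match = logical(0))
    return(res)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Per-chromosome physical-map table of candidate genes
#'
#' @param candidates result of [selectCandidates()]
#' @return list with `counts` (named integer vector per chromosome) and
#'   `genes` (data.frame `chrom`, `gene_id`, `pos_mb` ordered by
#'   chromosome and position)
#' @export
physicalMapTable <- function(candidates) {
  if (nrow(candidates) == 0L)
    return(list(counts = integer(0),
                genes = data.frame(chrom = character(0),
                                   gene_id = character(0),
                                   pos_mb = numeric(0))))
  ord <- order(candidates$chrom, candidates$start)
  genes <- candidates[ord, c("chrom", "gene_id", "pos_mb")]
  rownames(genes) <- NULL
  counts <- table(candidates$chrom)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       genes = genes)
}
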