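#' Consequence call by full re-translation
#'
#' The reference route of the consequence engine: instead of codon-local
#' reasoning it rebuilds the entire mutant coding sequence (applying the
#' variant to the genomic sequence and re-splicing with shifted exon
#' coordinates), translates reference and mutant proteins, and derives
#' the consequence from the protein diff. Used by the simulator to
#' verify every planted CDS variant at generation time and by the test
#' suite to cross-check the codon-local engine.
#'
#' The variant must lie entirely within one CDS segment of the gene.
#'
#' @param chrom,pos,ref,alt one normalized variant (1-based `pos`;
#'   `ref`/`alt` may be empty strings for pure insertions/deletions)
#' @param gene_id gene to evaluate against
#' @param models a `GeneModels`
#' @param genome `DNAStringSet`
#' @param ctx optional precomputed gene context (internal, for speed)
#' @return list with `consequence`, `new_protein_len`, `truncation`
#' @export
bruteForceConsequence <- function(chrom, pos, ref, alt, gene_id, models,
                                  genome, ctx = NULL) {
  if (is.null(ctx)) ctx <- .gene_ctx(gene_id, models, genome)
  if (ctx$chrom != chrom)
    .stopf("variant chromosome %s does not match gene %s", chrom, gene_id)
  ref_prot <- translateCds(ctx$cds)
  net <- nchar(alt) - nchar(ref)
  mutant <- .mutant_cds(ctx, pos, ref, alt)
  if (is.null(mutant))
    .stopf("variant at %s:%d spans a splice boundary of %s", chrom, pos,
           gene_id)
  mut_prot <- if (nchar(mutant) >= 3L) translateCds(mutant) else ""
  new_len <- nchar(mut_prot)
  trunc <- nchar(ref_prot) - new_len
  cons <- if (net != 0L) {
    if (net %% 3L != 0L) "frameshift"
    else if (net < 0L) "codon_deletion" else "codon_insertion"
  } else if (mut_prot == ref_prot) {
    "synonymous"
  } else if (startsWith(ctx$cds, "ATG") && !startsWith(mutant, "ATG")) {
    "start_lost"
  } else if (new_len < nchar(ref_prot)) {
    "stopgain"
  } else if (new_len > nchar(ref_prot)) {
    "stop_lost"
  } else {
    "nonsynonymous"
  }
  list(consequence = cons, new_protein_len = new_len, truncation = trunc)
}
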