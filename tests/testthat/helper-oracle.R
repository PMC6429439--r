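# Independent translate-and-diff oracle used to cross-check the
# consequence engine. Deliberately written from scratch: it edits the
# raw chromosome string, re-derives the exon layout arithmetically and
# translates with Biostrings, sharing no code path with the package's
# codon-local engine or its CDS rebuilder.

oracle_translate <- function(nt) {
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
  if (nchar(nt) < 3L) return("")
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(nt),
                          no.init.codon = TRUE, if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) substr(aa, 1L, stop_at - 1L) else aa
}

oracle_revcomp <- function(nt)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))

# Splice a CDS out of a chromosome string given exon start/end pairs.
oracle_splice <- function(chrom_seq, starts, ends, strand) {
  parts <- mapply(substr, starts, ends,
                  MoreArgs = list(x = chrom_seq), SIMPLIFY = TRUE)
  out <- paste(parts, collapse = "")
  if (strand == "-") oracle_revcomp(out) else out
}

# Consequence of one variant (1-based pos; ref/alt possibly empty) on a
# gene given as exon coordinates, by full re-translation.
oracle_consequence <- function(chrom_seq, starts, ends, strand,
                               pos, ref, alt) {
  ref_cds <- oracle_splice(chrom_seq, starts, ends, strand)
  ref_prot <- oracle_translate(ref_cds)
  # edit the chromosome
  before <- substr(chrom_seq, 1L, pos - 1L)
  after <- substr(chrom_seq, pos + nchar(ref), nchar(chrom_seq))
  mut_seq <- paste0(before, alt, after)
  net <- nchar(alt) - nchar(ref)
  # shift exon coordinates lying after the edited point
  edit_end <- pos + max(nchar(ref) - 1L, 0L)
  s2 <- ifelse(starts > edit_end, starts + net, starts)
  e2 <- ifelse(ends >= edit_end, ends + net, ends)
  mut_cds <- oracle_splice(mut_seq, s2, e2, strand)
  mut_prot <- oracle_translate(mut_cds)
  cons <- if (net != 0L) {
    if (net %% 3L != 0L) "frameshift"
    else if (net < 0L) "codon_deletion" else "codon_insertion"
  } else if (mut_prot == ref_prot) {
    "synonymous"
  } else if (substr(ref_cds, 1L, 3L) == "ATG" &&
             substr(mut_cds, 1L, 3L) != "ATG") {
    "start_lost"
  } else if (nchar(mut_prot) < nchar(ref_prot)) {
    "stopgain"
  } else if (nchar(mut_prot) > nchar(ref_prot)) {
    "stop_lost"
  } else {
    "nonsynonymous"
  }
  list(consequence = cons, truncation = nchar(ref_prot) - nchar(mut_prot))
}

# Oracle wrapper over package objects.
oracle_for_gene <- function(sim, gene_id, pos, ref, alt) {
  seg <- as.data.frame(cdsByGene(sim$models)[[gene_id]])
  chrom <- as.character(seg$seqnames[1])
  oracle_consequence(as.character(sim$genome[[chrom]]),
                     seg$start, seg$end, as.character(seg$strand[1]),
                     pos, ref, alt)
}
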