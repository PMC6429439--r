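#' Splice the coding sequence of a gene model
#'
#' Concatenates CDS segments in transcription order: genomic order for
#' plus-strand genes, reverse-complemented for minus-strand genes. A CDS
#' whose total length is not divisible by 3 is returned with attribute
#' `frame_warning = TRUE` (classification still proceeds downstream).
#'
#' @param gene_id gene identifier present in `models`
#' @param models a [GeneModels-class]
#' @param genome `DNAStringSet`
#' @return character scalar of the spliced CDS (5'->3' of the mRNA)
#' @export
spliceCds <- function(gene_id, models, genome) {
  seg <- models@cds[[gene_id]]
  if (is.null(seg)) .stopf("unknown gene_id: %s", gene_id)
  chrom <- as.character(GenomeInfoDb::seqnames(seg))[1]
  if (!chrom %in% names(genome))
    .stopf("coordinate error: chromosome %s absent from genome", chrom)
  chrom_len <- length(genome[[chrom]])
  if (any(GenomicRanges::start(seg) < 1L) ||
      any(GenomicRanges::end(seg) > chrom_len))
    .stopf("coordinate error: CDS of %s outside chromosome bounds", gene_id)
  pieces <- vapply(seq_along(seg), function(k)
    as.character(Biostrings::subseq(genome[[chrom]],
                                    GenomicRanges::start(seg)[k],
                                    GenomicRanges::end(seg)[k])),
    character(1))
  cds <- paste(pieces, collapse = "")
  if (as.character(GenomicRanges::strand(seg))[1] == "-")
    cds <- .revcomp(cds)
  if (nchar(cds) %% 3L != 0L) {
    .warnf("CDS length of %s not divisible by 3", gene_id)
    attr(cds, "frame_warning") <- TRUE
  }
  cds
}

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at the first stop codon,
#' which is excluded from the returned protein. Codons containing `N`
#' translate to `X`.
#'
#' @param cds nucleotide string, length >= 3
#' @return character scalar amino-acid sequence
#' @examples
#' translateCds("ATGGCCTAA")  # "MA"
#' @export
translateCds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) < 3L) .stopf("CDS shorter than one codon")
  aa <- .translate_codons(.codons(cds))
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

# ---- internal gene context -------------------------------------------------

# Per-gene precomputation: exon table in genomic order, cumulative CDS
# offsets, spliced CDS, strand. Used by the consequence engine.
.gene_ctx <- function(gene_id, models, genome) {
  seg <- models@cds[[gene_id]]
  starts <- GenomicRanges::start(seg)
  ends <- GenomicRanges::end(seg)
  widths <- ends - starts + 1L
  cum <- c(0L, cumsum(widths))
  cds <- suppressWarnings(spliceCds(gene_id, models, genome))
  list(gene_id = gene_id,
       chrom = as.character(GenomeInfoDb::seqnames(seg))[1],
       strand = as.character(GenomicRanges::strand(seg))[1],
       starts = starts, ends = ends, cum = cum,
       total = cum[length(cum)], cds = as.character(cds),
       frame_warning = isTRUE(attr(cds, "frame_warning")) ||
         !startsWith(as.character(cds), "ATG"))
}

# 0-based position within the spliced CDS of genomic position gpos;
# NA when gpos is not inside a CDS segment.
.cds_pos <- function(ctx, gpos) {
  k <- which(gpos >= ctx$starts & gpos <= ctx$ends)
  if (length(k) == 0L) return(NA_integer_)
  plus_off <- ctx$cum[k] + (gpos - ctx$starts[k])
  if (ctx$strand == "-") ctx$total - 1L - plus_off else plus_off
}

.severity <- c(stopgain = 7, stop_lost = 6, start_lost = 5, frameshift = 4,
               codon_deletion = 3, codon_insertion = 3, nonsynonymous = 2,
               sv_cds_overlap = 2, synonymous = 1, none = 0)

.aa_change <- function(ref_aa, idx1, alt_aa)
  sprintf("p.%s%d%s", .AA3[ref_aa], idx1, .AA3[alt_aa])

# SNP consequence for one alt allele at a known cds position.
.snp_consequence <- function(ctx, cds_pos, alt_base) {
  if (ctx$strand == "-") alt_base <- .revcomp(alt_base)
  ci <- cds_pos %/% 3L
  wi <- cds_pos %% 3L
  codon <- substr(ctx$cds, 3L * ci + 1L, 3L * ci + 3L)
  if (nchar(codon) < 3L)                      # partial trailing codon
    return(list(consequence = "nonsynonymous", aa_change = ""))
  mut <- codon
  substr(mut, wi + 1L, wi + 1L) <- alt_base
  tab <- .codon_table()
  ref_aa <- unname(tab[codon]); alt_aa <- unname(tab[mut])
  ref_aa[is.na(ref_aa)] <- "X"; alt_aa[is.na(alt_aa)] <- "X"
  cons <-
    if (ref_aa == alt_aa) "synonymous"
    else if (ci == 0L && codon == "ATG") "start_lost"
    else if (alt_aa == "*") "stopgain"
    else if (ref_aa == "*") "stop_lost"
    else "nonsynonymous"
  list(consequence = cons,
       aa_change = if (cons == "synonymous") ""
                   else .aa_change(ref_aa, ci + 1L, alt_aa))
}

# Rebuild the spliced CDS after applying a genomic-coordinate edit that
# lies entirely within one CDS segment, then return the mutant string.
.mutant_cds <- function(ctx, gpos, ref, alt) {
  del_len <- nchar(ref)
  span_end <- if (del_len > 0L) gpos + del_len - 1L else gpos - 1L
  k <- which(gpos >= ctx$starts &
             (if (del_len > 0L) span_end <= ctx$ends else gpos <= ctx$ends))
  if (length(k) == 0L) return(NULL)           # crosses a splice boundary
  k <- k[1]
  if (del_len > 0L) {
    p0 <- ctx$cum[k] + (gpos - ctx$starts[k])          # 0-based plus offset
    p1 <- p0 + del_len - 1L
  } else {
    p0 <- ctx$cum[k] + (gpos - ctx$starts[k])          # insert before p0
    p1 <- p0 - 1L
  }
  plus_cds <- if (ctx$strand == "-") .revcomp(ctx$cds) else ctx$cds
  mutant <- paste0(substr(plus_cds, 1L, p0),
                   alt,
                   substr(plus_cds, p1 + 2L, nchar(plus_cds)))
  if (ctx$strand == "-") .revcomp(mutant) else mutant
}

# Indel consequence for one alt allele.
.indel_consequence <- function(ctx, gpos, ref, alt) {
  net <- nchar(alt) - nchar(ref)
  mutant <- .mutant_cds(ctx, gpos, ref, alt)
  boundary <- is.null(mutant)
  if (boundary || net %% 3L != 0L) {
    cons <- "frameshift"
  } else {
    cons <- if (net < 0L) "codon_deletion" else "codon_insertion"
  }
  ref_len <- nchar(translateCds(ctx$cds))
  new_len <- if (!is.null(mutant) && nchar(mutant) >= 3L)
    nchar(translateCds(mutant)) else NA_integer_
  list(consequence = cons, boundary = boundary, net = net,
       new_protein_len = new_len,
       truncation = if (!is.na(new_len)) ref_len - new_len else NA_integer_)
}

# ---- region + consequence driver ------------------------------------------

.variant_spans <- function(tb) {
  ref_w <- nchar(tb$ref)
  start <- tb$pos
  end <- ifelse(tb$var_class == "SV",
                ifelse(is.na(tb$sv_end), tb$pos, pmax(tb$pos, tb$sv_end)),
                ifelse(ref_w > 0L, tb$pos + ref_w - 1L, tb$pos))
  GenomicRanges::GRanges(tb$chrom, IRanges::IRanges(start, end))
}

#' Classify variants by genomic region
#'
#' Assigns each (variant, overlapping gene) pair a region class:
#' `genic_cds` when the variant touches a CDS segment, `genic_exon_utr`
#' when it touches an exon outside the CDS (only possible when the
#' annotation provides exon features), `genic_intron` when inside the
#' gene span but outside all exons, and `intergenic` otherwise. A
#' variant overlapping two genes yields one row per gene. Translocation
#' breakpoint records (ITX/CTX) are tested at both breakpoints.
#'
#' @param vs a `VariantSet`
#' @param models a `GeneModels`
#' @return data.frame with columns `variant` (row index into `vs`),
#'   `gene_id` (`NA` for intergenic) and `region_class`
#' @export
classifyRegion <- function(vs, models) {
  tb <- variantTable(vs)
  n <- nrow(tb)
  if (n == 0L)
    return(data.frame(variant = integer(0), gene_id = character(0),
                      region_class = character(0)))
  spans <- .variant_spans(tb)
  span_var <- seq_len(n)
  # translocations: test the two breakpoints, not the in-between span
  bp <- which(tb$var_class == "SV" & tb$sv_type %in% c("ITX", "CTX"))
  if (length(bp)) {
    pts <- GenomicRanges::GRanges(
      rep(tb$chrom[bp], 2L),
      IRanges::IRanges(c(tb$pos[bp], tb$sv_end[bp]),
                       c(tb$pos[bp], tb$sv_end[bp])))
    keep <- setdiff(seq_len(n), bp)
    spans <- c(spans[keep], pts)
    span_var <- c(keep, rep(bp, 2L))
  }
  genes <- models@genes
  hits <- GenomicRanges::findOverlaps(spans, genes, ignore.strand = TRUE)
  vi <- span_var[S4Vectors::queryHits(hits)]
  gi <- S4Vectors::subjectHits(hits)
  pairs <- unique(data.frame(variant = vi, gene = gi))
  out <- data.frame(variant = pairs$variant,
                    gene_id = as.character(genes$gene_id)[pairs$gene],
                    region_class = rep("genic_intron", nrow(pairs)),
                    stringsAsFactors = FALSE)
  # refine with CDS / exon overlap, one bulk query per feature type
  pair_keys <- function(grl) {
    flat <- unlist(grl, use.names = FALSE)
    if (length(flat) == 0L) return(character(0))
    gid <- rep(names(grl), lengths(grl))
    ov <- GenomicRanges::findOverlaps(spans, flat, ignore.strand = TRUE)
    unique(paste(span_var[S4Vectors::queryHits(ov)],
                 gid[S4Vectors::subjectHits(ov)]))
  }
  key <- paste(out$variant, out$gene_id)
  out$region_class[key %in% pair_keys(models@exons)] <- "genic_exon_utr"
  out$region_class[key %in% pair_keys(models@cds)] <- "genic_cds"
  inter <- setdiff(seq_len(n), out$variant)
  if (length(inter))
    out <- rbind(out, data.frame(variant = inter, gene_id = NA_character_,
                                 region_class = "intergenic"))
  out[order(out$variant, out$gene_id, na.last = TRUE), , drop = FALSE]
}

#' Annotate variant consequences
#'
#' The per-variant consequence engine. Every (variant, overlapping gene)
#' pair is classified by region; CDS SNPs are classified codon-locally
#' (synonymous / nonsynonymous / stopgain / stop_lost / start_lost), CDS
#' indels by net length (frameshift when not divisible by 3, in-frame
#' codon deletion/insertion otherwise; an indel spanning a splice
#' boundary is called frameshift with `boundary = TRUE`), and structural
#' variants touching a CDS are called `sv_cds_overlap`. Multi-allelic
#' records are evaluated per alternate allele and labelled with the most
#' severe consequence. For frameshifts the mutant CDS is re-translated
#' and the truncation (reference protein length minus mutant protein
#' length) is reported.
#'
#' @param vs a `VariantSet`
#' @param models a `GeneModels`
#' @param genome `DNAStringSet`
#' @return data.frame with one row per (variant, gene) pair (intergenic
#'   variants get a single gene-less row): columns `variant`, `chrom`,
#'   `pos`, `ref`, `alt`, `var_class`, `gene_id`, `region_class`,
#'   `consequence`, `aa_change`, `cds_pos`, `net_len`,
#'   `new_protein_len`, `truncation`, `boundary`, `model_warning`
#' @export
annotateEffects <- function(vs, models, genome) {
  tb <- variantTable(vs)
  reg <- classifyRegion(vs, models)
  n <- nrow(reg)
  reg$chrom <- tb$chrom[reg$variant]
  reg$pos <- tb$pos[reg$variant]
  reg$ref <- tb$ref[reg$variant]
  reg$alt <- tb$alt[reg$variant]
  reg$var_class <- tb$var_class[reg$variant]
  reg$consequence <- "none"
  reg$aa_change <- ""
  reg$cds_pos <- NA_integer_
  reg$net_len <- NA_integer_
  reg$new_protein_len <- NA_integer_
  reg$truncation <- NA_integer_
  reg$boundary <- FALSE
  reg$model_warning <- FALSE
  if (n == 0L) return(reg)

  ctx_cache <- new.env(parent = emptyenv())
  get_ctx <- function(gid) {
    if (is.null(ctx_cache[[gid]]))
      ctx_cache[[gid]] <- .gene_ctx(gid, models, genome)
    ctx_cache[[gid]]
  }

  todo <- which(reg$region_class == "genic_cds")
  for (r in todo) {
    i <- reg$variant[r]
    ctx <- get_ctx(reg$gene_id[r])
    reg$model_warning[r] <- ctx$frame_warning
    cls <- tb$var_class[i]
    if (cls == "SV") { reg$consequence[r] <- "sv_cds_overlap"; next }
    alts <- .split_alts(tb$alt[i])[[1]]
    if (cls == "SNP") {
      cp <- .cds_pos(ctx, tb$pos[i])
      if (is.na(cp)) next  # touches gene CDS set but position outside (defensive)
      k <- which(tb$pos[i] >= ctx$starts & tb$pos[i] <= ctx$ends)[1]
      plus_off <- ctx$cum[k] + (tb$pos[i] - ctx$starts[k])
      plus_cds <- if (ctx$strand == "-") .revcomp(ctx$cds) else ctx$cds
      gbase <- substr(plus_cds, plus_off + 1L, plus_off + 1L)
      if (nzchar(gbase) && gbase != tb$ref[i])
        .stopf("integrity error: reference mismatch at %s:%d (genome %s, record %s)",
               tb$chrom[i], tb$pos[i], gbase, tb$ref[i])
      best <- NULL
      for (a in alts) {
        res <- .snp_consequence(ctx, cp, a)
        if (is.null(best) ||
            .severity[res$consequence] > .severity[best$consequence])
          best <- res
      }
      reg$consequence[r] <- best$consequence
      reg$aa_change[r] <- best$aa_change
      reg$cds_pos[r] <- cp
    } else if (cls == "INDEL") {
      best <- NULL
      for (a in alts) {
        if (nchar(a) == nchar(tb$ref[i])) next    # non-indel alt of mixed record
        res <- .indel_consequence(ctx, tb$pos[i], tb$ref[i], a)
        if (is.null(best) ||
            .severity[res$consequence] > .severity[best$consequence])
          best <- res
      }
      if (is.null(best)) next
      reg$consequence[r] <- best$consequence
      reg$net_len[r] <- best$net
      reg$new_protein_len[r] <- best$new_protein_len
      reg$truncation[r] <- best$truncation
      reg$boundary[r] <- best$boundary
      cp <- .cds_pos(ctx, tb$pos[i])
      reg$cds_pos[r] <- if (is.na(cp)) NA_integer_ else cp
    }
  }
  reg
}

#' Write an effect table as TSV
#'
#' Output positions are 1-based, matching the internal convention.
#'
#' @param effects result of [annotateEffects()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeEffectTable <- function(effects, path) {
  cols <- c("chrom", "pos", "ref", "alt", "gene_id", "region_class",
            "consequence", "aa_change")
  writeTsv(effects[, cols], path)
}
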