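#' Read a reference genome from FASTA
#'
#' Loads all records, uppercases the sequence (N allowed), and returns a
#' [Biostrings::DNAStringSet] named by the first whitespace-delimited
#' token of each header.
#'
#' @param path FASTA file
#' @return `DNAStringSet`, one element per chromosome
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    .stopf("FASTA format error in %s: empty file (line 1)", path)
  if (!startsWith(first, ">"))
    .stopf("FASTA format error in %s: line 1 does not start with '>'", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    .stopf("FASTA format error in %s: no records", path)
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  # uppercase without round-tripping huge strings more than once
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a genome to FASTA
#'
#' @param genome `DNAStringSet`
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome `DNAStringSet`
#' @return named integer vector of base-pair lengths
#' @export
chromLengths <- function(genome) {
  stats::setNames(as.integer(Biostrings::width(genome)), names(genome))
}

.parse_gff_attrs <- function(attr) {
  # returns list with ID and Parent (first Parent kept)
  kv <- strsplit(attr, ";", fixed = TRUE)
  lapply(kv, function(p) {
    p <- p[nzchar(p)]
    keys <- sub("=.*", "", p)
    vals <- sub("^[^=]*=", "", p)
    list(ID = if ("ID" %in% keys) vals[match("ID", keys)] else NA_character_,
         Parent = if ("Parent" %in% keys)
           strsplit(vals[match("Parent", keys)], ",", fixed = TRUE)[[1]][1]
         else NA_character_)
  })
}

#' Read gene models from GFF3
#'
#' Parses `gene`, `mRNA` and `CDS` (and, when present, `exon`) features.
#' For multi-transcript genes the first mRNA encountered is kept and the
#' choice is logged via `message()`. CDS features whose `Parent` cannot
#' be resolved are skipped with a warning. GFF3 coordinates are 1-based
#' inclusive and are stored unchanged (the package-wide convention).
#'
#' @param path GFF3 file
#' @return a [GeneModels-class] object
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) .stopf("GFF3 file not found: %s", path)
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) == 0L)
    return(GeneModels(
      GenomicRanges::GRanges(gene_id = character(0), biotype = character(0)),
      GenomicRanges::GRangesList()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9L))
    .stopf("GFF3 format error in %s: line %d has %d fields (9 required)",
           path, which(nf < 9L)[1], nf[nf < 9L][1])
  tab <- data.frame(
    chrom = vapply(f, `[`, "", 1L), type = vapply(f, `[`, "", 3L),
    start = as.integer(vapply(f, `[`, "", 4L)),
    end = as.integer(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L),
    attr = vapply(f, `[`, "", 9L), stringsAsFactors = FALSE)
  if (any(tab$end < tab$start))
    .stopf("GFF3 format error in %s: end < start at line %d",
           path, which(tab$end < tab$start)[1])
  at <- .parse_gff_attrs(tab$attr)
  tab$ID <- vapply(at, `[[`, "", "ID")
  tab$Parent <- vapply(at, `[[`, "", "Parent")

  genes <- tab[tab$type == "gene", , drop = FALSE]
  mrna <- tab[tab$type == "mRNA", , drop = FALSE]
  # first-isoform policy
  mrna_gene <- mrna$Parent
  keep_mrna <- !duplicated(mrna_gene)
  if (any(!keep_mrna)) {
    for (gid in unique(mrna_gene[!keep_mrna]))
      message("readGeneModels: gene ", gid,
              " has multiple mRNAs; keeping first isoform ",
              mrna$ID[mrna_gene == gid][1])
  }
  mrna2gene <- stats::setNames(mrna$Parent, mrna$ID)  # all isoforms resolve
  mrna <- mrna[keep_mrna, , drop = FALSE]
  gene_ids <- genes$ID

  resolve_gene <- function(parent) {
    out <- unname(mrna2gene[parent])             # CDS -> mRNA -> gene
    direct <- parent %in% gene_ids               # CDS attached to gene
    out[is.na(out) & direct] <- parent[is.na(out) & direct]
    out
  }

  collect <- function(type) {
    seg <- tab[tab$type == type, , drop = FALSE]
    if (nrow(seg) == 0L) return(seg[0, ])
    seg$gene <- resolve_gene(seg$Parent)
    bad <- is.na(seg$gene)
    if (any(bad)) {
      .warnf("%d %s feature(s) without resolvable Parent skipped", sum(bad),
             type)
      seg <- seg[!bad, , drop = FALSE]
    }
    # keep only segments of the retained isoform (Parent is kept mRNA or gene)
    seg[seg$Parent %in% c(mrna$ID, gene_ids), , drop = FALSE]
  }
  cds <- collect("CDS")
  exon <- collect("exon")

  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$ID, biotype = "protein_coding")
  seg_list <- function(seg) {
    if (nrow(seg) == 0L) return(GenomicRanges::GRangesList())
    gr <- GenomicRanges::GRanges(seg$chrom,
                                 IRanges::IRanges(seg$start, seg$end),
                                 strand = seg$strand)
    sp <- GenomicRanges::split(gr, seg$gene)
    S4Vectors::endoapply(sp, GenomicRanges::sort)
  }
  GeneModels(gr_genes, seg_list(cds), seg_list(exon))
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features (one mRNA per gene) with
#' 1-based inclusive coordinates per the GFF3 standard.
#'
#' @param models a `GeneModels` object
#' @param path output file
#' @return `path`, invisibly
#' @export
writeGff3 <- function(models, path) {
  gt <- geneTable(models)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ord <- order(gt$chrom, gt$start)
  for (i in ord) {
    gid <- gt$gene_id[i]
    writeLines(sprintf("%s\tvircontrast\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       gt$chrom[i], gt$start[i], gt$end[i], gt$strand[i], gid),
               con)
    mid <- paste0(gid, ".t1")
    writeLines(sprintf("%s\tvircontrast\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       gt$chrom[i], gt$start[i], gt$end[i], gt$strand[i],
                       mid, gid), con)
    seg <- models@cds[[gid]]
    phase <- 0L
    sidx <- seq_along(seg)
    if (gt$strand[i] == "-") sidx <- rev(sidx)
    for (k in sidx) {
      writeLines(sprintf("%s\tvircontrast\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                         gt$chrom[i], GenomicRanges::start(seg)[k],
                         GenomicRanges::end(seg)[k], gt$strand[i], phase,
                         gid, mid), con)
      phase <- (3L - ((GenomicRanges::width(seg)[k] - phase) %% 3L)) %% 3L
    }
  }
  invisible(path)
}

# Left-normalize one record: trim context shared by ref and ALL alts,
# prefix first (position advances), then suffix. Alleles may become
# empty strings; pos is the first altered base (1-based).
.normalize_alleles <- function(pos, ref, alts) {
  repeat {
    lens <- c(nchar(ref), nchar(alts))
    if (any(lens == 0L) || all(lens == 1L)) break
    first <- substr(c(ref, alts), 1L, 1L)
    if (length(unique(first)) != 1L) break
    ref <- substr(ref, 2L, nchar(ref))
    alts <- substr(alts, 2L, nchar(alts))
    pos <- pos + 1L
  }
  repeat {
    lens <- c(nchar(ref), nchar(alts))
    if (any(lens == 0L) || all(lens == 1L)) break
    last <- substr(c(ref, alts), lens, lens)
    if (length(unique(last)) != 1L) break
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alts <- substr(alts, 1L, nchar(alts) - 1L)
  }
  list(pos = pos, ref = ref, alts = alts)
}

# Normalize one VCF-style record (position, REF, comma-joined ALT,
# INFO string) into the internal representation and class it.
.normalize_record <- function(pos, ref, alt, info = "") {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  symbolic <- startsWith(alts, "<")
  if (any(symbolic)) {
    sym <- sub("^<(.*)>$", "\\1", alts[symbolic][1])
    svt <- .info_field(info, "SVTYPE")
    sv_type <- if (!is.na(svt)) svt else sym
    if (!sv_type %in% c("DEL", "INS", "INV", "ITX", "CTX"))
      sv_type <- "UNKNOWN"
    endf <- suppressWarnings(as.integer(.info_field(info, "END")))
    return(list(pos = pos, ref = ref, alt = alt, var_class = "SV",
                sv_type = sv_type,
                sv_end = if (!is.na(endf)) endf else pos))
  }
  nrm <- .normalize_alleles(pos, ref, alts)
  d <- abs(nchar(nrm$alts) - nchar(nrm$ref))
  if (all(d == 0L) && nchar(nrm$ref) == 1L) {
    cls <- "SNP"; svt <- NA_character_; sve <- NA_integer_
  } else if (any(d > 30L)) {
    cls <- "SV"
    svt <- if (nchar(nrm$ref) > max(nchar(nrm$alts))) "DEL" else "INS"
    sve <- nrm$pos + max(0L, nchar(nrm$ref) - 1L)
  } else {
    cls <- "INDEL"; svt <- NA_character_; sve <- NA_integer_
  }
  list(pos = nrm$pos, ref = nrm$ref,
       alt = paste(nrm$alts, collapse = ","), var_class = cls,
       sv_type = svt, sv_end = sve)
}

#' Read variant calls from a VCF file
#'
#' Wraps [vcfR::read.vcfR] and converts records into the package's
#' normalized representation: shared allele context is trimmed (prefix
#' first, advancing the position, then suffix), multi-allelic records
#' are kept as a single record, and records in which every requested
#' sample has a missing genotype are dropped with a message. Symbolic
#' alternate alleles (`<DEL>` etc.) and indels whose net length exceeds
#' 30 bp are classed as structural variants (SV); 1-bp substitutions as
#' SNP; the rest as INDEL (net length 1-30 bp).
#'
#' @param path VCF file (v4.x text)
#' @param samples sample names to load; all must be present in the header
#' @return a [VariantSet-class]
#' @export
readVariants <- function(path, samples) {
  if (!file.exists(path)) .stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  hdr_samples <- colnames(v@gt)[-1]
  missing <- setdiff(samples, hdr_samples)
  if (length(missing))
    .stopf("configuration error: sample(s) %s absent from VCF header",
           paste(missing, collapse = ", "))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L)
    return(VariantSet(
      data.frame(chrom = character(0), pos = integer(0), id = character(0),
                 ref = character(0), alt = character(0),
                 var_class = character(0), sv_type = character(0),
                 sv_end = integer(0), qual = numeric(0)),
      matrix(NA_character_, 0, length(samples)), samples))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, samples, drop = FALSE]
  has_dp <- grepl("DP", v@gt[1, "FORMAT"], fixed = TRUE)
  dp <- if (has_dp)
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[
      , samples, drop = FALSE]
  else matrix(NA_real_, nrow(fix), length(samples))
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = length(samples))

  miss <- matrix(.is_missing_gt(as.vector(gt)), nrow = nrow(gt))
  all_missing <- rowSums(!miss) == 0L
  if (any(all_missing))
    message("readVariants: dropping ", sum(all_missing),
            " record(s) with all-missing genotypes")
  keep <- !all_missing
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  dp <- dp[keep, , drop = FALSE]
  n <- nrow(fix)

  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  info <- fix[, "INFO"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  sv_type <- rep(NA_character_, n)
  sv_end <- rep(NA_integer_, n)
  var_class <- character(n)
  out_ref <- character(n)
  out_alt <- character(n)

  # fast path: plain biallelic SNPs need no normalization
  plain_snp <- nchar(ref) == 1L & nchar(alt) == 1L & alt != "<"
  var_class[plain_snp] <- "SNP"
  out_ref[plain_snp] <- ref[plain_snp]
  out_alt[plain_snp] <- alt[plain_snp]
  for (i in which(!plain_snp)) {
    rec <- .normalize_record(pos[i], ref[i], alt[i], info[i])
    pos[i] <- rec$pos
    out_ref[i] <- rec$ref
    out_alt[i] <- rec$alt
    var_class[i] <- rec$var_class
    sv_type[i] <- rec$sv_type
    sv_end[i] <- rec$sv_end
  }
  no_dp <- rowSums(!is.na(dp)) == 0L
  if (any(no_dp)) {
    info_dp <- suppressWarnings(as.numeric(.info_field(info[no_dp], "DP")))
    dp[which(no_dp)[!is.na(info_dp)], ] <- info_dp[!is.na(info_dp)]
  }
  tab <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                    ref = out_ref, alt = out_alt, var_class = var_class,
                    sv_type = sv_type, sv_end = sv_end, qual = qual,
                    stringsAsFactors = FALSE)
  ord <- order(tab$chrom, tab$pos)
  VariantSet(tab[ord, , drop = FALSE], gt[ord, , drop = FALSE], samples,
             dp[ord, , drop = FALSE])
}

#' Write regions to BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention at this boundary, and writes rows sorted by
#' (chrom, start).
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), plus optional `name`
#' @param path output file
#' @return `path`, invisibly
#' @export
writeBed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  ord <- order(regions$chrom, regions$start)
  regions <- regions[ord, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d", regions$chrom,
                   as.integer(regions$start) - 1L, as.integer(regions$end))
  if (!is.null(regions$name))
    lines <- paste(lines, regions$name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a table as TSV
#'
#' Header row included; rows written in (chrom, start/pos) order when
#' those columns exist, otherwise in input order.
#'
#' @param table data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
writeTsv <- function(table, path) {
  poscol <- intersect(c("start", "pos"), names(table))
  if ("chrom" %in% names(table) && length(poscol))
    table <- table[order(table$chrom, table[[poscol[1]]]), , drop = FALSE]
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check SNP reference-allele agreement with the genome
#'
#' For every SNP record the genome base at `pos` must equal the record's
#' reference allele. Violations are counted and reported, not fatal.
#'
#' @param vs a `VariantSet`
#' @param genome `DNAStringSet`
#' @return list with `n_checked`, `n_mismatch` and the mismatching row
#'   indices
#' @export
checkReferenceAgreement <- function(vs, genome) {
  tb <- variantTable(vs)
  idx <- which(tb$var_class == "SNP")
  if (length(idx) == 0L)
    return(list(n_checked = 0L, n_mismatch = 0L, mismatch_rows = integer(0)))
  bases <- vapply(idx, function(i) {
    s <- genome[[tb$chrom[i]]]
    as.character(Biostrings::subseq(s, tb$pos[i], tb$pos[i]))
  }, character(1))
  bad <- idx[bases != tb$ref[idx]]
  if (length(bad))
    .warnf("%d SNP record(s) disagree with the reference genome", length(bad))
  list(n_checked = length(idx), n_mismatch = length(bad), mismatch_rows = bad)
}
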