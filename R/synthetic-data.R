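#' Configuration for the synthetic two-sample study
#'
#' Defaults emulate the downstream structure of a two-selfing-line
#' resequencing contrast on a seven-chromosome diploid genome:
#' genome-wide SNP density near 12,900 per Mb and indel density near
#' 1,940 per Mb, a transition/transversion ratio of 1.57, 84% of
#' carried calls homozygous outside planted homozygous blocks, indel
#' lengths 1-30 bp concentrated in 1-4 bp, region-dependent variant
#' densities, and sample-specific homozygous blocks aligned to the
#' 100-kb scan grid.
#'
#' @param seed integer seed controlling every stochastic draw
#' @param n_chroms,chrom_length genome shape (default 7 x 2 Mb)
#' @param n_genes_per_chrom protein-coding genes per chromosome
#' @param snp_rate,indel_rate intergenic per-bp rates
#' @param snp_region_weights,indel_region_weights relative rates per
#'   region class (intergenic/exon/intron); defaults reproduce the
#'   observed density orderings (SNPs: intergenic > exon > intron;
#'   indels: intergenic > intron > exon)
#' @param ts_tv_target transition/transversion ratio of planted SNPs
#' @param hom_fraction probability a carried call is homozygous outside
#'   a planted block
#' @param n_blocks number of planted homozygous blocks (assigned to the
#'   two samples alternately, disjoint, aligned to `block_window` bp)
#' @param block_window block grid/window size in bp
#' @param block_windows_range block lengths in windows (inclusive range)
#' @param effect_counts named vector of CDS variants to plant per
#'   consequence class in neutral genes (carried by both samples)
#' @param n_candidate_genes genes receiving 1-3 qualifying variants in
#'   exactly one sample
#' @param n_decoy_genes genes receiving only synonymous variants
#' @param n_sv_per_chrom background structural variants per chromosome
#' @param sample_names the two sample names
#' @param classify_background verify background CDS variants with the
#'   re-translation route so the truth table covers their consequences
#'   (disable for large runs where only scan/summary truth is needed)
#' @return a validated config list
#' @export
simulationConfig <- function(seed = 1L, n_chroms = 7L,
                             chrom_length = 2000000L,
                             n_genes_per_chrom = 100L,
                             snp_rate = 0.0129, indel_rate = 0.0019,
                             snp_region_weights = c(intergenic = 1,
                                                    exon = 0.75,
                                                    intron = 0.5),
                             indel_region_weights = c(intergenic = 1,
                                                      exon = 0.35,
                                                      intron = 0.7),
                             ts_tv_target = 1.57, hom_fraction = 0.84,
                             n_blocks = 30L, block_window = 100000L,
                             block_windows_range = c(2L, 4L),
                             effect_counts = c(synonymous = 50,
                                               nonsynonymous = 50,
                                               stopgain = 25,
                                               stop_lost = 15,
                                               start_lost = 15,
                                               frameshift = 50,
                                               codon_deletion = 25,
                                               codon_insertion = 25),
                             n_candidate_genes = 20L, n_decoy_genes = 30L,
                             n_sv_per_chrom = 15L,
                             sample_names = c("lineA", "lineB"),
                             classify_background = TRUE) {
  stopifnot(snp_rate >= 0, indel_rate >= 0,
            hom_fraction > 0, hom_fraction < 1,
            ts_tv_target > 0, length(sample_names) == 2L)
  as.list(environment())
}

.nonstop_codons <- function() {
  tab <- .codon_table()
  names(tab)[tab != "*"]
}

.domain_families <- c(
  "Leucine-rich repeat", "F-box domain", "NB-ARC domain", "Thioredoxin",
  "Calmodulin-binding domain", "NADH(P)-binding", "Pentapeptide repeats",
  "Protein kinase domain", "WD40 repeat", "RING finger", "UBA domain",
  "BTB/POZ domain")

#' Generate a synthetic reference genome, gene models and domain table
#'
#' Random nucleotide sequence with non-overlapping protein-coding genes
#' (1-4 CDS exons, both strands, valid ATG...stop open reading frames
#' with no internal stop codon) and Pfam-style protein-domain intervals
#' inside each protein span. Deterministic given `config$seed`.
#'
#' @param config see [simulationConfig()]
#' @return list with `genome` (`DNAStringSet`), `models`
#'   ([GeneModels-class]) and `domains` (data.frame)
#' @export
generateReference <- function(config) {
  set.seed(.subseed(config$seed, 1L))
  bases <- c("A", "C", "G", "T")
  nonstop <- .nonstop_codons()
  stops <- c("TAA", "TAG", "TGA")
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- character(config$n_chroms)
  gene_rows <- list(); cds_rows <- list(); dom_rows <- list()
  gnum <- 0L
  for (ci in seq_along(chroms)) {
    chars <- sample(bases, config$chrom_length, replace = TRUE)
    slot <- config$chrom_length %/% max(1L, config$n_genes_per_chrom)
    for (g in seq_len(config$n_genes_per_chrom)) {
      gnum <- gnum + 1L
      gid <- sprintf("gene%05d", gnum)
      placed <- FALSE
      for (try in 1:20) {
        ncod <- sample(80:320, 1L)
        total <- 3L * ncod
        n_ex <- sample(1:4, 1L)
        widths <- NULL
        for (k in 1:50) {                      # exon split, min 30 bp each
          cuts <- sort(sample(seq_len(total - 1L), n_ex - 1L))
          w <- diff(c(0L, cuts, total))
          if (all(w >= 30L)) { widths <- w; break }
        }
        if (is.null(widths)) next
        introns <- if (n_ex > 1L) sample(80:400, n_ex - 1L, replace = TRUE)
          else integer(0)
        glen <- total + sum(introns)
        room <- slot - glen - 60L
        if (room < 1L) next
        start <- (g - 1L) * slot + sample.int(room, 1L) + 30L
        if (start + glen - 1L > config$chrom_length) next
        strand <- sample(c("+", "-"), 1L)
        cds <- paste0("ATG",
                      paste(sample(nonstop, ncod - 2L, replace = TRUE),
                            collapse = ""),
                      sample(stops, 1L))
        plus_seq <- if (strand == "-") .revcomp(cds) else cds
        # lay exon chunks across the genomic span, introns between
        ex_start <- start
        off <- 0L
        for (k in seq_len(n_ex)) {
          chunk <- substr(plus_seq, off + 1L, off + widths[k])
          chars[ex_start:(ex_start + widths[k] - 1L)] <-
            strsplit(chunk, "", fixed = TRUE)[[1]]
          cds_rows[[length(cds_rows) + 1L]] <- data.frame(
            gene_id = gid, chrom = chroms[ci], start = ex_start,
            end = ex_start + widths[k] - 1L, strand = strand)
          off <- off + widths[k]
          if (k < n_ex) ex_start <- ex_start + widths[k] + introns[k]
          else ex_start <- ex_start + widths[k]
        }
        gene_rows[[gnum]] <- data.frame(
          gene_id = gid, chrom = chroms[ci], start = start,
          end = start + glen - 1L, strand = strand)
        protlen <- ncod - 1L
        for (d in seq_len(sample(0:2, 1L))) {
          a0 <- sample.int(max(1L, protlen - 15L), 1L)
          a1 <- min(protlen, a0 + sample(10:60, 1L) - 1L)
          dom_rows[[length(dom_rows) + 1L]] <- data.frame(
            gene_id = gid, family = sample(.domain_families, 1L),
            aa_start = a0, aa_end = a1)
        }
        placed <- TRUE
        break
      }
      if (!placed)
        .stopf("config error: could not place gene %s on %s", gid,
               chroms[ci])
    }
    seqs[ci] <- paste(chars, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  if (length(gene_rows) == 0L) {
    models <- GeneModels(
      GenomicRanges::GRanges(gene_id = character(0),
                             biotype = character(0)),
      GenomicRanges::GRangesList())
    return(list(genome = genome, models = models,
                domains = data.frame(gene_id = character(0),
                                     family = character(0),
                                     aa_start = integer(0),
                                     aa_end = integer(0))))
  }
  gdf <- do.call(rbind, gene_rows)
  cdf <- do.call(rbind, cds_rows)
  genes_gr <- GenomicRanges::GRanges(
    gdf$chrom, IRanges::IRanges(gdf$start, gdf$end), strand = gdf$strand,
    gene_id = gdf$gene_id, biotype = "protein_coding")
  cds_gr <- GenomicRanges::GRanges(
    cdf$chrom, IRanges::IRanges(cdf$start, cdf$end), strand = cdf$strand)
  cds_list <- S4Vectors::endoapply(
    GenomicRanges::split(cds_gr, cdf$gene_id), GenomicRanges::sort)
  models <- GeneModels(genes_gr, cds_list)
  domains <- if (length(dom_rows)) do.call(rbind, dom_rows)
    else data.frame(gene_id = character(0), family = character(0),
                    aa_start = integer(0), aa_end = integer(0))
  list(genome = genome, models = models, domains = domains)
}

# ---- variant planting ------------------------------------------------------

# genomic position of 0-based spliced-CDS position p
.cds_to_g <- function(ctx, p) {
  plus_off <- if (ctx$strand == "-") ctx$total - 1L - p else p
  k <- findInterval(plus_off, ctx$cum)         # cum starts at 0
  ctx$starts[k] + (plus_off - ctx$cum[k])
}

# all single-base substitutions of a codon, as (within, base, aa) rows
.codon_subs <- function(codon) {
  tab <- .codon_table()
  out <- list()
  for (wi in 0:2) {
    cur <- substr(codon, wi + 1L, wi + 1L)
    for (b in setdiff(c("A", "C", "G", "T"), cur)) {
      mut <- codon
      substr(mut, wi + 1L, wi + 1L) <- b
      out[[length(out) + 1L]] <- list(within = wi, base = b,
                                      aa = unname(tab[mut]))
    }
  }
  out
}

# Plant one SNP of the requested class in gene ctx; returns a record or
# NULL. `used` is an environment tracking reserved codon indices.
.plant_snp <- function(cls, ctx, used, genome) {
  tab <- .codon_table()
  ncod <- ctx$total %/% 3L
  cand_i <- switch(cls,
    synonymous = ,
    nonsynonymous = ,
    stopgain = seq.int(1L, ncod - 2L),
    stop_lost = ncod - 1L,
    start_lost = 0L)
  cand_i <- setdiff(cand_i, used$codons)
  if (!length(cand_i)) return(NULL)
  for (i in sample(as.list(cand_i))) {
    i <- as.integer(i)
    codon <- substr(ctx$cds, 3L * i + 1L, 3L * i + 3L)
    aa_old <- unname(tab[codon])
    subs <- .codon_subs(codon)
    ok <- switch(cls,
      synonymous = vapply(subs, function(s) s$aa == aa_old, logical(1)),
      nonsynonymous = vapply(subs, function(s)
        s$aa != aa_old && s$aa != "*" && aa_old != "*", logical(1)),
      stopgain = vapply(subs, function(s)
        s$aa == "*" && aa_old != "*", logical(1)),
      stop_lost = vapply(subs, function(s)
        aa_old == "*" && s$aa != "*", logical(1)),
      start_lost = vapply(subs, function(s) codon == "ATG", logical(1)))
    if (!any(ok)) next
    ok_idx <- which(ok)
    s <- subs[[ok_idx[sample.int(length(ok_idx), 1L)]]]
    cds_pos <- 3L * i + s$within
    gpos <- .cds_to_g(ctx, cds_pos)
    alt_g <- if (ctx$strand == "-") .revcomp(s$base) else s$base
    ref_g <- as.character(Biostrings::subseq(genome[[ctx$chrom]], gpos, gpos))
    used$codons <- c(used$codons, i)
    return(list(chrom = ctx$chrom, pos = gpos, ref = ref_g, alt = alt_g,
                var_class = "SNP", cls = cls))
  }
  NULL
}

# Plant one CDS indel (frameshift / codon_deletion / codon_insertion).
.plant_indel <- function(cls, ctx, used, genome) {
  d <- if (cls == "frameshift") sample(1:2, 1L) else 3L
  ins <- if (cls == "codon_insertion") TRUE
    else if (cls == "codon_deletion") FALSE
    else sample(c(TRUE, FALSE), 1L)
  nseg <- length(ctx$starts)
  for (try in 1:30) {
    k <- sample.int(nseg, 1L)
    lo <- ctx$cum[k]; hi <- ctx$cum[k + 1L] - 1L
    # keep away from CDS start/stop codons and segment edges
    lo2 <- max(lo + 2L, 6L)
    hi2 <- min(hi - d - 1L, ctx$total - 7L - d)
    if (hi2 <= lo2) next
    plus_off <- sample(lo2:hi2, 1L)
    codon_i <- {p <- if (ctx$strand == "-") ctx$total - 1L - plus_off
                  else plus_off
                p %/% 3L}
    if (any(abs(used$codons - codon_i) <= 1L)) next
    gpos <- ctx$starts[k] + (plus_off - ctx$cum[k])
    if (ins) {
      alt <- paste(sample(c("A", "C", "G", "T"), d, replace = TRUE),
                   collapse = "")
      rec <- list(chrom = ctx$chrom, pos = gpos, ref = "", alt = alt)
    } else {
      ref <- as.character(Biostrings::subseq(genome[[ctx$chrom]], gpos,
                                             gpos + d - 1L))
      rec <- list(chrom = ctx$chrom, pos = gpos, ref = ref, alt = "")
    }
    used$codons <- c(used$codons, codon_i + (-1:1))
    rec$var_class <- "INDEL"
    rec$cls <- cls
    return(rec)
  }
  NULL
}

# sample n positions uniformly from a reduced GRanges region set
.sample_positions <- function(gr, n) {
  w <- GenomicRanges::width(gr)
  tot <- sum(as.numeric(w))
  if (tot == 0 || n == 0L)
    return(data.frame(chrom = character(0), pos = integer(0)))
  off <- sort(sample.int(tot, min(n, tot)))
  cw <- cumsum(as.numeric(w))
  k <- findInterval(off - 1, c(0, cw))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr))[k],
             pos = GenomicRanges::start(gr)[k] +
               as.integer(off - c(0, cw)[k]) - 1L)
}

.place_blocks <- function(config) {
  if (config$n_blocks == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sample = character(0)))
  win <- config$block_window
  n_win <- config$chrom_length %/% win
  chroms <- paste0("chr", seq_len(config$n_chroms))
  occupied <- stats::setNames(
    rep(list(logical(n_win)), config$n_chroms), chroms)
  len_rng <- config$block_windows_range[1]:config$block_windows_range[2]
  feasible <- function(len_w) {
    out <- list()
    for (ch in chroms) {
      free <- !occupied[[ch]]
      if (len_w > n_win) next
      ok <- vapply(seq_len(n_win - len_w + 1L), function(w0)
        all(free[w0:(w0 + len_w - 1L)]), logical(1))
      if (any(ok)) out[[ch]] <- which(ok)
    }
    out
  }
  rows <- list()
  for (b in seq_len(config$n_blocks)) {
    s <- config$sample_names[1L + (b - 1L) %% 2L]
    len_w <- len_rng[sample.int(length(len_rng), 1L)]
    slots <- feasible(len_w)
    while (length(slots) == 0L && len_w > len_rng[1]) {
      len_w <- len_w - 1L             # shrink on a crowded genome
      slots <- feasible(len_w)
    }
    if (length(slots) == 0L)
      .stopf("config error: could not place block %d", b)
    ch <- names(slots)[sample.int(length(slots), 1L)]
    w0 <- slots[[ch]][sample.int(length(slots[[ch]]), 1L)]
    occupied[[ch]][w0:(w0 + len_w - 1L)] <- TRUE
    rows[[b]] <- data.frame(chrom = ch, start = (w0 - 1L) * win + 1L,
                            end = (w0 + len_w - 1L) * win, sample = s)
  }
  do.call(rbind, rows)
}

#' Plant variants with a full truth table
#'
#' Draws background SNPs and indels at region-dependent rates (alt
#' alleles tuned to the transition/transversion target; indel lengths
#' 1-30 bp skewed to 1-4 bp), plants CDS variants per consequence class
#' (each verified at generation time with the re-translation route,
#' [bruteForceConsequence()]), gives a configured set of candidate
#' genes qualifying variants in exactly one sample and decoy genes only
#' synonymous variants, adds background structural variants, and
#' assigns zygosity: inside a sample's planted homozygous block every
#' call of that sample is homozygous; elsewhere calls are homozygous
#' with probability `hom_fraction`.
#'
#' @param config see [simulationConfig()]
#' @param reference result of [generateReference()]
#' @return list with `variants` (a [VariantSet-class]) and `truth`
#'   (lists `variants`, `blocks`, `genes`)
#' @export
plantVariants <- function(config, reference) {
  set.seed(.subseed(config$seed, 2L))
  genome <- reference$genome
  models <- reference$models
  chrlen <- chromLengths(genome)
  chroms <- names(chrlen)
  samples <- config$sample_names
  blocks <- .place_blocks(config)

  gt_tab <- geneTable(models)
  n_genes <- nrow(gt_tab)
  roles <- rep("neutral", n_genes)
  ord <- sample.int(n_genes)
  n_cand <- min(config$n_candidate_genes, n_genes)
  n_dec <- min(config$n_decoy_genes, n_genes - n_cand)
  roles[ord[seq_len(n_cand)]] <- "candidate"
  if (n_dec > 0) roles[ord[n_cand + seq_len(n_dec)]] <- "decoy"
  carrier <- rep(NA_character_, n_genes)
  carrier[roles == "candidate"] <-
    samples[1L + (seq_len(n_cand) - 1L) %% 2L]

  ctx_cache <- new.env(parent = emptyenv())
  get_ctx <- function(gid) {
    if (is.null(ctx_cache[[gid]]))
      ctx_cache[[gid]] <- .gene_ctx(gid, models, genome)
    ctx_cache[[gid]]
  }
  used_env <- new.env(parent = emptyenv())
  get_used <- function(gid) {
    if (is.null(used_env[[gid]])) {
      e <- new.env(parent = emptyenv()); e$codons <- integer(0)
      used_env[[gid]] <- e
    }
    used_env[[gid]]
  }

  recs <- list()   # each: chrom,pos,ref,alt,var_class,sv_type,sv_end,
                   #       qual, origin, gene_id, cls, carrier
  add_rec <- function(r, origin, gene_id = NA_character_,
                      carrier = "both", qual = NULL, sv_type = NA,
                      sv_end = NA, depth = NA_real_) {
    recs[[length(recs) + 1L]] <<- data.frame(
      chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
      var_class = r$var_class,
      sv_type = if (!is.null(r$sv_type)) r$sv_type else sv_type,
      sv_end = if (!is.null(r$sv_end)) r$sv_end else sv_end,
      qual = if (!is.null(qual)) qual else round(stats::runif(1, 60, 900)),
      origin = origin, gene_id = gene_id,
      cls = if (!is.null(r$cls)) r$cls else NA_character_,
      carrier = carrier, depth = depth, stringsAsFactors = FALSE)
  }

  # ---- planted CDS variants (candidates, decoys, neutral class mix) ----
  plant_in_gene <- function(cls, gid, origin, carrier) {
    ctx <- get_ctx(gid)
    used <- get_used(gid)
    rec <- if (cls %in% c("frameshift", "codon_deletion",
                          "codon_insertion"))
      .plant_indel(cls, ctx, used, genome)
    else if (cls == "sv_cds_overlap") {
      k <- sample.int(length(ctx$starts), 1L)
      s0 <- max(1L, ctx$starts[k] - 200L)
      e0 <- min(chrlen[[ctx$chrom]], ctx$starts[k] + 300L)
      list(chrom = ctx$chrom, pos = s0,
           ref = as.character(Biostrings::subseq(genome[[ctx$chrom]], s0, s0)),
           alt = "<DEL>", var_class = "SV", sv_type = "DEL", sv_end = e0,
           cls = "sv_cds_overlap")
    } else .plant_snp(cls, ctx, used, genome)
    if (is.null(rec)) return(FALSE)
    if (rec$var_class != "SV") {
      chk <- bruteForceConsequence(rec$chrom, rec$pos, rec$ref, rec$alt,
                                   gid, models, genome, ctx = ctx)
      rec$cls <- chk$consequence   # truth is the verified class
    }
    add_rec(rec, origin, gene_id = gid, carrier = carrier,
            qual = if (rec$var_class == "SV") round(stats::runif(1, 25, 80))
                   else NULL,
            depth = if (rec$var_class == "SV") sample(10:90, 1L)
                    else NA_real_)
    TRUE
  }

  qual_classes <- c("nonsynonymous", "stopgain", "frameshift",
                    "codon_deletion", "sv_cds_overlap")
  for (gi in which(roles == "candidate")) {
    gid <- gt_tab$gene_id[gi]
    n_ev <- sample(1:3, 1L)
    planted <- 0L
    for (cls in sample(qual_classes, n_ev, replace = TRUE))
      planted <- planted + plant_in_gene(cls, gid, "candidate", carrier[gi])
    while (planted == 0L)   # every candidate must carry evidence
      planted <- planted + plant_in_gene("nonsynonymous", gid, "candidate",
                                         carrier[gi])
  }
  for (gi in which(roles == "decoy")) {
    gid <- gt_tab$gene_id[gi]
    for (k in seq_len(sample(1:3, 1L)))
      plant_in_gene("synonymous", gid, "decoy", "both")
  }
  neutral_ids <- gt_tab$gene_id[roles == "neutral"]
  if (length(neutral_ids) && length(config$effect_counts)) {
    for (cls in names(config$effect_counts)) {
      n_want <- config$effect_counts[[cls]]
      planted <- 0L
      gpool <- sample(rep(neutral_ids,
                          length.out = max(n_want * 3L, length(neutral_ids))))
      k <- 0L
      while (planted < n_want && k < length(gpool)) {
        k <- k + 1L
        planted <- planted + plant_in_gene(cls, gpool[k], "effect_mix",
                                           "both")
      }
      if (planted < n_want)
        .stopf("config error: only %d of %d %s variants could be planted",
               planted, n_want, cls)
    }
  }

  # ---- background SNPs and indels at region-dependent rates ----
  genic_gr <- GenomicRanges::reduce(models@genes, ignore.strand = TRUE)
  cds_gr <- if (length(models@cds))
    GenomicRanges::reduce(unlist(models@cds), ignore.strand = TRUE)
  else GenomicRanges::GRanges()
  genome_gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(1L, unname(chrlen)))
  intergenic_gr <- GenomicRanges::setdiff(genome_gr, genic_gr,
                                          ignore.strand = TRUE)
  intron_gr <- GenomicRanges::setdiff(genic_gr, cds_gr,
                                      ignore.strand = TRUE)
  region_sets <- list(intergenic = intergenic_gr, exon = cds_gr,
                      intron = intron_gr)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  p_ts <- config$ts_tv_target / (1 + config$ts_tv_target)
  chrom_str <- stats::setNames(as.character(genome), chroms)

  bg_snp <- list(); bg_ind <- list()
  for (reg in names(region_sets)) {
    gr <- region_sets[[reg]]
    w <- sum(as.numeric(GenomicRanges::width(gr)))
    n_snp <- stats::rbinom(1L, as.integer(w),
                           config$snp_rate * config$snp_region_weights[[reg]])
    ps <- .sample_positions(gr, n_snp)
    if (nrow(ps)) {
      refb <- substring(chrom_str[ps$chrom], ps$pos, ps$pos)
      is_ts <- stats::runif(nrow(ps)) < p_ts
      altb <- ifelse(is_ts, ts_map[refb],
                     vapply(refb, function(b) sample(tv_map[[b]], 1L),
                            character(1)))
      bg_snp[[reg]] <- data.frame(chrom = ps$chrom, pos = ps$pos,
                                  ref = refb, alt = unname(altb),
                                  region = reg)
    }
    n_ind <- stats::rbinom(1L, as.integer(w),
                           config$indel_rate *
                             config$indel_region_weights[[reg]])
    pi <- .sample_positions(gr, n_ind)
    if (nrow(pi)) {
      lw <- c(4, 3, 2, 1.5, 1.5 * 0.75 ^ (1:26))
      lens <- sample(1:30, nrow(pi), replace = TRUE, prob = lw / sum(lw))
      is_ins <- stats::runif(nrow(pi)) < 0.5
      ref <- character(nrow(pi)); alt <- character(nrow(pi))
      for (i in seq_len(nrow(pi))) {
        if (is_ins[i]) {
          ref[i] <- ""
          alt[i] <- paste(sample(c("A", "C", "G", "T"), lens[i],
                                 replace = TRUE), collapse = "")
        } else {
          end <- min(pi$pos[i] + lens[i] - 1L, chrlen[[pi$chrom[i]]])
          ref[i] <- substring(chrom_str[pi$chrom[i]], pi$pos[i], end)
          alt[i] <- ""
        }
      }
      bg_ind[[reg]] <- data.frame(chrom = pi$chrom, pos = pi$pos,
                                  ref = ref, alt = alt, region = reg)
    }
  }
  bg_snp <- if (length(bg_snp))
    do.call(rbind, c(bg_snp, list(make.row.names = FALSE))) else NULL
  bg_ind <- if (length(bg_ind))
    do.call(rbind, c(bg_ind, list(make.row.names = FALSE))) else NULL

  # ---- background SVs (valid under the depth/quality filter; placed
  #      clear of CDS so candidate truth stays exact) ----
  sv_rows <- list()
  for (ch in chroms) {
    for (k in seq_len(config$n_sv_per_chrom)) {
      typ <- sample(c("DEL", "INV", "ITX", "CTX"), 1L,
                    prob = c(0.55, 0.15, 0.1, 0.2))
      len <- s0 <- NULL
      for (try in 1:50) {
        len <- sample(1000:10000, 1L)
        s0 <- sample.int(chrlen[[ch]] - len, 1L)
        span <- GenomicRanges::GRanges(ch, IRanges::IRanges(s0, s0 + len - 1L))
        if (sum(GenomicRanges::countOverlaps(span, cds_gr)) == 0L) break
        s0 <- NULL
      }
      if (is.null(s0)) next
      sv_rows[[length(sv_rows) + 1L]] <- data.frame(
        chrom = ch, pos = s0,
        ref = substring(chrom_str[ch], s0, s0),
        alt = paste0("<", typ, ">"), var_class = "SV", sv_type = typ,
        sv_end = s0 + len - 1L, qual = round(stats::runif(1, 25, 80)),
        origin = "background_sv", gene_id = NA_character_,
        cls = NA_character_, carrier = "both",
        depth = sample(10:90, 1L), stringsAsFactors = FALSE)
    }
  }

  planted <- if (length(recs))
    do.call(rbind, c(recs, list(make.row.names = FALSE)))
  else NULL

  fill_bg <- function(df, cls) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
               var_class = cls, sv_type = NA_character_,
               sv_end = NA_integer_,
               qual = round(stats::runif(nrow(df), 60, 900)),
               origin = paste0("background_", df$region),
               gene_id = NA_character_, cls = NA_character_,
               carrier = "both", depth = NA_real_,
               stringsAsFactors = FALSE)
  }
  all_rec <- rbind(planted, fill_bg(bg_snp, "SNP"), fill_bg(bg_ind, "INDEL"),
                   if (length(sv_rows))
                     do.call(rbind, c(sv_rows, list(make.row.names = FALSE))))

  # drop collisions: background records touching a planted record's span
  span_end <- ifelse(all_rec$var_class == "SV",
                     ifelse(is.na(all_rec$sv_end), all_rec$pos,
                            all_rec$sv_end),
                     all_rec$pos + pmax(0L, nchar(all_rec$ref) - 1L))
  is_planted <- all_rec$origin %in% c("candidate", "decoy", "effect_mix")
  if (any(is_planted) && any(!is_planted)) {
    pg <- GenomicRanges::GRanges(
      all_rec$chrom[is_planted],
      IRanges::IRanges(pmax(1L, all_rec$pos[is_planted] - 2L),
                       span_end[is_planted] + 2L))
    bg <- GenomicRanges::GRanges(
      all_rec$chrom[!is_planted],
      IRanges::IRanges(all_rec$pos[!is_planted], span_end[!is_planted]))
    hit <- GenomicRanges::countOverlaps(bg, pg) > 0
    drop_idx <- which(!is_planted)[hit]
    if (length(drop_idx)) all_rec <- all_rec[-drop_idx, , drop = FALSE]
  }
  all_rec <- all_rec[!duplicated(all_rec[, c("chrom", "pos")]), ,
                     drop = FALSE]
  all_rec <- all_rec[order(all_rec$chrom, all_rec$pos), , drop = FALSE]
  n <- nrow(all_rec)

  # ---- classify background CDS variants for the truth table ----
  if (isTRUE(config$classify_background) && n > 0L) {
    bg_idx <- which(startsWith(all_rec$origin, "background_") &
                      all_rec$var_class %in% c("SNP", "INDEL"))
    if (length(bg_idx)) {
      bg_end <- ifelse(nchar(all_rec$ref[bg_idx]) > 0L,
                       all_rec$pos[bg_idx] + nchar(all_rec$ref[bg_idx]) - 1L,
                       all_rec$pos[bg_idx])
      vg <- GenomicRanges::GRanges(
        all_rec$chrom[bg_idx],
        IRanges::IRanges(all_rec$pos[bg_idx], bg_end))
      cds_flat <- unlist(models@cds)
      ov <- GenomicRanges::findOverlaps(vg, cds_flat, ignore.strand = TRUE,
                                        type = "within")
      gid_of <- names(cds_flat)[S4Vectors::subjectHits(ov)]
      qh <- S4Vectors::queryHits(ov)
      keep1 <- !duplicated(qh)
      for (j in which(keep1)) {
        i <- bg_idx[qh[j]]
        gid <- gid_of[j]
        res <- tryCatch(
          bruteForceConsequence(all_rec$chrom[i], all_rec$pos[i],
                                all_rec$ref[i], all_rec$alt[i], gid,
                                models, genome, ctx = get_ctx(gid)),
          error = function(e) NULL)
        if (!is.null(res)) {
          all_rec$gene_id[i] <- gid
          all_rec$cls[i] <- res$consequence
        }
      }
    }
  }

  # ---- zygosity / genotypes ----
  block_hit <- function(sample) {
    hit <- rep(FALSE, n)
    bl <- blocks[blocks$sample == sample, , drop = FALSE]
    if (nrow(bl) == 0L) return(hit)
    bg <- GenomicRanges::GRanges(bl$chrom, IRanges::IRanges(bl$start,
                                                            bl$end))
    vg <- GenomicRanges::GRanges(all_rec$chrom,
                                 IRanges::IRanges(all_rec$pos, all_rec$pos))
    GenomicRanges::countOverlaps(vg, bg) > 0
  }
  gt <- matrix("0/0", n, 2L, dimnames = list(NULL, samples))
  for (j in 1:2) {
    s <- samples[j]
    carries <- all_rec$carrier %in% c("both", s)
    in_block <- block_hit(s)
    hom <- in_block | stats::runif(n) < config$hom_fraction
    gt[, j] <- ifelse(!carries, "0/0", ifelse(hom, "1/1", "0/1"))
  }
  depth <- matrix(NA_real_, n, 2L, dimnames = list(NULL, samples))
  depth[, 1] <- all_rec$depth
  depth[, 2] <- all_rec$depth

  tab <- data.frame(chrom = all_rec$chrom, pos = all_rec$pos,
                    id = ".", ref = all_rec$ref, alt = all_rec$alt,
                    var_class = all_rec$var_class,
                    sv_type = all_rec$sv_type, sv_end = all_rec$sv_end,
                    qual = all_rec$qual, stringsAsFactors = FALSE)
  vs <- VariantSet(tab, gt, samples, depth)

  truth_variants <- data.frame(
    chrom = all_rec$chrom, pos = all_rec$pos, ref = all_rec$ref,
    alt = all_rec$alt, var_class = all_rec$var_class,
    origin = all_rec$origin, gene_id = all_rec$gene_id,
    consequence = all_rec$cls, carrier = all_rec$carrier,
    gt_a = gt[, 1], gt_b = gt[, 2], stringsAsFactors = FALSE)
  qual_set <- qualifyingConsequences()
  gene_qual <- vapply(gt_tab$gene_id, function(gid) {
    any(!is.na(all_rec$gene_id) & all_rec$gene_id == gid &
          !is.na(all_rec$cls) & all_rec$cls %in% qual_set)
  }, logical(1))
  truth_genes <- data.frame(
    gene_id = gt_tab$gene_id, chrom = gt_tab$chrom, start = gt_tab$start,
    role = roles, carrier = carrier, qualifies = unname(gene_qual),
    stringsAsFactors = FALSE)

  list(variants = vs,
       truth = list(variants = truth_variants, blocks = blocks,
                    genes = truth_genes))
}

#' Run the full simulator
#'
#' Generates the reference bundle and plants variants; optionally
#' writes `ref.fa`, `genes.gff3`, `domains.tsv`, `calls.vcf` and the
#' truth tables to a directory.
#'
#' @param config see [simulationConfig()]
#' @param dir optional output directory (created if needed)
#' @return list with `genome`, `models`, `domains`, `variants`, `truth`
#'   (and `paths` when `dir` is given)
#' @export
simulateStudy <- function(config = simulationConfig(), dir = NULL) {
  ref <- generateReference(config)
  pv <- plantVariants(config, ref)
  out <- c(ref, pv)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "ref.fa"),
      gff3 = file.path(dir, "genes.gff3"),
      domains = file.path(dir, "domains.tsv"),
      vcf = file.path(dir, "calls.vcf"),
      truth_variants = file.path(dir, "truth_variants.tsv"),
      truth_blocks = file.path(dir, "truth_blocks.tsv"),
      truth_genes = file.path(dir, "truth_genes.tsv"))
    writeFasta(ref$genome, paths$fasta)
    writeGff3(ref$models, paths$gff3)
    writeTsv(ref$domains, paths$domains)
    writeVcf(pv$variants, ref$genome, paths$vcf)
    writeTsv(pv$truth$variants, paths$truth_variants)
    writeTsv(pv$truth$blocks, paths$truth_blocks)
    writeTsv(pv$truth$genes, paths$truth_genes)
    out$paths <- paths
  }
  out
}

#' Write a VariantSet as a VCF 4.2 text file
#'
#' Re-anchors normalized indels on the preceding reference base (VCF
#' representation requires non-empty alleles); symbolic SV records get
#' `SVTYPE` and `END` INFO fields. Reading the file back with
#' [readVariants()] reproduces the normalized records.
#'
#' @param vs a `VariantSet`
#' @param genome `DNAStringSet` (for anchor bases and contig headers)
#' @param path output file
#' @return `path`, invisibly
#' @export
writeVcf <- function(vs, genome, path) {
  tb <- variantTable(vs)
  gt <- genotypes(vs)
  dp <- readDepth(vs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(genome),
                       Biostrings::width(genome)),
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sampleNames(vs)),
                     collapse = "\t")), con)
  n <- nrow(tb)
  if (n == 0L) return(invisible(path))
  pos <- tb$pos; ref <- tb$ref; alt <- tb$alt
  info <- rep(".", n)
  is_sv_sym <- tb$var_class == "SV" & grepl("^<", tb$alt)
  info[is_sv_sym] <- sprintf("SVTYPE=%s;END=%d", tb$sv_type[is_sv_sym],
                             tb$sv_end[is_sv_sym])
  needs_anchor <- !is_sv_sym &
    (nchar(ref) == 0L |
       vapply(.split_alts(alt), function(a) any(nchar(a) == 0L),
              logical(1)))
  for (i in which(needs_anchor)) {
    anchor_pos <- pos[i] - 1L
    anchor <- as.character(Biostrings::subseq(genome[[tb$chrom[i]]],
                                              anchor_pos, anchor_pos))
    ref[i] <- paste0(anchor, ref[i])
    alts <- .split_alts(alt[i])[[1]]
    alt[i] <- paste(paste0(anchor, alts), collapse = ",")
    pos[i] <- anchor_pos
  }
  fmt_dp <- ifelse(is.na(dp), ".", as.character(as.integer(dp)))
  geno <- vapply(seq_len(n), function(i)
    paste(paste(gt[i, ], fmt_dp[i, ], sep = ":"), collapse = "\t"),
    character(1))
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\tPASS\t%s\tGT:DP\t%s",
                   tb$chrom, pos, tb$id, ref, alt,
                   ifelse(is.na(tb$qual), ".", as.character(tb$qual)),
                   info, geno)
  writeLines(lines, con)
  invisible(path)
}
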