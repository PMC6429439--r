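#' Transition/transversion ratio of SNP calls
#'
#' Transitions are A<->G and C<->T; every other substitution is a
#' transversion. Multi-allelic SNPs contribute one observation per
#' alternate allele.
#'
#' @param vs a `VariantSet` (only SNP records are used)
#' @return list with `ts`, `tv` and `ratio` (`NA` when `tv` is 0)
#' @export
tsTvRatio <- function(vs) {
  tb <- variantTable(vs)
  tb <- tb[tb$var_class == "SNP", , drop = FALSE]
  if (nrow(tb) == 0L) return(list(ts = 0L, tv = 0L, ratio = NA_real_))
  ref <- rep(tb$ref, lengths(strsplit(tb$alt, ",", fixed = TRUE)))
  alt <- unlist(strsplit(tb$alt, ",", fixed = TRUE), use.names = FALSE)
  pair <- paste0(ref, alt)
  is_ts <- pair %in% c("AG", "GA", "CT", "TC")
  ts <- sum(is_ts); tv <- sum(!is_ts)
  list(ts = ts, tv = tv, ratio = if (tv == 0L) NA_real_ else ts / tv)
}

#' Signed indel length spectrum
#'
#' Histogram of net indel lengths over -30..-1 (deletions) and 1..30
#' (insertions). For multi-allelic records each length-changing alt
#' contributes once. A record with no net length change is an
#' integrity error.
#'
#' @param vs a `VariantSet` (only INDEL records are used)
#' @return data.frame with columns `length` (signed bp) and `count`
#' @export
indelSpectrum <- function(vs) {
  tb <- variantTable(vs)
  tb <- tb[tb$var_class == "INDEL", , drop = FALSE]
  lens <- integer(0)
  if (nrow(tb)) {
    alts <- .split_alts(tb$alt)
    for (i in seq_len(nrow(tb))) {
      d <- nchar(alts[[i]]) - nchar(tb$ref[i])
      d <- d[d != 0L]
      if (length(d) == 0L)
        .stopf("integrity error: INDEL record %s:%d has zero net length",
               tb$chrom[i], tb$pos[i])
      lens <- c(lens, d)
    }
  }
  bins <- c(-30:-1, 1:30)
  data.frame(length = bins,
             count = vapply(bins, function(b) sum(lens == b), integer(1)))
}

#' Partition the genome into region classes
#'
#' Flattens (unions) all gene spans so overlapping genes never double
#' count a base, then partitions: intergenic + genic = genome length and
#' exon + intron = genic span. "Exon" is the union of CDS and exon
#' features (CDS only when the annotation has no exon features); a
#' CDS-only exon span is also reported separately.
#'
#' @param models a `GeneModels`
#' @param chrom_lengths named chromosome lengths
#' @return data.frame with columns `region` and `span_bp`
#' @export
regionComposition <- function(models, chrom_lengths) {
  total <- sum(as.numeric(chrom_lengths))
  genic_gr <- GenomicRanges::reduce(models@genes, ignore.strand = TRUE)
  genic <- sum(as.numeric(GenomicRanges::width(genic_gr)))
  cds_all <- GenomicRanges::reduce(unlist(models@cds), ignore.strand = TRUE)
  ex_all <- if (length(models@exons))
    GenomicRanges::reduce(c(unlist(models@exons), unlist(models@cds)),
                          ignore.strand = TRUE)
  else cds_all
  exon <- sum(as.numeric(GenomicRanges::width(ex_all)))
  cds <- sum(as.numeric(GenomicRanges::width(cds_all)))
  data.frame(
    region = c("genome", "intergenic", "genic", "exon", "intron", "cds"),
    span_bp = c(total, total - genic, genic, exon, genic - exon, cds))
}

#' Variant density per region class
#'
#' Counts SNPs and indels per region class from an effect table and
#' divides by the class span in Mb. A variant overlapping several genes
#' is counted once, by its most specific region class (cds > exon/UTR >
#' intron); intergenic variants count toward `intergenic`.
#'
#' @param effects result of [annotateEffects()]
#' @param composition result of [regionComposition()]
#' @return data.frame with columns `region`, `span_bp`, `n_snp`,
#'   `n_indel`, `snp_per_mb`, `indel_per_mb`
#' @export
regionDensity <- function(effects, composition) {
  rank <- c(genic_cds = 3L, genic_exon_utr = 2L, genic_intron = 1L,
            intergenic = 0L)
  best <- stats::aggregate(rank[effects$region_class],
                           by = list(variant = effects$variant), FUN = max)
  cls_of <- names(rank)[match(best$x, rank)]
  vc <- effects$var_class[match(best$variant, effects$variant)]
  region_of <- c(genic_cds = "exon", genic_exon_utr = "exon",
                 genic_intron = "intron", intergenic = "intergenic")
  counts <- function(var_cls) {
    tab <- table(factor(region_of[cls_of][vc == var_cls],
                        levels = c("intergenic", "exon", "intron")))
    as.integer(tab)
  }
  n_snp3 <- counts("SNP")
  n_ind3 <- counts("INDEL")
  # genic = exon + intron
  regions <- c("intergenic", "genic", "exon", "intron")
  n_snp <- c(n_snp3[1], n_snp3[2] + n_snp3[3], n_snp3[2], n_snp3[3])
  n_ind <- c(n_ind3[1], n_ind3[2] + n_ind3[3], n_ind3[2], n_ind3[3])
  span <- composition$span_bp[match(regions, composition$region)]
  data.frame(region = regions, span_bp = span, n_snp = n_snp,
             n_indel = n_ind,
             snp_per_mb = n_snp / (span / 1e6),
             indel_per_mb = n_ind / (span / 1e6))
}

#' Structural-variant validation filter parameters
#'
#' Defaults retain an SV call only when its coverage depth lies in
#' 2x-100x and its quality exceeds 20.
#'
#' @param min_depth,max_depth inclusive depth bounds
#' @param min_quality exclusive quality floor
#' @return named list
#' @export
svFilterParams <- function(min_depth = 2, max_depth = 100,
                           min_quality = 20) {
  stopifnot(min_depth < max_depth)
  list(min_depth = min_depth, max_depth = max_depth,
       min_quality = min_quality)
}

#' Filter structural-variant records
#'
#' Retains SV records with depth within `[min_depth, max_depth]` and
#' quality strictly above `min_quality`. Depth per record is the
#' maximum per-sample read depth. Rejected records are returned with a
#' reason (`no_depth`, `depth`, `quality`).
#'
#' @param vs a `VariantSet`
#' @param params see [svFilterParams()]
#' @return list with `retained` (a `VariantSet` of surviving SVs plus
#'   all non-SV records untouched) and `rejected` (data.frame `variant`,
#'   `reason`)
#' @export
filterSV <- function(vs, params = svFilterParams()) {
  tb <- variantTable(vs)
  is_sv <- tb$var_class == "SV"
  depth <- suppressWarnings(apply(readDepth(vs), 1L, max, na.rm = TRUE))
  depth[!is.finite(depth)] <- NA_real_
  reason <- rep(NA_character_, nrow(tb))
  reason[is_sv & is.na(depth)] <- "no_depth"
  reason[is_sv & !is.na(depth) &
           (depth < params$min_depth | depth > params$max_depth)] <- "depth"
  reason[is_sv & !is.na(depth) & is.na(reason) &
           !(tb$qual > params$min_quality) ] <- "quality"
  reason[is_sv & is.na(reason) & is.na(tb$qual)] <- "quality"
  rejected <- data.frame(variant = which(!is.na(reason)),
                         reason = reason[!is.na(reason)])
  if (nrow(rejected))
    message("filterSV: rejected ", nrow(rejected), " SV record(s): ",
            paste(sprintf("%s:%d (%s)", tb$chrom[rejected$variant],
                          tb$pos[rejected$variant], rejected$reason),
                  collapse = ", "))
  list(retained = vs[is.na(reason)], rejected = rejected)
}

#' Genome-contrast summary statistics
#'
#' Per-sample variant counts and homozygote fractions, the Ts/Tv ratio,
#' the signed indel spectrum, per-chromosome variant densities and the
#' per-sample nonsynonymous/synonymous SNP ratio.
#'
#' @param vs a `VariantSet`
#' @param effects result of [annotateEffects()] (optional; the
#'   nonsyn/syn ratio and region densities are skipped when absent)
#' @param models a `GeneModels` (optional, needed for region densities)
#' @param chrom_lengths named chromosome lengths
#' @return a nested list; see the individual components
#' @export
variationSummary <- function(vs, chrom_lengths, effects = NULL,
                             models = NULL) {
  tb <- variantTable(vs)
  per_sample <- lapply(sampleNames(vs), function(s) {
    z <- classifyZygosity(vs, s)
    carrier <- z %in% c("hom_alt", "het")
    cls <- tb$var_class[carrier]
    list(sample = s,
         n = c(SNP = sum(cls == "SNP"), INDEL = sum(cls == "INDEL"),
               SV = sum(cls == "SV")),
         hom_fraction = c(
           SNP = mean(z[carrier & tb$var_class == "SNP"] == "hom_alt"),
           INDEL = mean(z[carrier & tb$var_class == "INDEL"] == "hom_alt")))
  })
  names(per_sample) <- sampleNames(vs)
  dens <- vapply(names(chrom_lengths), function(ch)
    sum(tb$chrom == ch) / (chrom_lengths[[ch]] / 1e6), numeric(1))
  out <- list(per_sample = per_sample, ts_tv = tsTvRatio(vs),
              indel_spectrum = indelSpectrum(vs), per_mb_density = dens)
  if (!is.null(effects)) {
    cds <- effects[effects$region_class == "genic_cds" &
                     effects$var_class == "SNP", , drop = FALSE]
    ns <- lapply(sampleNames(vs), function(s) {
      z <- classifyZygosity(vs, s)
      carries <- z[cds$variant] %in% c("hom_alt", "het")
      n_non <- sum(cds$consequence[carries] == "nonsynonymous")
      n_syn <- sum(cds$consequence[carries] == "synonymous")
      c(nonsyn = n_non, syn = n_syn,
        ratio = if (n_syn > 0) n_non / n_syn else NA_real_)
    })
    names(ns) <- sampleNames(vs)
    out$nonsyn_syn <- ns
    if (!is.null(models)) {
      comp <- regionComposition(models, chrom_lengths)
      out$region_density <- regionDensity(effects, comp)
      out$region_composition <- comp
    }
  }
  out
}
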