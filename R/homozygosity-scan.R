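#' Parameters for the sliding-window homozygosity scan
#'
#' Defaults follow the analysis conditions: 100-kb windows tiled across
#' each chromosome (step = window) with a heterozygosity threshold of
#' 10% of calls; windows with fewer than `min_variants` calls are not
#' classified (`no_call`).
#'
#' @param window_size window width in bp
#' @param step step in bp (must not exceed `window_size`)
#' @param het_threshold fraction of heterozygous calls below which a
#'   window is homozygous (exclusive)
#' @param min_variants minimum calls for a window to be classifiable
#' @return a named list of validated parameters
#' @export
scanParams <- function(window_size = 100000L, step = window_size,
                       het_threshold = 0.10, min_variants = 10L) {
  stopifnot(step <= window_size, het_threshold > 0, het_threshold < 1,
            window_size > 0, min_variants >= 0)
  list(window_size = as.integer(window_size), step = as.integer(step),
       het_threshold = het_threshold, min_variants = as.integer(min_variants))
}

#' Windowed heterozygosity scan of one sample
#'
#' Tiles each chromosome with windows and, per window, counts the
#' sample's variant calls (records in which the sample carries at least
#' one alternate allele) and the heterozygous calls among them. A
#' window is `homozygous` when it has at least `min_variants` calls and
#' a heterozygous fraction below the threshold, `heterozygous` when
#' classifiable but above, and `no_call` otherwise.
#'
#' @param vs a `VariantSet`
#' @param chrom_lengths named vector of chromosome lengths (see
#'   [chromLengths()])
#' @param sample sample name
#' @param params see [scanParams()]
#' @param classes variant classes counted (default SNPs only)
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `n_variants`, `n_het`, `het_fraction`, `status`
#' @export
scanHeterozygosity <- function(vs, chrom_lengths, sample,
                               params = scanParams(), classes = "SNP") {
  tb <- variantTable(vs)
  zyg <- classifyZygosity(vs, sample)
  use <- tb$var_class %in% classes & zyg %in% c("hom_alt", "het")
  bad_chrom <- setdiff(unique(tb$chrom[use]), names(chrom_lengths))
  if (length(bad_chrom))
    .stopf("coordinate error: chromosome %s not in chrom_lengths",
           bad_chrom[1])
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    starts <- seq.int(1L, max(1L, len), by = params$step)
    starts <- starts[starts <= len]
    ends <- pmin(starts + params$window_size - 1L, len)
    sel <- use & tb$chrom == chrom
    pos <- tb$pos[sel]
    het <- zyg[sel] == "het"
    wi <- findInterval(pos, starts)            # tiling: step = window
    if (params$step < params$window_size) {
      # overlapping windows: count per window explicitly
      n_var <- vapply(seq_along(starts), function(k)
        sum(pos >= starts[k] & pos <= ends[k]), integer(1))
      n_het <- vapply(seq_along(starts), function(k)
        sum(het & pos >= starts[k] & pos <= ends[k]), integer(1))
    } else {
      n_var <- tabulate(wi, nbins = length(starts))
      n_het <- tabulate(wi[het], nbins = length(starts))
    }
    frac <- ifelse(n_var > 0L, n_het / n_var, NA_real_)
    status <- ifelse(n_var < params$min_variants, "no_call",
                     ifelse(frac < params$het_threshold, "homozygous",
                            "heterozygous"))
    out[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                               n_variants = n_var, n_het = n_het,
                               het_fraction = frac, status = status,
                               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Merge consecutive homozygous windows into regions
#'
#' Maximal runs of consecutive `homozygous` windows are merged into one
#' region per run. `no_call` windows break runs unless
#' `bridge_no_call = TRUE`, in which case they are bridged (but never
#' start or end a region).
#'
#' @param windows output of [scanHeterozygosity()]
#' @param bridge_no_call bridge `no_call` windows inside runs
#' @return data.frame with columns `chrom`, `start`, `end`
#' @export
mergeHomozygousRegions <- function(windows, bridge_no_call = FALSE) {
  out <- list()
  for (chrom in unique(windows$chrom)) {
    w <- windows[windows$chrom == chrom, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    ok <- w$status == "homozygous"
    if (bridge_no_call) {
      # no_call windows flanked by homozygous windows are absorbed
      nc <- w$status == "no_call"
      for (i in which(nc)) {
        left <- if (i > 1) ok[i - 1L] else FALSE
        right <- if (i < length(ok)) w$status[i + 1L] %in%
            c("homozygous", "no_call") else FALSE
        if (left && right) ok[i] <- TRUE
      }
    }
    r <- rle(ok)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
      i0 <- starts_idx[k]; i1 <- ends_idx[k]
      # never start or end on a bridged no_call window
      while (i0 <= i1 && w$status[i0] != "homozygous") i0 <- i0 + 1L
      while (i1 >= i0 && w$status[i1] != "homozygous") i1 <- i1 - 1L
      if (i0 > i1) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = w$start[i0], end = w$end[i1])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.regions_gr <- function(regions) {
  if (nrow(regions) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start, regions$end))
}

.gr_regions <- function(gr, sample = NULL) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if (!is.null(sample) && nrow(df)) df$sample <- sample
  else if (!is.null(sample)) df$sample <- character(0)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Regions homozygous in exactly one sample
#'
#' Interval difference between the two samples' homozygous-region sets.
#' Sub-window slivers (shorter than `min_width`, by default one window)
#' are discarded.
#'
#' @param regions_a,regions_b per-sample region tables from
#'   [mergeHomozygousRegions()]
#' @param sample_a,sample_b labels used in the output
#' @param min_width minimum reported width in bp
#' @return data.frame with columns `chrom`, `start`, `end`, `sample`
#' @export
differentialRegions <- function(regions_a, regions_b,
                                sample_a = "A", sample_b = "B",
                                min_width = 100000L) {
  ga <- .regions_gr(regions_a)
  gb <- .regions_gr(regions_b)
  only_a <- GenomicRanges::setdiff(ga, gb, ignore.strand = TRUE)
  only_b <- GenomicRanges::setdiff(gb, ga, ignore.strand = TRUE)
  only_a <- only_a[GenomicRanges::width(only_a) >= min_width]
  only_b <- only_b[GenomicRanges::width(only_b) >= min_width]
  out <- rbind(.gr_regions(only_a, sample_a), .gr_regions(only_b, sample_b))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Jaccard index between two region sets
#'
#' Base-pair intersection over union; used to score recovery of planted
#' homozygous blocks.
#'
#' @param regions_a,regions_b region tables (`chrom`, `start`, `end`)
#' @return numeric scalar in `[0, 1]` (1 when both sets are empty)
#' @export
regionJaccard <- function(regions_a, regions_b) {
  ga <- GenomicRanges::reduce(.regions_gr(regions_a))
  gb <- GenomicRanges::reduce(.regions_gr(regions_b))
  if (length(ga) == 0L && length(gb) == 0L) return(1)
  inter <- sum(GenomicRanges::width(
    GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(
    GenomicRanges::union(ga, gb, ignore.strand = TRUE)))
  inter / uni
}
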