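#' Classify zygosity of each variant in one sample
#'
#' Unphased genotypes: `0/0` is `hom_ref`, `k/k` (k > 0) `hom_alt`,
#' two distinct allele indices `het`, and an uncalled genotype
#' `missing`. Phase separators (`|`) are ignored.
#'
#' @param vs a `VariantSet`
#' @param sample sample name
#' @return character vector, one of `hom_ref`, `hom_alt`, `het`,
#'   `missing` per record
#' @export
classifyZygosity <- function(vs, sample) {
  if (!sample %in% sampleNames(vs))
    .stopf("configuration error: unknown sample %s", sample)
  idx <- .parse_gt(genotypes(vs)[, sample])
  out <- rep("missing", nrow(idx))
  called <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  out[called & idx[, 1] == idx[, 2] & idx[, 1] == 0L] <- "hom_ref"
  out[called & idx[, 1] == idx[, 2] & idx[, 1] > 0L] <- "hom_alt"
  out[called & idx[, 1] != idx[, 2]] <- "het"
  out
}

# allele multiset (sorted index pair) per record for one sample
.allele_multiset <- function(vs, sample) {
  idx <- .parse_gt(genotypes(vs)[, sample])
  apply(idx, 1L, function(p) {
    if (anyNA(p)) NA_character_ else paste(sort(p), collapse = "/")
  })
}

#' Contrast each locus between two samples
#'
#' Compares the unphased allele multisets of the two samples at every
#' record. A locus is `consistent` when the multisets are equal;
#' `between_sample_variant` when they differ and at least one sample
#' carries a non-reference allele the other lacks. Loci with a missing
#' genotype in either sample are flagged `unresolvable` and excluded
#' from the between-sample set.
#'
#' @param vs a `VariantSet`
#' @param sample_a,sample_b the two sample names
#' @return data.frame with columns `variant`, `zygosity_a`,
#'   `zygosity_b`, `consistent`, `between_sample_variant`,
#'   `unresolvable`
#' @export
contrastLoci <- function(vs, sample_a, sample_b) {
  za <- classifyZygosity(vs, sample_a)
  zb <- classifyZygosity(vs, sample_b)
  ia <- .parse_gt(genotypes(vs)[, sample_a])
  ib <- .parse_gt(genotypes(vs)[, sample_b])
  n <- nVariants(vs)
  unres <- za == "missing" | zb == "missing"
  consistent <- rep(NA, n)
  between <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (unres[i]) next
    a <- sort(ia[i, ]); b <- sort(ib[i, ])
    consistent[i] <- identical(a, b)
    if (!consistent[i]) {
      only_a <- setdiff(a, b); only_b <- setdiff(b, a)
      between[i] <- any(only_a > 0L) || any(only_b > 0L)
    }
  }
  data.frame(variant = seq_len(n), zygosity_a = za, zygosity_b = zb,
             consistent = consistent, between_sample_variant = between,
             unresolvable = unres)
}

#' Summary of a two-sample contrast
#'
#' @param vs a `VariantSet`
#' @param sample_a,sample_b sample names
#' @return list with per-sample homozygote fractions (among calls
#'   carrying an alternate allele), between-sample variant counts per
#'   variant class, and the unresolvable tally
#' @export
contrastSummary <- function(vs, sample_a, sample_b) {
  ct <- contrastLoci(vs, sample_a, sample_b)
  tb <- variantTable(vs)
  hom_frac <- function(z) {
    carrier <- z %in% c("hom_alt", "het")
    if (!any(carrier)) return(NA_real_)
    sum(z == "hom_alt") / sum(carrier)
  }
  cls <- tb$var_class
  list(
    samples = c(sample_a, sample_b),
    hom_fraction = c(
      stats::setNames(hom_frac(ct$zygosity_a), sample_a),
      stats::setNames(hom_frac(ct$zygosity_b), sample_b)),
    between_sample = vapply(
      c(SNP = "SNP", INDEL = "INDEL", SV = "SV"),
      function(k) sum(ct$between_sample_variant & cls == k), integer(1)),
    n_unresolvable = sum(ct$unresolvable))
}

# ---- worked example: cloned-cDNA variant comparison table ------------------

#' Read a variant comparison table
#'
#' Reads the layout used for the FIP2-like cloned-cDNA comparison: one
#' row per locus with a variation type (`Syn`, `Nonsyn`, `FRAME_SHIFT`,
#' `CODON_DELETION`, `CODON_INSERTION`), a location, the reference
#' allele and one comma-separated allele-set column per sample.
#'
#' @param path TSV with columns `gene`, `type`, `location`, `reference`,
#'   then one column per sample
#' @return data.frame
#' @export
readComparisonTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("gene", "type", "location", "reference")
  if (!all(need %in% names(tab)))
    .stopf("comparison table must have columns %s plus sample columns",
           paste(need, collapse = ", "))
  known <- c("Syn", "Nonsyn", "FRAME_SHIFT", "CODON_DELETION",
             "CODON_INSERTION")
  bad <- setdiff(unique(tab$type), known)
  if (length(bad))
    .stopf("comparison table format error: unknown variation type '%s'",
           bad[1])
  tab
}

#' Count allele differences of one sample against the reference column
#'
#' SNP-typed rows (`Syn`/`Nonsyn`) are counted when the sample's allele
#' set contains an allele different from the reference allele. Indel
#' rows (`FRAME_SHIFT`, `CODON_DELETION`, `CODON_INSERTION`) are
#' counted separately when the sample carries an allele whose length
#' differs from the reference allele's; the net length of each such
#' difference is reported.
#'
#' @param tab data.frame from [readComparisonTable()]
#' @param sample name of the sample column to compare
#' @return list with `n_snp`, `n_indel` and `indel_lengths` (net bp,
#'   negative for deletions)
#' @export
countAlleleDifferences <- function(tab, sample) {
  if (!sample %in% names(tab))
    .stopf("configuration error: no column '%s' in comparison table", sample)
  alleles <- strsplit(gsub(" ", "", tab[[sample]]), ",", fixed = TRUE)
  is_snp <- tab$type %in% c("Syn", "Nonsyn")
  snp_diff <- vapply(seq_len(nrow(tab)), function(i)
    is_snp[i] && any(alleles[[i]] != tab$reference[i]), logical(1))
  indel_lengths <- integer(0)
  for (i in which(!is_snp)) {
    d <- nchar(alleles[[i]]) - nchar(tab$reference[i])
    d <- d[d != 0L]
    if (length(d)) indel_lengths <- c(indel_lengths, min(d))
  }
  list(n_snp = sum(snp_diff), n_indel = length(indel_lengths),
       indel_lengths = indel_lengths)
}
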