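#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges GRangesList
NULL

#' Gene models: stranded multi-exon CDS on a shared reference
#'
#' Container for protein-coding gene models used as the coordinate frame
#' for consequence calls. Gene spans are stored as a [GenomicRanges::GRanges]
#' with a `gene_id` column; CDS (and optionally exon) segments are stored
#' as [GenomicRanges::GRangesList] objects named by `gene_id`, sorted by
#' genomic start. All coordinates are 1-based inclusive, the native
#' GRanges convention; conversion to other conventions happens only at
#' format boundaries (e.g. BED export).
#'
#' @slot genes `GRanges` of gene spans, with metadata columns `gene_id`
#'   and `biotype`.
#' @slot cds `GRangesList` of CDS segments, named by `gene_id`.
#' @slot exons `GRangesList` of exon segments (may be empty when the
#'   source annotation carries no exon features; UTR classification is
#'   then unavailable).
#'
#' @seealso [readGeneModels()], [spliceCds()]
#' @export
setClass("GeneModels",
  slots = c(genes = "GRanges", cds = "GRangesList", exons = "GRangesList")
)

setValidity("GeneModels", function(object) {
  g <- object@genes
  msgs <- character(0)
  if (length(g) > 0 && is.null(g$gene_id))
    msgs <- c(msgs, "genes must carry a gene_id metadata column")
  ids <- g$gene_id
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate gene_id")
  if (!all(names(object@cds) %in% ids))
    msgs <- c(msgs, "cds names must be gene_ids")
  for (id in names(object@cds)) {
    seg <- object@cds[[id]]
    if (length(seg) == 0) { msgs <- c(msgs, paste0(id, ": empty CDS")); next }
    st <- GenomicRanges::start(seg)
    if (is.unsorted(st)) msgs <- c(msgs, paste0(id, ": CDS not sorted"))
    if (length(seg) > 1 &&
        any(GenomicRanges::start(seg)[-1] <= GenomicRanges::end(seg)[-length(seg)]))
      msgs <- c(msgs, paste0(id, ": overlapping CDS segments"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Normalized variant calls with per-sample genotypes
#'
#' Container for variant records shared by the downstream modules. Each
#' row of the variant table is one locus (multi-allelic records are kept
#' intact, not split). `pos` is the 1-based position of the first altered
#' base after left-normalization: shared leading context is trimmed (the
#' position advancing past it) and shared trailing context is trimmed,
#' so an indel's length is `abs(nchar(ref) - nchar(alt))` and a pure
#' insertion may have an empty `ref`.
#'
#' @slot tab `data.frame` with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt` (comma-separated alternate alleles), `var_class`
#'   (`"SNP"`, `"INDEL"` or `"SV"`), `sv_type` (`NA` unless SV),
#'   `sv_end` (`NA` unless SV), `qual`.
#' @slot gt character matrix (variants x samples) of unphased genotype
#'   strings such as `"0/1"`; `NA` for missing calls.
#' @slot depth numeric matrix (variants x samples) of read depths, `NA`
#'   where unavailable.
#' @slot samples character vector of sample names (column order of `gt`).
#'
#' @seealso [readVariants()], [classifyZygosity()]
#' @export
setClass("VariantSet",
  slots = c(tab = "data.frame", gt = "matrix", depth = "matrix",
            samples = "character")
)

setValidity("VariantSet", function(object) {
  tb <- object@tab
  msgs <- character(0)
  need <- c("chrom", "pos", "id", "ref", "alt", "var_class", "sv_type",
            "sv_end", "qual")
  if (!all(need %in% names(tb)))
    return(paste("tab must have columns:", paste(need, collapse = ", ")))
  if (nrow(tb) != nrow(object@gt) || nrow(tb) != nrow(object@depth))
    return("gt/depth row count must match variant table")
  if (ncol(object@gt) != length(object@samples))
    return("gt column count must match samples")
  if (nrow(tb) > 0) {
    n_alt <- pmax(1L, lengths(gregexpr(",", tb$alt, fixed = TRUE)) + 1L)
    n_alt[!grepl(",", tb$alt, fixed = TRUE)] <- 1L
    is_snp <- tb$var_class == "SNP"
    # for SNPs every allele is 1 bp, so the comma-joined alt string has
    # length 2 * n_alt - 1
    if (any(is_snp & (nchar(tb$ref) != 1L |
                      nchar(tb$alt) != 2L * n_alt - 1L)))
      msgs <- c(msgs, "SNP records must have 1-bp ref and alt alleles")
    is_ind <- tb$var_class == "INDEL"
    if (any(is_ind)) {
      alts <- .split_alts(tb$alt[is_ind])
      refn <- nchar(tb$ref[is_ind])
      # at least one alt with net change 1..30 bp; none beyond 30 bp
      bad <- vapply(seq_along(alts), function(i) {
        d <- abs(nchar(alts[[i]]) - refn[i])
        !any(d >= 1L & d <= 30L) || any(d > 30L)
      }, logical(1))
      if (any(bad)) msgs <- c(msgs, "INDEL net length must be 1..30 bp")
    }
    # genotype allele indices must address ref or a declared alt
    for (j in seq_along(object@samples)) {
      idx <- .parse_gt(object@gt[, j])
      ok <- is.na(idx) | idx <= rep(n_alt, 2L)
      if (!all(ok)) msgs <- c(msgs, sprintf(
        "sample %s: genotype allele index exceeds alternate-allele count",
        object@samples[j]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GeneModels number of gene models
#' @param x,object a `GeneModels` or `VariantSet`
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", length(object), "genes on",
      length(unique(as.character(GenomeInfoDb::seqnames(object@genes)))),
      "sequences\n")
  if (length(object) > 0) {
    n_seg <- lengths(object@cds)
    cat("  CDS segments per gene:", min(n_seg), "-", max(n_seg), "\n")
  }
})

setMethod("show", "VariantSet", function(object) {
  cls <- table(object@tab$var_class)
  cat("VariantSet with", nrow(object@tab), "records (",
      paste(names(cls), as.integer(cls), collapse = ", "),
      ") for samples:", paste(object@samples, collapse = ", "), "\n")
})

#' Accessors for GeneModels and VariantSet
#'
#' `geneTable()` returns gene spans as a data.frame; `cdsByGene()` the
#' CDS `GRangesList`; `variantTable()` the variant table;
#' `genotypes()` the genotype string matrix; `sampleNames()` the sample
#' names; `nVariants()` the record count.
#'
#' @param x a `GeneModels` or `VariantSet`
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
geneTable <- function(x) {
  stopifnot(is(x, "GeneModels"))
  g <- x@genes
  data.frame(gene_id = g$gene_id,
             chrom = as.character(GenomeInfoDb::seqnames(g)),
             start = GenomicRanges::start(g), end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             biotype = g$biotype, stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
cdsByGene <- function(x) { stopifnot(is(x, "GeneModels")); x@cds }

#' @rdname accessors
#' @export
variantTable <- function(x) { stopifnot(is(x, "VariantSet")); x@tab }

#' @rdname accessors
#' @export
genotypes <- function(x) { stopifnot(is(x, "VariantSet")); x@gt }

#' @rdname accessors
#' @export
sampleNames <- function(x) { stopifnot(is(x, "VariantSet")); x@samples }

#' @rdname accessors
#' @export
nVariants <- function(x) { stopifnot(is(x, "VariantSet")); nrow(x@tab) }

#' @rdname accessors
#' @export
readDepth <- function(x) { stopifnot(is(x, "VariantSet")); x@depth }

#' Construct a VariantSet from parts
#'
#' Low-level constructor used by the readers and the simulator.
#'
#' @param tab variant table (see [VariantSet-class])
#' @param gt genotype string matrix, one column per sample
#' @param samples sample names
#' @param depth optional read-depth matrix (defaults to all-`NA`)
#' @return a `VariantSet`
#' @export
VariantSet <- function(tab, gt, samples, depth = NULL) {
  gt <- as.matrix(gt)
  if (is.null(depth))
    depth <- matrix(NA_real_, nrow(gt), ncol(gt))
  depth <- as.matrix(depth)
  colnames(gt) <- samples
  colnames(depth) <- samples
  rownames(tab) <- NULL
  new("VariantSet", tab = tab, gt = gt, depth = depth,
      samples = as.character(samples))
}

#' Construct GeneModels from parts
#'
#' @param genes `GRanges` of gene spans with `gene_id` (and optionally
#'   `biotype`) metadata columns
#' @param cds `GRangesList` of CDS segments named by gene id
#' @param exons optional `GRangesList` of exon segments
#' @return a `GeneModels` object
#' @export
GeneModels <- function(genes, cds, exons = NULL) {
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (is.null(exons)) exons <- GenomicRanges::GRangesList()
  new("GeneModels", genes = genes, cds = cds, exons = exons)
}

#' Subset a VariantSet by row index
#'
#' @param x a `VariantSet`
#' @param i integer or logical index over variant records
#' @param j,...,drop ignored
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  VariantSet(x@tab[i, , drop = FALSE],
             x@gt[i, , drop = FALSE],
             x@samples,
             x@depth[i, , drop = FALSE])
})
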