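# Internal helpers shared across modules. Nothing here is exported.

# Standard genetic code, keyed by codon. Codons containing N (or any
# non-ACGT base) translate to "X".
.codon_table <- function() Biostrings::GENETIC_CODE

.AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter", X = "Xaa"
)

.revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split a nucleotide string into codons (trailing partial codon dropped).
.codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character(0))
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Translate codon vector; unknown codons (with N etc.) -> "X".
.translate_codons <- function(codons) {
  aa <- unname(.codon_table()[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# Split comma-joined alternate alleles; an empty string (pure deletion
# after normalization) is one empty allele, not zero alleles.
.split_alts <- function(alt) {
  out <- strsplit(alt, ",", fixed = TRUE)
  out[lengths(out) == 0L] <- list("")
  out
}

# Parse diploid GT strings ("0/1", "1|1", ".", "./.") into a two-column
# integer matrix of allele indices; missing calls -> NA rows.
.parse_gt <- function(gt) {
  gt <- as.character(gt)
  gt[is.na(gt)] <- "."
  parts <- strsplit(gt, "[/|]")
  a1 <- vapply(parts, function(p) p[1], character(1))
  a2 <- vapply(parts, function(p) if (length(p) > 1L) p[2] else p[1],
               character(1))
  conv <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out
  }
  cbind(conv(a1), conv(a2))
}

.is_missing_gt <- function(gt) {
  m <- .parse_gt(gt)
  is.na(m[, 1]) | is.na(m[, 2])
}

# INFO field extraction from raw VCF INFO strings.
.info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic sub-seed derivation (kept < 2^31).
.subseed <- function(seed, k) (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
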