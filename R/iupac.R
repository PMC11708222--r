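# IUPAC nucleotide codes as 4-bit sets over (A, C, G, T).
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# Inverse map: bit pattern -> canonical IUPAC letter.
BITS_IUPAC <- character(15L)
BITS_IUPAC[IUPAC_BITS] <- names(IUPAC_BITS)

#' Convert a nucleotide string to IUPAC bit sets
#'
#' Each character becomes a 4-bit integer over (A, C, G, T); `-` becomes 0.
#' Used internally by the probe scanner and distance computations.
#'
#' @param x single nucleotide string (IUPAC alphabet, optionally with `-`).
#' @return integer vector of bit sets, one per character.
#' @keywords internal
seq_bits <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bits <- unname(IUPAC_BITS[chars])
  bits[chars == "-"] <- 0L
  bad <- which(is.na(bits))
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  bits
}

bits_to_char <- function(bits) {
  out <- rep("-", length(bits))
  nz <- bits > 0L
  out[nz] <- BITS_IUPAC[bits[nz]]
  out
}

#' Test whether two IUPAC codes are compatible
#'
#' Two codes are compatible when the nucleotide sets they denote intersect:
#' `R` (A or G) is compatible with `G` but not with `T`; `N` is compatible
#' with everything.  The relation is symmetric.  This is the semantics under
#' which heterozygous positions encoded as ambiguity codes still match a
#' probe built from a homozygous reference.
#'
#' @param observed,expected single IUPAC nucleotide characters (vectorized).
#' @return logical vector.
#' @examples
#' iupac_compatible("R", "G")  # TRUE
#' iupac_compatible("R", "T")  # FALSE
#' @export
iupac_compatible <- function(observed, expected) {
  ob <- IUPAC_BITS[toupper(observed)]
  eb <- IUPAC_BITS[toupper(expected)]
  if (anyNA(ob)) stop("non-IUPAC character: ", observed[which(is.na(ob))[1L]], call. = FALSE)
  if (anyNA(eb)) stop("non-IUPAC character: ", expected[which(is.na(eb))[1L]], call. = FALSE)
  unname(bitwAnd(ob, eb) > 0L)
}

#' Expand an IUPAC codon into the concrete codons it denotes
#'
#' @param codon 3-character string, possibly containing ambiguity codes.
#' @return character vector of concrete (ACGT) codons, in a fixed order.
#' @keywords internal
expand_codon <- function(codon) {
  bits <- seq_bits(codon)
  if (length(bits) != 3L || any(bits == 0L)) {
    stop("codon must be 3 IUPAC nucleotides, got '", codon, "'", call. = FALSE)
  }
  base_sets <- lapply(bits, function(b) {
    c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
  })
  grid <- expand.grid(base_sets[[3L]], base_sets[[2L]], base_sets[[1L]],
                      stringsAsFactors = FALSE)
  sort(paste0(grid[[3L]], grid[[2L]], grid[[1L]]))
}

#' Translate an IUPAC codon into its amino-acid set
#'
#' Expands ambiguity codes and translates every concrete codon with the
#' standard genetic code; stop codons translate to `*`.
#'
#' @param codon 3-character IUPAC string.
#' @return sorted character vector of distinct amino-acid letters.
#' @keywords internal
codon_aas <- function(codon) {
  codons <- expand_codon(codon)
  sort(unique(unname(Biostrings::GENETIC_CODE[codons])))
}

# Position-wise IUPAC union of two equal-length nucleotide strings.
iupac_union <- function(a, b) {
  ba <- seq_bits(a)
  bb <- seq_bits(b)
  paste(bits_to_char(bitwOr(ba, bb)), collapse = "")
}

# Codons (ACGT) encoding a given amino-acid letter (stop = "*").
codons_for_aa <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == aa])
}
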