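## Small shared helpers (internal).

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("TAC")  # "GTA"
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement of a vector of single bases, N-safe
comp_bases <- function(b) unname(COMPLEMENT[b])

## variant identity key: the 4-tuple the recurrence filter matches on
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## classify ref/alt allele pair
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

check_alleles <- function(ref, alt, where = "variant table") {
  bad_chr <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad_chr)) {
    stop(sprintf("%s: alleles must be non-empty strings over {A,C,G,T} (first bad row: %d)",
                 where, which(bad_chr)[1L]))
  }
  same <- ref == alt
  if (any(same)) {
    stop(sprintf("%s: ref and alt must differ (first bad row: %d)",
                 where, which(same)[1L]))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
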