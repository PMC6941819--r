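## CIGAR geometry: the in-read position of a reference coordinate, and
## soft-clip detection.  This is the read-level primitive the whole
## positional-bias feature rests on, so it is implemented (and fuzz-tested
## against a per-base expansion oracle) rather than delegated.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")   # consume query
REF_OPS   <- c("M", "D", "N", "=", "X")   # consume reference

#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR string, e.g. `"5S95M"`.
#' @return `data.frame` with columns `op` (character) and `len` (integer),
#'   in alignment order.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    stop("read has no CIGAR (unaligned?)")
  }
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar)) {
    stop(sprintf("malformed CIGAR string '%s'", cigar))
  }
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

## query length implied by a CIGAR (SEQ length, excluding hard clips)
cigar_query_len <- function(ops) sum(ops$len[ops$op %in% QUERY_OPS])

## reference span consumed by a CIGAR
cigar_ref_span <- function(ops) sum(ops$len[ops$op %in% REF_OPS])

#' In-read position of a reference coordinate
#'
#' Walks the CIGAR left to right keeping a (query, reference) cursor pair:
#' `M`/`=`/`X` advance both, `I`/`S` advance the query only, `D`/`N` advance
#' the reference only, `H`/`P` advance neither.  Returns the 1-based query
#' index aligned to `ref_pos`, or `NA` when `ref_pos` falls inside a
#' deletion/skip (`D`/`N`) segment.
#'
#' @param cigar CIGAR string of the read.
#' @param ref_start 1-based leftmost aligned reference position (SAM `POS`).
#' @param ref_pos 1-based reference coordinate to locate; must lie within the
#'   read's aligned span.
#' @return 1-based query offset, or `NA_integer_` for a deleted position.
#' @examples
#' query_offset("100M", 1001, 1011)   # 11
#' query_offset("5S95M", 1001, 1001)  # 6 (leading soft clip shifts the cursor)
#' query_offset("50M10D50M", 1, 56)   # NA (inside the deletion)
#' @export
query_offset <- function(cigar, ref_start, ref_pos) {
  ops <- parse_cigar(cigar)
  span <- cigar_ref_span(ops)
  if (ref_pos < ref_start || ref_pos >= ref_start + span) {
    stop(sprintf("ref_pos %d outside aligned span [%d, %d] of CIGAR '%s'",
                 ref_pos, ref_start, ref_start + span - 1L, cigar))
  }
  q <- 0L
  r <- ref_start - 1L  # last reference base consumed so far
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    qc <- op %in% QUERY_OPS
    rc <- op %in% REF_OPS
    if (rc && ref_pos <= r + len) {
      if (!qc) return(NA_integer_)           # D/N: position deleted from read
      return(q + (ref_pos - r))
    }
    if (qc) q <- q + len
    if (rc) r <- r + len
  }
  stop("internal error: CIGAR walk exhausted")  # unreachable given span check
}

#' Does a CIGAR carry a soft clip?
#'
#' @param cigar CIGAR string.
#' @param min_clip minimum `S` operation length to qualify (default 1).
#' @return logical.
#' @export
has_soft_clip <- function(cigar, min_clip = 1L) {
  ops <- parse_cigar(cigar)
  any(ops$op == "S" & ops$len >= min_clip)
}
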