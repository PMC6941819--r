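## read_evidence: per-variant read-level features.  Artifacts from
## endonuclease fragmentation betray themselves on the reads that carry
## them: the variant base clusters 10-15 bases from a read end (positional
## bias, scored by a two-sample KS test against wildtype reads) and the
## carrying reads are frequently soft-clipped.

## Locate the anchor base of a variant in a read and describe the CIGAR op
## boundary immediately to its right (needed for indel classification).
.anchor_context <- function(cigar, ref_start, ref_pos) {
  ops <- parse_cigar(cigar)
  q <- 0L
  r <- ref_start - 1L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    qc <- op %in% QUERY_OPS
    rc <- op %in% REF_OPS
    if (rc && ref_pos <= r + len) {
      if (!qc) return(list(q = NA_integer_))
      offset_in_op <- ref_pos - r
      nxt <- if (offset_in_op == len && i < nrow(ops)) ops[i + 1L, ] else NULL
      return(list(q = q + offset_in_op,
                  at_op_end = offset_in_op == len,
                  next_op = if (is.null(nxt)) NA_character_ else nxt$op,
                  next_len = if (is.null(nxt)) NA_integer_ else nxt$len))
    }
    if (qc) q <- q + len
    if (rc) r <- r + len
  }
  list(q = NA_integer_)
}

#' Classify which allele a read supports
#'
#' For an SNV the query base aligned to the variant position is compared to
#' the alt and ref alleles.  For an insertion, a read supports alt iff an `I`
#' operation of the inserted length immediately follows the anchor base; for
#' a deletion, iff a `D` operation of the deleted length follows the anchor.
#' Reads in which the anchor falls in a deletion, carries a third allele, or
#' shows a different-length indel are classified `"other"` and excluded from
#' both evidence samples.
#'
#' @param read one read: a list or single-row `data.frame` with `pos`,
#'   `cigar`, `seq` (see [fetch_reads_at()]).
#' @param variant one variant call row (see [variant_calls()]).
#' @return `"alt"`, `"ref"` or `"other"`.
#' @export
classify_read_allele <- function(read, variant) {
  if (variant$vtype == "SNV") {
    q <- query_offset(read$cigar, read$pos, variant$pos)
    if (is.na(q)) return("other")
    base <- substr(read$seq, q, q)
    if (base == variant$alt) return("alt")
    if (base == variant$ref) return("ref")
    return("other")
  }
  ctx <- .anchor_context(read$cigar, read$pos, variant$pos)
  if (is.na(ctx$q)) return("other")
  indel_len <- abs(nchar(variant$alt) - nchar(variant$ref))
  want_op <- if (variant$vtype == "insertion") "I" else "D"
  adjacent <- isTRUE(ctx$at_op_end) && identical(ctx$next_op, want_op)
  if (adjacent && ctx$next_len == indel_len) return("alt")
  if (isTRUE(ctx$at_op_end) && ctx$next_op %in% c("I", "D")) return("other")
  "ref"
}

#' Collect per-variant read evidence
#'
#' @param reads reads covering the variant position, from [fetch_reads_at()].
#' @param variant one variant call row.
#' @param min_clip minimum soft-clip (`S`) length for a read to count as
#'   soft-clipped (default 1).
#' @return an object of class `variant_evidence`: the variant key plus
#'   1-based in-read offsets and read lengths of alt- and ref-supporting
#'   reads, `n_alt`, `n_ref`, and `n_alt_softclipped`.
#' @export
collect_evidence <- function(reads, variant, min_clip = 1L) {
  n <- nrow(reads)
  allele <- character(n)
  offset <- integer(n)
  for (i in seq_len(n)) {
    rd <- reads[i, ]
    allele[i] <- classify_read_allele(rd, variant)
    offset[i] <- if (allele[i] == "other") NA_integer_ else {
      q <- query_offset(rd$cigar, rd$pos, variant$pos)
      if (is.na(q)) NA_integer_ else q
    }
  }
  is_alt <- allele == "alt" & !is.na(offset)
  is_ref <- allele == "ref" & !is.na(offset)
  if (!any(is_alt)) {
    stop(sprintf("variant %s has no alt-supporting reads in this BAM (uncallable)",
                 variant_key(variant$chrom, variant$pos, variant$ref, variant$alt)))
  }
  clipped <- vapply(reads$cigar[is_alt], has_soft_clip, logical(1L),
                    min_clip = min_clip, USE.NAMES = FALSE)
  structure(list(
    variant = variant_key(variant$chrom, variant$pos, variant$ref, variant$alt),
    alt_offsets = offset[is_alt],
    alt_read_len = nchar(reads$seq[is_alt]),
    ref_offsets = offset[is_ref],
    ref_read_len = nchar(reads$seq[is_ref]),
    n_alt = sum(is_alt),
    n_ref = sum(is_ref),
    n_alt_softclipped = sum(clipped)
  ), class = "variant_evidence")
}

#' @export
print.variant_evidence <- function(x, ...) {
  cat(sprintf("<variant_evidence> %s: %d alt / %d ref reads, %d alt soft-clipped\n",
              x$variant, x$n_alt, x$n_ref, x$n_alt_softclipped))
  invisible(x)
}

## fold a 1-based in-read offset to its distance from the nearest read end
## (0 = terminal base); symmetric in the 5'/3' ends, as the artifact is.
.end_distance <- function(offset, read_len) pmin(offset - 1L, read_len - offset)

#' Positional-bias test
#'
#' Two-sample two-sided Kolmogorov-Smirnov test comparing the in-read
#' positions of the variant on alt-supporting reads against the same
#' positions on wildtype (ref-supporting) reads.  By default positions are
#' folded to the distance from the nearest read end, since the fragmentation
#' artifact clusters near either end.  The exact conditional null
#' distribution (which accounts for ties) is used whenever
#' `n_alt * n_ref <= 10000`, the asymptotic distribution otherwise.
#'
#' When either sample has fewer than `min_n` reads the test is not evaluable
#' and `ks_p = 1` is returned by convention (no evidence of bias).
#'
#' @param evidence a `variant_evidence` object.
#' @param transform `"end_distance"` (default) or `"raw_offset"`.
#' @param min_n minimum reads per sample (default 3).
#' @return list with `ks_p`, `ks_D`, `evaluable`.
#' @export
positional_bias <- function(evidence,
                            transform = c("end_distance", "raw_offset"),
                            min_n = 3L) {
  transform <- match.arg(transform)
  a <- evidence$alt_offsets
  r <- evidence$ref_offsets
  if (transform == "end_distance") {
    a <- .end_distance(a, evidence$alt_read_len)
    r <- .end_distance(r, evidence$ref_read_len)
  }
  if (length(a) < min_n || length(r) < min_n) {
    return(list(ks_p = 1, ks_D = NA_real_, evaluable = FALSE))
  }
  kt <- suppressWarnings(
    stats::ks.test(a, r, alternative = "two.sided",
                   exact = length(a) * length(r) <= 10000))
  list(ks_p = unname(kt$p.value), ks_D = unname(kt$statistic), evaluable = TRUE)
}

#' Soft-clipped read ratio
#'
#' Fraction of alt-supporting reads bearing a soft clip.
#'
#' @param evidence a `variant_evidence` object.
#' @return fraction in \[0, 1\].
#' @export
soft_clip_ratio <- function(evidence) {
  if (evidence$n_alt == 0L) stop("no alt-supporting reads")
  evidence$n_alt_softclipped / evidence$n_alt
}

#' Binned histogram of in-read variant offsets
#'
#' @param evidence a `variant_evidence` object.
#' @param bin_width bin width in bases (default 5).
#' @return `data.frame` with `bin_start`, `bin_end` (1-based, inclusive) and
#'   counts `alt` and `ref`.
#' @export
offset_histogram <- function(evidence, bin_width = 5L) {
  max_len <- max(c(evidence$alt_read_len, evidence$ref_read_len, 1L))
  n_bins <- ceiling(max_len / bin_width)
  starts <- (seq_len(n_bins) - 1L) * bin_width + 1L
  bin_of <- function(off) pmin((off - 1L) %/% bin_width + 1L, n_bins)
  data.frame(
    bin_start = starts,
    bin_end = starts + bin_width - 1L,
    alt = tabulate(bin_of(evidence$alt_offsets), nbins = n_bins),
    ref = tabulate(bin_of(evidence$ref_offsets), nbins = n_bins))
}
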