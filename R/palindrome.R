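## SNV-centered palindromes (SCPs).  The endonuclease implicated in
## enzymatic fragmentation prefers palindromic recognition sites; erroneous
## fill-in at hairpin centers then shows up as an SNV at the exact center of
## a palindromic reference context.  The SCP length (2*arm + 1, odd) is the
## maximal such context; length 0 denotes "no reportable palindrome".

#' Maximal SNV-centered palindrome at a reference window
#'
#' Starting from the window center (the variant base, which is a free "loop"
#' position and never compared), arms are extended symmetrically while the
#' base `i` positions 3' of the center pairs with the base `i` positions 5'
#' of it: complementary in `revcomp` mode (a hairpin: the 3' arm is the
#' reverse complement of the 5' arm), equal in `mirror` mode.  Any `N`
#' stops extension.
#'
#' @param window a reference window from [fetch_reference_window()], or a
#'   plain odd-length character string.
#' @param mode `"revcomp"` (default, hairpin-forming) or `"mirror"`.
#' @param min_arm minimum arm length for a reportable SCP (default 2, i.e.
#'   reported lengths are 0 or >= 5).
#' @param max_arm maximum arm length to test; defaults to the window flank.
#' @return object of class `scp`: `arm_len` (maximal matching arm, before
#'   the `min_arm` cutoff), `scp_len` (`2*arm_len + 1`, or 0 when
#'   `arm_len < min_arm`), `arm_seq` (the 5' arm), `mode`.
#' @examples
#' scp_length("TACGGTA")  # arm 3: "GTA" reverse-complements "TAC"
#' scp_length("AAAAA")    # no hairpin: scp_len 0
#' @export
scp_length <- function(window, mode = c("revcomp", "mirror"),
                       min_arm = 2L, max_arm = NULL) {
  mode <- match.arg(mode)
  seq <- if (is.list(window)) window$seq else window
  n <- nchar(seq)
  if (n %% 2L == 0L) stop("window must have odd length (centered on the variant)")
  center <- (n + 1L) %/% 2L
  flank <- center - 1L
  max_arm <- min(max_arm %||% flank, flank)
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  k <- 0L
  while (k < max_arm) {
    left <- bases[center - k - 1L]
    right <- bases[center + k + 1L]
    ok <- if (mode == "revcomp") {
      left %in% DNA_BASES && right == COMPLEMENT[[left]]
    } else {
      left %in% DNA_BASES && right == left
    }
    if (!ok) break
    k <- k + 1L
  }
  structure(list(
    arm_len = k,
    scp_len = if (k >= min_arm) 2L * k + 1L else 0L,
    arm_seq = if (k > 0L) substr(seq, center - k, center - 1L) else "",
    mode = mode
  ), class = "scp")
}

#' @export
print.scp <- function(x, ...) {
  cat(sprintf("<scp> length %d (arm %d, mode %s)%s\n", x$scp_len, x$arm_len,
              x$mode, if (x$scp_len > 0L) paste0(" arm=", x$arm_seq) else ""))
  invisible(x)
}

#' Annotate variant calls with their SCP
#'
#' @param calls a variant call table (SNVs get an SCP; indels get 0 by
#'   contract, since the "center" of an indel is undefined).
#' @param ref reference (path or `DNAStringSet`).
#' @param max_arm maximum arm length tested (window flank; default 20,
#'   covering SCP lengths up to 41).
#' @inheritParams scp_length
#' @return `calls` with columns `arm_len`, `scp_len`, `arm_seq` appended.
#' @export
scp_annotate <- function(calls, ref, mode = "revcomp", min_arm = 2L,
                         max_arm = 20L) {
  ref <- load_reference(ref)
  n <- nrow(calls)
  arm_len <- integer(n); scp_len <- integer(n); arm_seq <- character(n)
  for (i in seq_len(n)) {
    if (calls$vtype[i] != "SNV") next
    w <- fetch_reference_window(ref, calls$chrom[i], calls$pos[i], max_arm)
    s <- scp_length(w, mode = mode, min_arm = min_arm, max_arm = max_arm)
    arm_len[i] <- s$arm_len; scp_len[i] <- s$scp_len; arm_seq[i] <- s$arm_seq
  }
  calls$arm_len <- arm_len
  calls$scp_len <- scp_len
  calls$arm_seq <- arm_seq
  calls
}

#' SCP length spectrum
#'
#' Histogram of SNV counts per odd SCP length (0 = no reportable
#' palindrome); counts conserve the number of input SNVs.
#'
#' @param x either an `scp_annotate()`d call table or a vector of SCP
#'   lengths.
#' @param max_len largest length to tabulate (longer SCPs are counted at
#'   their own length; the table extends to cover them).
#' @return `data.frame` with `scp_len` (0, 5, 7, ...) and `count`.
#' @export
scp_spectrum <- function(x, max_len = 21L) {
  lens <- if (is.data.frame(x)) x$scp_len[x$vtype == "SNV"] else x
  lens <- lens[!is.na(lens)]
  levels <- c(0L, seq(5L, max(max_len, lens, 5L), by = 2L))
  data.frame(scp_len = levels,
             count = vapply(levels, function(l) sum(lens == l), integer(1L)))
}

#' Fraction of alt reads with the whole palindrome nested near a read edge
#'
#' For each alt-supporting read the in-read span of the full palindrome
#' (center +/- arm) is computed; the read counts as "nested" when that span
#' lies entirely within `margin` bases of either read end.  Reads in which
#' the span is not fully aligned (e.g. crosses a deletion or runs off the
#' aligned portion) are excluded from the denominator.
#'
#' @param reads reads covering the variant (see [fetch_reads_at()]).
#' @param variant one SNV call row.
#' @param arm_len palindrome arm length (> 0).
#' @param margin edge margin in bases (default 30).
#' @return list with `fraction`, `n_nested`, `n_evaluable`.
#' @export
scp_read_nesting <- function(reads, variant, arm_len, margin = 30L) {
  stopifnot(arm_len > 0L)
  n_nested <- 0L; n_eval <- 0L
  for (i in seq_len(nrow(reads))) {
    rd <- reads[i, ]
    if (classify_read_allele(rd, variant) != "alt") next
    ops <- parse_cigar(rd$cigar)
    span_lo <- variant$pos - arm_len
    span_hi <- variant$pos + arm_len
    if (span_lo < rd$pos || span_hi >= rd$pos + cigar_ref_span(ops)) next
    qlo <- query_offset(rd$cigar, rd$pos, span_lo)
    qhi <- query_offset(rd$cigar, rd$pos, span_hi)
    if (is.na(qlo) || is.na(qhi) || (qhi - qlo) != 2L * arm_len) next
    n_eval <- n_eval + 1L
    read_len <- nchar(rd$seq)
    if (qhi <= margin || qlo > read_len - margin) n_nested <- n_nested + 1L
  }
  list(fraction = if (n_eval > 0L) n_nested / n_eval else NA_real_,
       n_nested = n_nested, n_evaluable = n_eval)
}

#' Palindrome recurrence across samples
#'
#' Counts distinct palindromes (identified by their 5' arm sequence, i.e.
#' the reference-allele sequence of the SCP) and whether each is seen in one
#' sample or recurrently across samples.
#'
#' @param annotated an `scp_annotate()`d call table with `sample_id`.
#' @return `data.frame` with one row per distinct (scp_len, arm_seq):
#'   `scp_len`, `arm_seq`, `n_samples`, `recurrent`.
#' @export
scp_recurrence_table <- function(annotated) {
  keep <- annotated$vtype == "SNV" & annotated$scp_len > 0L
  a <- annotated[keep, , drop = FALSE]
  if (nrow(a) == 0L) {
    return(data.frame(scp_len = integer(), arm_seq = character(),
                      n_samples = integer(), recurrent = logical()))
  }
  key <- paste(a$scp_len, a$arm_seq, sep = ":")
  n_samples <- vapply(split(a$sample_id, key),
                      function(s) length(unique(s)), integer(1L))
  parts <- strsplit(names(n_samples), ":", fixed = TRUE)
  data.frame(scp_len = as.integer(vapply(parts, `[[`, "", 1L)),
             arm_seq = vapply(parts, `[[`, "", 2L),
             n_samples = unname(n_samples),
             recurrent = unname(n_samples) > 1L)
}
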