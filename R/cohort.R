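## cohort_filter: stage 1 of the two-stage algorithm.  Fragmentation
## artifacts hit the same preferred cleavage sites in every library, so the
## identical call (chrom, pos, ref, alt) recurs across unrelated samples of
## a pooled enzymatically fragmented cohort.  Recurrent calls are removed,
## unless whitelisted as known-genuine (driver mutations also recur across
## tumors), in which case they are passed on to the stage-2 classifier.

#' Build a cohort recurrence table
#'
#' Tallies, for every variant key, the number of distinct samples in the
#' pooled cohort carrying that exact call (duplicate listings within one
#' sample contribute once).
#'
#' @param calls variant call table over the whole cohort (with `sample_id`),
#'   or a list of per-sample call tables.
#' @return object of class `recurrence_table`: named integer vector of
#'   per-key sample counts plus the cohort sample ids.
#' @export
build_recurrence <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) {
    ids <- vapply(calls, function(x) unique(x$sample_id)[1L], "")
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate sample_id '%s' in cohort", ids[duplicated(ids)][1L]))
    }
    calls <- do.call(rbind, calls)
  }
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  uniq <- unique(data.frame(key = key, sample_id = calls$sample_id))
  counts <- table(uniq$key)
  structure(list(
    counts = setNames(as.integer(counts), names(counts)),
    samples = unique(calls$sample_id)
  ), class = "recurrence_table")
}

#' @export
print.recurrence_table <- function(x, ...) {
  cat(sprintf("<recurrence_table> %d keys over %d samples (%d keys recurrent)\n",
              length(x$counts), length(x$samples), sum(x$counts >= 2L)))
  invisible(x)
}

#' Look up recurrence counts
#'
#' @param table a `recurrence_table`.
#' @param keys variant keys (`chrom:pos:ref:alt`).
#' @return integer counts; keys absent from the cohort return 0.
#' @export
recurrence_count <- function(table, keys) {
  out <- table$counts[keys]
  out[is.na(out)] <- 0L
  setNames(as.integer(out), keys)
}

#' Stage-1 cohort recurrence filter with whitelist rescue
#'
#' A call is removed when it is carried by at least `recurrence_min`
#' distinct samples and is not whitelisted.  Whitelisted recurrent calls are
#' "rescued": kept at this stage and passed on to the stage-2 classifier.
#'
#' The reported `recurrence_count` is the number of distinct cohort samples
#' carrying the key, always counting the query sample itself as a carrier:
#' in the default leave-one-out mode the query sample's own calls are
#' excluded from the pooled tally and 1 is added back for self, so a private
#' variant has count 1 and `recurrence_min = 2` means "seen in another
#' sample too" under either mode.
#'
#' @param calls query-sample call table.
#' @param table cohort `recurrence_table` (may include the query sample).
#' @param whitelist character vector of whitelisted keys (from
#'   [read_whitelist()]), or `NULL`.
#' @param recurrence_min minimum number of distinct carrying samples for
#'   removal (default 2).
#' @param include_self if `FALSE` (default, leave-one-out) and the query
#'   sample was pooled into `table`, its own contribution is removed from
#'   the tally before self is counted back.
#' @return `calls` with columns `recurrence_count`, `whitelisted`, `removed`
#'   and `reason` (`passed` / `recurrent_not_whitelisted` /
#'   `rescued_whitelist`) appended.
#' @export
stage_one_filter <- function(calls, table, whitelist = NULL,
                             recurrence_min = 2L, include_self = FALSE) {
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  count <- recurrence_count(table, key)
  self_pooled <- length(unique(calls$sample_id)) == 1L &&
    unique(calls$sample_id) %in% table$samples
  if (!include_self && self_pooled) {
    ## drop self from the pooled tally, then count self back as a carrier
    count <- pmax(count - 1L, 0L) + 1L
  } else if (!self_pooled) {
    ## cohort of other samples only: the query sample still carries the call
    count <- count + 1L
  }
  whitelisted <- key %in% (whitelist %||% character())
  recurrent <- count >= recurrence_min
  removed <- recurrent & !whitelisted
  calls$recurrence_count <- unname(count)
  calls$whitelisted <- whitelisted
  calls$removed <- removed
  calls$reason <- ifelse(removed, "recurrent_not_whitelisted",
                         ifelse(recurrent & whitelisted, "rescued_whitelist",
                                "passed"))
  calls
}
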