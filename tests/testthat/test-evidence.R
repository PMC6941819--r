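## a clean 100M read whose sequence is all ref except possibly the variant base
ref_read <- function(pos, base_at, at, len = 100L, cigar = NULL) {
  seq <- strrep("A", len)
  substr(seq, at, at) <- base_at
  make_read(pos, cigar %||% paste0(len, "M"), seq)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SNV allele classification matches the read base at the variant offset", {
  v <- make_variant(pos = 150L, ref = "A", alt = "T")
  expect_equal(classify_read_allele(ref_read(101L, "T", 50L), v), "alt")
  expect_equal(classify_read_allele(ref_read(101L, "A", 50L), v), "ref")
  ## third allele is excluded from both samples
  expect_equal(classify_read_allele(ref_read(101L, "G", 50L), v), "other")
  ## variant position deleted from the read
  del <- make_read(101L, "40M20D60M", strrep("A", 100L))
  expect_equal(classify_read_allele(del, v), "other")
})

test_that("indel allele classification requires the matching-length op at the anchor", {
  ins <- make_variant(pos = 100L, ref = "A", alt = "ATT")
  ## 50M covers ref 51..100, anchor at query 50, then a 2-base insertion
  rd_alt <- make_read(51L, "50M2I48M", strrep("A", 100L))
  expect_equal(classify_read_allele(rd_alt, ins), "alt")
  rd_ref <- make_read(51L, "100M", strrep("A", 100L))
  expect_equal(classify_read_allele(rd_ref, ins), "ref")
  ## wrong-length insertion: neither allele
  rd_other <- make_read(51L, "50M3I47M", strrep("A", 100L))
  expect_equal(classify_read_allele(rd_other, ins), "other")

  del <- make_variant(pos = 100L, ref = "ATT", alt = "A")
  expect_equal(classify_read_allele(make_read(51L, "50M2D50M", strrep("A", 100L)), del), "alt")
  expect_equal(classify_read_allele(make_read(51L, "100M", strrep("A", 100L)), del), "ref")
  expect_equal(classify_read_allele(make_read(51L, "50M3D50M", strrep("A", 100L)), del), "other")
})

test_that("collect_evidence tallies offsets and soft clips, and flags uncallable variants", {
  v <- make_variant(pos = 150L, ref = "A", alt = "T")
  reads <- rbind(
    ref_read(101L, "T", 50L),                         # alt, unclipped
    ref_read(131L, "T", 30L, cigar = "10S90M"),       # alt at query 30, soft-clipped
    ref_read(101L, "T", 50L, len = 95L, cigar = "95M"),  # alt, shorter read, no clip
    ref_read(101L, "A", 50L),                         # ref
    ref_read(101L, "G", 50L))                         # other
  ev <- collect_evidence(reads, v)
  expect_s3_class(ev, "variant_evidence")
  expect_equal(ev$n_alt, 3L)
  expect_equal(ev$n_ref, 1L)
  expect_equal(ev$n_alt_softclipped, 1L)
  expect_equal(sort(ev$alt_offsets), c(30L, 50L, 50L))
  expect_equal(soft_clip_ratio(ev), 1 / 3)

  only_ref <- ref_read(101L, "A", 50L)
  expect_error(collect_evidence(only_ref, v), "no alt-supporting reads")
})

test_that("positional bias is a valid two-sided KS test with the small-sample convention", {
  ev <- structure(list(alt_offsets = c(11L, 12L, 13L, 14L),
                       alt_read_len = rep(100L, 4L),
                       ref_offsets = c(20L, 40L, 55L, 70L, 90L),
                       ref_read_len = rep(100L, 5L),
                       n_alt = 4L, n_ref = 5L, n_alt_softclipped = 0L),
                  class = "variant_evidence")
  pb <- positional_bias(ev)
  expect_true(pb$evaluable)
  expect_gte(pb$ks_p, 0); expect_lte(pb$ks_p, 1)
  expect_gte(pb$ks_D, 0); expect_lte(pb$ks_D, 1)

  ## identical samples: no bias evidence
  same <- ev
  same$ref_offsets <- same$alt_offsets
  same$ref_read_len <- same$alt_read_len
  pb_same <- positional_bias(same, transform = "raw_offset")
  expect_equal(pb_same$ks_D, 0)
  expect_equal(pb_same$ks_p, 1)

  ## too few reads: not evaluable, p = 1 by convention
  tiny <- ev
  tiny$alt_offsets <- c(11L, 12L); tiny$alt_read_len <- rep(100L, 2L)
  pb_tiny <- positional_bias(tiny)
  expect_false(pb_tiny$evaluable)
  expect_equal(pb_tiny$ks_p, 1)
})

test_that("KS p is symmetric in the two samples and end-folding treats both ends alike", {
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:100, sample(3:10, 1), replace = TRUE)
    r <- sample(1:100, sample(3:10, 1), replace = TRUE)
    mk <- function(x, y) structure(
      list(alt_offsets = x, alt_read_len = rep(100L, length(x)),
           ref_offsets = y, ref_read_len = rep(100L, length(y)),
           n_alt = length(x), n_ref = length(y), n_alt_softclipped = 0L),
      class = "variant_evidence")
    expect_equal(positional_bias(mk(a, r))$ks_p, positional_bias(mk(r, a))$ks_p)
  }
  ## offsets d and read_len + 1 - d fold to the same end distance
  near5 <- mk_ev <- structure(
    list(alt_offsets = c(11L, 13L, 15L), alt_read_len = rep(100L, 3L),
         ref_offsets = c(30L, 50L, 70L, 20L), ref_read_len = rep(100L, 4L),
         n_alt = 3L, n_ref = 4L, n_alt_softclipped = 0L),
    class = "variant_evidence")
  near3 <- near5
  near3$alt_offsets <- 101L - near5$alt_offsets
  expect_equal(positional_bias(near5)$ks_p, positional_bias(near3)$ks_p)
})

test_that("offset histograms bin correctly and conserve read counts", {
  ev <- structure(list(alt_offsets = 1:5, alt_read_len = rep(100L, 5L),
                       ref_offsets = c(1L, 6L, 99L), ref_read_len = rep(100L, 3L),
                       n_alt = 5L, n_ref = 3L, n_alt_softclipped = 0L),
                  class = "variant_evidence")
  h <- offset_histogram(ev, bin_width = 5L)
  expect_equal(h$alt[1L], 5L)              # offsets 1..5 all in first bin
  expect_equal(sum(h$alt), ev$n_alt)
  expect_equal(sum(h$ref), ev$n_ref)
  expect_equal(h$ref[2L], 1L)              # offset 6 in second bin

  none <- ev; none$alt_offsets <- integer(0); none$ref_offsets <- integer(0)
  h0 <- offset_histogram(none)
  expect_true(all(h0$alt == 0L) && all(h0$ref == 0L))
})
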