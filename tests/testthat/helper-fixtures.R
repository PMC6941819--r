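## In-code fixtures shared across test files.

## a read record as fetch_reads_at() would return it
make_read <- function(pos, cigar, seq, qname = "r", flag = 0L, chrom = "chr1") {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             cigar = cigar, seq = seq)
}

## a single SNV/indel call row
make_variant <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                         sample_id = "s1") {
  variant_calls(chrom, pos, ref, alt, sample_id = sample_id)
}

## write SAM records (list of character vectors of fields) to an indexed BAM
write_test_bam <- function(records, contig = "chr1", contig_len = 10000L,
                           prefix = tempfile("testbam")) {
  sam <- paste0(prefix, ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  writeLines(c(hdr, vapply(records, paste, "", collapse = "\t")), sam)
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

sam_record <- function(qname, flag, pos, cigar, seq, chrom = "chr1") {
  c(qname, flag, chrom, pos, 60L, cigar, "*", 0L, 0L, seq,
    strrep("I", nchar(seq)))
}

## small in-memory reference
make_reference <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  x
}

## small, fast simulation shared by simulator/pipeline tests (computed once)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11L, ref_len = 30000L, n_samples = 2L,
                        n_artifact = 30L, n_genuine = 10L, depth = 30L,
                        n_whitelist_artifacts = 4L)
      cache <<- simulate_cohort(cfg, dir = tempfile("smallsim"))
    }
    cache
  }
})

## end-to-end pipeline run on the small simulation (computed once)
small_eval <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressWarnings(evaluate_pipeline(small_sim()))
    cache
  }
})
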