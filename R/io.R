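## core_io: readers/writers for the formats the pipeline touches.
## All positions are 1-based closed, the convention of VCF, SAM and the
## Bioconductor stack this package is built on.

#' Read a somatic variant call table
#'
#' Accepts either a VCF file (via [VariantAnnotation::readVcf()];
#' multi-allelic records are expanded to one call per ALT) or a tab-delimited
#' table whose first four columns are `chrom`, `pos`, `ref`, `alt` (header
#' optional, extra columns ignored).
#'
#' @param path path to a VCF (`.vcf`/`.vcf.gz`) or TSV file.
#' @param sample_id sample label attached to every call.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return a `data.frame` of variant calls with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `vtype` (`SNV`/`insertion`/`deletion`) and
#'   `sample_id`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tref\talt", "chr1\t100\tA\tT"), tf)
#' read_variant_calls(tf, sample_id = "s1")
#' @export
read_variant_calls <- function(path, sample_id,
                               format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  calls <- if (format == "vcf") .read_calls_vcf(path) else .read_calls_tsv(path)
  if (nrow(calls) == 0L) {
    warning(sprintf("no variant records in '%s'", path))
    return(variant_calls(character(), integer(), character(), character(),
                         sample_id = character()))
  }
  variant_calls(calls$chrom, calls$pos, calls$ref, calls$alt, sample_id = sample_id)
}

.read_calls_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  }
  ## tolerate an optional header row
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 2L && is.na(suppressWarnings(as.integer(first[2L])))
  if (has_header) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("malformed variant row at line %d of '%s' (need >= 4 tab-separated fields)",
                 which(nf < 4L)[1L] + has_header, path))
  }
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos)) {
    stop(sprintf("malformed position at line %d of '%s'",
                 which(is.na(pos))[1L] + has_header, path))
  }
  data.frame(chrom = vapply(fields, `[[`, "", 1L),
             pos = pos,
             ref = toupper(vapply(fields, `[[`, "", 3L)),
             alt = toupper(vapply(fields, `[[`, "", 4L)))
}

.read_calls_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)  # one row per ALT allele
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (length(rr) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(rr$REF),
             alt = as.character(rr$ALT))
}

#' Construct a validated variant call table
#'
#' @param chrom,pos,ref,alt vectors defining the calls; `pos` is the 1-based
#'   reference position (for indels, the leftmost anchor base as in VCF).
#' @param sample_id sample label (length 1 or one per call).
#' @return a variant call `data.frame`; see [read_variant_calls()].
#' @export
variant_calls <- function(chrom, pos, ref, alt, sample_id = "sample") {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  if (n > 0L) {
    check_alleles(rep_len(ref, n), rep_len(alt, n))
    if (any(pos < 1L)) stop("positions must be >= 1 (1-based)")
  }
  out <- data.frame(chrom = as.character(chrom), pos = pos, ref = ref,
                    alt = alt)
  out$vtype <- variant_type(out$ref, out$alt)
  out$sample_id <- if (n) rep_len(sample_id, n) else character()
  out
}

#' Write a variant call table as TSV
#'
#' Round-trips through [read_variant_calls()].
#'
#' @param calls a variant call `data.frame`.
#' @param path output path.
#' @export
write_variant_calls <- function(calls, path) {
  write.table(calls[, c("chrom", "pos", "ref", "alt", "vtype", "sample_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a whitelist of known-genuine variants
#'
#' Tab-delimited `chrom`, `pos` (1-based), `ref`, `alt` — the role the COSMIC
#' registry plays in cohort-recurrence rescue.
#'
#' @param path TSV path.
#' @return character vector of variant keys (`chrom:pos:ref:alt`).
#' @export
read_whitelist <- function(path) {
  tab <- .read_calls_tsv(path)
  if (nrow(tab)) check_alleles(tab$ref, tab$alt, where = "whitelist")
  unique(variant_key(tab$chrom, tab$pos, tab$ref, tab$alt))
}

#' Fetch reads covering a position from a BAM file
#'
#' Returns mapped, primary, non-duplicate reads whose aligned reference span
#' covers `pos` (soft/hard clips consume no reference, so clip-only overlap
#' does not count as coverage).
#'
#' @param path coordinate-sorted, indexed BAM file.
#' @param chrom,pos contig name and 1-based position.
#' @return `data.frame` with one row per read: `qname`, `flag`, `chrom`,
#'   `pos` (1-based leftmost aligned position), `cigar`, `seq`.
#' @export
fetch_reads_at <- function(path, chrom, pos) {
  bf <- Rsamtools::BamFile(path)
  hdr_contigs <- names(Rsamtools::scanBamHeader(bf)$targets)
  if (!chrom %in% hdr_contigs) {
    stop(sprintf("contig '%s' not present in BAM header of '%s'", chrom, path))
  }
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bf, param = param)[[1L]]
  data.frame(qname = res$qname, flag = res$flag,
             chrom = as.character(res$rname), pos = res$pos,
             cigar = res$cigar, seq = as.character(res$seq))
}

#' Load a reference genome
#'
#' @param ref a FASTA path or a [Biostrings::DNAStringSet].
#' @return a `DNAStringSet` keyed by contig name.
#' @export
load_reference <- function(ref) {
  if (methods::is(ref, "DNAStringSet")) return(ref)
  x <- Biostrings::readDNAStringSet(ref)
  ## FASTA headers may carry descriptions after the contig name
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Extract a reference window centered on a variant position
#'
#' @param ref reference (path or `DNAStringSet`, see [load_reference()]).
#' @param chrom contig name.
#' @param pos 1-based center position.
#' @param flank number of bases on each side; the window spans
#'   `2 * flank + 1` bases. Windows running off a contig end are padded with
#'   `N` and flagged.
#' @return list with `chrom`, `start` (1-based position of the first window
#'   base, possibly < 1 when padded), `seq` (uppercase character string) and
#'   `padded` (logical).
#' @export
fetch_reference_window <- function(ref, chrom, pos, flank) {
  stopifnot(flank >= 0)
  ref <- load_reference(ref)
  if (!chrom %in% names(ref)) {
    stop(sprintf("contig '%s' not found in reference", chrom))
  }
  contig <- ref[[chrom]]
  len <- length(contig)
  if (pos < 1L || pos > len) {
    stop(sprintf("position %d outside contig '%s' (length %d)", pos, chrom, len))
  }
  lo <- pos - flank
  hi <- pos + flank
  core <- as.character(Biostrings::subseq(contig, max(lo, 1L), min(hi, len)))
  seq <- paste0(strrep("N", max(0L, 1L - lo)), toupper(core),
                strrep("N", max(0L, hi - len)))
  list(chrom = chrom, start = lo, seq = seq,
       padded = lo < 1L || hi > len)
}
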