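## synthetic_data: a fully synthetic test bed emulating the study design.
## A random reference gets non-overlapping hairpin palindromes implanted;
## artifact variants sit at palindrome centers, land 10-15 bases from a read
## edge on their supporting reads, ride soft-clipped reads about half the
## time, and recur across samples.  Genuine variants are private, uniformly
## positioned in-read, rarely clipped, and draw their trinucleotide classes
## from a known signature mixture.  Everything is deterministic under the
## configured seed.

#' Simulation configuration
#'
#' Defaults mirror the magnitudes reported for endonuclease-fragmentation
#' artifacts: in-read offsets 10-15 bases from an edge, soft-clip rates of
#' about 50% (artifact) versus 5% (genuine), 100-base reads, and a cohort in
#' which ~90% of artifact sites recur across samples.
#'
#' @param seed integer seed; fully determines every output.
#' @param chrom contig name of the synthetic reference.
#' @param ref_len reference length in bases.
#' @param n_samples number of cohort samples.
#' @param n_artifact,n_genuine implanted artifact / genuine variants per
#'   sample.
#' @param artifact_recurrence fraction of each sample's artifact sites drawn
#'   from the cohort-shared pool (shared sites appear in every sample).
#' @param arm_range palindrome arm-length range (SCP lengths `2k+1`).
#' @param artifact_edge_window in-read distance-to-nearest-end range for
#'   artifact variants (bases).
#' @param artifact_softclip_prob,genuine_softclip_prob per-read soft-clip
#'   probabilities for alt reads of each class (wildtype reads clip at the
#'   genuine rate).
#' @param read_len read length (bases).
#' @param depth reads covering each variant site.
#' @param vaf variant allele fraction.
#' @param error_rate per-base sequencing error rate.
#' @param clip_len_range soft-clip length range (bases).
#' @param n_whitelist_artifacts shared artifact sites whose keys are written
#'   to the whitelist (exercising the rescue path).
#' @param genuine_sig_weights named mixture weights over the genuine
#'   signatures of [synthetic_signature_matrix()] used to draw genuine
#'   variant classes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, chrom = "chrS", ref_len = 100000L,
                       n_samples = 3L, n_artifact = 200L, n_genuine = 50L,
                       artifact_recurrence = 0.9,
                       arm_range = c(2L, 10L),
                       artifact_edge_window = c(10L, 15L),
                       artifact_softclip_prob = 0.5,
                       genuine_softclip_prob = 0.05,
                       read_len = 100L, depth = 50L, vaf = 0.5,
                       error_rate = 0.001,
                       clip_len_range = c(3L, 9L),
                       n_whitelist_artifacts = 10L,
                       genuine_sig_weights = c(sig_deamination = 0.6,
                                               sig_oxidation = 0.4)) {
  cfg <- list(seed = as.integer(seed), chrom = chrom,
              ref_len = as.integer(ref_len),
              n_samples = as.integer(n_samples),
              n_artifact = as.integer(n_artifact),
              n_genuine = as.integer(n_genuine),
              artifact_recurrence = artifact_recurrence,
              arm_range = as.integer(arm_range),
              artifact_edge_window = as.integer(artifact_edge_window),
              artifact_softclip_prob = artifact_softclip_prob,
              genuine_softclip_prob = genuine_softclip_prob,
              read_len = as.integer(read_len), depth = as.integer(depth),
              vaf = vaf, error_rate = error_rate,
              clip_len_range = as.integer(clip_len_range),
              n_whitelist_artifacts = as.integer(n_whitelist_artifacts),
              genuine_sig_weights = genuine_sig_weights)
  probs <- c(cfg$artifact_recurrence, cfg$artifact_softclip_prob,
             cfg$genuine_softclip_prob, cfg$vaf, cfg$error_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$arm_range[1L] >= 2L, cfg$arm_range[2L] >= cfg$arm_range[1L],
            cfg$depth >= 1L, cfg$read_len >= 4L * cfg$artifact_edge_window[2L],
            cfg$n_samples >= 1L)
  class(cfg) <- "sim_config"
  cfg
}

## slot bookkeeping: the reference is partitioned into equal slots, one per
## variant site, so palindromes never overlap and read pileups stay clean
.sim_slots <- function(cfg) {
  n_shared <- round(cfg$artifact_recurrence * cfg$n_artifact)
  n_private <- cfg$n_artifact - n_shared
  n_pool <- n_shared + cfg$n_samples * n_private
  n_slots <- n_pool + cfg$n_samples * cfg$n_genuine
  slot_w <- cfg$ref_len %/% n_slots
  min_w <- max(2L * cfg$arm_range[2L] + 10L, 2L * cfg$read_len %/% 2L + 20L)
  if (slot_w < min_w) {
    stop(sprintf("ref_len %d too short for %d variant sites (slot %d < %d bases)",
                 cfg$ref_len, n_slots, slot_w, min_w))
  }
  list(n_shared = n_shared, n_private = n_private, n_pool = n_pool,
       n_slots = n_slots, slot_w = slot_w)
}

#' Simulate a reference with embedded hairpin palindromes
#'
#' Bases are i.i.d. uniform; non-overlapping hairpin insertions (random arm,
#' free center base, reverse-complement arm) are written at slot centers.
#' The registry records each constructed center and arm length (a lower
#' bound: flanking bases may extend the palindrome by chance).
#'
#' @param config a [sim_config()].
#' @return list with `ref` (a `DNAStringSet`), `registry` (`data.frame`:
#'   `site`, `pos`, `arm_len`, `ref`, `alt`, `shared`), and `genuine_slots`
#'   (start positions of the slots reserved for genuine variants).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  s <- .sim_slots(config)
  bases <- sample(DNA_BASES, config$ref_len, replace = TRUE)
  slot_starts <- (seq_len(s$n_slots) - 1L) * s$slot_w + 1L
  slot_role <- sample(rep(c("palindrome", "genuine"),
                          c(s$n_pool, s$n_slots - s$n_pool)))
  pal_starts <- slot_starts[slot_role == "palindrome"]
  registry <- data.frame(site = seq_len(s$n_pool),
                         pos = pal_starts + s$slot_w %/% 2L,
                         arm_len = sample(seq(config$arm_range[1L],
                                              config$arm_range[2L]),
                                          s$n_pool, replace = TRUE),
                         ref = NA_character_, alt = NA_character_,
                         shared = c(rep(TRUE, s$n_shared),
                                    rep(FALSE, s$n_pool - s$n_shared)))
  for (i in seq_len(nrow(registry))) {
    p <- registry$pos[i]; k <- registry$arm_len[i]
    arm <- sample(DNA_BASES, k, replace = TRUE)
    bases[(p - k):(p - 1L)] <- arm
    bases[(p + 1L):(p + k)] <- rev(comp_bases(arm))
    registry$ref[i] <- bases[p]
    registry$alt[i] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
  }
  ref <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(ref) <- config$chrom
  list(ref = ref, registry = registry,
       genuine_slots = slot_starts[slot_role == "genuine"],
       slot_w = s$slot_w)
}

#' Synthetic signature probability matrix
#'
#' Four synthetic profiles over the 96 classes: two peaked "biological"
#' signatures (`sig_deamination`, uniform over the 16 C>T classes;
#' `sig_oxidation`, uniform over the 16 C>A classes), one `sig_transition`
#' (uniform over the 16 T>C classes), and `sig_hairpin`, uniform over the 24
#' classes whose 3' flank complements the 5' flank — exactly the contexts a
#' variant at a hairpin-palindrome center can occupy, i.e. the artifact
#' spectrum.
#'
#' @return 96 x 4 probability matrix (columns sum to 1).
#' @export
synthetic_signature_matrix <- function() {
  ctx <- sbs96_contexts()
  f5 <- substr(ctx, 1L, 1L)
  f3 <- substr(ctx, 7L, 7L)
  sub <- substr(ctx, 3L, 5L)
  mk <- function(sel) { p <- as.numeric(sel) / sum(sel); p }
  mat <- cbind(sig_deamination = mk(sub == "C>T"),
               sig_oxidation = mk(sub == "C>A"),
               sig_transition = mk(sub == "T>C"),
               sig_hairpin = mk(f3 == comp_bases(f5)))
  rownames(mat) <- ctx
  mat
}

## draw the (5'flank, ref, alt, 3'flank) of one genuine variant from the
## configured signature mixture
.draw_genuine_class <- function(sigmat, weights) {
  probs <- drop(sigmat[, names(weights), drop = FALSE] %*% weights)
  lab <- sample(rownames(sigmat), 1L, prob = probs)
  list(f5 = substr(lab, 1L, 1L), ref = substr(lab, 3L, 3L),
       alt = substr(lab, 5L, 5L), f3 = substr(lab, 7L, 7L))
}

## find a position in [lo, hi] whose trinucleotide matches the class (either
## strand); returns list(pos, ref, alt) -- falls back to the window center
## with its natural context when the motif is absent
.place_genuine <- function(bases, lo, hi, cls) {
  f5 <- bases[(lo - 1L):(hi - 1L)]
  ct <- bases[lo:hi]
  f3 <- bases[(lo + 1L):(hi + 1L)]
  fwd <- which(f5 == cls$f5 & ct == cls$ref & f3 == cls$f3)
  if (length(fwd)) {
    pos <- lo + fwd[sample.int(length(fwd), 1L)] - 1L
    return(list(pos = pos, ref = cls$ref, alt = cls$alt))
  }
  rc <- which(f3 == COMPLEMENT[[cls$f5]] & ct == COMPLEMENT[[cls$ref]] &
                f5 == COMPLEMENT[[cls$f3]])
  if (length(rc)) {
    pos <- lo + rc[sample.int(length(rc), 1L)] - 1L
    return(list(pos = pos, ref = COMPLEMENT[[cls$ref]],
                alt = COMPLEMENT[[cls$alt]]))
  }
  pos <- lo + (hi - lo) %/% 2L
  list(pos = pos, ref = bases[pos],
       alt = sample(setdiff(DNA_BASES, bases[pos]), 1L))
}

## construct one aligned read covering ref position p with the variant base
## at query offset q (1-based), optionally soft-clipped at `side`
.make_read <- function(bases, ref_len, p, q, L, clip, side, clip_len, base_at_q) {
  if (clip && side == 5L && q - clip_len < 2L) clip <- FALSE
  if (clip && side == 3L && q > L - clip_len) clip <- FALSE
  if (clip && side == 5L) {
    c <- clip_len
    start <- p - (q - c - 1L)
    span <- L - c
    if (start < 1L || start + span - 1L > ref_len) return(NULL)
    seq <- c(sample(DNA_BASES, c, replace = TRUE),
             bases[start:(start + span - 1L)])
    cigar <- sprintf("%dS%dM", c, span)
  } else if (clip && side == 3L) {
    c <- clip_len
    start <- p - q + 1L
    span <- L - c
    if (start < 1L || start + span - 1L > ref_len) return(NULL)
    seq <- c(bases[start:(start + span - 1L)],
             sample(DNA_BASES, c, replace = TRUE))
    cigar <- sprintf("%dM%dS", span, c)
  } else {
    start <- p - q + 1L
    if (start < 1L || start + L - 1L > ref_len) return(NULL)
    seq <- bases[start:(start + L - 1L)]
    cigar <- sprintf("%dM", L)
  }
  seq[q] <- base_at_q
  list(start = start, cigar = cigar, seq = seq)
}

#' Simulate aligned reads for one sample's variants
#'
#' For each variant site, `depth` reads cover the position; alt-supporting
#' reads of artifact variants place the variant 10-15 bases (configurable)
#' from a read edge and are soft-clipped at the proximal end with the
#' artifact clip probability, while genuine-variant and wildtype reads place
#' it uniformly.  Reads are written as SAM and converted to a sorted,
#' indexed BAM.
#'
#' @param config a [sim_config()].
#' @param refsim output of [simulate_reference()].
#' @param calls this sample's implanted calls with a `label` column
#'   (`artifact`/`genuine`).
#' @param bam_prefix output path prefix (writes `<prefix>.bam` + index).
#' @param seed RNG seed for this sample's reads.
#' @return path to the BAM file.
#' @export
simulate_reads <- function(config, refsim, calls, bam_prefix, seed) {
  if (config$depth < 1L) stop("depth must be >= 1")
  set.seed(seed)
  bases <- strsplit(as.character(refsim$ref[[1L]]), "", fixed = TRUE)[[1L]]
  L <- config$read_len
  ew <- config$artifact_edge_window
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    p <- calls$pos[i]
    is_art <- calls$label[i] == "artifact"
    n_alt <- rbinom(1L, config$depth, config$vaf)
    n_alt <- min(max(n_alt, 3L), config$depth - 3L)
    reads <- vector("list", config$depth)
    for (j in seq_len(config$depth)) {
      alt_read <- j <= n_alt
      if (alt_read && is_art) {
        d <- sample(seq(ew[1L], ew[2L]), 1L)
        side <- sample(c(5L, 3L), 1L)
        q <- if (side == 5L) d + 1L else L - d
        clip <- runif(1L) < config$artifact_softclip_prob
      } else {
        q <- sample.int(L, 1L)
        side <- if (q - 1L <= L - q) 5L else 3L
        clip <- runif(1L) < config$genuine_softclip_prob
      }
      clip_len <- sample(seq(config$clip_len_range[1L],
                             config$clip_len_range[2L]), 1L)
      b <- if (alt_read) calls$alt[i] else calls$ref[i]
      rd <- .make_read(bases, config$ref_len, p, q, L, clip, side, clip_len, b)
      if (is.null(rd)) next
      n_err <- rbinom(1L, L, config$error_rate)
      if (n_err > 0L) {
        at <- sample.int(L, n_err)
        rd$seq[at] <- sample(DNA_BASES, n_err, replace = TRUE)
      }
      rd$qname <- sprintf("%s_v%d_r%d", calls$sample_id[i], i, j)
      reads[[j]] <- rd
    }
    out[[i]] <- reads[!vapply(reads, is.null, logical(1L))]
  }
  reads <- unlist(out, recursive = FALSE)
  sam <- paste0(bam_prefix, ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", config$chrom, config$ref_len))
  recs <- vapply(reads, function(r) {
    paste(r$qname, 0L, config$chrom, r$start, 60L, r$cigar, "*", 0L, 0L,
          paste(r$seq, collapse = ""), strrep("I", length(r$seq)), sep = "\t")
  }, character(1L))
  writeLines(c(hdr, recs), sam)
  bam <- Rsamtools::asBam(sam, destination = bam_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Simulate a complete synthetic cohort
#'
#' Writes, under `dir`: the reference FASTA, one sorted+indexed BAM and one
#' call-table TSV per sample, a ground-truth TSV (per-variant labels and
#' constructed arm lengths), a whitelist TSV, and the synthetic signature
#' matrix TSV.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return manifest list: `config`, `fasta`, `bams`, `call_tables` (named
#'   per-sample paths), `calls` (combined `data.frame` with truth labels),
#'   `truth`, `whitelist`, `sigmat` (paths), `registry`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = tempfile("simcohort")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refsim <- simulate_reference(config)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(refsim$ref, fasta)

  sigmat <- synthetic_signature_matrix()
  sigmat_path <- file.path(dir, "signatures.tsv")
  write_signature_matrix(sigmat, sigmat_path)

  set.seed(config$seed + 1L)
  bases <- strsplit(as.character(refsim$ref[[1L]]), "", fixed = TRUE)[[1L]]
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  reg <- refsim$registry
  shared <- reg[reg$shared, , drop = FALSE]
  private <- reg[!reg$shared, , drop = FALSE]
  n_priv <- nrow(private) %/% config$n_samples
  free_slots <- sample(refsim$genuine_slots)  # shuffled assignment
  slot_i <- 0L
  all_calls <- vector("list", config$n_samples)
  for (s in seq_along(samples)) {
    priv_s <- private[seq_len(n_priv) + (s - 1L) * n_priv, , drop = FALSE]
    art <- rbind(shared, priv_s)
    art_calls <- data.frame(chrom = config$chrom, pos = art$pos,
                            ref = art$ref, alt = art$alt,
                            label = "artifact", arm_len = art$arm_len)
    gen <- vector("list", config$n_genuine)
    for (g in seq_len(config$n_genuine)) {
      slot_i <- slot_i + 1L
      lo <- free_slots[slot_i] + 30L
      hi <- free_slots[slot_i] + refsim$slot_w - 30L
      cls <- .draw_genuine_class(sigmat, config$genuine_sig_weights)
      gp <- .place_genuine(bases, lo, hi, cls)
      gen[[g]] <- data.frame(chrom = config$chrom, pos = gp$pos,
                             ref = gp$ref, alt = gp$alt,
                             label = "genuine", arm_len = NA_integer_)
    }
    sc <- rbind(art_calls, do.call(rbind, gen))
    sc$sample_id <- samples[s]
    all_calls[[s]] <- sc
  }

  bams <- character(0L); call_paths <- character(0L)
  for (s in seq_along(samples)) {
    sc <- all_calls[[s]]
    bam <- simulate_reads(config, refsim, sc,
                          file.path(dir, samples[s]),
                          seed = config$seed + 1000L + s)
    calls_path <- file.path(dir, paste0(samples[s], ".calls.tsv"))
    write_variant_calls(variant_calls(sc$chrom, sc$pos, sc$ref, sc$alt,
                                      sample_id = samples[s]),
                        calls_path)
    bams[samples[s]] <- bam
    call_paths[samples[s]] <- calls_path
  }

  calls <- do.call(rbind, all_calls)
  calls$vtype <- variant_type(calls$ref, calls$alt)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(calls[, c("chrom", "pos", "ref", "alt", "sample_id",
                        "label", "arm_len")],
              truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  wl <- shared[seq_len(min(config$n_whitelist_artifacts, nrow(shared))), ,
               drop = FALSE]
  wl_path <- file.path(dir, "whitelist.tsv")
  write.table(data.frame(chrom = config$chrom, pos = wl$pos,
                         ref = wl$ref, alt = wl$alt),
              wl_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(config = config, dir = dir, fasta = fasta, bams = bams,
       call_tables = call_paths, calls = calls, truth = truth_path,
       whitelist = wl_path, sigmat = sigmat_path, registry = refsim$registry)
}

#' Draw a mutation spectrum from a signature mixture
#'
#' Multinomial draw of `n` mutations from the mixed 96-class distribution
#' `sigmat %*% weights`.
#'
#' @param n number of mutations.
#' @param weights mixture weights on the simplex (nonnegative, sum 1; named
#'   by signature or in column order).
#' @param sigmat signature matrix (96 x K).
#' @param seed optional RNG seed.
#' @return named 96-class count vector with a `total` attribute.
#' @export
simulate_spectra <- function(n, weights, sigmat, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
    stop("mixture weights must be nonnegative and sum to 1")
  }
  w <- if (!is.null(names(weights))) {
    full <- setNames(numeric(ncol(sigmat)), colnames(sigmat))
    full[names(weights)] <- weights
    full
  } else weights
  probs <- drop(as.matrix(sigmat) %*% w)
  counts <- drop(rmultinom(1L, n, probs))
  out <- setNames(as.integer(counts), rownames(sigmat))
  attr(out, "total") <- n
  out
}
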