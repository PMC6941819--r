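## pipeline: feature extraction -> stage-1 recurrence filter -> stage-2
## classifier -> annotated output and before/after reports.  Every input
## variant ends in exactly one terminal state (PASS / recurrent_artifact /
## model_noise) and the report accounting closes exactly.

## one scanBam call for all variant positions of a sample
.fetch_reads_multi <- function(path, chrom, positions) {
  bf <- Rsamtools::BamFile(path)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(positions, positions))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE))
  lapply(Rsamtools::scanBam(bf, param = param), function(res) {
    data.frame(qname = res$qname, flag = res$flag,
               chrom = as.character(res$rname), pos = res$pos,
               cigar = res$cigar, seq = as.character(res$seq))
  })
}

#' Extract per-variant classifier features from a BAM
#'
#' Computes, for every call: alt/ref read counts, the positional-bias KS
#' test, the soft-clipped read ratio, and the SCP annotation.  Variants with
#' no alt-supporting reads in the BAM are flagged uncallable and given the
#' no-evidence convention (`ks_p = 1`, `clip_ratio = 0`).
#'
#' @param calls variant call table for one sample.
#' @param bam indexed BAM path for the same sample.
#' @param ref reference (path or `DNAStringSet`).
#' @param min_clip minimum soft-clip length (see [collect_evidence()]).
#' @param transform positional transform (see [positional_bias()]).
#' @param scp_max_arm maximum palindrome arm tested (see [scp_annotate()]).
#' @return `calls` with `n_alt`, `n_ref`, `ks_p`, `ks_D`, `clip_ratio`,
#'   `uncallable`, `arm_len`, `scp_len`, `arm_seq` appended.
#' @export
extract_features <- function(calls, bam, ref, min_clip = 1L,
                             transform = "end_distance", scp_max_arm = 20L) {
  ref <- load_reference(ref)
  n <- nrow(calls)
  reads_by_call <- if (n > 0L) {
    .fetch_reads_multi(bam, calls$chrom[1L], calls$pos)
  } else list()
  n_alt <- integer(n); n_ref <- integer(n)
  ks_p <- numeric(n); ks_D <- numeric(n); clip <- numeric(n)
  uncallable <- logical(n)
  for (i in seq_len(n)) {
    ev <- tryCatch(collect_evidence(reads_by_call[[i]], calls[i, ],
                                    min_clip = min_clip),
                   error = function(e) NULL)
    if (is.null(ev)) {
      uncallable[i] <- TRUE
      ks_p[i] <- 1; ks_D[i] <- NA_real_; clip[i] <- 0
      next
    }
    pb <- positional_bias(ev, transform = transform)
    n_alt[i] <- ev$n_alt; n_ref[i] <- ev$n_ref
    ks_p[i] <- pb$ks_p; ks_D[i] <- pb$ks_D
    clip[i] <- soft_clip_ratio(ev)
  }
  if (any(uncallable)) {
    warning(sprintf("%d variant(s) had no alt-supporting reads in '%s'",
                    sum(uncallable), bam))
  }
  calls$n_alt <- n_alt; calls$n_ref <- n_ref
  calls$ks_p <- ks_p; calls$ks_D <- ks_D; calls$clip_ratio <- clip
  calls$uncallable <- uncallable
  scp_annotate(calls, ref, max_arm = scp_max_arm)
}

#' Two-stage filter bookkeeping
#'
#' Pure accounting of the filter cascade: of `input` calls, `recurrent` are
#' cohort-recurrent, of which `rescued` are whitelist-rescued (passed on to
#' the model instead of removed); the model then removes `model_removed` of
#' the stage-1 survivors.
#'
#' @param input,recurrent,rescued,model_removed stage counts.
#' @return list with `stage1_removed`, `stage1_survivors`, `removed_total`,
#'   `retained`, `removal_rate` (percent of input removed),
#'   `rescue_fraction` (percent of recurrent calls whitelisted).  Closure:
#'   `retained + removed_total == input`.
#' @export
filter_accounting <- function(input, recurrent, rescued, model_removed) {
  stopifnot(recurrent <= input, rescued <= recurrent)
  stage1_removed <- recurrent - rescued
  survivors <- input - stage1_removed
  stopifnot(model_removed <= survivors)
  removed_total <- stage1_removed + model_removed
  list(input = input,
       stage1_removed = stage1_removed,
       stage1_survivors = survivors,
       model_removed = model_removed,
       removed_total = removed_total,
       retained = input - removed_total,
       removal_rate = 100 * removed_total / input,
       rescue_fraction = if (recurrent > 0) 100 * rescued / recurrent else NA_real_)
}

#' Run the two-stage artifact filter on one sample
#'
#' Applies the cohort recurrence filter (with whitelist rescue), then the
#' logistic noise classifier to every stage-1 survivor (including rescued
#' calls).  Records are annotated, not dropped: the `filter` column holds
#' `PASS`, `recurrent_artifact` or `model_noise`.
#'
#' @param calls one sample's call table.
#' @param bam that sample's BAM (ignored when `features` is given).
#' @param ref reference (path or `DNAStringSet`).
#' @param cohort a [build_recurrence()] table, or cohort calls to build one
#'   from.
#' @param model a fitted [fit_noise_model()].
#' @param whitelist whitelisted keys (see [read_whitelist()]), or `NULL`.
#' @param recurrence_min,include_self see [stage_one_filter()].
#' @param features optional precomputed [extract_features()] output.
#' @param ... passed to [extract_features()].
#' @return object of class `scp_filter_result`: `calls` (annotated table)
#'   and `report` (accounting, see [filter_accounting()]).
#' @export
run_filter <- function(calls, bam, ref, cohort, model, whitelist = NULL,
                       recurrence_min = 2L, include_self = FALSE,
                       features = NULL, ...) {
  if (!inherits(cohort, "recurrence_table")) cohort <- build_recurrence(cohort)
  if (is.null(features)) {
    features <- extract_features(calls, bam, ref, ...)
  }
  ann <- stage_one_filter(features, cohort, whitelist = whitelist,
                          recurrence_min = recurrence_min,
                          include_self = include_self)
  ann$filter <- ifelse(ann$removed, "recurrent_artifact", "PASS")
  survivors <- which(!ann$removed)
  if (length(survivors)) {
    cls <- classify_noise(model, ann[survivors, , drop = FALSE])
    ann$filter[survivors][cls == "noise"] <- "model_noise"
  }
  acct <- filter_accounting(
    input = nrow(ann),
    recurrent = sum(ann$reason != "passed"),
    rescued = sum(ann$reason == "rescued_whitelist"),
    model_removed = sum(ann$filter == "model_noise"))
  acct$rescued_then_removed <-
    sum(ann$reason == "rescued_whitelist" & ann$filter == "model_noise")
  structure(list(calls = ann, report = acct), class = "scp_filter_result")
}

#' @export
print.scp_filter_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<scp_filter_result> %d calls: %d removed stage 1 ",
                     "(recurrence), %d removed stage 2 (model), %d retained ",
                     "(%.1f%% removed)\n"),
              r$input, r$stage1_removed, r$model_removed, r$retained,
              r$removal_rate))
  invisible(x)
}

#' Before/after filtering report
#'
#' Summaries in the style of the study's before/after panels: SNV/indel
#' counts, SCP length spectra, and (when a signature matrix is supplied)
#' refitted signature exposures, before and after filtering.
#'
#' @param result an `scp_filter_result` (or a list of them, pooled).
#' @param ref reference, required for the spectra.
#' @param sigmat optional signature matrix for exposure refitting.
#' @return list with `counts` (`data.frame`: SNVs/indels before/after),
#'   `scp_before`, `scp_after` (spectra), and optionally `exposures_before`,
#'   `exposures_after`.
#' @export
run_report <- function(result, ref, sigmat = NULL) {
  anns <- if (inherits(result, "scp_filter_result")) list(result$calls)
          else lapply(result, function(r) r$calls)
  ann <- do.call(rbind, anns)
  kept <- ann[ann$filter == "PASS", , drop = FALSE]
  out <- list(
    counts = data.frame(
      stage = c("before", "after"),
      snvs = c(sum(ann$vtype == "SNV"), sum(kept$vtype == "SNV")),
      indels = c(sum(ann$vtype != "SNV"), sum(kept$vtype != "SNV"))),
    scp_before = scp_spectrum(ann),
    scp_after = scp_spectrum(kept))
  if (!is.null(sigmat)) {
    ref <- load_reference(ref)
    out$exposures_before <- refit_exposures(mutation_spectrum(ann, ref), sigmat)
    out$exposures_after <- refit_exposures(mutation_spectrum(kept, ref), sigmat)
  }
  out
}

#' Write an annotated call table as a minimal VCF
#'
#' One record per call with the filter decision in the `FILTER` column
#' (`PASS`, `recurrent_artifact` or `model_noise`) and the computed features
#' in `INFO`.  With `hard_filter = TRUE` only passing records are written.
#'
#' @param annotated annotated calls from [run_filter()] (`$calls`).
#' @param path output `.vcf` path.
#' @param hard_filter drop non-PASS records instead of tagging them.
#' @export
write_filtered_vcf <- function(annotated, path, hard_filter = FALSE) {
  if (hard_filter) annotated <- annotated[annotated$filter == "PASS", , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=scpfilter",
           "##FILTER=<ID=recurrent_artifact,Description=\"Cohort-recurrent, not whitelisted\">",
           "##FILTER=<ID=model_noise,Description=\"Classified as fragmentation noise by the logistic model\">",
           "##INFO=<ID=KSP,Number=1,Type=Float,Description=\"Positional-bias KS p-value\">",
           "##INFO=<ID=SCR,Number=1,Type=Float,Description=\"Soft-clipped read ratio\">",
           "##INFO=<ID=REC,Number=1,Type=Integer,Description=\"Cohort recurrence count\">",
           "##INFO=<ID=SCP,Number=1,Type=Integer,Description=\"SNV-centered palindrome length\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  info <- sprintf("KSP=%.6g;SCR=%.4g;REC=%d;SCP=%d",
                  annotated$ks_p %||% rep(1, nrow(annotated)),
                  annotated$clip_ratio %||% rep(0, nrow(annotated)),
                  annotated$recurrence_count, annotated$scp_len)
  recs <- paste(annotated$chrom, annotated$pos, ".", annotated$ref,
                annotated$alt, ".", annotated$filter, info, sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Run and score the pipeline on a simulated cohort
#'
#' Convenience end-to-end driver for a [simulate_cohort()] manifest: extracts
#' features for every sample, trains the noise model on the ground-truth
#' labels, runs the two-stage filter per sample (leave-one-out recurrence),
#' and scores the removed set against the truth.
#'
#' @param manifest a [simulate_cohort()] manifest.
#' @param recurrence_min see [stage_one_filter()].
#' @return list: `sensitivity` (fraction of implanted artifacts removed),
#'   `specificity` (fraction of genuine variants retained), `auroc` (of the
#'   classifier alone), `model`, `results` (per-sample
#'   `scp_filter_result`s), `features` (pooled labeled features), `report`
#'   (pooled [run_report()] with exposures).
#' @export
evaluate_pipeline <- function(manifest, recurrence_min = 2L) {
  cfg <- manifest$config
  ref <- load_reference(manifest$fasta)
  samples <- names(manifest$bams)
  feats <- lapply(samples, function(s) {
    calls <- manifest$calls[manifest$calls$sample_id == s, , drop = FALSE]
    extract_features(variant_calls(calls$chrom, calls$pos, calls$ref,
                                   calls$alt, sample_id = s),
                     manifest$bams[[s]], ref)
  })
  names(feats) <- samples
  pooled <- do.call(rbind, feats)
  truth_key <- paste(manifest$calls$sample_id,
                     variant_key(manifest$calls$chrom, manifest$calls$pos,
                                 manifest$calls$ref, manifest$calls$alt))
  pooled$label <- manifest$calls$label[
    match(paste(pooled$sample_id,
                variant_key(pooled$chrom, pooled$pos, pooled$ref, pooled$alt)),
          truth_key)]
  model <- suppressWarnings(fit_noise_model(pooled))
  cohort <- build_recurrence(pooled)
  whitelist <- read_whitelist(manifest$whitelist)
  results <- lapply(samples, function(s) {
    f <- feats[[s]]
    run_filter(f, bam = NULL, ref = ref, cohort = cohort, model = model,
               whitelist = whitelist, recurrence_min = recurrence_min,
               features = f)
  })
  names(results) <- samples
  ann <- do.call(rbind, lapply(results, function(r) r$calls))
  ann$label <- pooled$label[
    match(paste(ann$sample_id, variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)),
          paste(pooled$sample_id,
                variant_key(pooled$chrom, pooled$pos, pooled$ref, pooled$alt)))]
  removed <- ann$filter != "PASS"
  sigmat <- read_signature_matrix(manifest$sigmat)
  list(sensitivity = sum(removed & ann$label == "artifact") /
         sum(ann$label == "artifact"),
       specificity = sum(!removed & ann$label == "genuine") /
         sum(ann$label == "genuine"),
       auroc = model$training$auroc,
       model = model,
       results = results,
       features = pooled,
       annotated = ann,
       report = run_report(results, ref, sigmat = sigmat))
}
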