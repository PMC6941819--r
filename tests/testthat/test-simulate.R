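test_that("simulated references are deterministic and embed verifiable palindromes", {
  cfg <- sim_config(seed = 11L, ref_len = 30000L, n_samples = 2L,
                    n_artifact = 30L, n_genuine = 10L)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(as.character(a$ref), as.character(b$ref))
  expect_identical(a$registry, b$registry)

  ## every registry entry is at least the constructed hairpin
  for (i in seq_len(nrow(a$registry))) {
    w <- fetch_reference_window(a$ref, cfg$chrom, a$registry$pos[i], 20L)
    expect_gte(scp_length(w)$arm_len, a$registry$arm_len[i])
    expect_equal(substr(w$seq, 21L, 21L), a$registry$ref[i])
  }
})

test_that("impossible simulation configurations are rejected", {
  expect_error(sim_config(vaf = 1.5), "probs")
  expect_error(sim_config(arm_range = c(1L, 5L)), "arm_range")
  expect_error(simulate_reference(sim_config(ref_len = 2000L)), "too short")
})

test_that("simulated BAMs are valid alignments consistent with the call tables", {
  m <- small_sim()
  cfg <- m$config
  bam <- m$bams[[1L]]
  ## CIGAR/SEQ consistency on every read of the first sample
  all_reads <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("pos", "cigar", "seq")))[[1L]]
  expect_gt(length(all_reads$pos), 0L)
  for (i in seq_along(all_reads$pos)) {
    ops <- parse_cigar(all_reads$cigar[i])
    expect_equal(sum(ops$len[ops$op %in% c("M", "I", "S")]),
                 nchar(as.character(all_reads$seq[i])))
  }
  ## coordinate consistency: the flank-0 reference window equals the ref allele
  ref <- load_reference(m$fasta)
  s1 <- m$calls[m$calls$sample_id == "S01", ]
  for (i in seq_len(nrow(s1))) {
    expect_equal(fetch_reference_window(ref, s1$chrom[i], s1$pos[i], 0L)$seq,
                 s1$ref[i])
  }
})

test_that("implanted artifacts show edge-biased offsets and elevated soft clipping", {
  m <- small_sim()
  cfg <- m$config
  s1 <- m$calls[m$calls$sample_id == "S01", ]
  art <- s1[s1$label == "artifact", ][1:8, ]
  gen <- s1[s1$label == "genuine", ][1:8, ]
  feat_of <- function(v) {
    reads <- fetch_reads_at(m$bams[[1L]], v$chrom, v$pos)
    ev <- collect_evidence(reads, v)
    list(p = positional_bias(ev)$ks_p,
         dists = pmin(ev$alt_offsets - 1L, ev$alt_read_len - ev$alt_offsets),
         clipped = ev$n_alt_softclipped, n_alt = ev$n_alt)
  }
  af <- lapply(seq_len(nrow(art)), function(i) feat_of(art[i, ]))
  gf <- lapply(seq_len(nrow(gen)), function(i) feat_of(gen[i, ]))
  ## artifact alt reads put the variant 10-15 bases from an end
  for (x in af) expect_true(all(x$dists >= cfg$artifact_edge_window[1L] &
                                x$dists <= cfg$artifact_edge_window[2L]))
  ## positional bias is detected for artifacts, not for genuine variants
  expect_lt(median(vapply(af, `[[`, 0, "p")),
            median(vapply(gf, `[[`, 0, "p")))
  ## soft-clip rate near the configured probabilities (binomial tolerance)
  clip_rate <- sum(vapply(af, `[[`, 0L, "clipped")) /
    sum(vapply(af, `[[`, 0L, "n_alt"))
  n <- sum(vapply(af, `[[`, 0L, "n_alt"))
  expect_lt(abs(clip_rate - cfg$artifact_softclip_prob),
            4 * sqrt(0.25 / n))
})

test_that("cohort structure matches the configured recurrence fraction", {
  m <- small_sim()
  cfg <- m$config
  per_sample <- table(m$calls$sample_id, m$calls$label)
  expect_true(all(per_sample[, "artifact"] == cfg$n_artifact))
  expect_true(all(per_sample[, "genuine"] == cfg$n_genuine))
  tab <- build_recurrence(m$calls)
  art <- m$calls[m$calls$label == "artifact" & m$calls$sample_id == "S01", ]
  keys <- variant_key(art$chrom, art$pos, art$ref, art$alt)
  shared_frac <- mean(recurrence_count(tab, keys) >= 2L)
  expect_equal(shared_frac, round(cfg$artifact_recurrence * cfg$n_artifact) /
                 cfg$n_artifact)
  ## genuine variants are private
  gen <- m$calls[m$calls$label == "genuine", ]
  gkeys <- variant_key(gen$chrom, gen$pos, gen$ref, gen$alt)
  expect_true(all(recurrence_count(tab, gkeys) == 1L))
})

test_that("simulate_spectra draws from the mixture and validates the simplex", {
  P <- synthetic_signature_matrix()
  expect_equal(dim(P), c(96L, 4L))
  expect_equal(unname(colSums(P)), rep(1, 4L), tolerance = 1e-12)
  sp <- simulate_spectra(5000L, c(sig_deamination = 1), P, seed = 4L)
  expect_equal(sum(sp), 5000L)
  ## a pure C>T signature yields only C>T classes
  sub <- substr(names(sp), 3L, 5L)
  expect_equal(sum(sp[sub != "C>T"]), 0L)
  expect_error(simulate_spectra(10L, c(sig_deamination = 0.5), P), "sum to 1")
})
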