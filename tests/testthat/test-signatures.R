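## small synthetic 3-signature matrix with full column rank
three_sigs <- function() {
  ctx <- sbs96_contexts()
  sub <- substr(ctx, 3L, 5L)
  mk <- function(sel) as.numeric(sel) / sum(sel)
  mat <- cbind(s1 = mk(sub == "C>T"), s2 = mk(sub == "C>A"),
               s3 = mk(sub %in% c("T>A", "T>G")))
  rownames(mat) <- ctx
  mat
}

test_that("the 96 trinucleotide classes are complete, unique and canonically ordered", {
  ctx <- sbs96_contexts()
  expect_length(ctx, 96L)
  expect_false(anyDuplicated(ctx) > 0L)
  expect_equal(ctx[1L], "A[C>A]A")
  expect_equal(ctx[96L], "T[T>G]T")
  expect_true(all(substr(ctx, 3L, 3L) %in% c("C", "T")))  # pyrimidine ref
})

test_that("trinucleotide classes are strand-normalized to the pyrimidine reference", {
  expect_equal(trinucleotide_class("ACA", "C", "A"), "A[C>A]A")
  ## purine reference: revcomp TGA -> TCA, G>T -> C>A
  expect_equal(trinucleotide_class("TGA", "G", "T"), "T[C>A]A")
  expect_equal(trinucleotide_class("AAT", "A", "G"), "A[T>C]T")
  ## N in the context excludes the variant
  expect_true(is.na(trinucleotide_class("ANA", "N", "A")))
  expect_true(is.na(trinucleotide_class("NCA", "C", "A")))
  expect_error(trinucleotide_class("ACA", "G", "A"), "does not match")
})

test_that("mutation_spectrum counts SNVs in the right classes and skips N contexts", {
  ref <- make_reference(c(k = "NACATGAN"))
  calls <- variant_calls(rep("k", 4L),
                         c(3L, 5L, 2L, 4L),
                         c("C", "T", "A", "AT"),
                         c("A", "C", "T", "A"), "s")
  expect_message(sp <- mutation_spectrum(calls, ref), "excluded")
  expect_equal(attr(sp, "total"), 2L)      # indel skipped, N-context skipped
  expect_equal(attr(sp, "n_excluded"), 1L)
  expect_equal(unname(sp["A[C>A]A"]), 1L)  # ACA, C>A
  expect_equal(unname(sp["A[T>C]G"]), 1L)  # ATG, T>C
})

test_that("signature matrices round-trip through TSV and are validated", {
  P <- three_sigs()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_matrix(P, path)
  P2 <- read_signature_matrix(path)
  expect_equal(P2, P)

  bad <- P
  bad[1L, 1L] <- bad[1L, 1L] + 0.01
  expect_error(validate_signature_matrix(bad), "sums to")
  neg <- P; neg[1L, 1L] <- -0.1
  expect_error(validate_signature_matrix(neg), "nonnegative")
  expect_error(validate_signature_matrix(P[1:95, ]), "96")
})

test_that("refitting recovers vertices and exact mixtures, beating the grid oracle", {
  P <- three_sigs()
  ## vertex recovery at arbitrary scale
  for (j in 1:3) {
    fit <- refit_exposures(P[, j] * 500, P)
    expect_equal(unname(fit$weights[j]), 1, tolerance = 1e-6)
    expect_lt(fit$residual, 1e-12)
    expect_true(fit$kkt_ok)
  }
  ## exact two-signature mixture
  f <- 0.6 * P[, 1L] + 0.4 * P[, 2L]
  fit <- refit_exposures(f * 10000, P)
  expect_equal(unname(fit$weights), c(0.6, 0.4, 0), tolerance = 1e-6)
  expect_lt(fit$residual, 1e-12)
  ## never worse than a dense simplex grid search
  grid <- grid_refit_best(f, P, step = 0.001)
  expect_lte(fit$residual, grid$obj + 1e-12)
  expect_equal(unname(fit$weights), unname(grid$w), tolerance = 2e-3)
})

test_that("refitted solution beats every single-signature solution and ignores scale", {
  set.seed(6)
  P <- three_sigs()
  f <- as.numeric(rmultinom(1L, 300L, 0.5 * P[, 1L] + 0.5 * P[, 3L]))
  names(f) <- rownames(P)
  fit <- refit_exposures(f, P)
  freq <- f / sum(f)
  for (j in 1:3) {
    expect_lte(fit$residual, sum((freq - P[, j])^2) + 1e-12)
  }
  fit10 <- refit_exposures(f * 10, P)
  expect_equal(fit10$weights, fit$weights, tolerance = 1e-8)
  expect_error(refit_exposures(setNames(rep(0, 96), rownames(P)), P), "zero total")
})

test_that("multinomial sampling recovers mixtures within L1 0.05 at n = 10000", {
  P <- three_sigs()
  w <- c(s1 = 0.5, s2 = 0.3, s3 = 0.2)
  sp <- simulate_spectra(10000L, w, P, seed = 123L)
  expect_equal(sum(sp), 10000L)
  fit <- refit_exposures(sp, P)
  expect_lt(sum(abs(fit$weights - w)), 0.05)
})

test_that("exposure tables have one simplex row per sample", {
  P <- three_sigs()
  spectra <- list(a = simulate_spectra(500L, c(s1 = 1, s2 = 0, s3 = 0), P, seed = 1L),
                  b = simulate_spectra(500L, c(s1 = 0.2, s2 = 0.8, s3 = 0), P, seed = 2L))
  tab <- exposure_table(spectra, P)
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(unname(rowSums(tab)), c(1, 1), tolerance = 1e-8)
  expect_gt(tab["a", "s1"], 0.95)
})
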