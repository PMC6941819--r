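## signatures: 96-class trinucleotide mutation spectra and constrained
## signature refitting.  A sample's spectrum is expressed as a nonnegative,
## sum-to-one combination of fixed signature probability profiles by
## minimizing the squared Euclidean distance between observed class
## frequencies and the mixed profile — the standard refitting convention.
## Removing fragmentation noise should shrink the exposure of whatever
## signature the artifacts load on and restore the biological composition.

#' The 96 trinucleotide substitution classes
#'
#' Canonical ordering: substitutions C>A, C>G, C>T, T>A, T>C, T>G (pyrimidine
#' reference), each crossed with 5' and 3' flanking bases in A, C, G, T
#' order; labels like `"A[C>A]A"`.
#'
#' @return character vector of 96 class labels.
#' @export
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(DNA_BASES, DNA_BASES,
                      function(f5, f3) paste0(f5, "[", s, "]", f3))))))
}

#' Trinucleotide class of an SNV
#'
#' Purine-reference variants are strand-normalized: the trinucleotide is
#' reverse-complemented and ref/alt complemented so the reference base is a
#' pyrimidine (C or T).
#'
#' @param context the 3-base reference context (5' flank, ref, 3' flank), or
#'   a window from [fetch_reference_window()] with flank 1.
#' @param ref,alt single-base alleles; `ref` must equal the window center.
#' @return a class label such as `"T[C>A]A"`, or `NA` when the context
#'   contains `N`.
#' @examples
#' trinucleotide_class("ACA", "C", "A")  # "A[C>A]A"
#' trinucleotide_class("TGA", "G", "T")  # "T[C>A]A" (strand-normalized)
#' @export
trinucleotide_class <- function(context, ref, alt) {
  seq <- toupper(if (is.list(context)) context$seq else context)
  stopifnot(nchar(seq) == 3L)
  if (grepl("N", seq)) return(NA_character_)
  if (substr(seq, 2L, 2L) != ref) {
    stop(sprintf("window center '%s' does not match ref allele '%s'",
                 substr(seq, 2L, 2L), ref))
  }
  if (ref %in% c("A", "G")) {
    seq <- revcomp(seq)
    ref <- COMPLEMENT[[ref]]
    alt <- COMPLEMENT[[alt]]
  }
  paste0(substr(seq, 1L, 1L), "[", ref, ">", alt, "]", substr(seq, 3L, 3L))
}

#' 96-class mutation spectrum of a sample's SNVs
#'
#' @param calls variant call table (only SNVs contribute; variants whose
#'   context contains `N` are excluded and counted in the `n_excluded`
#'   attribute).
#' @param ref reference (path or `DNAStringSet`).
#' @return named integer vector over [sbs96_contexts()], with attributes
#'   `total` (sum) and `n_excluded`.
#' @export
mutation_spectrum <- function(calls, ref) {
  ref <- load_reference(ref)
  snvs <- calls[calls$vtype == "SNV", , drop = FALSE]
  classes <- character(nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    w <- fetch_reference_window(ref, snvs$chrom[i], snvs$pos[i], 1L)
    classes[i] <- trinucleotide_class(w, snvs$ref[i], snvs$alt[i])
  }
  excluded <- sum(is.na(classes))
  if (excluded > 0L) {
    message(sprintf("%d SNV(s) excluded from spectrum (N in context)", excluded))
  }
  ctx <- sbs96_contexts()
  counts <- table(factor(classes[!is.na(classes)], levels = ctx))
  out <- setNames(as.integer(counts), ctx)
  attr(out, "total") <- sum(out)
  attr(out, "n_excluded") <- excluded
  out
}

#' Read a signature probability matrix
#'
#' Tab-delimited: first column the 96 context labels (`"A[C>A]A"` style),
#' remaining columns one probability profile per signature (header row of
#' signature names).  Rows are reordered to the canonical
#' [sbs96_contexts()] order; each profile must sum to 1 within 1e-6.
#'
#' @param path TSV path.
#' @return numeric matrix, 96 rows (contexts) x K signatures.
#' @export
read_signature_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  contexts <- tab[[1L]]
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  validate_signature_matrix(mat, contexts)
  rownames(mat) <- contexts
  mat[sbs96_contexts(), , drop = FALSE]
}

#' @rdname read_signature_matrix
#' @param sigmat matrix to write or validate.
#' @param contexts row labels (defaults to `rownames(sigmat)`).
#' @export
write_signature_matrix <- function(sigmat, path) {
  validate_signature_matrix(sigmat)
  df <- data.frame(Context = rownames(sigmat), sigmat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_signature_matrix
#' @export
validate_signature_matrix <- function(sigmat, contexts = rownames(sigmat)) {
  if (length(contexts) != 96L || anyDuplicated(contexts) ||
      !setequal(contexts, sbs96_contexts())) {
    stop("signature matrix must have exactly the 96 trinucleotide context rows")
  }
  if (any(sigmat < 0)) stop("signature profiles must be nonnegative")
  sums <- colSums(sigmat)
  if (any(abs(sums - 1) > 1e-6)) {
    stop(sprintf("signature profile '%s' sums to %.8f, not 1",
                 colnames(sigmat)[which.max(abs(sums - 1))],
                 sums[which.max(abs(sums - 1))]))
  }
  invisible(TRUE)
}

#' Refit signature exposures to a mutation spectrum
#'
#' Finds the exposure vector `w` on the K-simplex (`w >= 0`, `sum(w) = 1`)
#' minimizing `|| f - P w ||^2`, where `f` is the spectrum's class frequency
#' vector and `P` the signature matrix.  Solved as a quadratic program
#' (equality + nonnegativity constraints); the returned solution is verified
#' against the Karush-Kuhn-Tucker conditions to 1e-6.
#'
#' @param spectrum 96-class counts (from [mutation_spectrum()]) or
#'   frequencies.
#' @param sigmat signature matrix (96 x K, from [read_signature_matrix()]).
#' @return object of class `signature_refit`: `weights` (named, sums to 1),
#'   `residual` (the minimized objective), `kkt_ok`.
#' @export
refit_exposures <- function(spectrum, sigmat) {
  stopifnot(length(spectrum) == 96L, nrow(sigmat) == 96L)
  if (!is.null(names(spectrum))) {
    spectrum <- spectrum[rownames(sigmat)]
  }
  total <- sum(spectrum)
  if (total <= 0) stop("spectrum has zero total count")
  f <- as.numeric(spectrum) / total
  P <- unname(as.matrix(sigmat))
  K <- ncol(P)
  ## min ||f - Pw||^2  =  min 1/2 w' (2P'P) w - (2P'f)' w
  D <- 2 * crossprod(P) + diag(1e-10, K)  # jitter keeps D positive definite
  d <- 2 * crossprod(P, f)
  A <- cbind(rep(1, K), diag(K))          # sum(w) = 1 (equality), w >= 0
  sol <- quadprog::solve.QP(D, d, A, bvec = c(1, rep(0, K)), meq = 1L)
  w <- pmax(sol$solution, 0)
  w <- w / sum(w)
  resid <- sum((f - P %*% w)^2)
  ## KKT: gradient components must vanish (active) or be >= 0 (at w = 0),
  ## up to the simplex multiplier
  g <- drop(2 * crossprod(P, P %*% w - f))
  mu <- mean(g[w > 1e-8])
  kkt_ok <- all(abs(g[w > 1e-8] - mu) < 1e-6) && all(g[w <= 1e-8] >= mu - 1e-6)
  structure(list(
    weights = setNames(w, colnames(sigmat)),
    residual = resid,
    kkt_ok = kkt_ok,
    total = total
  ), class = "signature_refit")
}

#' @export
print.signature_refit <- function(x, ...) {
  cat(sprintf("<signature_refit> %d mutations, residual %.3g%s\n",
              x$total, x$residual, if (!x$kkt_ok) " [KKT check failed]" else ""))
  top <- sort(x$weights, decreasing = TRUE)
  top <- top[top > 0.01]
  cat("  exposures:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample exposure table
#'
#' @param spectra a named list of 96-class spectra, one per sample.
#' @param sigmat signature matrix.
#' @return numeric matrix, samples x signatures; each row sums to 1.
#' @export
exposure_table <- function(spectra, sigmat) {
  rows <- lapply(spectra, function(s) refit_exposures(s, sigmat)$weights)
  out <- do.call(rbind, rows)
  rownames(out) <- names(spectra)
  out
}
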