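## Independent brute-force oracles.  Each is deliberately written as a
## different algorithm from the implementation it checks.

## per-base expansion of an alignment: one row per CIGAR-consumed base with
## its query index (NA for D/N) and reference index (NA for I/S)
expand_alignment <- function(cigar, ref_start) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  ops <- substr(toks, nchar(toks), nchar(toks))
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  q <- integer(0); r <- integer(0)
  qi <- 0L; ri <- ref_start - 1L
  for (i in seq_along(ops)) {
    for (j in seq_len(lens[i])) {
      qc <- ops[i] %in% c("M", "I", "S", "=", "X")
      rc <- ops[i] %in% c("M", "D", "N", "=", "X")
      if (qc) qi <- qi + 1L
      if (rc) ri <- ri + 1L
      q <- c(q, if (qc) qi else NA_integer_)
      r <- c(r, if (rc) ri else NA_integer_)
    }
  }
  data.frame(q = q, r = r)
}

## oracle for query_offset: look the reference position up in the expansion
oracle_query_offset <- function(cigar, ref_start, ref_pos) {
  tab <- expand_alignment(cigar, ref_start)
  hit <- which(!is.na(tab$r) & tab$r == ref_pos)
  if (!length(hit)) stop("ref_pos not covered")
  tab$q[hit]
}

## random valid CIGAR: clips at the ends, M blocks separated by I/D/N,
## starting and ending in M
random_cigar <- function() {
  n_mid <- sample(0:3, 1)
  ops <- "M"
  for (i in seq_len(n_mid)) ops <- c(ops, sample(c("I", "D", "N"), 1), "M")
  if (runif(1) < 0.4) ops <- c("S", ops)
  if (runif(1) < 0.4) ops <- c(ops, "S")
  if (runif(1) < 0.15) ops <- c("H", ops)
  if (runif(1) < 0.15) ops <- c(ops, "H")
  lens <- sample(1:30, length(ops), replace = TRUE)
  paste0(lens, ops, collapse = "")
}

## exact two-sample two-sided KS p-value by enumerating every assignment of
## the pooled sample to the two labels
perm_ks_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  D_of <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(v) - ecdf(b)(v)))
  }
  obs <- D_of(x, y)
  combs <- utils::combn(length(pooled), n1)
  ds <- apply(combs, 2, function(idx) D_of(pooled[idx], pooled[-idx]))
  mean(ds >= obs - 1e-12)
}

## exhaustive-k SCP oracle: test every arm length explicitly
oracle_scp_arm <- function(seq, mode = "revcomp") {
  n <- nchar(seq)
  center <- (n + 1L) %/% 2L
  flank <- center - 1L
  bases <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0L
  for (k in seq_len(flank)) {
    left <- bases[(center - k):(center - 1L)]
    right <- bases[(center + 1L):(center + k)]
    ok <- if (mode == "revcomp") {
      ## center - i pairs with center + i as complements
      all(left %in% names(comp)) && all(rev(right) == comp[left])
    } else {
      ## mirror: base at center - i equals base at center + i
      all(left %in% names(comp)) && all(rev(right) == left)
    }
    if (ok) best <- k else break
  }
  best
}

## dense grid search over the 2-simplex (3 signatures) at a given step
grid_refit_best <- function(f, P, step = 0.001) {
  w1 <- seq(0, 1, by = step)
  grid <- do.call(rbind, lapply(w1, function(a) {
    b <- seq(0, 1 - a, by = step)
    cbind(a, b, 1 - a - b)
  }))
  Q <- crossprod(P)
  bv <- crossprod(P, f)
  obj <- sum(f^2) - 2 * drop(grid %*% bv) + rowSums((grid %*% Q) * grid)
  list(w = grid[which.min(obj), ], obj = min(obj))
}

## exhaustive threshold sweep: best sensitivity+specificity over all cuts
sweep_threshold <- function(p, y_artifact) {
  cand <- sort(unique(p))
  score <- numeric(length(cand))
  for (i in seq_along(cand)) {
    sens <- sum(p >= cand[i] & y_artifact) / sum(y_artifact)
    spec <- sum(p < cand[i] & !y_artifact) / sum(!y_artifact)
    score[i] <- sens + spec
  }
  list(best_score = max(score),
       best_t = max(cand[score >= max(score) - 1e-12]))
}
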