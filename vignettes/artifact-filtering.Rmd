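---
title: "Filtering enzymatic-fragmentation artifacts from somatic variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering enzymatic-fragmentation artifacts from somatic variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpfilter)
```

## The problem and the model

Endonuclease-based DNA fragmentation kits make exome sequencing possible for
nanogram-quantity samples, but the fragmenting enzyme prefers palindromic
recognition sites. After cutting, the polymerase fill-in step that repairs
the fragment ends can misincorporate nucleotides — and because the enzyme
cuts the *same* preferred sites in every library, the misincorporations show
up as somatic SNV/indel calls that are reproducible across unrelated
samples. Three read-level fingerprints accompany them: the variant sits at
the center of a palindromic reference context (a hairpin can form there
during fill-in), the variant base lies 10–15 bases from a read end (the
distance between the cut site and the misincorporation), and the supporting
reads are frequently soft-clipped (several adjacent bases were
misincorporated, so the aligner clips the read tail).

scpfilter models artifact removal as a two-stage decision per call:

1. **Recurrence.** A call carried by at least `recurrence_min` distinct
   samples of a pooled enzymatically fragmented cohort is removed — unless
   whitelisted as known-genuine, in which case it proceeds to stage 2
   (driver mutations also recur across tumors, so recurrence alone cannot
   condemn a whitelisted call).
2. **Classification.** For the survivors, a logistic regression models
   `P(artifact)` from two features: `x_bias = -log10(p_KS)`, where `p_KS` is
   the two-sample KS p-value comparing in-read variant positions on
   variant-supporting versus wildtype reads, and `x_clip`, the fraction of
   variant-supporting reads bearing a soft clip. A call is noise when its
   predicted probability reaches the threshold that maximized
   sensitivity + specificity on the training data. The decision boundary is
   a straight line in `(x_bias, x_clip)` space.

The model's central assumptions: artifact positional bias is symmetric in
the two read ends (we fold offsets to distance-from-nearest-end by default;
`transform = "raw_offset"` is available); wildtype reads at the same locus
are an adequate null for the position distribution; and the two features
are monotone evidence for noise, which the logistic link respects.

## Coordinates and read-level evidence

All coordinates are 1-based and closed — the convention of VCF, SAM and of
every Bioconductor backend this package uses (Rsamtools, Biostrings,
VariantAnnotation) — including in-read offsets (first read base = 1).
Derived features are convention-invariant: the distance of offset `q` from
the nearest end of an `L`-base read is `min(q - 1, L - q)` whichever origin
is used.

`query_offset()` walks the CIGAR keeping a (query, reference) cursor pair
(`M/=/X` advance both, `I/S` query only, `D/N` reference only, `H/P`
neither) and is fuzz-tested against a per-base expansion oracle. Indel
calls are anchored at their leftmost (VCF) base: a read supports the indel
allele iff an `I`/`D` operation of exactly the indel's length immediately
follows the anchor, supports reference iff the anchor is aligned with no
adjacent indel, and is excluded (`other`) otherwise — base content of an
insertion is deliberately not compared, since callers disagree about it
more than aligners do about its length.

Reads counted at a locus are mapped, primary, non-duplicate,
non-supplementary alignments whose *reference-consuming* span covers the
position; clip-only overlap is not coverage. These defaults are deliberate
package choices (a study need not state read-level filters for its caller
stack) and can matter at high duplication rates.

## The positional-bias test

`positional_bias()` uses the two-sided two-sample KS test, with the exact
conditional null (which accounts for ties — in-read offsets are small
integers, so ties are the rule) whenever `n_alt * n_ref <= 10000`, and the
asymptotic distribution above that. The exact path equals a full
permutation enumeration of the pooled sample; the test suite asserts this
identity for every sample-size pair with pooled `n <= 10`.

When either group has fewer than 3 reads the test is declared not evaluable
and `p = 1` is returned. This is the conservative "no bias evidence"
convention: such a variant can still be removed, but only if its soft-clip
ratio says so. The choice is ours; with so few wildtype reads no positional
comparison is meaningful, and `-log10(1) = 0` simply contributes nothing to
the classifier.

## SNV-centered palindromes

`scp_length()` grows arms outward from the variant base, which is a free
loop position and never compared. In the default `revcomp` mode the base
`i` positions 3' of the center must complement the base `i` positions 5' of
it — the hairpin-forming definition. This is the only definition compatible
with an *odd*-length palindrome centered on a single base (a strict
full-length reverse-complement palindrome has even length), and hairpin
formation is the proposed error mechanism; a literal `mirror` mode is kept
as an option. Arms are exact matches: no mismatch tolerance, because any
tolerance parameter would be arbitrary, and `N` stops extension. Reportable
SCPs need `arm >= 2` (length ≥ 5); shorter matches report length 0. The
default search window (`max_arm = 20`, SCP lengths to 41) covers everything
the artifact process generates at observable frequency.

## Threshold choice and degenerate fits

`choose_threshold()` sweeps every distinct predicted probability as a
candidate cut and returns the maximizer of sensitivity + specificity,
breaking ties toward the *larger* threshold — fewer removals, i.e. when two
cuts are equally good we prefer the one that keeps more variants. The
boundary convention is `>=`: a point exactly at threshold is noise.

Clean training cohorts are often linearly separable in these two features,
where the logistic MLE diverges. `fit_noise_model()` detects this
(non-convergence, exploding coefficients, or all fitted probabilities
saturated) and refits with a tiny ridge penalty (1e-6, intercept
unpenalized) via IRLS, warning the user. Predictions and the threshold are
unaffected in practice; only the standard errors are dropped (reported as
`NA`) since the Fisher information is no longer trustworthy there.

## Signature refitting

`refit_exposures()` minimizes the squared Euclidean distance between the
observed 96-class frequency vector and `P %*% w` over the exposure simplex.
Squared error on frequencies is the standard refitting convention; the
constraint set makes the problem a small convex quadratic program, solved
with `quadprog::solve.QP` (one equality, K nonnegativity constraints). The
returned solution is checked against the KKT conditions at tolerance 1e-6
(`kkt_ok`), and the test suite certifies it against a dense 0.001-step grid
search on the simplex and against exact-mixture recovery. Exposures depend
only on frequencies, never on the total count, and a spectrum equal to a
single profile recovers that vertex exactly.

## What the simulator emulates — and what it does not

`simulate_cohort()` reproduces the *features the method consumes*, under
the study conditions: three samples of 200 artifact + 50 genuine variants
at depth 50, 100-base reads, artifact offsets 10–15 bases from either end,
soft-clip rates 0.5 versus 0.05, ~90% of artifact sites shared across the
cohort, palindrome arms 2–10 (SCP lengths 5–21), variant allele fraction
0.5, per-base error rate 0.001. The shared/private split is deterministic
(`round(artifact_recurrence * n_artifact)` shared sites appear in every
sample) so cohort structure does not fluctuate with the seed. Genuine
variants draw their trinucleotide classes from a configured mixture of
synthetic signatures; artifacts occupy palindrome centers, whose contexts
necessarily have complementary flanks — exactly the support of the
`sig_hairpin` profile — which is what makes the before/after exposure
comparison a meaningful end-to-end check.

Not emulated: indels (the simulator implants SNVs only, though the filter
handles indel calls), mate pairs and overlapping-mate double counting,
realistic base-quality strings, alignment ambiguity (reads are emitted
pre-aligned with constructed CIGARs, not passed through an aligner),
germline contamination, and copy-number-driven allele-fraction variation.
Passing the end-to-end criteria therefore shows the pipeline's logic and
numerics are sound under its own generative assumptions — not that real
libraries are this separable. On the study's real training data the
published classifier achieved specificity 0.914 and sensitivity 0.979;
simulated clusters are cleaner than that.

One simulator subtlety: implanted arm lengths are lower bounds, since
flanking random bases can extend a palindrome by chance (probability 1/4
per extra step). The registry stores the constructed arm; tests assert
`scp_length() >= constructed`.

## Numerical and bookkeeping choices

- `-log10(p + 1e-300)` guards exact-zero p-values while leaving every
  representable p unchanged to double precision.
- Recurrence counts are "distinct samples carrying the key, self included":
  in leave-one-out mode (default) the query sample's pooled contribution is
  subtracted and self is counted back, so `recurrence_min = 2` means "seen
  in at least one *other* sample" under either counting mode. The
  include-self mode reproduces pooled-cohort bookkeeping exactly.
- The filter report closes exactly: every call ends in exactly one of
  `PASS`, `recurrent_artifact`, `model_noise`; rescued-then-removed calls
  are tracked separately. The published training-data narrative is
  reproduced by `filter_accounting()` from its component counts (which sum
  to the printed removal rates of 99.1% and 2.2%).
- Problem sizes in the test suite follow the oracle-equivalence scales the
  design calls for: 10,000 fuzzed CIGARs, 1,000 random 41-mers, exhaustive
  permutation KS up to pooled n = 10, logistic recovery at n = 5,000,
  grid-certified refitting at step 0.001, and the default three-sample
  simulation end-to-end.

## Limitations

- Stage 1 needs a pooled cohort of libraries fragmented with the same
  enzyme; with a handful of samples, recurrence loses power and the
  classifier carries the load.
- The classifier needs labeled training data (e.g. paired
  enzymatic/ultrasonic libraries of the same DNA, or the simulator's
  labels); coefficients fitted on one cohort transfer only to comparable
  read lengths and depths, which is why models serialize to JSON with their
  transform metadata.
- Whitelist rescue is identity-based (`chrom:pos:ref:alt`); representation
  differences (indel left-alignment, MNV decomposition) must be normalized
  upstream.
- The KS test treats reads as independent; overlapping mates and PCR
  siblings violate this mildly at high duplication rates.
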