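---
title: "Codon usage bias: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
library(dplyr)
```

# The problem

Synonymous codons are not used uniformly: selection for translational
efficiency, mutational pressure and base composition all leave a
signature in which codon of a family a gene prefers.  Summarising that
signature per gene (is this gene built from "preferred" codons?) and per
codon (which codons are over- or under-used?) is the basis for
predicting expression level from sequence alone.  This package
implements the four standard indices of that literature and the
downstream summaries typically run on them, end to end from a FASTA
file, with a synthetic-data generator that makes every stage testable
against known ground truth.

# Sequence QC

A record enters the analysis only if it is a clean coding sequence:
A/C/G/T alphabet (RNA `U` is mapped to `T` on read; ambiguity codes such
as `N` are rejected outright, because every index below assumes
unambiguous codons — skipping ambiguous codons silently would bias the
counts), length a positive multiple of 3, `ATG` first codon,
`TAA`/`TAG`/`TGA` last codon.  Exact-sequence duplicates are removed
(first occurrence kept): duplicate here means identical nucleotide
string, the only reading that is checkable from sequence alone.

Full mRNA records with UTRs fail these checks by design.  For them,
`cds_only = TRUE` scans frames 0/1/2 of the forward strand for the
longest `ATG`-to-stop ORF and runs the indices on that ORF, while GC%
and length stay reported on the full record — composition is a property
of the transcript, codon choice a property of the CDS.  Whether GC%
should instead be computed on the extracted CDS is a genuinely open
choice; the full-record default matches how transcript tables are
usually presented, and `gc_content()` can be applied to the ORF tibble
directly when the other convention is wanted.  Coordinates are 0-based
half-open internally; FASTA output wraps at 60 columns.

# The indices

Let `x_c` be the count of codon `c` in a gene, `N = Σ x_c`, and let
families be the synonymous codon sets of the standard genetic code
(stop codons form a 3-codon family; they are counted like any codon and
excluded only where a convention says so).

**CAI.** Relative adaptiveness from a reference count table:
`w_c = count_c / max count in family`; the gene score is the geometric
mean of `w` over all counted occurrences,
`exp( Σ_c x_c log w_c / N )`.  Three conventions matter:

- *Reference set.* Defaults to the pooled counts of the analysis corpus
  itself.  This makes the analysis self-contained and exactly
  reproducible from its inputs; an external highly-expressed reference
  can be supplied instead.  CAI values are therefore comparable within a
  corpus but not across references — which is also why published CAI
  columns are generally not reproducible unless the reference is stated.
- *Exclusions.* Met, Trp (single-codon families, `w ≡ 1`, no
  information) and stops (not translated) are excluded from the mean,
  the Sharp–Li convention; configurable.
- *Pseudo-weights.* A codon unobserved in a used reference family gets
  `w = 0.5 / max count` instead of 0, so `log w` is defined.  The floor
  shrinks as the reference deepens; this is intentional (a deeper
  reference is stronger evidence the codon is truly avoided), and it is
  the one place where index values are not invariant to scaling all
  reference counts.

**RSCU.** The default is the within-family fraction
`x_c / Σ_family x`, whose values sum to 1 per used family, neutral point
`1/n_i`, with 0.5 the equal-usage threshold for two-fold families.  The
classical convention (multiplied by family size `n_i`, equal usage ⇒ 1,
over-representation ⇒ > 1) is `variant = "classical"`; the two are
algebraically `classical = fraction × n_i`, and both are provided because
both thresholds (0.5 and 1) circulate in the applied literature.
Unused families get 0 and a `family_used = FALSE` flag rather than
`NaN`.

**RCBS.** `f_xyz / (f1(x) f2(y) f3(z))`, with `f_xyz = x_c / N` and
`fn(m)` the positional base frequencies computed from the same gene's
counted codons.  Under positional independence RCBS → 1.  Its sampling
noise per codon is multinomial: at 10,000 codons a uniform-composition
gene has ≈ 156 occurrences per codon and hence ≈ 8% relative noise, so
individual codons deviate from 1 by up to ~0.2 while the mean absolute
deviation stays below 0.1 and the gene-level geometric mean is within a
few parts per thousand of 1 — the calibration the tests assert.

**MRCBS.** RCBS divided by the maximum RCBS in the codon's family among
counted codons: values in [0, 1], at least one 1 per used family, ties
all map to 1.  The per-amino-acid mean — averaged over codons *and*
sequences, since no other averaging order is canonical — classifies
amino acids as high predicted expression when strictly above the 0.62
threshold, the conventional operating point for this index (a value
exactly at the threshold is low).

**Gene-level scores.** The printed form of both CAI and gene-level
MRCBS is a product over codon occurrences; an unrooted product of
hundreds of factors ≤ 1 underflows to 0 for any realistic gene, and
published gene-level MRCBS values sit well inside (0, 1], which is only
possible with the `1/N` geometric-mean root (present explicitly in the
CAI definition).  Both scores therefore take the root and are computed
in log space; the tests verify agreement with direct
product-then-Nth-root evaluation to 1e-10 on short genes where the
direct product is representable.

# Downstream summaries

**ANOVA.** `anova_fixed()` fits the additive fixed-effects model with
sequential (Type I) sums of squares via `stats::aov`, for any ordered
subset of {sequence, amino acid, codon}.  One structural point decides
the presentation: the codon factor *determines* the amino-acid factor,
so a single model containing both can give codon only the within-family
degrees of freedom left after amino acid (43 instead of 63 in a full
design).  The conventional three-source table — sequences at 18 df,
amino acids at 20, codons at 63, each against its own residual — is
therefore the combination of two two-way fits (sequence + amino acid
and sequence + codon), and that is what `run_analysis()` reports as the
combined table, the two underlying fits alongside.  The aliased
three-factor call remains available and warns.  On balanced designs
sequential SS are order-invariant and sum with the residual to the total
SS; both are asserted in the tests.

**z-screen.** The per-codon significance screen standardises each
codon's value against the across-codon mean and sd and flags two-sided
normal p < α (default 0.05).  With a single value per codon this
one-sample construction is the only z-test that can flag individual
codons; it is a descriptive screen, not an inferential test — the 64
values are not independent draws.  Flags are invariant under affine
transformations of the values.

**Normality summary.** Mean, sd (n − 1) and empirical coverage of
mean ± 1·sd and ± 2·sd — the descriptive 68–95 check.  A formal
normality test is deliberately not bundled: which test to run is a
user's choice (`shapiro.test` et al. apply directly to the same
vector), and the empirical coverage is what the index distributions are
usually quoted by.  Constant input is reported as degenerate with
coverage 1.

**PCA.** Correlation-matrix PCA (columns standardised; eigenvalues sum
to the number of indices, proportions are eigenvalue/k) over the full
sequence × codon long table of RSCU, MRCBS and RCBS — per-codon means
would discard the between-sequence variation that the sequence-level
interpretation needs.  Sign convention: the largest-magnitude loading
of each component is made positive, so output is reproducible across
LAPACK builds.  Constant columns are an error naming the column.
Variance proportions are reported from eigenvalues only; quoting
percentages inconsistent with the stated eigenvalues (as applied papers
sometimes do) is avoided by construction.

# The synthetic generator

`synthetic_spec()`/`generate_corpus()` draw clean ORFs: `ATG`, a body of
i.i.d. codons (amino acid from `aa_composition`, codon within family
from `codon_preferences`), one stop from `stop_preferences` (uniform
default, so the stop family is exercised).  Stops never occur in the
body, so every generated sequence passes validation — the round-trip the
tests rely on.  Defaults emulate a small plant stress-transcript corpus:
19 sequences, 801–3999 nt (multiples of 3), GC% in the 33–45 band,
uniform amino-acid composition, family preferences drawn once from a
flat Dirichlet under the corpus seed.

GC control is by rejection, not by distorting preferences, so the drawn
preferences remain the exact recovery target.  Two layers: (i) when
preferences are Dirichlet-sampled and a band is set, the draw is
repeated until the implied expected body GC lands in the band's central
60% — for sequences this long, realised GC concentrates within ~1% of
its expectation, so a preference set whose expectation sits outside the
band would make per-sequence rejection hopeless; (ii) each sequence is
redrawn (fresh sub-seed per attempt, cap 1000) until its realised GC is
in band.  User-specified preferences are never altered; if they are
incompatible with the band the corpus generation fails with an
explanatory error.  Determinism: every draw runs under a sub-seed
derived from `(seed, sequence index, attempt)` (kept below 2^31), and
the caller's RNG state is restored afterwards.

What the generator does *not* emulate: UTRs and mRNA structure (the
ORF-extraction path is tested by wrapping a generated ORF in fixed dummy
UTRs), phylogenetic correlation between sequences, within-gene
positional autocorrelation, indels or sequencing error.  Passing tests
on this generator therefore demonstrate correctness of the estimators
under i.i.d. codon sampling, not robustness to those real-data features.

# Numerical choices and problem sizes

Family-sum and bound invariants are asserted to 1e-12; log-space vs
direct-product equivalence to 1e-10; ANOVA SS conservation to 1e-8;
eigenvalue sums to 1e-8.  Ties for a family maximum give every tied
codon weight/MRCBS 1.  The test suite runs at desk scale: corpora of
5–50 sequences of 0.3–7.5 kb, one 50,000-codon pooled-recovery corpus
(observed mean absolute recovery error is computed in the acceptance
run), a 10,000-codon RCBS null gene, and 10,000 normal draws for the
coverage check — all generated in-process in a couple of minutes.

# Limitations

CAI values depend on the reference set and are not comparable across
references; the package's self-referential default measures conformity
to the corpus consensus, not absolute expression.  The z-screen and the
high/low classification are descriptive conventions, not calibrated
tests.  The ORF extractor takes the longest forward-strand ORF, which
can pick an incorrect frame in records with long spurious ORFs.  The
generator's i.i.d. model cannot produce codon-pair or autocorrelation
structure, so indices sensitive to such structure (none of the four
here) would need a richer simulator.
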