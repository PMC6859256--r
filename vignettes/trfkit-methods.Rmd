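---
title: "tRFkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tRFkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRFkit)
```

# The biological objects

tRNA genes are transcribed as precursors carrying a 5' leader (removed
by RNase P) and a 3' trailer (removed by RNase Z); CCA is added to the
mature 3' end post-transcriptionally. Four fragment classes derive from
this life cycle and are modeled as genomic loci:

* **tRF-5**: 5' end of the mature tRNA, 14–30 nt, starting exactly at
  the gene's 5' boundary.
* **tRF-3**: 3' end of the mature tRNA, 14–30 nt, ending exactly at the
  gene's 3' boundary. The mature molecule carries a terminal CCA that is
  *not* genome-templated, so a genome-space annotation cannot represent
  or verify it; `sequence_flags()` records this explicitly
  (`cca_non_templated`) instead of faking a positive check.
* **tsRNA (tRF-1)**: the 3' trailer, beginning immediately after the
  gene's 3' end and typically ending in poly-U. Records labeled tRF-1
  are aliased to this class on import.
* **5' leader RNA**: a fragment lying within the 20 nt upstream of the
  gene — the modeled extent of the pre-tRNA leader.

Internally every locus lives in a `GRanges` (1-based inclusive
coordinates). This is a deliberate choice: the whole R genomics stack —
overlap engines, BAM readers, GTF/BED IO — speaks GRanges, and keeping a
second private coordinate convention would only invite off-by-one
errors. Importers require the caller to declare the dialect of incoming
tables (`zero_half_open` or `one_inclusive`), the GTF writer emits
1-based inclusive, and the BED writer 0-based half-open, so no
convention is ever guessed.

# Annotation construction

`build_leader_loci()` places the leader locus strictly 5' of the gene on
its own strand (upstream-left for `+` genes, upstream-right for `-`
genes). Loci overrunning a contig start/end are clipped and flagged
`truncated`; a gene with zero upstream bases yields no locus and a
diagnostic, never a silent empty interval. Leader loci that overlap a
neighboring gene are flagged `overlaps_gene` and kept — resolving such
collisions would require information the inputs do not carry. tRNA
introns are stored but ignored by locus construction: all four classes
are defined relative to gene and precursor ends, not spliced bodies.

The canonical 14–30 nt tRF length range is enforced as a *flag-only*
policy (`length_out_of_range`): questionable loci stay visible through
the whole pipeline rather than disappearing at import.

# Conservative counting

Small-RNA fragments map to repeated tRNA loci, so the counting rules
bias deliberately toward under- rather than over-counting. A BAM record
is

* `MULTIMAPPED` when its query reports more than one alignment — the
  `NH` tag when present, otherwise duplicated query names within the
  file (tag takes precedence);
* otherwise assigned by union overlap (any overlap of at least
  `min_overlap` = 1 bp between an aligned block and a locus, honoring
  strandedness): exactly one overlapped locus assigns the read, two or
  more make it `AMBIGUOUS`, zero make it `NONE`.

Both `MULTIMAPPED` and `AMBIGUOUS` reads are excluded from counts and
tallied separately. Default strandedness is `same` because small-RNA
protocols are stranded and fragment identity is strand-defined; both
the mode and the minimum overlap are arguments. Per sample the
conservation identity holds exactly and is asserted at run time:
`sum(counts) + ambiguous + multimapped + unassigned = mapped records`.

# Normalization and filtering

Two normalizations are provided, and only these two:

* `rpm()`: count x 10^6 / *total mapped reads in the library* — the
  library-wide denominator, not the within-annotation sum, so RPM
  column sums over the annotation can only reach 10^6 when every mapped
  read was assigned.
* `tpm()`: count / locus length in bp, rescaled per sample so the
  column sums to 10^6. The denominator sum runs over the features of
  this annotation only, matching the custom-annotation context in which
  the quantification is defined.

Zero-total samples become all-zero columns with a warning — never a
division by zero.

The expression filter removes features whose mean over samples of
log2(TPM + pseudocount) is *strictly less than* 1; a feature sitting
exactly at the threshold is kept. The pseudocount (default 1) is
exposed because "log2 TPM" is undefined at zero; with pseudocount 1 the
printed threshold of 1 is meaningful exactly at TPM = 1
(log2(1 + 1) = 1). Both threshold and pseudocount are arguments of
`filter_by_mean_log2_tpm()`.

# Subclasses and sequence flags

Length subclasses follow the published windows: tRF-5a 14–16 nt, tRF-5b
22–24 nt, tRF-5c 28–30 nt. The tRF-3 subclasses are described in the
field as "about 18" and "about 22" nt; tRFkit implements them as ±1
windows, tRF-3a [17, 19] and tRF-3b [21, 23], and any other tolerance
can be supplied as a custom rule table (`subclass_rules()` rejects
overlapping windows at load time). Lengths between windows are
legitimately unclassified. Assignment is a pure function of
(class, length), so permuting rules never changes results.

The tsRNA poly-U signature is a run of at least `polyU_min_run` = 3
consecutive T within the final `polyU_window` = 6 nt of the sense
sequence (reverse-complemented for minus-strand loci); both parameters
are exposed since the literature states only "poly-U at the 3' end".
Flags annotate, never filter.

# Differential expression

`moderated_t_de()` fits, per feature, the two-group mean model on log2
expression (log2(TPM + 1) is the intended input; the transform is the
caller's choice and is applied automatically when a `NormalizedMatrix`
is passed). With pooled residual variance s² on d = n1 + n2 − 2 df, the
empirical-Bayes prior (d0, s0²) is moment-matched on the log sample
variances: e = log s² − digamma(d/2) + log(d/2) has variance
trigamma(d/2) + trigamma(d0/2) under the scaled-F model, so the excess
of var(e) over trigamma(d/2) identifies d0 through a numerical trigamma
inverse, and s0² follows from the mean of e. The posterior variance
s²_post = (d0 s0² + d s²)/(d0 + d) gives
t = logFC / sqrt(s²_post (1/n1 + 1/n2)) on d0 + d df, and p-values are
BH-adjusted. When the observed variances are at least as homogeneous as
sampling alone predicts, the estimator diverges; d0 is then capped at
10^7 with a warning (numerically indistinguishable from the infinite
limit). Forcing `df_prior = 0` recovers the ordinary pooled t, and
`df_prior = Inf` uses the prior variance exactly — both limits are
tested. Only two-group contrasts are supported; categorical covariates
are handled as user-chosen binary contrasts.

The test suite cross-checks this machinery in two independent ways: a
brute-force reimplementation (per-feature OLS, explicit moment
equations, `uniroot` trigamma inversion) agreeing to 10^-8, and limma's
`eBayes`, agreeing to 10^-10 on heterogeneous-variance data.

One documented property deserves a note: BH adjustment is *not*
idempotent — re-adjusting an adjusted vector multiplies by m/rank a
second time (p = (0.01, 0.9) adjusts to (0.02, 0.9) and re-adjusts to
(0.04, 0.9)). The suite therefore asserts the true invariants:
agreement with the literal step-up definition, permutation stability,
rank monotonicity and the cap at 1.

# Correlation screening

`correlate()` computes Pearson or Spearman correlation for all
(feature, covariate) pairs over samples shared *by name*, using
pairwise-complete observations, and reports only |r| strictly greater
than 0.5 — the screening convention, taken as strict. P-values use the
t-transform of r on n − 2 df (for Spearman, the same large-sample
approximation on rank correlations; adequate for a screen whose
decision rule is the |r| threshold, not the p-value). No multiplicity
adjustment is applied to correlations, since the reported quantity is
the threshold-screened coefficient. Zero-variance vectors make r
undefined; such pairs are skipped and listed with a reason rather than
propagated as NA.

# The simulator: what it emulates, and what it does not

`simulate_dataset()` generates the study conditions every test runs
under: a random-sequence toy genome (default 2 x 10 kb), tRNA genes
(70–90 bp) placed non-overlapping with at least 20 nt upstream and
40 nt downstream clearance, strands drawn per gene (default mix 0.5),
and optional boundary-case genes with clipped leaders. Each gene gets
one locus per class with class-anchored geometry; tRF-5/tRF-3 locus
lengths are drawn uniformly from their subclass windows, tsRNA from
16–40 nt, leaders from the upstream 20 nt.

Reads are drawn per the abundance table (default: total fragment mass
0.85 split equally; remainder background after the designated
feature-ambiguous fraction). Each fragment read copies its locus span
exactly — length variation is realized across loci, not within them —
which makes the class end-point structure exact: every error-free tRF-5
read starts at its gene's 5' end, and analogously for the other
classes. Substitution errors are applied per base (default 0.001).
Feature-ambiguous reads straddle the abutting tRF-3/tsRNA junction at a
gene's 3' end; multi-mapping is simulated by setting the reported hit
count (`NH:i:2`) on a designated fraction of fragment and background
reads rather than by physically re-placing them — the counting rules
only see the reported hit count, so this exercises exactly the code
path of interest. Ambiguous-junction reads are never marked
multi-mapped, keeping the realized ambiguous fraction an unbiased
binomial draw of its parameter.

What the simulator does **not** model: indels, quality-score decay,
position-dependent error profiles, true repeat-induced multi-mapping,
partial-length fragments within a locus, and tiRNA/i-tRF classes.
Passing tests therefore demonstrate the correctness of the counting,
normalization and statistical machinery under known truth — not
robustness to every artifact of real libraries.

Everything is deterministic given the config seed; the genome, the
annotation and each sample's reads use distinct seeds derived from it
so that multiple libraries can be drawn from one design.

# Numerical choices and problem sizes

* TPM column sums are exact to floating tolerance (asserted at 10^-6
  relative; observed ~10^-16).
* The trigamma inverse iterates Newton steps to relative tolerance
  10^-10 (at most 50 iterations).
* Ties in Spearman use average ranks (`stats::cor` default).
* Zero-variance features never divide by zero as long as d0 > 0; with
  `df_prior = 0` forced, a constant feature yields an undefined t and
  is left to the caller, matching the ordinary-t limit semantics.

The default verification scales — 200-gene catalogs for leader
geometry, 10^4 reads x 100 loci for the counting oracle, 100 random
matrices for TPM conservation, 20 x 2,000 features for the null size of
the moderated t, and 10^5 reads over a 10-fragment design for abundance
recovery — were chosen so the full suite and the acceptance script each
complete in a few minutes on a single core while leaving the binomial /
multinomial acceptance bounds tight enough to be meaningful.

# Known limitations

* The pipeline consumes aligned BAM; adapter trimming and alignment are
  upstream, external steps.
* Counting operates in genome space against genome-space loci; reads
  aligned to a spliced/mature-tRNA space (where tRF-3 CCA would be
  visible) are out of scope, and positive CCA verification is only
  possible with mature-space sequences.
* Only the two printed normalizations (RPM, TPM) are provided — no TMM
  or quantile normalization.
* DE supports two-group contrasts only; no precision weights, no
  multi-factor designs, no survival analysis.
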