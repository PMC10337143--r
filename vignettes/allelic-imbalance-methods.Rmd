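---
title: "Methods: uncertainty-aware allelic imbalance testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-aware allelic imbalance testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseboot)
```

# Scope and data model

`aseboot` tests for allelic imbalance (AI) across samples of a phased
diploid organism, from allele-level transcript quantifications with
bootstrap inferential replicates. The central container,
`allelic_matrix`, holds estimated counts as a
features × samples × 2-alleles array plus `B` bootstrap replicate arrays
of the same shape. The paired structure is an invariant: every feature is
present for both alleles, and the first allele label is by convention the
maternal/reference one, so positive statistics and log fold changes always
mean "second (paternal/alternate) allele higher".

The package assumes the samples share one genotype (replicates of an F1
cross, or one donor across conditions or time). It does not align
haplotypes across genotypes, construct diploid references, or run the
quantifier; it consumes quantifier output (quant.sf-dialect tables plus
plain-text bootstrap matrices) or simulates statistically equivalent data.

# Grouping isoforms by transcription start site

Testing at sub-gene resolution trades signal strength against uncertainty:
isoform-level estimates are noisy because isoforms share sequence, while
gene-level sums can cancel opposite imbalance among isoforms. The
intermediate we recommend groups isoforms by their TSS, the natural unit
when imbalance is driven by promoter-proximal regulatory variants.

`make_tx2tss()` derives the TSS strand-aware from exon extremes (minimum
exon start on `+`, maximum exon end on `-`, 1-based GTF coordinates) and
groups start sites within one gene and strand. With `window > 0`, distinct
TSS are sorted and chained while consecutive sites are at most `window` bp
apart. This is *single-linkage* clustering; a chain of close sites can span
more than `window` bp in total. A diameter-bounded alternative would also
be defensible; single-linkage was chosen because it is order-invariant,
matches the intuition of "nearby start sites share a promoter region", and
is testable against a graph-components oracle (which the test suite does).
The default window of 50 bp reflects the observation that isoforms with
start sites within ~50 bp usually share estimated allelic fold change;
`window = 0` gives exact-position groups. Groups never span genes or
strands, and group ids `<gene>-<k>` number groups by ascending genomic
coordinate of their leftmost TSS — a stable ordering independent of strand
polarity, convenient for plotting along a gene model.

# Aggregation and filtering

`aggregate_allelic()` sums point estimates *and every bootstrap replicate*
within groups, per sample and allele, so an aggregated object is a
full-fledged dataset at the new resolution; the grand total is conserved
exactly, which the tests assert replicate by replicate.

Two filters run after aggregation, in this order:

1. `filter_uninformative()` removes features whose two allele estimates
   are exactly equal in every sample. When no read distinguishes the
   alleles, EM-based quantifiers split the feature's reads exactly 50/50,
   so the estimated allelic fold change is identically 1 and the feature
   carries no information. Equality is tested with a 1e-8 absolute
   tolerance so that values surviving a text round-trip still match.
2. `filter_min_count()` keeps features with a count of at least 10 in at
   least 3 of the 2·S allele-sample columns. Counting allele-sample
   columns is the more permissive reading of a minimum-count rule on a
   wide allelic layout; `per_sample_total = TRUE` switches to per-sample
   totals. Whether a minimum-count filter should precede or follow the
   uninformative filter is immaterial for correctness (both are row
   filters); we fixed uninformative-first and document the pipeline order
   as aggregate → uninformative → min-count.

Dropped features and reasons accumulate in a `filter_report()` attached to
the object.

No library-size normalisation is performed anywhere. The tests compare the
two alleles *within* a sample, and sequencing depth multiplies both alleles
of a sample equally; scaling would only perturb the within-sample pairing.
The simulator deliberately jitters per-sample depths (uniformly within
±20% of the design's mean library size) so that this claim is exercised
rather than vacuous.

# The tests

All three tests in `ai_test()` share one scheme: a nonparametric statistic
is computed per feature on *every* bootstrap replicate and averaged, so
features whose signal is unstable under read reassignment are shrunk
toward the null; significance comes from permutations applied identically
to all features, pooled into one null distribution.

**Global AI.** The statistic is the raw Wilcoxon signed-rank sum of
`d = a2 - a1` across samples: zero differences are excluded, ties among
`|d|` get midranks, all-zero rows give 0. The raw sum (rather than a
normalised variant) is order-equivalent to any monotone rescaling and
bounded by `S(S+1)/2`. The null swaps allele labels within a random subset
of samples — equivalently, sign-flips the paired differences — one shared
flip vector per permutation. Because `|d|`, and hence the ranks, are
invariant under sign flips, the bootstrap-averaged signed-rank matrix can
be precomputed once and every permutation reduces to a matrix product;
this makes 100 permutations over thousands of features cheap.

**Dynamic AI.** Per sample and replicate, the allelic log fold change is
`log2((a2+c)/(a1+c))` with pseudocount `c = 5` (the default used for
bulk RNA-seq count stabilisation; it bounds the LFC of low-count features
without affecting well-expressed ones). The statistic is the mean over
replicates of the Pearson (default) or Spearman correlation between the
per-sample LFCs and a continuous covariate; a constant LFC vector within
a replicate contributes correlation 0. The null permutes the covariate
across samples, the same permutation for all features per draw. The
covariate must take at least 3 distinct values.

**Differential AI.** The per-sample LFCs are compared between two groups
with a centered Mann–Whitney rank sum (midranks), averaged over
replicates; the null permutes group labels. Both groups need at least two
samples.

**P-values and q-values.** The pooled two-sided empirical p-value uses an
add-one correction, `p = (1 + #{|null| >= |obs|}) / (1 + #null)`, which
guarantees `p > 0` and super-uniformity under the null. Pooling across
features gives a p-value resolution of about `1/(n_perm × n_features)`,
which is why the default of `n_perm = 100` permutations suffices for
genome-scale feature sets; sharing one permutation across features also
preserves cross-feature correlation in the null. The null proportion π₀
is estimated by Storey's smoother (λ grid 0.05–0.95 step 0.05, cubic
smoothing spline evaluated at λ = 0.95, clipped into `[1/N, 1]`), and
q-values are Benjamini–Hochberg step-up values scaled by π₀ and
monotonised. All permutation draws flow from `seed`, and the caller's RNG
state is restored, so results are bit-reproducible.

**Beta-binomial comparator.** `beta_binomial_test()` fits, per feature,
an intercept-only beta-binomial to the rounded point-estimate counts
(allele 2 successes out of total) with free precision, by maximum
likelihood in the (logit-mean, log-precision) parameterisation, and reports
the Wald p-value for a zero allelic log odds ratio with BH correction. It
uses only point estimates — no inferential replicates — and exists as the
uncertainty-blind baseline against which the averaged nonparametric tests
are compared. Near the binomial limit the precision direction of the
likelihood is flat; the implementation bounds log-precision at 15 and falls
back to the intercept curvature when the full Hessian is numerically
singular. Non-converging features are flagged and get `NA` p-values.

# The simulator

`simulate_allelic()` generates data at the *count* level; it emulates the
statistical consequences of read-level simulation plus quantification
without modelling sequences.

**Structure.** Background genes carry 1–6 isoforms (uniform); AI-eligible
genes carry 3–6 (uniform) and are built to satisfy three criteria: at
least two distinct TSS, and at least two isoforms sharing one TSS. The
construction draws the number of distinct TSS uniformly between 2 and one
less than the isoform count and assigns isoforms by a random surjection,
so a shared site exists by pigeonhole. Distinct TSS are spaced ≥ 200 bp so
the default 50-bp fuzzy window never merges designed groups. Transcripts
are single-exon with lengths uniform on 500–3000 bp — enough structure for
strand-aware TSS logic and length-weighted counts, with no claim of
splicing realism.

**Abundances.** Maternal abundance is constant per transcript, drawn
log-uniformly on [1, 100] (the distribution is not prescribed by the
benchmark design; log-uniform spreads features across two orders of
magnitude of expression, which the tertile-stratified coverage analysis
needs). Concordant genes multiply all paternal abundances by 1.25 or 0.75,
chosen per gene. We read "25% downregulated" as × 0.75 (the symmetric
percent change); the reciprocal reading × 1/1.25 = 0.8 is equally
detectable and the choice only shifts effect size slightly. Discordant
genes pick one TSS at random; its `n` isoforms get paternal fold
`1 + 1/(2n)`, and the remaining isoforms are scaled by the unique factor
restoring the gene's paternal total to its maternal total — exact
gene-level balance, asserted to 1e-12 in the tests. If the balancing
factor would be negative the TSS choice is resampled; if no choice is
feasible the gene's abundances are redrawn.

**Counts.** Expected counts are proportional to abundance × length,
normalised to each sample's library size; observed counts are negative
binomial with `size = 100` (variance `μ + μ²/100`), independent per
transcript-allele-sample — across-sample biological variation on allelic
counts. The desk profile (2000 genes, 500 AI genes split 250/250, 10
samples, 2M reads, B = 30) is the routine-testing scale; the paper-scale
profile (14,821 genes, 1000 AI, 50M reads) is configuration-reachable, and
its truth composition (500/500 concordant/discordant, 93.3% of genes
balanced) is instant to verify because no counts are needed.

**Ambiguity and bootstraps.** A fraction ρ (default 0.2) of each feature's
reads is allelically ambiguous. The emulated quantifier (i) redistributes
transcript-pair totals within a sample by one multinomial draw of the
sample's reads — point estimates thereby carry an estimation error whose
variance matches the bootstrap's total-resampling variance, the premise
under which normal-approximation bootstrap intervals are calibrated — and
(ii) splits the ambiguous fraction exactly 50/50 between alleles, which is
what an EM quantifier does when reads carry no allelic information. With
ρ = 1 a feature's estimates are exactly equal-split, feeding the
uninformative filter. `emulate_bootstraps()` then treats its input as such
point estimates: it inverts the equal split to recover the unambiguous
allele shares, and per replicate resamples totals multinomially and
redraws the ambiguous portion as Binomial(m, 1/2). Replicates are
therefore centred on the point estimates, replicate totals per sample
equal the observed total, and the replicate-mean allelic proportion of a
feature with true origin proportion `p` converges to `(1-ρ)p + ρ/2` —
the property the tests check on the composed pipeline. ρ is a free knob:
real ambiguity comes from sequence similarity, which a count-level
simulator cannot derive; 0.2 is large enough to exercise the
uncertainty-aware machinery without drowning the signal.

**What the simulator does not emulate.** No sequences, SNP placement,
mappability or GC bias, fragment-length effects, positional bias, or
isoform-level multi-mapping between transcripts of different genes;
ambiguity is allele-level and feature-local. Passing tests on simulated
data show that the statistical machinery is correct and calibrated under
the designed generative process, not that real quantifier output satisfies
that process.

# Interval coverage and its replicate dependence

`bootstrap_coverage()` builds, per feature/sample/allele, the interval
`boot_mean ± 1.959964 × boot_sd` from the first `B_sub` replicates and
checks whether the true count lies inside; features are binned into
expression tertiles on true counts pooled over samples (ties broken by
rank), and the coverage rate is summarised as mean and SD across samples.
Coverage is evaluated against the *realised* simulated counts (the NB
draws) — the quantity the estimate targets — not the expected counts,
whose deviation includes biological noise that quantification bootstraps
cannot and should not cover. Nested replicate prefixes make coverage
comparable across `B_sub` on one dataset.

One calibration fact is worth stating because the test suite encodes it:
with `B` replicates, a normal error model, and bootstrap spread matching
the estimation error, coverage of the 95% interval is
`2·pt(1.96/sqrt(1+1/B), B-1) - 1` — about 93.6% at B = 30 and 94.2% at
B = 50, approaching 95% from below as B grows. The emulated pipeline sits
close to this regime, which also means its 30→50 coverage increment
(≈ 0.5–0.7 points) is near the maximum the t-arithmetic allows; pipelines
whose bootstrap spread over- or under-states the estimation error show
smaller increments. This is a known, quantified property of the emulation,
discussed alongside the corresponding benchmark check.

# Evaluation conventions

`propagate_calls()` turns group-level significance into transcript-level
calls (a transcript is positive iff its group is called), optionally
restricted to "expressed" transcripts, which we define as those surviving
the transcript-level minimum-count filter — a concrete reading of
"expressed isoforms" that needs no extra threshold. `fdr_tpr()` uses
`FDR = FP / max(1, FP + TP)` (an empty call set has FDR 0) and stratifies
sensitivity by concordant/discordant truth status. The discordant stratum
is where aggregation level matters: gene-level testing cannot see
imbalance that cancels in the gene total, while TSS-level testing can —
the benchmark suite asserts this ordering at the 5% nominal cutoff.

LFC-sign-based within-gene aggregation (grouping isoforms by the sign of
their estimated allelic fold change, then testing the groups) is
deliberately not offered: it uses the data twice and breaks error control.

# Problem sizes and numerical choices

Routine tests run on 20–400-gene simulations; the benchmark checks use the
desk profile (2000 genes, ≈ 7000–7500 transcripts, 10 samples, 50
replicates, 100 permutations) and run in well under a minute. Degenerate
inputs are defined rather than accidental: all-zero difference vectors
give statistic 0; constant LFCs give correlation 0; a constant covariate,
groups with fewer than two samples, empty feature sets after filtering,
and `B_sub < 2` (bootstrap SD undefined) are errors; `π₀` is clipped into
`[1/N, 1]`; q-values are monotone in p-value rank by construction.

# Known limitations

- Single-genotype designs only; no haplotype alignment across donors.
- TSS grouping targets promoter-driven regulation; isoform-specific AI
  from internal splicing or NMD-coupled variation is better served by
  splice-event aggregation, which the framework admits but does not ship.
- The simulator's ambiguity model is feature-local; it cannot produce the
  correlated, sequence-driven uncertainty structure of real multi-mapping.
- The beta-binomial comparator rounds estimated counts to integers, as its
  likelihood requires.
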