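---
title: "Methods: targeted OXPHOS panel analysis of pooled heat-stress RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted OXPHOS panel analysis of pooled heat-stress RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical and algorithmic
choices: the model each stage assumes, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open.

## The design and its analysis unit

The target experiment is a pooled factorial: 3 strains (desert, montane,
F1 hybrid) x 2 temperature regimes (constant 15 degC control; diel heat
stress scored as 28 degC) x 3 replicate tanks x 4 sampling days (1, 3, 7,
28), one library of 3 pooled fish per cell — 72 libraries
(`make_design()`).

The analysis unit is the **tank**. Days are treated as repeated measures
and collapsed by averaging (`average_over_time()`), giving 18 tank means
per gene (3 strains x 2 temperatures x 3 tanks). Pooling means individual
fish are never observed; all inference is at the tank level with n = 3
per cell. No mixed model is fitted: with days averaged out, the tank means
are independent and a fixed-effects two-way ANOVA is exact for the
balanced design.

## Normalization: per-compartment expression indices

Counts are converted to indices: `index(g, s) = 1000 * count(g, s) /
(sum of counts of g's genome compartment in library s)`. Nuclear and
mitochondrial transcripts are normalized separately because every cell has
one diploid nucleus but a variable number of mitochondrial genome copies;
mixing compartments would let mtDNA copy-number shifts masquerade as
nuclear expression changes. Consequences the tests assert: each
compartment's indices sum to exactly 1000 per library, indices are
invariant to library-depth rescaling, and a perturbation confined to one
compartment never moves the other.

Indices are compositional within a compartment: a gene holding a large
share of its compartment (e.g. an abundant mitochondrial transcript) shows
a slightly attenuated index fold-change when only it changes. This is a
property of the method, not a bug, and it is visible in the planted-effect
recovery (mean recovered fold-change ~1.8 for planted 2-fold effects that
include high-share mitochondrial genes).

The log transform is `log2(index + pseudo)` with `pseudo = 0.5` index
units. The base and pseudocount are conventions, not derivable from the
analysis being emulated (which states only that counts were
log-transformed); base 2 matches fold-change vocabulary and 0.5 keeps
zeros finite while perturbing nonzero indices (typically 10-60 units)
mildly. Both are arguments of `log_transform()`.

## Differential expression

Per gene, a fixed-effects two-way ANOVA with interaction is fitted to the
18 tank means (`two_way_anova()`, via `stats::lm`): temperature (1 df),
population (2 df), interaction (2 df), error (12 df). The interaction is
included because strain-specific temperature responses — the scientific
question — *are* interaction effects. The test suite verifies the fit
against an explicit grand/marginal/cell-mean decomposition to 1e-8
relative.

Post-hoc contrasts (`posthoc_contrasts()`) test, within each strain, the
three 15 degC tank means against the three 28 degC tank means, and, among
strains at 15 degC, the three strain pairs. The default is the
**pooled-variance t-test** (4 df). This was a genuinely open choice: a
Welch test avoids the equal-variance assumption, but with n = 3 per group
its degrees of freedom can drop to 2, and the heavy t2 tails bound
attainable p-values near 1.5e-3 no matter how large the effect — which
makes panel-wide FDR rejection at alpha = 0.01 essentially impossible for
any single gene. Under the study's own conditions a 2-fold shift must be
detectable (such calls are reported at P < 0.001), so the pooled test is
the default and Welch remains available (`var_equal = FALSE`).

Multiplicity is controlled per contrast family across the 80 genes with
the Benjamini-Yekutieli step-up procedure at alpha = 0.01
(`by_fdr()`, via `stats::p.adjust`). BY carries the harmonic factor
c(m) = sum(1/k), making it valid under arbitrary dependence — appropriate
here because OXPHOS subunits are co-regulated. The suite checks the
implementation against a hand-evaluated step-up formula (for m = 4 and
p = 0.001 the smallest q is exactly 1/120) and the elementwise dominance
of BY over Benjamini-Hochberg.

Fold-changes are computed on untransformed index means with the
negative-reciprocal convention: `+r` when the ratio is >= 1, else `-1/r`,
so magnitudes are always >= 1 and sign encodes direction. Significance
stars mirror the reporting convention one star p < 0.01, two stars
p < 0.001 (raw p). `summarize_by_complex()` tallies rejected
within-strain contrasts by complex and compartment and appends
per-compartment percentages using the panel's own denominators (67
nuclear, 13 mitochondrial). Published summaries of this design imply a
69-transcript nuclear denominator, which the 80-transcript panel as
described cannot produce (80 − 13 = 67); the summary deliberately uses
the panel's denominator.

## The pooled variant / RNA-editing caller

Per site and library (`score_site()`):

1. the putative variant is the highest-count non-reference base
   (lexicographic tie-break, flagged);
2. the sequencing-error rate is estimated from the *smallest* strictly
   positive count among the remaining bases (neither reference nor
   putative variant), floored at one read: `p_hat = max(smallest, 1)/n`,
   and 0 only when no non-reference base is observed at all. The floor
   matters: a finite pileup cannot certify a zero error rate, and without
   it two stray errors at high coverage already exceed a zero-width
   interval;
3. the score is `s = (alt_count/n − p_hat) / halfwidth`, where the
   halfwidth is the Wilson score interval of Binomial(n, p_hat) at
   z = 1.96. Wilson is preferred to Wald for its behaviour at small
   p_hat. A site is called when `s > 1` — one confidence-interval unit
   beyond the error estimate. z and the threshold are arguments.

The exact functional form of the original platform's score is not
published; this scoring is a declared interpretation, validated by its
properties (monotonicity in the alternate fraction, ~0-1% null
per-library call rate at 100-150x coverage and 1% error, >99% call rate
for allele frequency >= 0.25 at 100x), not by equivalence with that
platform.

Across libraries, each population's evidence at a site is
`chi_sq = sum(s^2)` with df = number of contributing libraries (the
original df convention is unstated; libraries are the natural unit).
Populations are compared with `F = (chi_a/df_a)/(chi_b/df_b)` and a
two-sided p from F(df_a, df_b) (sidedness was also unstated; two-sided is
the conservative reading). A variant is "present" in a population when
called in at least one of its libraries — each pooled library already
aggregates three fish — with a stricter fraction rule available; the
presence pattern counts only libraries calling the site's consensus
alternate base, since a different alternate is a different variant.
Editing candidates are coding-strand A-reference, G-alternate sites
(A-to-I editing reads as G); direction matters. `fixed_difference_scan()`
reports sites where two populations' major alleles differ with both
frequencies >= 0.99 at >= 50x pooled coverage. Allele-frequency
estimation from pools is deliberately not attempted.

## Alignment-free quantification

A k-mer index (default k = 31, odd, 11-63) maps every k-mer unique to one
panel gene to that gene; k-mers shared between genes — typically isoform
partners — are ambiguous and never vote. A read is assigned to the gene
holding a strict majority of its unique-k-mer votes, in the orientation
(forward or reverse complement) with more hits; ties and vote-free reads
are unassigned. This is conservative by construction: reads lying wholly
inside an isoform-shared block cannot be assigned, so isoform-level DE
claims rest only on isoform-discriminating reads. Assigned reads are
placed ungapped by their first positionally unique k-mer to build per-site
base pileups; bases falling outside the CDS are clipped. Ungapped
placement is correct for the CDS-only panel and indel-free simulated
reads, and is a documented limitation for real data.

## What the synthetic-data generator emulates

`simulate_counts()` draws, per library and gene, a Poisson count whose
mean is baseline x strain/temperature effect x per-fish lognormal noise,
summed over the 3 pooled fish and scaled so that the expected no-effect
library total equals `library_size`. Scaling by the *expected* rather
than realized total keeps planted fold-changes exact in expectation;
downstream normalization is scale-invariant either way. Marginally the
counts are overdispersed (gamma-lognormal-Poisson), close to but not
exactly negative binomial; the pool is a **sum** of fish, since read
counts are additive even though equal RNA volumes are closer to an
average — the distinction washes out under proportional normalization.
Per-library RNG substreams are derived from one master seed, so outputs
are byte-reproducible and order-independent.

Defaults, chosen once as the study conditions:

- `library_size = 2e5` panel-assigned reads per library for count
  simulation. Real libraries carried ~32 M transcriptome-wide reads; the
  panel's share is unknown, and 2e5 gives per-gene counts (hundreds to
  tens of thousands) at which Poisson noise is subdominant to biological
  noise, as in the real data.
- `fish_sdlog = 0.08` (lognormal sd of per-fish, per-gene expression).
  This is calibrated to the only empirical anchor available: the study
  design demonstrably resolves a 1.2-fold between-group difference at
  P < 0.001 with n = 3 tanks, which implies a tank-mean log2 SD of about
  log2(1.2)/(10.3 x sqrt(2/3)) ~ 0.03, i.e. ~6% per-library CV, i.e.
  fish-level sdlog ~0.08 after 3-fish pooling and Poisson noise.
- mitochondrial baselines 20x nuclear with 2-fold gene-to-gene lognormal
  spread: mitochondrial transcripts dominate cellular mRNA mass and the
  compartments are normalized separately, so only the rough ratio
  matters.
- `read_length = 100` (the platform's single-end read length),
  `error_rate = 0.01` per base, constant FASTQ qualities.
- Editing is simulated only as coding-strand A-to-G, with per-condition
  rates (default 0.3 at planted sites — mid-range for measurable A-to-I
  editing).
- `fish_weight_sdlog` (default 0) exposes unequal pool contributions,
  which real volume-based pooling cannot rule out.

What is *not* emulated: the diel temperature ramp (temperature enters
only as a 2-level factor, as in the statistical analysis), paired ends,
quality-score decay, adapters, indels, rRNA carry-over, and
position-dependent coverage bias. Passing tests therefore demonstrate
correctness of the statistics and bookkeeping under a clean generative
model, not robustness to every artefact of real libraries.

The synthetic 80-gene panel (`simulate_panel()`) reproduces the published
panel's *composition* — 13 mitochondrial subunits, 38 complex I subunits,
the five isoform groups (COX6B, COX6C, COX7, COX8B, QCR6), cytochrome c —
with synthetic random-sense coding sequences; isoform partners share an
identical central block (40% of the CDS) so k-mer ambiguity between
isoforms is real. Reference bases at the nine published SNP coordinates
are pinned so codon arithmetic at those sites is reproducible. The true
transcript identities beyond the mitochondrial 13 and the named isoforms
live in supplementary material not reproduced here; the remaining names
are standard subunit symbols, and the sequences are synthetic throughout.

## Numerical and degenerate-input choices

- A fully constant gene is flagged `degenerate` with p = 1 rather than
  NaN; zero-variance post-hoc groups give p = 1 when means are equal and
  p = 0 otherwise.
- `fold_change()` returns NA (with a warning) on a zero denominator.
- An all-zero compartment yields zero indices plus a warning rather than
  NaN.
- Site scoring errors on zero coverage; alternate-base ties break
  lexicographically and are flagged.
- The F-test reports F = Inf, p = 0, flagged degenerate, when the
  denominator chi-square is 0.
- Balanced-design identities (SS additivity to 1e-8 relative, index sums
  to 1e-9 relative) are asserted, not assumed.

## Problem sizes used by the test and acceptance suites

The suites run the full 80-gene x 72-library count pipeline (200
zero-effect replicates for false-rejection control; 20 replicates for
planted-effect recovery), 1000-library pileup simulations at exactly 100x
coverage for caller operating characteristics, and read-level simulations
on 4-6-gene subpanels at ~120x coverage (3000-3500 reads per library, 18
libraries) for presence-pattern recovery and quantifier exactness. These
sizes were chosen so each property is measured with adequate Monte-Carlo
precision while the whole suite completes in minutes on one CPU.

## Known limitations

- The caller's score is an interpretation of an unpublished algorithm;
  absolute score values are not comparable to the original platform's.
- Ungapped, CDS-only placement cannot handle spliced or indel-bearing
  reads.
- The tank-mean analysis discards day-to-day dynamics; a time-course
  model is out of scope.
- Presence calls at very high coverage (>300x) with 1% error begin to
  admit sporadic false per-library calls (a fixed CI-unit threshold
  admits more errors as absolute counts grow); the per-library call rate
  is the controlled quantity, not the per-site candidate rate.
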