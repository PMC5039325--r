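---
title: "Windowed nucleotide diversity loss: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed nucleotide diversity loss: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divloss)
```

`divloss` measures how much standing genetic variation a cohort loses
between two developmental timepoints under two rearing conditions, and
whether that loss differs between the conditions. This vignette documents
the statistical model, every tunable that matters, the synthetic-data
generator, and the numerical and design decisions — in enough detail that a
reader could reimplement the package from it.

## Filtering model

Input is one multi-sample VCF per treatment group (or one joint table with
a group map), with GT required and DP/GQ consumed when present. Two layers:

* **Genotype mask** (`mask_genotypes()`): a call with depth < 50 or
  Phred-scaled genotype quality < 20 is set to missing. Thresholds are
  inclusive (DP 50 and GQ 20 pass), matching VCFtools `--minDP/--minGQ`.
  GQ 20 corresponds to roughly 99% call confidence. Absent DP or GQ
  subfields count as 0 and therefore fail: if quality cannot be verified,
  the call is not trusted.
* **Site filter** (`site_passes()`): indels (any allele longer than 1 bp)
  are removed; only biallelic sites (exactly one ALT) are kept —
  multiallelic sites are dropped, not decomposed; and at least 80% of a
  site's genotypes must be non-missing after masking (the VCFtools
  `--max-missing 0.8` convention, where 1 would mean no missing data).

The depth rule is applied per genotype by default because it is
conventionally listed alongside the per-genotype GQ rule; a site-level
alternative (`depth_mode = "site_mean"`, mean depth across calls >= the
threshold, like `--min-meanDP`) is exposed for users whose upstream
filtering worked site-wise. GQ is consumed as given, never recomputed.

Filtering is idempotent and depends only on the multiset of a site's calls,
never on sample order; both properties are asserted in the test suite.

## Nucleotide diversity

For a biallelic site with c0 reference and c1 alternate haplotypes observed
(n = c0 + c1; each diploid call contributes two haplotypes, missing calls
none), per-site diversity is the unordered-pair heterozygosity

$$\pi_{site} = \frac{c_0\,c_1}{\binom{n}{2}},$$

i.e. the exact proportion of the n(n-1)/2 haplotype pairs that differ. n
may vary from site to site because up to 20% missingness is allowed. Sites
with fewer than two haplotypes are skipped and counted.

Windows are non-overlapping, 1-based and inclusive: [1, W], [W+1, 2W], ...
per chromosome, W = 10 000 bp by default. Window pi is the **sum of site pi
divided by the full window length W**, counting unobserved positions as
zero contribution — the VCFtools `--window-pi` convention. With sparse
transcriptome-derived coverage this understates per-accessible-bp
diversity, but it does so identically in every group, which is what the
between-group comparison needs. Windows containing no passing variant are
not emitted, and the per-group mean pi is the mean over emitted windows
(unweighted by variant count — coverage weighting would entangle the
diversity contrast with coverage differences between groups).

A site is a *polymorphic SNP* within a group when both alleles are observed
in that group's calls (0 < c1 < n). Percent lost through time is
100 (v_d1 − v_d7)/v_d1 within each condition, for both the mean window pi
and the SNP count; the excess-loss ratio 100 (loss_high − loss_low)/
loss_low summarises how much faster diversity disappears in the high
condition, and is reported only when the low-condition loss is positive.

## Permutation ANOVA

Window pi is right-skewed, so the response is log pi; windows whose pi is 0
within a group (possible when every variant they contain is monomorphic in
that group) are excluded and counted. The natural log is used — the base
shifts all values by a constant factor and provably cannot change any sum
of squares ratio, F or p; the suite asserts this invariance.

The observed model is the fixed-effects 2 x 2 ANOVA value ~ day +
condition + day:condition with **sequential (Type I) sums of squares in
that order**, the default of `anova(lm(...))` in R. Window counts per group
are unequal, so term order genuinely matters; Type I in this order is what
a conventional R analysis of this design produces. The implementation
computes the sequential SS from one QR factorization of the 4-column design
matrix, which lets a B-column matrix of permuted responses be decomposed in
a single pass; `stats::lm` + `stats::anova` serve as the independent
reference in the tests (agreement to 1e-8), never as the permutation path.

The null is built by shuffling the response values across **all windows of
the entire dataset** — labels keep their original multiset; values are
permuted without replacement — and refitting each of B = 10 000 rounds.
The empirical p per factor is the proportion of permuted rounds with p
**strictly** below the observed p; an empirical p of 0 is reported as
"< 1/B". Because the degrees of freedom never change, ranking permuted
rounds by p is equivalent to ranking by F; both comparators are implemented
and asserted to agree. A conservative (k+1)/(B+1) estimator is available
via `estimator = "add_one"` but is not the default, which follows the
strict-proportion definition. Windows are treated as independent
observations; no spatial autocorrelation correction is attempted.

Degenerate designs — an empty cell, fewer than five observations, zero
residual variance, a rank-deficient design — raise an error before any
permutation work.

One master seed drives R's single RNG stream; the permutation index matrix
is drawn in one block up front, so a run is exactly reproducible from the
seed. Per-permutation derived streams (which would allow parallel
reproduction) were considered and not implemented: no parallel backend is
in scope, and a single stream keeps determinism trivial to audit.

## The synthetic cohort generator

`simulate_cohorts()` emulates the selective-mortality design end to end so
that every pipeline stage is testable without external data:

* **Design constants** (defaults): 7 replicate population pools per group;
  4 groups (day 1/7 x low/high pCO2); pools of N0 = 1000 larvae at day 1;
  N7 = 250 survivors at day 7; 20 000 biallelic loci spread over 20
  chromosomes of 100 kb.
* **Ancestral frequencies**: i.i.d. Beta(0.5, 0.5). The mildly U-shaped
  prior approximates a folded site-frequency spectrum — most segregating
  variants rare, a minority at intermediate frequency — without committing
  to a demographic model. Chosen once on that rationale.
* **Day-1 pools**: binomial sampling of 2 N0 gametes from the ancestral
  frequency, independently per pool and per arm (the rearing arms were
  separate replicate cultures).
* **Day 7, low arm**: binomial survival drift — 2 N7 gametes resampled
  from the pool frequency.
* **Day 7, high arm**: one deterministic generation of viability selection
  at the selected loci (default: a random 10% of loci, s = 0.1, h = 0.5,
  fitnesses 1+s / 1+hs / 1), followed by the identical drift step.
  Selection acts on frequencies before finite survival sampling —
  infinite-population selection plus finite-sample drift — because that is
  fast and analytically checkable. The favored allele is the minor allele
  with probability 0.5, so selection can either purge or fix variation.
  Loci are independent (no linkage): pi and SNP counts are marginal
  per-site statistics, so linkage would add realism the downstream
  statistics cannot see.
* **Genotyping emulation**: each pool is sequenced as one diploid library —
  depth ~ Poisson(80), alternate reads ~ Binomial(depth, q(1−e)+(1−q)e)
  with e = 0.005, and the call is the maximum-likelihood diploid genotype
  over alternate-allele fractions {e, 1/2, 1−e}, ties to the heterozygote;
  GQ is the Phred-scaled best/second-best likelihood ratio capped at 99;
  zero depth gives a missing call. This reproduces the *shape* of
  pooled-library data treated as single diploid genotypes — a deliberate
  quirk of the emulated study design — not a likelihood model for pools.

A truth table (ancestral frequency, selected flag, favored allele, realized
pool frequencies) accompanies every simulation, so tests can compare
pipeline output against generator ground truth.

## What the generator can and cannot show

The simulator validates the pipeline's *mechanics*: filters behave like
their VCFtools counterparts, pi and window sums are conserved, the
permutation test is calibrated on exchangeable nulls, reports are
internally consistent and bit-reproducible under a fixed seed.

It does **not** reproduce the magnitude of diversity loss seen in real
selective-mortality data, and with the default gentle-selection settings it
cannot: treating each ~1000-larva pool as one diploid genotype quantises
each pool to three states, and a call only changes when the pool frequency
crosses roughly 0.13 or 0.87 (the ML boundaries at depth 80). One
generation of s = 0.1 selection moves a frequency by at most ~0.012,
while survival drift to N7 = 250 has standard deviation ~0.022 — so the
selection signal is far below the resolution of 7 three-state calls per
group. Two consequences, both visible in simulated runs:

* Day-7 groups tend to show a small *gain* in called diversity: drift
  spreads sub-threshold rare alleles, and some pools cross the call
  boundary, making sites newly visible as polymorphic.
* Even strong selection does not reliably *reduce* called diversity when
  the favored allele is the minor one half the time: pushing rare favored
  alleles upward makes variation visible at least as often as pushing
  common ones to fixation removes it, given the U-shaped frequency prior.

Real data differ in exactly the ways that matter: selective mortality
operates over many days on thousands of individuals (a far larger effective
shift), and hundreds of thousands of observed SNPs average over call-level
granularity. Conclusions about the pipeline's correctness transfer from
simulation to real data; conclusions about effect sizes do not, and the
simulator's absolute pi values are not comparable to transcriptome-derived
estimates.

## Numerical choices and degenerate inputs

* All filter thresholds inclusive; missing genotype <=> both alleles
  missing; a half-missing GT is treated as fully missing.
* `site_pi` errors on n < 2 rather than returning 0: silent zeros would
  bias window sums.
* Residual-variance degeneracy is detected with a relative tolerance
  (RSS <= 1e-12 x total SS).
* Genotype-call ties (het vs hom likelihood equal) resolve to the
  heterozygote; GQ is rounded to integer and capped at 99; the empirical-p
  label switches to "< 1/B" exactly at 0.
* Windows, positions and coordinates are 1-based throughout; window
  membership of position p is floor((p−1)/W).
* JSON reports are written at full precision; rounding happens only in the
  presentation TSV.

## Problem sizes used by the test suite

Unit tests run the generator at 800 loci across 4 chromosomes — enough for
every window and group to be populated — with B of 50–300 for permutation
checks. The deeper checks use 1000-site pi-oracle sweeps, 50 random ANOVA
designs against the linear-model reference, 200 exchangeable-null datasets
(4 x 50 windows, B = 200) for calibration, and 50 full-pipeline replicates
at the generator defaults (20 000 loci, B = 10 000) for the
direction-of-effect check. These sizes are the package's choice of a
thorough-but-routine regression suite; the statistical conclusions they
support are stated above.

## Known limitations

* The pooled-library "one diploid call per pool" convention discards most
  of the allele-frequency information a pool actually carries; the package
  reproduces that convention faithfully rather than improving on it.
* Mean pi over emitted windows depends on which windows pass filtering in
  each group; groups are compared on their own emitted-window sets, not on
  a common window set.
* The permutation test inherits the independence-of-windows assumption;
  physically linked windows make it anti-conservative.
* No Watterson's theta, Tajima's D, F_ST, or per-gene statistics; the
  package compares diversity *levels*, not the identity of lost variants.
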