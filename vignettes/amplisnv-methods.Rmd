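---
title: "Background error modelling and low-VAF SNV calling with amplisnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background error modelling and low-VAF SNV calling with amplisnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(amplisnv)
library(dplyr)
```

## The problem

Amplicon panels sequenced to depths of 1000x and beyond make it possible in
principle to detect single nucleotide variants at allele fractions of a few
percent — the regime of subclonal tumour mutations and of circulating
tumour DNA in liquid biopsies. In practice, detection at these fractions is
limited not by depth but by background error: PCR and sequencing artifacts
that reach ~1% VAF, are strongly position-, substitution- and
strand-specific, and on semiconductor platforms are systematically elevated
for transition-type substitutions (A>G/T>C and, less so, C>T/G>A) and in
homopolymer context. A caller that treats error as uniform must either
drown in false positives at noisy sites or give up sensitivity at quiet
ones. The remedy implemented here is empirical: measure the noise of every
(position, alternative allele, strand) from a cohort of normal samples, and
test each candidate variant against the noise of its own site.

## The error model

For each position, alternative allele $\alpha$ and strand $\pm$, pooling
read counts over the usable normal samples $i = 1..N$:

$$s^{\alpha,\pm} \;=\; \frac{\sum_i R_i^{\alpha,\pm}}{\sum_i RD_i^{\pm}} + C$$

with $R_i$ the reads supporting $\alpha$ on that strand, $RD_i$ the strand
depth, and $C$ an additive pseudo-count. Two filters define "usable":

* **Germline/noise separation.** A normal whose strand-combined VAF for
  $\alpha$ exceeds `vaf_cap` (default 0.05) is excluded *for that allele*:
  at such frequencies the signal is most likely a real polymorphism, not
  noise. The VAF here is strand-combined,
  $(k^+ + k^-)/(K^+ + K^-)$, since the threshold describes the allele, not
  a strand.
* **Coverage.** A normal with fewer than `min_strand_coverage` reads
  (default 100) on *either* strand at a position is excluded at that
  position for *all* alleles — a thin strand makes both the numerator and
  denominator unreliable. A position absent from a normal's count file is
  treated the same way.

If the excluded fraction of the cohort reaches `max_unusable_fraction`
(default 2/3, inclusive) for a (position, allele), no estimate is produced
and the entry is **non-callable**; candidate variants there are diverted to
a side report rather than scored. Callability is assessed jointly over both
strands per (position, allele) — the filters themselves are what make a
sample unusable, and both already operate at the position or allele level.

Each callable entry also records the **maximum VAF among its usable
normals**. This deliberately excludes the normals removed by the 5% filter:
had germline carriers been included, the maximum would sit near 50% at
every polymorphic site and the downstream high-noise flag would fire on
essentially every somatic call at such sites, destroying its diagnostic
value. The quantity is meant to describe the *noise* ceiling, so it is
computed over the noise samples.

The pseudo-count $C$ (default 0.002) regularises entries whose
alternative-allele counts are underestimated at modest depth, and doubles
as an explicit sensitivity control: since every rate satisfies
$s \ge C$, a variant at VAF $\le C$ has an expected noise count at least as
large as its observed support and is essentially never callable. Values
between 0.001 and 0.01 suit most applications; the trade-off is quantified
by the benchmarks below. With no normal cohort available,
`constant_error_model()` assigns a single rate everywhere (default 0.01);
its pseudo-count is recorded as that rate, so the floor interpretation and
the invariant $s \ge C$ carry over.

Cohorts of fewer than 10 normals trigger a warning rather than an error:
estimation still works, but each entry's rate then rests on so few
binomial draws that the model adds little beyond a constant rate.

## The caller

At every position of the sample of interest with strand depths strictly
above `rd_min` (default 100; the lenient preset uses 50), each alternative
allele with at least one supporting read is scored per strand with the
upper Poisson tail

$$p^{\pm} = P\!\left(X \ge k^{\pm}\right), \qquad X \sim
\mathrm{Poisson}\!\left(K^{\pm} s^{\alpha,\pm}\right),$$

where $K s$ is the expected number of random substitutions at that depth.
P-values are converted to Phred scores $Q = -10 \log_{10} p$ and a
substitution is reported when $Q \ge 5$ on *both* strands. P-values are not
corrected for multiple testing: the flags and the per-strand requirement
are the operating point controls. Reported calls carry warning flags:

| Flag | Condition |
|------|-----------|
| `LowQ` | $\min(Q^+, Q^-) < 20$ (i.e. $p > 0.01$ on a strand) |
| `LowSupportingReads` | $k < 5$ on either strand |
| `AmpliconEdge` | covered by ≥ 2 amplicons and within `edge_window` (10 bp, strict) of a covering amplicon's boundary |
| `StrandBias` | two-sided Fisher exact p-value below `sb_threshold` (default 0.05; lenient 0.01) on the table $[[k^+, K^+-k^+],[k^-, K^--k^-]]$ |
| `HomoPolymerRegion` | inside or immediately adjacent to a run of ≥ `homopolymer_min_run` (5) identical reference bases |
| `PositionWithHighNoise` | $k > 5$ on both strands but VAF below the entry's maximum normal VAF |

`PASS` is assigned exactly when no warning fires. `AmpliconEdge` and
`HomoPolymerRegion` are evaluated only when a panel BED or reference
sequence is supplied.

## Numerical and convention choices

* **Poisson tail.** Computed through the regularised incomplete gamma
  function (`ppois(k - 1, lower.tail = FALSE)`), not term-by-term
  summation, which loses precision in the deep tail. The test suite pins
  the implementation against a direct-summation oracle to 1e-12 over a
  grid of $k \le 50$, $\lambda \le 20$.
* **P-value floor.** At high $k$ the tail underflows to exactly 0; before
  the Phred transform p-values are clamped at `p_floor = 1e-320`, so Q
  saturates near 3200 instead of becoming infinite. Q scores are printed
  to two decimals in output files.
* **Strict inequalities.** Depth gating uses $K > RD_{min}$;
  `LowSupportingReads` uses $k < 5$ while the high-noise condition uses
  $k > 5$ — at exactly 5 reads per strand neither applies. Edge distance
  is strict ($< 10$ bp). The 2/3 callability cutoff is inclusive.
* **Fisher test.** Two-sided by the minimum-likelihood rule (the
  convention of `stats::fisher.test`); one-sided would only catch excess
  on a chosen strand. The suite checks it against exhaustive
  hypergeometric enumeration on all tables with strand depths up to 12 and
  a seeded sample of tables with margins up to 60.
* **Homopolymer rule.** A run of ≥ 5 identical bases containing, or
  immediately adjacent to, the call site. "Adjacent" is included because
  flow-chemistry errors concentrate at run boundaries.
* **Percent rendering.** `performance()` keeps fractional measures and
  renders integer percents rounding half *up* (never banker's rounding);
  undefined ratios (empty denominators) are `NA` rather than errors.
* **Coordinates.** Count files and call outputs are 1-based inclusive
  (pileup/VCF convention); panel BED files are 0-based half-open (BED
  convention).

## The simulator

`sim_noise_profile()` + `simulate_normals()` generate cohorts that emulate
the features of real amplicon noise that the method's behaviour depends
on:

* per-(position, allele, strand) true error rates, with transition-type
  substitutions elevated 3x by default, mirroring the platform's
  systematic bias (the exact magnitude is a free parameter);
* optional "hot" entries (default 2% error) standing in for recurrently
  noisy sites — the heterogeneity that motivates position-specific
  estimation;
* per-strand depths, constant by default (so analytic expectations are
  exact in tests) or negative-binomial (`depth_dispersion`) to emulate
  uneven amplicon coverage;
* germline heterozygous sites: each sample carries a listed site with
  probability `carrier_prob` (default 0.3) and carriers draw
  $\mathrm{Binomial}(\text{depth}, 0.5)$ supporting reads per strand. The
  carrier probability matters: if *every* normal carried a het variant,
  the 5% filter would exclude the whole cohort at that allele, the entry
  would be non-callable, and the self-consistency protocol below would be
  vacuous. A partial carrier frequency is what real population
  polymorphisms look like and keeps such sites callable.

Alternative-allele reads are binomial given depth and the true rate, so
estimation accuracy can be judged against exact binomial standard errors.
Every entry point requires a seed and is fully reproducible.

What the simulator does **not** model: read-level effects (mapping,
base-quality correlation, PCR duplicates), primer sequences, real amplicon
coverage profiles, and the empirical magnitudes of any specific platform's
noise. Tests passing on simulated cohorts therefore establish the
*statistical* correctness of estimation and calling — rates recovered
within binomial error, floors and flags behaving as specified — not
performance on any particular real dataset.

## Benchmark protocols

Two drivers reproduce the method's standard evaluation designs at desk
scale (sizes chosen as a balance of statistical resolution and runtime;
they are parameters, not constants):

**Self-consistency** (`run_self_consistency()`): repeatedly split a normal
cohort into M training samples and held-out test samples; train the model;
call the held-out samples; label alternative alleles with VAF ≥ 20% as
positives (germline variants) and the rest as negatives; report FDR and
TPR per repeat under two call definitions — Q ≥ 20 on both strands, and
PASS only. Only alleles with at least one supporting read enter the
labelling, since the caller cannot emit zero-count alleles. The packaged
configuration uses a 60-sample cohort over 120 positions at depth
2000/strand with 10 het sites, M = 20, 10 repeats. The same driver with
`baseline = TRUE` skips training and uses the constant model $s = C$ — the
comparison that quantifies what position-specific estimation buys. On
heterogeneous noise (5% hot entries) the trained model's median FDR is
dramatically lower than the baseline's; the improvement direction is
asserted in tests, its magnitude reported by `scripts/acceptance.R`.

**Spike-in sensitivity** (`run_synthetic_variant_experiment()`): for every
combination of total depth COV ∈ {800, 1600, 3200, 6400} and VAF ∈
{0.5, 1, 1.25, 2, 3, 4}%, inject a symmetric variant (depth COV/2 per
strand, $a = \mathrm{COV} \cdot \mathrm{VAF}/2$ supporting reads per
strand) at every panel position for each alternative allele, and report
the fraction recovered as PASS. These grids make $a$ a whole number by
construction. All injected variants are positives, so only TPR is defined.
Alleles are injected one per synthetic sample (three samples per cell) so
that high-VAF injections cannot exceed the fixed depth. With a constant
model $s = C = 0.005$, no calls occur at VAF = 0.5% at any tested depth,
and recovery is total at VAF = 50% — the pseudo-count floor in action.

## Limitations

* Population polymorphisms shared by most of the normal cohort become
  non-callable entries; the method targets somatic variants and accepts
  this.
* Somatic/germline separation is out of scope: call the matched normal
  and subtract.
* The model assumes the upstream count extractor already applied base- and
  read-quality filtering; counts are taken at face value.
* Indels, BAM-level processing and multi-allelic interactions beyond
  per-allele independence are not modelled.
* The Poisson tail treats reads as independent given the rate;
  overdispersion beyond the panel-of-normals stratification (e.g.
  batch effects within a run) is not captured and shows up as residual
  false positives at recurrent sites — a candidate for a post-hoc
  blacklist.
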