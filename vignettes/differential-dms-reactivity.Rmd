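---
title: "Differential DMS reactivity analysis with dmsdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential DMS reactivity analysis with dmsdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

Dimethyl sulphate (DMS) methylates the Watson-Crick face of adenines and
cytosines that are not base-paired (or otherwise protected), so the
accessibility of each A/C to DMS reports its single-strandedness inside
the cell.  In a Structure-seq2-style experiment the methylation sites are
read out as reverse-transcriptase (RT) stops: the enzyme halts adjacent to
a modified base, and sequencing the aborted cDNAs yields, per transcript,
a track of stop counts per nucleotide.  A DMS-untreated library measured
in parallel captures natural RT stops, which are subtracted in signal
space.  Comparing two cellular conditions — here called *control* and
*hipp*, after the eIF4A helicase inhibitor hippuristanol that motivates
the design — turns the per-nucleotide reactivity difference into a map of
where RNA structure forms or melts when the helicase is inactivated.

`dmsdiff` implements the full desk-side analysis:

1. stop-count (`.rtsc`) parsing and per-transcript quality metrics,
2. normalized reactivity (`.react`) derivation with a shared scale,
3. replicate averaging and delta reactivity (treated minus control),
4. regional statistics, Gini coefficients, binned meta-profiles,
5. sliding-window detection of localized remodeling in 5'UTRs,
6. (GGC)~4~/(GCC)~4~ motif reactivity normalization,
7. polysome-profiling translational efficiency and a Bayesian
   difference-of-differences dependency classifier,

together with a seeded synthetic-data generator that emulates the
statistical structure of such an experiment, so every stage can be
validated against known ground truth.

All external tables use 0-based half-open coordinates (`utr5_end` is both
the 5'UTR length and the CDS start); R-internal code is 1-based.

## Quality metrics and filters

**Coverage** is stops at A/C divided by (transcript length × AC
fraction), i.e. stops per A/C nucleotide; a transcript passes at coverage
≥ 1 in *every* DMS(+) replicate of both conditions.

**5' end coverage** flags transcripts whose annotated 5' end has no read
support (a symptom of a mis-annotated transcription start site).  The
underlying published figure panel defining the score is not reproduced in
the source text, so this package declares its own form with the stated
defaults: the score is `n × stops(5'-most ⌈L/n⌉ nt) / total stops`, 1 for
a uniform stop distribution, and transcripts scoring < 1.5 at `n = 10` on
the DMS(−) samples of both conditions are removed.  Real DMS(−) libraries
are enriched for stops at the very 5' end (RT runs off the 5' end of
intact transcripts), which is why well-annotated transcripts score well
above 1.

**3' trimming**: the 3'-most 125 nt are masked from every statistic
(coordinates preserved), because library construction depletes coverage at
transcript 3' ends; the remaining part of the 3'UTR is the analyzed "3'
region".  Transcripts not longer than the trim are excluded.

**Specificity and ligation bias**: the per-base composition of stops
(DMS(+) libraries should be dominated by A/C) and the composition of the
nucleotide immediately 3' of each stop versus the transcriptome
background.

## Reactivity normalization

For each transcript the defined positions are the A/C inside the
untrimmed span.  With `P` and `M` the `ln(count + 1)` tracks of the
DMS(+) and DMS(−) channels, each normalized to unit sum over defined
positions, the raw signal is `max(0, P − M)`.  The per-transcript scale is
the mean of the descending-sorted 2–8% quantile band of the raw values
(so dividing by it sets that band's mean to exactly 1), and reactivities
are capped at 7.  This is the canonical Structure-seq scheme; the band,
cap and trim are all arguments.

Two details matter in practice:

* **Shared scale.** In a multi-sample design the scale must be identical
  across samples or condition differences would be normalized away.
  `derive_reactivity_set()` generates scales from one reference sample
  (default: control replicate 1) and reuses them everywhere, mirroring
  the `.scale`-file workflow of the published pipelines.
* **Averaging contract.** Replicate averages are defined only where every
  replicate defines the position; delta reactivity is defined where both
  condition averages are.  Negative delta = less reactive under treatment
  = structure gained; this sign convention is preserved end to end.

## Regional statistics and meta-profiles

Transcripts are split into 5'UTR / CDS / 3' region; regional means use
defined positions only.  The Gini coefficient
`G = Σᵢⱼ|xᵢ−xⱼ| / (2n²x̄)` summarizes how unevenly reactivity is
distributed (0 = even, 1 = concentrated); it is computed over defined
positions only, since zero-filling G/U positions would inflate inequality
as a function of GC content.

Meta-profiles rescale each region to a fixed bin count (25/50/25).  A
0-based offset `p` in a region of length `L` maps to bin `⌊pB/L⌋`, so
bins never straddle region boundaries.  Each transcript contributes its
own bin mean and transcripts are weighted equally (the alternative —
nucleotide weighting — would let long transcripts dominate, and group
sizes would no longer match the transcript counts attached to the
confidence intervals).  Per-bin confidence limits use a paired two-sided
t test across transcripts for condition contrasts and an unpaired t test
for group contrasts.  Only transcripts whose three analyzed regions are
all ≥ 100 nt enter a meta-profile.

## Sliding-window remodeling analysis

Within each 5'UTR, `window_deltas()` scores every window of a given width
(step 1 by default, i.e. every possible window) by its mean delta over
defined positions; windows with fewer than `min_defined = 3` defined
positions are dropped rather than the stricter alternative of discarding
any window containing an undefined position, which would bias against
GC-rich (A/C-poor) stretches.  Per transcript, the windows with the most
negative and most positive mean are the extreme windows (ties break to
the smallest start, with a 1e-12 tolerance so floating-point noise cannot
break exact ties).  Downstream comparisons:

* relative positions `(start + width/2) / utr5 length`, binned into ten
  equal bins and compared between groups by an unpaired two-sided
  Wilcoxon test;
* Pearson correlation of per-transcript extreme deltas against 5'UTR
  length or GC content;
* a width sweep (default widths 5–50 nt) reporting raw, uncorrected
  per-width Wilcoxon p values — deliberately uncorrected, matching the
  descriptive use of the sweep;
* greedy nearest-neighbour length matching (on log length, without
  replacement, target processed in seeded random order) to build
  length-matched control groups.

GC content uses the same machinery with 50-nt windows at 10-nt steps.

## Motifs

`(GGC)₄` (G-quadruplex-capable) and its reverse complement `(GCC)₄`
(quadruplex-incapable control) are matched exactly, overlaps allowed,
within 5'UTRs; one hit per 5'UTR is chosen uniformly under a seed.  A
hit's normalized (delta) reactivity is its mean over defined positions
minus the 5'UTR mean — invariant to profile-wide shifts.  Only A/C carry
reactivity, so a (GGC)₄ value rests on 4 cytosines and a (GCC)₄ value on
8; the group tests (Wilcoxon) inherit this asymmetry, which is why it is
stated here rather than hidden.

## Translation: TE and dependency classification

Translational efficiency is `TE = (poly + ε)/(sub + ε)` from replicate
means with pseudocount ε = 0.5; tertile grouping takes the top and bottom
`⌊n/3⌋` genes by control TE with ties resolved by gene id.

The dependency classifier compares two models of the per-fraction
log-fold changes `y_sub`, `y_poly` (differences of replicate-mean log
expressions): a baseline in which one shared change explains both
fractions, and an alternate with fraction-specific changes.  Replicate
variance is pooled per gene over the four fraction × condition groups and
shrunk toward the across-gene median with `k = 5` pseudo-replicates;
the change parameters carry conjugate `N(0, σ₀²)` priors, making both
marginal likelihoods closed-form (the baseline induces a bivariate normal
with covariance σ₀²).  With prior probability 0.1 on the alternate,
genes are labeled *dep* (posterior > 0.25 and `y_poly − y_sub < 0`),
*antidep* (sign positive), *indep* (posterior < 0.02), else *unassigned*.
This is a deliberately simple conjugate formulation that preserves the
published decision structure (prior, thresholds, sign rule) and is fully
testable by recovery; it does not attempt to reproduce any particular
external implementation numerically.

σ₀ defaults to 2 natural-log units.  This is weakly informative, and the
choice is load-bearing: with only two observed fraction changes per gene,
the Bayes factor attainable in favour of the baseline model is bounded by
roughly `σ₀/√(2v)` (v the sampling variance of a fraction change), so an
overly tight prior makes the posterior floor sit above the 0.02
independence threshold at realistic replicate noise and no gene could
ever be declared independent.

The uTIS score is `upstream / (upstream + annotated)` TIS reads: 0 means
initiation only at the annotated start, 1 only upstream.

## The synthetic-data generator

`simulate_structure_seq()` produces a complete experiment under one
master seed; every transcript × sample × replicate (and every gene in the
expression simulators) draws from its own derived substream, so adding or
removing transcripts leaves the others' data untouched.

What it emulates, and the defaults chosen where no published value
dictates one:

* **Transcript architecture**: lognormal region lengths (5'UTR ~200 nt,
  CDS ~900 nt rounded to codons, 3'UTR ~400 nt with a 250-nt floor so the
  analyzed 3' region survives the 125-nt trim), all regions ≥ 100 nt; a
  5'-high GC gradient inside the 5'UTR (GC ≈ 0.55 at the midpoint,
  slope 0.2 cap→CDS), matching the observation that 5'UTRs are most
  structured away from the start codon.
* **Ground-truth accessibility**: Beta(2, 2) per position under control.
  Treatment subtracts `remodel_depth = 0.5` over one `remodel_width = 20`
  nt loss window per 5'UTR and adds the realized loss back over a
  disjoint, twice-as-wide gain window (proportionally to headroom,
  clipped to [0, 1]) — remodeling, not net structure gain, so the 5'UTR
  mean change is ~0 by construction.  *dep* transcripts centre the loss
  window near relative position 0.9 (just upstream of the CDS, ±0.1
  jitter); *indep* and *antidep* transcripts place it uniformly.  Depth
  and positions are recorded in a truth table.
* **Stop counts**: single-hit chemistry — DMS(+) stops are multinomial
  with weight `background_rate (0.02) + accessibility` at A/C and
  `background_rate` elsewhere, total Poisson with mean 2000 ×
  a mean-normalized lognormal abundance (sdlog 1.2).  DMS(−) stops are
  uniform over all bases at 30% of the DMS(+) depth, plus a 5'-end spike
  (20% of minus stops at position 0) emulating full-length cDNA stops —
  without it, a uniform DMS(−) model would score ~1 on the 5' end
  coverage statistic and the 1.5 filter would remove everything, which is
  not how annotated transcripts behave.
* **Polysome counts**: per gene, lognormal baseline expression split
  60/40 into polysomal/sub-polysomal mass; under treatment a *dep* gene's
  fractions are rescaled by factors a, b solving `log(a/b) = −te_shift`
  and `poly·a + sub·b = poly + sub`, so the true log-TE shift is exactly
  `−te_shift (= −1)` and gene totals are conserved; *antidep* uses the
  opposite sign, *indep* a small common factor in both fractions.  Counts
  are negative binomial with dispersion 0.05 (Poisson in the
  dispersion → 0 limit).
* **TIS counts**: a `utis_mix` fraction of genes initiates upstream;
  their reads split binomially (upstream probability 0.3) out of a
  Poisson total.

What it does **not** emulate: protein protection footprints, sequence-
dependent RT drop-off, uneven fragment recovery along transcripts,
isoform mixtures (one transcript per gene), or any coupling between a
transcript's structure and its expression level.  Passing recovery tests
therefore demonstrates that the analysis machinery is correct under the
stated generative assumptions — not that those assumptions capture every
property of cellular libraries.

Two measured consequences of the generative choices are worth stating so
nobody reads more into the tests than they show.  First, with ~1–2 stops
per nucleotide the pooled per-position *Spearman* replicate correlation
saturates near 0.7 (the rank statistic is dominated by tied zero counts);
the *Pearson* correlation sits in the 0.85–0.97 range typical of real
libraries, and the replicate-correlation test asserts Pearson.  Second,
because every transcript receives one fixed-depth remodeling window, the
negative correlation between per-transcript extreme window delta and
5'UTR length arises only from the extreme-value component (more windows
to take a minimum over in longer UTRs) and is therefore weaker than in
real data, where longer 5'UTRs genuinely remodel more.

## Problem sizes and numerical choices

The test suite and the bundled recovery analyses run, by design, at desk
scale: 150-transcript experiments for the shared fixtures, 800
transcripts (500 dependent, equal per-transcript depth) for window
localization and positional-bias recovery, 500 transcripts at default
settings for the length-correlation check, and 1500 genes for classifier
recovery.  Localization recovery checks that the most-negative 20-nt
window overlaps the injected window in ≥ 90% of dependent transcripts and
that the dependent-group meta-profile minimum falls in the 5'UTR bins
covering relative positions 0.8–1.0.

Degenerate inputs are handled explicitly: transcripts with no A/C, no
DMS(+) signal, or a nonpositive generated scale are unscorable and are
excluded with a record; zero-stop tracks have undefined end-coverage and
fail the filter; single-replicate genes are unassigned by the classifier;
all-zero or singleton vectors have undefined Gini.  Ties break
deterministically everywhere (smallest start, lexicographic ids), so a
fixed seed reproduces every output byte for byte — `run_pipeline()`
writes a manifest of input hashes, config, and per-stage transcript
counts sufficient to verify that.

## Known limitations

* The 5' end coverage score is a declared stand-in for an equation whose
  published form is unavailable; its defaults reproduce the stated
  filtering behaviour (uniform → 1, threshold 1.5 at n = 10).
* The dependency classifier is a conjugate simplification; posterior
  values are comparable within this package, not across tools.
* Reactivity-restrained folding, G-quadruplex propensity scores, motif
  discovery, and replicate-aware differential-window detection are out of
  scope; externally produced windows can be fed to the binning and
  position machinery as plain intervals.
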