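---
title: "Calling and modelling mRNA 3' tails: methods and design notes"
author: "TailSeqR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and modelling mRNA 3' tails: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TailSeqR)
```

## Scope

TailSeqR studies the 3' extremities of mRNAs: the length of the poly(A)
tail, the presence of untemplated 3' terminal uridines added by terminal
uridylyltransferases (TUTases such as Arabidopsis URT1), and the
heteropolymeric "A-rich" tails that mark degradation intermediates. The
package covers five analysis stages — read-level tail calling from
targeted 3'-end libraries, aggregation into tail-length and uridylation
profiles, quasi-likelihood negative-binomial enrichment statistics for
spectral counts and small-RNA counts, quasi-Poisson half-life estimation
for in vitro deadenylation time courses, and short-linear-motif scanning
in TUTase protein sequences — plus a synthetic-data module that generates
every input with ground truth.

## The tail model and its classification rule

A read pair from a targeted 3'-end library consists of a short
gene-identification read (41 nt, the 5' end of the amplicon) and a
tail-side read (111 nt) sequenced from the 3' adapter, so that the first
base of read 2 is the complement of the RNA 3' terminus. After
reverse-complementing read 2 into RNA sense, everything 3' of the last
templated nucleotide is the tail, and the tail string is decomposed by a
single deterministic rule, scanning from the 3' terminus:

1. the maximal terminal run of `U` is the terminal-uridine count;
2. a run of `C`/`G` immediately upstream is an *other-nucleotide 3'
   addition*;
3. the remaining core segment contributes the poly(A) length (its number
   of `A`s); any non-A inside it makes the tail *A-rich*;
4. otherwise the tail is *uridylated* (at least one terminal U),
   *non-uridylated* (homopolymeric poly(A)), or *untailed* (empty).

The rule is minimal by design: one internal non-A suffices for the
A-rich class, oligo(U)-only tails are uridylated with poly(A) length 0,
and no error correction is attempted at the decomposition level — a
mis-called base inside a poly(A) stretch becomes an A-rich call. An
error-correction heuristic would be unverifiable against any ground
truth, so robustness to sequencing error is instead quantified on
simulated reads (below). Classes are mutually exclusive and exhaustive;
when a tail has both an internal non-A and a terminal `C`/`G` run the
A-rich label wins, keeping the heteropolymeric signal visible.

```{r decompose}
decomposeTail(c("AAAAAAAAAAAAAA", "AAAAAAAAAAAAUU", "AAAAAGAAAAU"))
```

## Read processing

Gene assignment matches the gene-identification read against the
equal-length prefix of each catalog gene, tolerating one substitution
(`geneAssignMaxMismatch = 1`); ties are conservatively unassigned. Tail
extraction anchors the first 12 nt (`anchorMinMatch`) of the
sense-oriented tail read in the reference with at most one mismatch and
extends the templated match. The boundary stops early only when three
mismatches fall within one anchor length: a genuinely non-templated
region mismatches a random reference at roughly three quarters of
positions, while isolated substitution errors (0.1–0.5% per base) almost
never cluster that densely, so sequencing errors in the gene body are
absorbed instead of truncating the templated region. Coordinates are
0-based and half-open throughout; the signed `end_offset` is 0 when the
last templated base is the main polyadenylation site, and
`filterBySite()` keeps reads within ±50 nt of it by default.

With 111-nt tail reads, a tail longer than about 99 nt leaves no
templated anchor in the read, so such reads are counted as unalignable
rather than called — the reason distribution percentages use the 1–90 nt
denominator and report longer tails only as a separate fraction.

## Profiles and comparisons

`sizeDistribution()` reports percentages per integer tail length over
1–90 nt (summing to 100) plus the >90 fraction over all tailed reads.
`uridylationPercent()` uses a ≥20-read detection threshold per gene;
`drsMedianGeneProfile()` requires ≥100 reads in every replicate ×
genotype cell before a gene enters the per-bin median profile, matching
the detection filters used for transcriptome-wide tail profiling.
Tail-size bins split at <10 nt (excessively deadenylated), 10–25 nt
(oligo(A), the preferred uridylation substrate) and >25 nt. Nanopore
estimates are continuous and are binned by round-half-up to 1-nt bins.

Group comparisons are pairwise two-tailed Wilcoxon tests — signed-rank
when paired, rank-sum otherwise — exact for group sizes below 25 without
ties, with Benjamini–Hochberg adjustment across the pairwise family and
a compact letter display computed by the insert–absorb heuristic
(implemented here directly). Although the source convention describes
paired comparisons as "rank-sum ... paired", the behaviour of pairwise
paired testing is the signed-rank test, which is what `compareGroups()`
uses. Boxplot statistics use type-7 (linear interpolation) quartiles and
whiskers at the most extreme data within 1.5 interquartile ranges.
Uridylation-bin edges for response comparisons are left-closed and fully
configurable; no default is claimed to match any published figure.

## Quasi-likelihood NB enrichment

The spectral-count and small-RNA statistics re-implement the
quasi-likelihood negative-binomial GLM procedure end to end:

* **Size factors** by median-of-ratios: per-feature geometric-mean
  references over the all-positive features, per-sample median ratio,
  rescaled to geometric mean 1.
* **Dispersion** by Cox–Reid adjusted profile likelihood, maximized on a
  log-scale grid with golden-section refinement; the bottom 50% of
  features by total count are excluded because their noisy likelihoods
  adversely affect the estimate. Tagwise estimates maximize each
  feature's APL plus a prior-weighted average APL (prior df 10 by
  default), shrinking toward the common value.
* **Fitting** by iteratively reweighted least squares on the log link,
  batched across all features (closed-form 1×1 and 2×2 weighted
  least-squares solves), convergence at a relative deviance change of
  1e-8 within 100 iterations.
* **Testing** by a quasi-likelihood F-statistic: the deviance drop for
  the contrast over the empirical-Bayes-moderated quasi-dispersion
  (residual deviance/df squeezed toward a scaled inverse-chi-square
  prior fitted by moments on the log scale), with denominator df
  augmented by the prior df, then BH adjustment.

Agreement with the published implementations of this strategy is
approximate rather than bit-exact (the test suite checks rank agreement
with edgeR's QL pipeline and closeness of the dispersion estimates);
correctness is established by simulation calibration: type-I error at
nominal 5% within [0.035, 0.065] at 5000 null features, fold-4 spike-ins
recovered at ≥80% power with realized FDR ≤0.07, and common-dispersion
recovery within ±25% at 5000 features × 6 samples. Features with zero
counts in all samples are dropped before normalization, and reported
log2 fold changes guard against one-group zeros with a pseudo-fraction
of 0.5/(geometric-mean library size).

## Decay kinetics

Half-lives of in vitro deadenylation substrates are estimated by
quasi-Poisson regression of band intensity on time — log link, variance
proportional to the mean, applied to continuous intensities without
integerization, since quasi-likelihood does not require integer data.
The rate is the negative slope, the half-life `log(2)/rate`, and its SD
follows by the delta method, `sd(t1/2) = log(2) sd(k) / k^2`. Intervals
use the t quantile on the residual degrees of freedom because the
dispersion is itself estimated from a handful of timepoints; with the
default nine-timepoint design this yields 93–97% empirical coverage at
overdispersion 2 in the package's own calibration tests. Slopes within
numerical zero of 0 (rate ≤ 1e-10/min) are reported as an infinite
half-life.

## Motif scanning

Motif patterns use position-set semantics: each slot lists its allowed
residues (`"PPGF"` literal, `"[LM]xx[IL]"` sets and wildcards). Only the
PPGF motif — recognized by GYF-domain decapping regulators — ships as a
built-in literal; M1/M2-type consensus patterns must be supplied by the
user, typically derived from an ortholog alignment, to avoid inventing a
consensus that no primary source prints. Hits are leftmost
non-overlapping; occurrence maps normalize start positions (a declared
convention; centers are not used) onto a 0–100 scale. Logo information
content is `log2(20)` minus the column entropy with gaps excluded and
the small-sample correction off by default. The composition test is an
exact two-sided binomial test (summing outcome probabilities not
exceeding the observed one) of a residue group — default P/Q/N/G, the
bias characteristic of the TUTase N-terminal disordered region — against
a user-supplied background frequency such as a proteome-wide average.

## The synthetic-data generator

The generator emulates the study conditions end to end and is the
package's substitute for deposited raw data. Defaults, chosen once:

* poly(A) length mixture of short (<10 nt, uniform 1–9), oligo(A)
  (uniform 10–25) and long (26 + geometric with decay 0.04, truncated at
  250 nt) classes with weights 0.10/0.45/0.45 — a population centred on
  the oligo(A)-to-long range typical of steady-state plant mRNA;
* per-class uridylation probabilities 0.10/0.20/0.02, concentrating
  terminal uridines on oligo(A) tails; added-U counts follow a shifted
  geometric with mean 1.5 (mostly 1–2 uridines);
* A-rich tails at 2% with a 10% per-position interruption rate drawn
  from C/G/U at internal positions only, so the heteropolymeric core
  still ends in A and truth labels stay well defined under the
  classification rule;
* 41 × 111 nt read layout with the sequencing primer at the
  adapter/tail junction (read 2 base 1 complements the RNA 3' terminus;
  no adapter bases in the read), constant quality `I`, and a uniform
  0.1% substitution rate (0.5% in robustness experiments);
* DNA alphabet on disk (FASTQ convention), RNA sense (`U`) in memory.

Spectral counts, small-RNA counts and decay curves are negative
binomial: counts with mean baseline × size factor × fold and a common
dispersion; decay intensities with variance/mean pinned exactly at the
configured overdispersion. DRS tables draw log-normal per-gene medians
(median ≈ 70 nt) with log-normal read noise and an additive genotype
location shift. The generator does **not** emulate basecaller signal,
PCR duplication, adapter remnants, nanopore squiggles, or
position-dependent error profiles, so passing recovery tests demonstrate
correctness of the calling logic and statistics, not robustness to every
artefact of real libraries.

Two calibration experiments fix their configurations deliberately. The
profile-shift recovery experiment moves 10 percentage points of the
mixture from the oligo(A) class into the <10 nt class and bounds the
long component at 90 nt so that every simulated tail is within the
measurable range of a 111-nt read and the generative shift is exactly
+10 points; with the default 250-nt truncation, tails beyond ~99 nt are
unalignable pure-tail reads and would bias the realized shift. The
sequencing-error robustness experiment uses the excessively deadenylated
population (tails 1–9 nt): every tail base hit by an error changes the
called decomposition by construction, so recovery under error is bounded
by the clean-tail probability `(1 - e)^L`, and the short-tail population
is the regime where the ≥97% recovery contract is meaningful.

Problem sizes in the test suite (10 000 reads per recovery experiment,
5000 × 8 null features, 20 spike-in runs of 2000 × 8, 1000 decay
curves) were chosen so the binomial/simulation error of each checked
quantity is several times smaller than its acceptance band.

## Known limitations

* Tail extraction assumes the reference 3'-region ends at (or near) the
  main polyadenylation site; cleavage downstream of the provided
  reference cannot be recovered.
* Uridylation percentages use all tailed reads as the denominator (the
  1–90 nt alternative is available via the profile functions); the
  original convention is not printed and both are defensible.
* The QL machinery supports one- and two-coefficient designs with the
  fast batched path; larger designs fall back to a per-feature solver.
* No UMI deduplication, general-purpose alignment, or basecall
  intensity re-analysis.
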