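---
title: "Whole-chromosome analysis of meiotic crossovers and gene conversion"
author: "meiorec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-chromosome analysis of meiotic crossovers and gene conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiorec)
```

## The problem

When two isogenic parental lines differ at tens of thousands of marker
positions along a chromosome, the haplotype of a transmitted chromatid can be
read directly — on a hemizygous chromosome (the male *Drosophila* X) without
any heterozygous genotyping.  Each exchange of parental identity along the
chromatid is a crossover (CO); each short internal block of the opposite
parent, flanked on both sides by the background haplotype, is a noncrossover
gene conversion (GC) tract.  COs are essentially always visible because they
exchange flanking markers.  GC tracts are short (hundreds of bp) and are
invisible whenever they fall entirely between markers, so the raw count of
observed GC events underestimates the true rate; the whole point of the
model implemented here is to correct for that invisibility using the
distances between genotyped markers.

The package covers four stages, each usable on its own:

1. **Synthetic meiosis** (`generate_marker_map()`, `meiosis_params()`,
   `simulate_meiosis()`, `export_dataset()`): chromatids with known CO/GC
   truth, degraded by the observation process.
2. **Event detection** (`detect_events()`, `span_histogram()`,
   `summarize_events()`): segmentation of call vectors into parental runs,
   event classification, and the span histogram the likelihood consumes.
3. **Inference** (`gcml()` with `confint()`, `lrt_event_total()`,
   `derived_rates()`): the joint maximum-likelihood fit of the GC
   double-strand-break (DSB) rate and tract-length parameter.
4. **Resampling and motif statistics** (`min_distance_null()`,
   `interval_placement_null()`, `word_count_fisher()`, `pwm_scan()`,
   `flank_enrichment()`, `metamotif_components()`,
   `empirical_region_null()`).

## The model

GC-initiating DSBs fall on a transmitted chromatid as a Poisson process with
rate $\lambda$ per bp per meiosis.  From the break, conversion extends
independently leftward and rightward; each one-sided extension $L$ is
geometric with cessation probability $p$:

$$P(L) = (1-p)^L\,p, \qquad E[L] = \frac{1-p}{p},$$

so the mean total tract is $2(1-p)/p$.  The data factorize into two parts.

**Spans.**  A span of $i$ bp between adjacent genotyped markers that shows no
conversion contributes

$$P_{\text{noGC}}(i) \;=\; e^{-i\lambda} \;+\; i\lambda e^{-i\lambda}\,
\frac{1}{i}\sum_{k=1}^{i} F(k-1)\,F(i-k),$$

where $F$ is the geometric CDF of one-sided extension: the 0-DSB term plus
the 1-DSB term with the tract stopping short of both flanking markers.  The
DSB ordinate $k$ runs over the $i$ inter-nucleotide positions of the span
(distances $k$ and $i-k+1$ to the distal and proximal flanks).  DSB counts
beyond one are ignored and the probabilities are *not* renormalized — the
truncation is implemented exactly as the model states it.  The sum collapses
to a closed form in $q=1-p$, so evaluation is $O(1)$ per distinct span
length and the full likelihood over millions of spans costs milliseconds.

**Conformations.**  An observed conversion is summarized by its
*conformation*: the span $i$ between the nearest nonconverted flanking
markers and the offsets of the outermost converted markers from those
flanks.  Its probability sums, over the possible DSB ordinates, the chance
that each one-sided tract covers every converted marker on that side while
stopping short of the flank (`p_gc_conformation()`).

The log-likelihood is
$\sum_a N_a \ln P_{\text{noGC}}(a) + \sum_c \ln P_{\text{GC}}(c)$
with $N_a$ the count of no-conversion spans of length $a \le b$
(default $b = 10\,000$ bp; longer spans carry almost no information about
the tract process).  `gcml()` maximizes over a log-spaced
$60\times 60$ grid on $\lambda \in [10^{-10}, 10^{-6}]$,
$p \in [10^{-4}, 1]$, refined by Nelder–Mead on $(\log\lambda,
\operatorname{logit} p)$, with grid ties broken toward smaller $\lambda$.
Confidence intervals are profile-likelihood bounds at a drop of 2
ln-units with the other parameter fixed at its MLE; bounds that run into
the search range are flagged open-ended.  `lrt_event_total()` tests a
constrained total recombination rate (e.g. a cytological DSB count) by
fixing $\lambda$ so the implied genome-wide GC events per meiosis equal the
constraint minus the CO count, re-fitting $p$, and referring
$2\Delta\ln L$ to $\chi^2_1$.

### Coordinate conventions

Positions are 1-based inclusive throughout (BED export converts to 0-based
half-open).  Span and tract lengths are simple position differences, so a
conversion whose flanking markers sit at 6,633,119 and 6,633,865 has a
maximum tract of 746 bp.  In the likelihood the DSB is interstitial — it
sits between nucleotides and converts nothing by itself; this matches the
span model's count of $i$ possible DSB positions and makes $p=1$ a clean
limiting case in which nothing is ever converted.  In the simulator the DSB
is placed at a nucleotide and that nucleotide is always converted, so a
zero-extension event still converts exactly one site.  The two conventions
differ by at most one bp at tract edges, far below the marker spacing; the
Monte-Carlo oracles in the test suite use the likelihood's convention so
the equivalence of formula and simulation is testable exactly.

A deliberate consequence of the one-DSB truncation: the span and
conformation probabilities do **not** sum to the 0/1-DSB Poisson mass over
all outcomes, because conformation events overlap as events and tracts that
overrun a flanking marker belong to no conformation.  The truncated model
is a per-span approximation, adequate because $i\lambda \ll 1$ at realistic
rates; the test suite documents the deficit rather than hiding it.

## The synthetic meiosis generator

The generator's defaults emulate the study design the package targets: a
22.4-Mb chromosome arm carrying 93,538 polymorphisms, 30 transmitted
chromatids, and an observation process that genotypes ~70% of markers.

* **Marker map**: uniform placement, or block-wise gamma intensities
  (`clustering` > 0; default 0.5, i.e. shape-2 gamma multipliers over
  22-kb blocks).  The default makes regional marker density vary by factors
  of ~2–4 (gap variance ≈ 2.8× the uniform-placement value), emulating the
  patchy polymorphism density of real line comparisons.  A stronger choice
  (gamma shape ≤ 1) is degenerate — the intensity's inverse moment diverges
  and a few near-empty blocks dominate the gap distribution — which is why
  the default sits at shape 2.
* **Crossovers**: 0/1/2 per chromatid with probabilities (0.6, 0.3, 0.1),
  matching the observed design scale of 18 no-CO, 9 single-CO and 3
  double-CO chromatids per 30 (≈15 COs with ≈3 DCOs).  Positions follow a
  piecewise-constant density biased 3:1 toward the distal two-thirds of the
  arm; interference is a hard minimum separation (default 4 Mb) between the
  two COs of a DCO — the simplest mechanism reproducing the wide DCO
  spacings seen in real chromatids, not a calibrated gamma renewal model.
* **Conversions**: DSBs at `nco_dsb_rate` (default 1.8e-8 per bp, i.e. 0.40
  events per arm), uniform positions, geometric extensions with
  `tract_p = 1/239` (mean one-sided 238 bp, total 476 bp).
* **Observation**: markers are dropped independently (call rate 0.7) and
  called markers flip to the opposite parent with probability 1.2e-5.  The
  flip rate is calibrated so 30 chromatids yield ≈23 isolated false
  conversion candidates — the scale of false positives the study's
  resequencing triage had to remove (82% of its candidates).
* **Reproducibility**: one dataset seed; each chromatid and its observation
  draw use substreams derived deterministically from (seed, progeny index),
  so exports are byte-identical across runs.

What the generator does **not** emulate: read-level sequencing noise,
base-quality models, InDel-specific calling behaviour (marker kind is
carried but unused), heterozygous genotyping, or recombination on
autosomes.  Passing tests on synthetic data therefore demonstrate the
statistical machinery, not robustness to alignment artefacts — the false
calls here are idealized isolated flips, whereas real false candidates
cluster in repetitive regions.

## Detection and triage

`detect_events()` segments each progeny's called markers into maximal
parental runs.  An internal run whose outer-flank extent is at most
`max_gc_extent` (default 10 kb, separating GC from double-CO readings;
observed maximum tracts are ≤ 3.4 kb) becomes a conversion event; all other
run boundaries become crossovers.  Runs with fewer than `min_gc_markers`
(default 2) markers are *triaged*: reported as low-confidence candidates,
reverted to the flanking parent, and excluded from events — the in-silico
stand-in for resequencing verification, since isolated discordant calls are
overwhelmingly false.  Spans overlapping either a detected conversion or a
triaged candidate are excluded from the span histogram entirely: such spans
did not cleanly witness "no conversion".

The triage necessarily discards *true* conversions that cover exactly one
genotyped marker.  This matters for inference: the likelihood treats every
marker-touching conversion as observable, so fitting triaged data
undercounts events relative to the model's expectation and biases
$\hat\lambda$ downward by roughly the fraction of visible events that touch
only one marker (~40% at the default marker density).  In the study this
gap did not exist — every candidate was resolved by resequencing before
fitting, keeping true single-marker events and removing false ones.  The
package's simulation studies of estimator properties (parameter recovery,
profile-CI coverage, LRT calibration in the test suite) therefore use
*verification-equivalent* conditions: 70% marker calling but no false calls
and `min_gc_markers = 1`.  The detection-sensitivity study keeps the full
observation model, because it measures the pipeline rather than the
estimator.  Users fitting real, verified event tables are in the first
regime; users piping raw unverified calls into `gcml()` should expect the
downward bias.

## Resampling tests

* `min_distance_null()` draws sets of uniform integer coordinates (with
  replacement — duplicates allowed, so a minimum distance of 0 is possible)
  and records the minimum adjacent distance per set.  The defaults (15
  events on 14 Mb, the distal region where COs concentrate) reproduce the
  published result that a closest pair within 25 kb is expected about 31%
  of the time; the continuous closed form is
  $1-(1-(n-1)d/L)^n = 0.316$, and the exact expectation of the minimum
  gap is $L/((n-1)(n+1)) = 62.5$ kb (reported in the study, rounded, as
  "approximately 65 kb").
* `interval_placement_null()` re-places the observed spans uniformly and
  independently (overlaps permitted) and compares the aggregate exonic
  fraction; the empirical P uses the plain $\le$ count with no +1
  correction, matching the convention in which 15 of 1000 trials gives
  P = 0.015.
* `word_count_fisher()` builds the 2×2 table of word counts against
  non-overlapping word-length positions ($\lfloor \text{bp}/7\rfloor$) and
  uses the conventional two-sided Fisher exact test (all tables with
  probability at most the observed one).  On the published 25-vs-7
  core-word counts this two-sided P is 0.066; the one-sided P is 0.034.
  The study reports 0.038 for this contrast, which is consistent only with
  a one-sided reading; the package keeps the two-sided default and exposes
  `alternative` for the one-sided variants.

## Motif statistics

The package consumes externally discovered motifs (MEME-minimal text via
`read_meme_motifs()`) and implements the downstream statistics:

* `pwm_scan()` scores every offset and strand with log-odds against the
  motif's background and attaches an **exact** p-value — the tail mass of
  the score distribution under the background, computed by dynamic
  programming over scores discretized to `granularity` (default 1e-4 log2
  units), with scores floored so the discretized tail is conservative.
  Matches are kept when `p_value × width ≤ filter_constant` (default
  0.001).  Published descriptions of this filter sometimes print the
  inequality reversed, which would discard the best matches; the direction
  is configurable (`filter_direction = "ge"`) but defaults to the reading
  that keeps strong matches.
* `flank_enrichment()` runs per-motif Fisher tests of span versus flank
  match densities at several flank widths with Benjamini–Hochberg
  correction within each width; `flank_coordinates()` clips flanks at
  chromosome ends and never overlaps the focal span.
* `metamotif_components()` thresholds a pairwise motif-similarity table at
  `p_value × alignment_length ≤ 0.001` and extracts connected components,
  reporting for each how many distinct discovery runs contributed a member.
* `expected_word_count()` uses pooled nucleotide composition by default
  (per-region available); O/E against composition is the enrichment measure
  for low-complexity words, with zero-expectation compositions flagged
  rather than divided by.
* Core-word counting defaults to the forward strand only, with a
  `both_strands` flag (a palindromic word then counts twice per site, by
  design).

Reproducing the study's chromosome-wide numbers (the 5.9× GTGGAAA
enrichment, the metamotif empirical P of 0.02) requires the real release
5.22 X sequence and the original MEME outputs, which are external data;
the workflow is supported but not packaged.

## Numerical choices and problem sizes

Grid search 60×60 (log-spaced) with Nelder–Mead refinement; profile bounds
by bisection to a tolerance of 2 ln-units ± 1e-3; PWM score discretization
1e-4 with conservative flooring; histograms store distinct span lengths
sparsely.  The simulation studies in the test suite use: 20 datasets of 30
chromatids on the full 93,538-marker map for parameter recovery; 100 such
datasets for profile-CI coverage; 200 datasets on a 1/3-scale arm (31,179
markers on 7.466 Mb, identical marker density) for LRT type-I calibration —
the type-I error of the $\chi^2$ test does not depend on arm length, and
the smaller arm keeps the 200-dataset experiment quick; and 2,000
chromatids for detection sensitivity.  Monte-Carlo oracles for the span and
conformation formulas use 1e6 replicates conditioned on at most one DSB.

## Known limitations

* The per-span likelihood treats spans as independent; a tract near a
  marker interacts with two spans.  This is inherent to the model and
  shared by the analysis it reimplements.
* The likelihood ignores multiple DSBs per span (fine while
  $i\lambda \ll 1$) and does not model conversion tracts at CO sites —
  without reciprocal products there is no information about them.
* `lrt_event_total()` near the search boundary (zero observed conversions)
  returns a boundary-flagged fit whose LRT is conservative.
* The annotation generator produces exponential exon/non-exon segments —
  adequate for calibrating placement tests, not a gene model.
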