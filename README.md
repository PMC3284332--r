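# meiorec

Whole-chromosome analysis of meiotic recombination from dense marker
haplotypes of hemizygous chromatids.

When two isogenic parental lines differ at tens of thousands of SNP/InDel
positions along a chromosome, sequencing individual progeny reads out the
haplotype of each transmitted chromatid directly.  Crossovers (COs) appear
as exchanges of parental identity and are essentially always visible;
noncrossover gene-conversion (GC) tracts appear as short internal blocks of
the opposite parent and are *invisible* whenever they fall entirely between
genotyped markers.  `meiorec` implements the full analysis path for such
data — aimed at recombination geneticists working with whole-genome
sequenced single-meiosis progeny panels:

- a **synthetic meiosis generator** with known CO/GC truth (marker maps,
  distal-biased CO placement with interference, Poisson GC initiation with
  geometric tract extensions, and the observation process: partial marker
  calling plus isolated false calls);
- **event detection**: segmentation of per-progeny calls into parental
  runs, CO/GC classification with flanking-marker bounds, triage of
  single-marker candidates, and the no-conversion span histogram;
- **joint maximum-likelihood inference** of the GC initiation rate λ (per
  bp per chromatid) and geometric tract parameter *p*.  The likelihood

  ln L = Σ<sub>a</sub> N<sub>a</sub> ln P<sub>noGC</sub>(a) + Σ<sub>c</sub> ln P<sub>GC</sub>(c)

  combines every no-conversion inter-marker span (N<sub>a</sub> spans of
  length a ≤ 10 kb) with each observed conversion conformation, so the
  distances between markers correct the rate for conversions that fell
  between them.  Per-span probabilities allow at most one DSB:
  P<sub>noGC</sub>(i) = e<sup>−iλ</sup> + iλe<sup>−iλ</sup> · (1/i) Σ<sub>k</sub> F(k−1)F(i−k),
  with F the geometric CDF of one-sided tract extension (mean (1−p)/p).
  `gcml()` returns a classed fit with `print`, `summary`, `coef`,
  `logLik`, `confint` (profile likelihood, ±2 ln-units), `plot`,
  `predict` and `simulate` methods, plus `lrt_event_total()` for
  likelihood-ratio tests against a constrained total recombination rate
  and `derived_rates()` for genome-wide extrapolations;
- **resampling tests** (CO clustering null, exon-avoidance placement
  null, word-count Fisher contrasts) and **motif statistics** (PWM
  scanning with exact DP p-values, flank enrichment with BH correction,
  metamotif connected components, empirical region-set nulls).

## Worked example

The package ships the event tables of a 30-chromatid whole-X study (15
crossovers, 5 conversions) as plain-text fixtures:

```r
library(meiorec)
s <- summarize_events(xchrom_co_spans(), xchrom_gc_tracts())
#> localized CO spans: n=14, total=12925 bp, mean=923 bp
#> GC maximum tracts: total=8151 bp
#> SCO mean pairwise distance: 4.8 Mb; DCO mean separation: 8.6 Mb
```

The 14 localized crossover spans total 12,925 bp (mean 923 bp); with the
study's 426 exonic bp that is 3.3% exonic sequence against a chromosome
that is 23.7% exonic — crossovers avoid exons.  The five conversion tracts
total 8,151 bp (1,845 exonic bp, 22.6% — conversions do not avoid exons).

Derived rates at the study's joint ML estimates (λ = 1.8e-8, mean
one-sided tract 238 bp):

```r
derived_rates(1.8e-8, 1/239)
#> Derived conversion rates
#>   mean tract: 238 bp one-sided, 476 bp total
#>   per-bp conversion rate: 8.57e-06 per meiosis
#>   events per 2.24e+07-bp arm: 0.403;  per haploid genome (1.19e+08 bp): 2.142
#>   events per meiosis (4 products): 8.57;  GC:CO ratio: 1.71
```

That is: a 476-bp mean tract, a per-nucleotide conversion rate of
0.86 × 10⁻⁵, 0.40 GC events per arm (12 expected across 30 chromatids,
of which the study saw 5 — over half were invisible), 2.14 events per
haploid product, 8.6 per meiosis, and a GC:CO ratio of 1.7.

Are two crossovers 25 kb apart surprising among 15?  No:

```r
min_distance_null(seed = 1)
#> Minimum-distance null: 10000 trials of 15 coordinates on 1.4e+07 bp
#>   mean minimum adjacent distance: 62067 bp
#>   fraction with minimum <= 25000 bp: 0.320
```

End to end on synthetic data — simulate 30 chromatids at the study scale,
detect events, and re-estimate the generating parameters:

```r
map <- generate_marker_map(seed = 7)          # 93,538 markers on 22.4 Mb
sim <- simulate_meiosis(map, meiosis_params(seed = 7, false_call_rate = 0))
ev  <- detect_events(map, sim$calls, min_gc_markers = 1)
fit <- gcml(ev$spans, ev$conversions)
fit
#> Joint ML fit of gene-conversion rate and tract length
#>   data: 1963489 no-conversion spans, 10 conversion events
#>   lambda (DSB rate/bp/chromatid): 2.46e-08
#>   p (cessation): 0.003767;  mean one-sided tract: 264 bp;  total: 529 bp
#>   ln-likelihood: -133.332
signif(confint(fit), 3)
#>               lower    upper
#> lambda     1.21e-08 4.36e-08
#> tract_mean 1.59e+02 4.58e+02
```

Ten of thirteen simulated conversions were detected here; the profile
intervals comfortably cover the generating values (λ = 1.8e-8, one-sided
mean 238 bp).  See the vignette
(`vignettes/recombination-analysis.Rmd`) for the model, its assumptions,
the triage/verification distinction, and all tunable parameters.

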