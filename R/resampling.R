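#' Monte-Carlo null for the closest pair of crossover coordinates
#'
#' Draws `n_trials` sets of `n_events` uniform integer coordinates on
#' `[1, region_length]` (with replacement), sorts each set and records the
#' minimum adjacent difference.  The default emulates testing whether two
#' of 15 crossovers falling within 25 kb of each other on the distal
#' 14 Mb of a chromosome is surprising: under the null it is not (the
#' closed-form continuous approximation gives
#' 1 - (1 - (n-1) d / L)^n, about 0.316 at the defaults).
#'
#' @param n_events Number of coordinates per trial (>= 2).
#' @param region_length Region length in bp.
#' @param n_trials Number of Monte-Carlo trials.
#' @param threshold Distance (bp) defining "close" pairs.
#' @param seed Integer seed.
#' @return A list of class `mc_null`: `n_trials`, `threshold`,
#'   `mean_min_distance`, `fraction_below_threshold` and `min_distances`
#'   (the null distribution, length `n_trials`).
#' @examples
#' r <- min_distance_null(n_trials = 2000, seed = 1)
#' r$fraction_below_threshold
#' @export
min_distance_null <- function(n_events = 15, region_length = 1.4e7,
                              n_trials = 10000, threshold = 25000, seed = 1) {
  stop_if(n_events < 2, "need at least 2 events per trial")
  set.seed(seed)
  draws <- matrix(sample.int(region_length, n_events * n_trials, replace = TRUE),
                  nrow = n_events)
  mins <- apply(draws, 2, function(x) min(diff(sort(x))))
  structure(list(
    n_trials = n_trials, n_events = n_events,
    region_length = region_length, threshold = threshold,
    mean_min_distance = mean(mins),
    fraction_below_threshold = mean(mins <= threshold),
    min_distances = mins
  ), class = "mc_null")
}

#' @export
print.mc_null <- function(x, ...) {
  cat(sprintf("Minimum-distance null: %d trials of %d coordinates on %.3g bp\n",
              x$n_trials, x$n_events, x$region_length))
  cat(sprintf("  mean minimum adjacent distance: %.0f bp\n", x$mean_min_distance))
  cat(sprintf("  fraction with minimum <= %g bp: %.3f\n",
              x$threshold, x$fraction_below_threshold))
  invisible(x)
}

#' Randomization null for the annotation composition of placed intervals
#'
#' Re-places a set of spans uniformly and independently along the
#' chromosome `n_trials` times and computes the aggregate exonic fraction
#' of each random placement, yielding an empirical P-value for the
#' observed fraction; used to test whether crossover spans avoid exons.
#' Spans may overlap each other (independent placement).
#'
#' @param span_lengths Vector of span lengths in bp.
#' @param annotation Annotation data frame (`start`, `end`, `class`), e.g.
#'   from [generate_annotation()].
#' @param chromosome_length Chromosome length in bp.
#' @param n_trials Number of random placements.
#' @param observed_stat Observed exonic fraction; if `NULL`, no empirical
#'   P-value is computed.
#' @param alternative `"avoidance"` counts null placements with fraction
#'   `<=` observed; `"enrichment"` counts `>=`.  No +1 correction is
#'   applied (15 of 1000 trials at or below the observation gives
#'   P = 0.015).
#' @param seed Integer seed.
#' @return A list of class `placement_null` with the `null_stats` vector,
#'   `null_mean`, `observed_stat` and `empirical_P`.
#' @export
interval_placement_null <- function(span_lengths, annotation,
                                    chromosome_length, n_trials = 1000,
                                    observed_stat = NULL,
                                    alternative = c("avoidance", "enrichment"),
                                    seed = 1) {
  alternative <- match.arg(alternative)
  stop_if(any(span_lengths > chromosome_length),
          "span longer than the chromosome")
  stop_if(any(span_lengths < 1), "span lengths must be >= 1")
  set.seed(seed)
  exons <- annotation[annotation$class == "exon", , drop = FALSE]
  cov <- exon_coverage_fn(exons, chromosome_length)
  total_len <- sum(span_lengths)
  nsp <- length(span_lengths)
  null_stats <- vapply(seq_len(n_trials), function(t) {
    start <- floor(runif(nsp, 0, chromosome_length - span_lengths + 1)) + 1
    sum(cov(start + span_lengths - 1) - cov(start - 1)) / total_len
  }, numeric(1))
  emp <- NULL
  if (!is.null(observed_stat)) {
    emp <- if (alternative == "avoidance") mean(null_stats <= observed_stat)
           else mean(null_stats >= observed_stat)
  }
  structure(list(n_trials = n_trials, null_stats = null_stats,
                 null_mean = mean(null_stats), observed_stat = observed_stat,
                 alternative = alternative, empirical_P = emp),
            class = "placement_null")
}

#' @export
print.placement_null <- function(x, ...) {
  cat(sprintf("Placement null: %d trials;  null mean exonic fraction %.3f\n",
              x$n_trials, x$null_mean))
  if (!is.null(x$observed_stat)) {
    cat(sprintf("  observed %.3f;  empirical P (%s) = %.3g\n",
                x$observed_stat, x$alternative, x$empirical_P))
  }
  invisible(x)
}

# cumulative exonic coverage C(x) = exonic bp in [1, x], as a fast
# vectorized closure over the merged exon intervals
exon_coverage_fn <- function(exons, chromosome_length) {
  if (nrow(exons) == 0) return(function(x) numeric(length(x)))
  m <- IRanges::reduce(IRanges::IRanges(start = exons$start, end = exons$end))
  s <- BiocGenerics::start(m); e <- BiocGenerics::end(m)
  cum <- c(0, cumsum(e - s + 1))
  function(x) {
    x <- pmax(pmin(x, chromosome_length), 0)
    j <- findInterval(x, s)
    inside <- j >= 1 & x <= ifelse(j >= 1, e[pmax(j, 1)], 0)
    cum[j + 1] - ifelse(inside, e[pmax(j, 1)] - x, 0)
  }
}

#' Fisher test contrasting word counts between two sequence sets
#'
#' Compares occurrence counts of a fixed-length word between two pooled
#' sequence sets (for example crossover spans versus conversion tracts) by
#' a Fisher exact test on the 2x2 table of counts against the number of
#' non-overlapping word-length positions, `floor(length / word_length)`,
#' in each set.
#'
#' @param count_a,count_b Occurrence counts in the two sets.
#' @param length_a,length_b Total sequence lengths (bp) of the two sets.
#' @param word_length Word length in bp.
#' @param alternative Passed to [stats::fisher.test()]; the default
#'   two-sided P sums all tables with probability at most the observed
#'   table's.
#' @return A list with the 2x2 `table`, `p.value` and `estimate` (odds
#'   ratio).
#' @examples
#' word_count_fisher(25, 12925, 7, 8151)$p.value
#' @export
word_count_fisher <- function(count_a, length_a, count_b, length_b,
                              word_length = 7, alternative = "two.sided") {
  stop_if(any(c(count_a, count_b, length_a, length_b) < 0), "negative input")
  na <- floor(length_a / word_length)
  nb <- floor(length_b / word_length)
  stop_if(count_a > na || count_b > nb,
          "counts exceed the number of non-overlapping positions")
  tab <- matrix(c(count_a, na - count_a, count_b, nb - count_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("a", "b"), c("word", "other")))
  ft <- fisher.test(tab, alternative = alternative)
  list(table = tab, p.value = ft$p.value, estimate = unname(ft$estimate),
       alternative = alternative)
}

#' Pairwise-distance summaries of crossover events
#'
#' Computes the mean pairwise distance between the midpoints of
#' single-crossover events (one per SCO chromatid) and, for each
#' double-crossover chromatid, the separation between its two event
#' midpoints, with their mean.
#'
#' @param crossovers Crossover data frame with `progeny_id`,
#'   `distal_flank_pos`, `proximal_flank_pos` and `co_class` columns.
#' @return A list with `sco_mean_pairwise_distance`, `dco_separations`
#'   (named by chromatid), `dco_mean_separation`, and an `undefined`
#'   character vector naming fields that needed at least two events.
#' @export
pairwise_distance_summary <- function(crossovers) {
  mid <- (crossovers$distal_flank_pos + crossovers$proximal_flank_pos) / 2
  undefined <- character(0)
  sco_mid <- mid[crossovers$co_class %in% "SCO"]
  sco_mean <- if (length(sco_mid) >= 2) mean(dist(sco_mid)) else {
    undefined <- c(undefined, "sco_mean_pairwise_distance"); NA_real_
  }
  dco <- crossovers[crossovers$co_class %in% "DCO", , drop = FALSE]
  seps <- numeric(0)
  if (nrow(dco)) {
    seps <- vapply(split(mid[crossovers$co_class %in% "DCO"], dco$progeny_id),
                   function(m) if (length(m) == 2) abs(diff(m)) else NA_real_,
                   numeric(1))
    seps <- seps[!is.na(seps)]
  }
  dco_mean <- if (length(seps)) mean(seps) else {
    undefined <- c(undefined, "dco_mean_separation"); NA_real_
  }
  list(sco_mean_pairwise_distance = sco_mean,
       dco_separations = seps,
       dco_mean_separation = dco_mean,
       undefined = undefined)
}
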