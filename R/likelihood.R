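#' Geometric conversion-tract extension distribution
#'
#' A conversion tract extends from the initiating double-strand break
#' independently leftward and rightward; each one-sided extension length L
#' follows a geometric distribution with cessation probability `p`:
#' P(L) = (1 - p)^L p, mean (1 - p) / p.  `tract_cdf` gives
#' P(extension <= L) = 1 - (1 - p)^(L + 1); the probability of an extension
#' in a range is a difference of two CDF values.
#'
#' @param L Non-negative integer extension length(s) in bp.
#' @param p Cessation probability in (0, 1].
#' @return Probabilities, vectorized over `L`.
#' @examples
#' sum(0:1e5 * tract_pmf(0:1e5, 0.1))  # mean = (1 - p)/p = 9
#' @export
tract_pmf <- function(L, p) {
  stop_if(any(L < 0), "L must be >= 0")
  stop_if(p <= 0 || p > 1, "p must be in (0, 1]")
  (1 - p)^L * p
}

#' @rdname tract_pmf
#' @export
tract_cdf <- function(L, p) {
  stop_if(any(L < 0), "L must be >= 0")
  stop_if(p <= 0 || p > 1, "p must be in (0, 1]")
  1 - (1 - p)^(L + 1)
}

#' Probability that a span witnesses no conversion
#'
#' For a span of `i` bp between adjacent called markers, the model allows at
#' most one DSB (the 0- and 1-DSB terms of the Poisson at rate
#' `lambda` per bp) and requires any tract to stop short of both flanking
#' markers.  The DSB ordinate k runs over the `i` positions within the
#' span, at distances k and i - k + 1 from the distal and proximal flanks,
#' so
#' \deqn{P = e^{-i\lambda} + i\lambda e^{-i\lambda}\frac{1}{i}
#'   \sum_{k=1}^{i} F(k-1)\,F(i-k)}
#' with F the geometric extension CDF.  The sum has the closed form
#' \eqn{i - 2q(1-q^i)/(1-q) + i q^{i+1}} with q = 1 - p, so evaluation is
#' O(1) per span length.  Probabilities are not renormalized over the
#' dropped 2+-DSB terms.
#'
#' @param i Span length(s) in bp, >= 1.
#' @param lambda DSB rate per bp per chromatid.
#' @param p Geometric cessation probability.
#' @param log Return the log probability.
#' @return Probability (or log probability), vectorized over `i`.
#' @export
p_no_gc_span <- function(i, lambda, p, log = FALSE) {
  stop_if(any(i < 1), "span length i must be >= 1")
  stop_if(lambda < 0, "lambda must be >= 0")
  stop_if(p < 0 || p > 1, "p must be in [0, 1]")
  q <- 1 - p
  S <- if (q == 0) {
    i
  } else if (q == 1) {
    rep(0, length(i))
  } else {
    i - 2 * q * (1 - q^i) / (1 - q) + i * q^(i + 1)
  }
  lp <- -i * lambda + log1p(lambda * S)
  if (log) lp else exp(lp)
}

#' Observed gene-conversion conformations
#'
#' A conformation records what detection actually sees of a conversion
#' event: the span `i` between the nearest non-converted flanking markers,
#' and the offsets of the outermost converted markers from those flanks
#' (`left_offset` = first converted minus distal flank, `right_offset` =
#' proximal flank minus last converted).
#'
#' @param span Span(s) i between outer non-converted flanks, bp.
#' @param left_offset,right_offset Offsets in bp, >= 1, with
#'   `left_offset + right_offset <= span`.
#' @return A data frame of class `gc_conformation`.
#' @seealso [as_conformations()] to build one from a detection result.
#' @export
gc_conformation <- function(span, left_offset, right_offset) {
  df <- data.frame(span = as.numeric(span),
                   left_offset = as.numeric(left_offset),
                   right_offset = as.numeric(right_offset))
  stop_if(any(df$left_offset < 1 | df$right_offset < 1),
          "offsets must be >= 1 (flanking markers are not converted)")
  stop_if(any(df$left_offset + df$right_offset > df$span),
          "offsets leave no converted site inside the span")
  class(df) <- c("gc_conformation", "data.frame")
  df
}

#' @rdname gc_conformation
#' @param conversions Conversion-event data frame from [detect_events()] or
#'   [xchrom_gc_tracts()].
#' @export
as_conformations <- function(conversions) {
  gc_conformation(
    span = conversions$max_tract,
    left_offset = conversions$first_converted_pos - conversions$distal_flank_pos,
    right_offset = conversions$proximal_flank_pos - conversions$last_converted_pos
  )
}

#' Probability of an observed conversion conformation
#'
#' For a single DSB somewhere within the span, summed over all ordinates k,
#' the leftward tract must cover every converted marker left of the break
#' but stop short of the distal flank (and symmetrically rightward):
#' \deqn{P = i\lambda e^{-i\lambda}\frac{1}{i}\sum_{k=1}^{i}
#'   [F(\mathrm{maxL}_k) - F(\mathrm{minL}_k - 1)]
#'   [F(\mathrm{maxR}_k) - F(\mathrm{minR}_k - 1)]}
#' where for ordinate k (between nucleotides k - 1 and k of the span) the
#' maximum allowed extensions are k - 1 leftward and i - k rightward and
#' the minimum required extensions reach the outermost converted markers
#' on each side (0 when none lies on that side).
#'
#' @param conf A [gc_conformation()] (one or more rows).
#' @param lambda DSB rate per bp per chromatid.
#' @param p Geometric cessation probability.
#' @param log Return log probabilities.
#' @return Probability per conformation row.
#' @export
p_gc_conformation <- function(conf, lambda, p, log = FALSE) {
  stop_if(!inherits(conf, "gc_conformation"), "conf must be a gc_conformation")
  stop_if(lambda < 0, "lambda must be >= 0")
  stop_if(p <= 0 || p > 1, "p must be in (0, 1]")
  q <- 1 - p
  out <- vapply(seq_len(nrow(conf)), function(r) {
    i <- conf$span[r]
    a <- conf$left_offset[r]          # first converted marker offset
    e <- i - conf$right_offset[r]     # last converted marker offset
    k <- seq_len(i)
    minL <- pmax(0, k - a)
    minR <- pmax(0, e - k + 1)
    PL <- geom_cdf0(k - 1, q) - ifelse(minL > 0, geom_cdf0(minL - 1, q), 0)
    PR <- geom_cdf0(i - k, q) - ifelse(minR > 0, geom_cdf0(minR - 1, q), 0)
    s <- sum(PL * PR)
    if (s <= 0 || lambda == 0) -Inf else log(lambda) - i * lambda + log(s)
  }, numeric(1))
  if (log) out else exp(out)
}

# geometric extension CDF, F(x) = 1 - q^(x+1) for x >= 0
geom_cdf0 <- function(x, q) 1 - q^(x + 1)

#' Joint log-likelihood of spans and conformations
#'
#' The data factorize into the histogram of no-conversion spans (counts
#' N_a of spans of each length a) and the list of observed conversion
#' conformations:
#' \deqn{\ln L = \sum_a N_a \ln P_{\mathrm{noGC}}(a) +
#'   \sum_c \ln P_{\mathrm{GC}}(c).}
#' Spans of equal length share one evaluation.
#'
#' @param spans A [span_histogram()] or data frame with `length` and
#'   `count` columns.
#' @param conformations A [gc_conformation()] data frame (may have zero
#'   rows).
#' @param lambda,p Model parameters.
#' @return The log-likelihood; `-Inf` (with attribute `degenerate = TRUE`)
#'   if any component probability underflows to zero against a positive
#'   count.
#' @export
gc_loglik <- function(spans, conformations = NULL, lambda, p) {
  counts <- if (inherits(spans, "span_histogram")) spans$counts else spans
  ll <- 0
  if (!is.null(counts) && nrow(counts)) {
    lp <- p_no_gc_span(counts$length, lambda, p, log = TRUE)
    ll <- sum(counts$count * lp)
  }
  if (!is.null(conformations) && nrow(conformations)) {
    ll <- ll + sum(p_gc_conformation(conformations, lambda, p, log = TRUE))
  }
  if (!is.finite(ll)) {
    ll <- -Inf
    attr(ll, "degenerate") <- TRUE
  }
  ll
}
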