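# Independent oracles used across the suite.  Each one re-derives a
# quantity by brute force or direct simulation, never by calling the code
# path it checks.

# Monte-Carlo estimate of the span / conformation probabilities of the
# truncated one-DSB model, conditioned on <= 1 DSB and rescaled back to the
# unconditional (truncated, unnormalized) probability.  Shares the package's
# coordinate convention: DSB at interstice k in 1..i, a nucleotide at offset
# m is converted iff (m <= k-1 and left >= k-m) or (m >= k and
# right >= m-k+1); the distal flank sits at distance k, the proximal at
# i-k+1.  Returns the estimate and its Monte-Carlo standard error.
mc_span_oracle <- function(i, lambda, p, conf = NULL, nrep = 1e6, seed = 42) {
  set.seed(seed)
  mass <- exp(-i * lambda) * c(1, i * lambda)
  N <- sample(0:1, nrep, replace = TRUE, prob = mass / sum(mass))
  k <- sample.int(i, nrep, replace = TRUE)
  l <- rgeom(nrep, p)
  r <- rgeom(nrep, p)
  flank_safe <- l <= k - 1 & r <= i - k
  hit <- if (is.null(conf)) {
    N == 0 | (N == 1 & flank_safe)
  } else {
    a <- conf$left_offset
    e <- i - conf$right_offset
    covers <- (a >= k | l >= k - a) & (e < k | r >= e - k + 1)
    N == 1 & flank_safe & covers
  }
  ph <- mean(hit)
  scale <- sum(mass)
  list(estimate = ph * scale, se = sqrt(ph * (1 - ph) / nrep) * scale)
}

# brute-force overlapping word count by position-by-position comparison
brute_word_count <- function(seqs, word) {
  w <- nchar(word)
  sum(vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < w) return(0L)
    sum(vapply(seq_len(n - w + 1), function(o)
      substr(s, o, o + w - 1) == word, logical(1)))
  }, integer(1)))
}

# union-find connected components over an edge list of character ids
union_find_components <- function(vertices, edges_a, edges_b) {
  parent <- setNames(vertices, vertices)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(vertices, find, character(1))
  split(vertices, roots)
}

# Benjamini-Hochberg step-up by the direct formula
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# two-sided Fisher P by explicit hypergeometric summation over all tables
# with the observed margins
fisher_oracle <- function(x11, x12, x21, x22) {
  m <- x11 + x12            # row 1 total
  n <- x21 + x22            # row 2 total
  k <- x11 + x21            # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(x11, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# fraction of true GC events recovered by detection, given truths and the
# detected conversion table
match_sensitivity <- function(truths, conversions) {
  tot <- 0L; det <- 0L
  for (truth in truths) {
    g <- truth$gc_events
    conv <- conversions[conversions$progeny_id == truth$progeny_id, , drop = FALSE]
    tot <- tot + nrow(g)
    for (i in seq_len(nrow(g))) {
      lo <- g$dsb[i] - g$left[i]
      hi <- g$dsb[i] + g$right[i]
      det <- det + any(conv$first_converted_pos >= lo &
                         conv$last_converted_pos <= hi)
    }
  }
  c(detected = det, total = tot)
}

# small dense marker map shared by detection tests
tiny_map <- function(n = 2000, L = 1e6, seed = 99) {
  generate_marker_map(n, L, clustering = 0, seed = seed)
}
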