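#' Position weight matrix constructor
#'
#' @param motif_id Motif identifier.
#' @param probs 4 x W matrix of per-position base probabilities with rows
#'   A, C, G, T; every column must sum to 1 (tolerance 1e-9).
#' @param background Background base frequencies (A, C, G, T).
#' @return An object of class `pwm_motif`.
#' @export
pwm_motif <- function(motif_id, probs, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  stop_if(nrow(probs) != 4, "probs must have 4 rows (A, C, G, T)")
  stop_if(ncol(probs) < 1, "motif width must be >= 1")
  stop_if(any(abs(colSums(probs) - 1) > 1e-9), "columns must sum to 1")
  stop_if(abs(sum(background) - 1) > 1e-9, "background must sum to 1")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, probs = probs,
                 width = ncol(probs), background = background),
            class = "pwm_motif")
}

#' @export
print.pwm_motif <- function(x, ...) {
  consensus <- paste(rownames(x$probs)[apply(x$probs, 2, which.max)],
                     collapse = "")
  cat(sprintf("PWM %s: width %d, consensus %s\n", x$motif_id, x$width, consensus))
  invisible(x)
}

#' Read motifs in MEME minimal text format
#'
#' Parses the minimal motif format (`MEME version`, optional background
#' frequency line, and per-motif `letter-probability matrix` blocks) used
#' to exchange discovered motifs between motif tools.
#'
#' @param path File path.
#' @return A list of [pwm_motif()] objects.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)][1:4]
  }
  motif_at <- grep("^MOTIF\\b", lines)
  lapply(seq_along(motif_at), function(m) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[motif_at[m]])), "\\s+")[[1]][1]
    hdr <- grep("letter-probability matrix", lines)
    hdr <- hdr[hdr > motif_at[m]][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    probs <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    # rows of the file are positions; renormalize tiny rounding drift
    probs <- probs / rowSums(probs)
    pwm_motif(id, t(probs), bg)
  })
}

as_dss <- function(regions) {
  if (inherits(regions, "DNAStringSet")) return(regions)
  x <- Biostrings::DNAStringSet(toupper(as.character(regions)))
  if (is.null(names(x))) names(x) <- paste0("region", seq_along(x))
  x
}

#' Count occurrences of a word in sequence regions
#'
#' Counts overlapping occurrences by sliding window; with
#' `both_strands = TRUE` reverse-complement occurrences are added (a
#' palindromic word is then counted twice per site).
#'
#' @param regions `DNAStringSet` or character vector of DNA sequences.
#' @param word DNA word (A/C/G/T).
#' @param both_strands Also count the reverse complement.
#' @return A list with `per_region` (named integer vector) and `total`.
#' @examples
#' count_words(c("GTGGAAATTGTGGAAA", "AAAA"), "GTGGAAA")$total
#' @export
count_words <- function(regions, word, both_strands = FALSE) {
  stop_if(nchar(word) < 1 || grepl("[^ACGT]", toupper(word)),
          "word must be a non-empty A/C/G/T string")
  dss <- as_dss(regions)
  word <- toupper(word)
  n <- Biostrings::vcountPattern(word, dss)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(word)))
    n <- n + Biostrings::vcountPattern(rc, dss)
  }
  names(n) <- names(dss)
  list(per_region = n, total = sum(n))
}

#' Expected word count from nucleotide composition
#'
#' The expectation for a width-w word is the number of window positions
#' times the product of the letter frequencies of the word under the
#' region composition (pooled across regions by default, or per region),
#' giving the observed/expected enrichment ratio used to judge low-
#' complexity motifs.
#'
#' @param regions `DNAStringSet` or character vector.
#' @param word DNA word.
#' @param composition `"pooled"` (one composition across all regions) or
#'   `"per_region"`.
#' @return A list with `observed`, `expected`, `oe_ratio` (`NA` with
#'   `undefined = TRUE` when the expectation is 0) and the composition
#'   used.
#' @export
expected_word_count <- function(regions, word,
                                composition = c("pooled", "per_region")) {
  composition <- match.arg(composition)
  dss <- as_dss(regions)
  stop_if(length(dss) == 0, "regions must be non-empty")
  word <- toupper(word)
  w <- nchar(word)
  letters_w <- strsplit(word, "")[[1]]
  freq <- Biostrings::letterFrequency(dss, c("A", "C", "G", "T"))
  widths <- Biostrings::width(dss)
  if (composition == "pooled") {
    f <- colSums(freq) / sum(colSums(freq))
    per_window <- prod(f[letters_w])
    expected <- sum(pmax(widths - w + 1, 0)) * per_window
  } else {
    f <- freq / pmax(rowSums(freq), 1)
    per_window <- apply(f, 1, function(fr) prod(fr[letters_w]))
    expected <- sum(pmax(widths - w + 1, 0) * per_window)
  }
  observed <- count_words(dss, word)$total
  if (expected <= 0) {
    return(list(observed = observed, expected = 0, oe_ratio = NA_real_,
                undefined = TRUE, composition = composition))
  }
  list(observed = observed, expected = expected,
       oe_ratio = observed / expected, undefined = FALSE,
       composition = composition)
}

# integer score matrix and exact tail p-values of the PWM log-odds score
# under the background, by dynamic programming over discretized scores.
# Cells with probability 0 score -Inf (encoded NA); their background mass
# falls below every finite score and is excluded from finite tails.
pwm_score_table <- function(pwm, granularity = 1e-4) {
  lo <- log2(pwm$probs / pwm$background)
  S <- matrix(NA_integer_, 4, pwm$width)
  finite <- is.finite(lo)
  S[finite] <- as.integer(floor(lo[finite] / granularity))
  S
}

pwm_pvalue_fn <- function(pwm, granularity = 1e-4) {
  S <- pwm_score_table(pwm, granularity)
  bg <- pwm$background
  mins <- apply(S, 2, min, na.rm = TRUE)
  maxs <- apply(S, 2, max, na.rm = TRUE)
  offset <- sum(mins)           # smallest achievable finite sum
  span <- sum(maxs - mins)
  dp <- numeric(span + 1)
  dp[1] <- 1
  base <- 0                      # dp[i] = P(sum == offset_partial + i - 1)
  for (j in seq_len(pwm$width)) {
    new <- numeric(span + 1)
    for (b in 1:4) {
      if (is.na(S[b, j])) next   # -Inf path, excluded from finite mass
      sh <- S[b, j] - mins[j]
      idx <- seq_len(span + 1 - sh)
      new[idx + sh] <- new[idx + sh] + bg[b] * dp[idx]
    }
    dp <- new
  }
  tail_p <- rev(cumsum(rev(dp)))
  function(score_int) {
    i <- score_int - offset + 1
    ifelse(is.na(score_int), 1,
           ifelse(i < 1, 1, ifelse(i > length(tail_p), 0, tail_p[pmax(i, 1)])))
  }
}

#' Scan regions with a position weight matrix
#'
#' Scores every offset (both strands by default) with the log-odds of the
#' PWM against its background, attaches an exact P-value (the tail mass of
#' the score distribution under the background, computed by dynamic
#' programming over scores discretized to `granularity`, rounding scores
#' down so tails are conservative), and keeps matches whose
#' `p_value * width` passes `filter_constant`.  The filter direction
#' defaults to `<=`; the opposite direction is available because published
#' descriptions of this filter sometimes print it reversed.
#'
#' @param regions `DNAStringSet` or character vector.
#' @param pwm A [pwm_motif()].
#' @param filter_constant Threshold on `p_value * width`; 0 keeps nothing
#'   under the default direction.
#' @param granularity Score discretization step (log2 units).
#' @param filter_direction `"le"` keeps `p * width <= filter_constant`;
#'   `"ge"` keeps `>=`.
#' @param both_strands Scan the reverse strand too.
#' @return A data frame of matches: `motif_id`, `region_id`, `offset`
#'   (1-based start in the region on the forward strand), `strand`,
#'   `score` (log2 odds) and `p_value`.
#' @export
pwm_scan <- function(regions, pwm, filter_constant = 0.001,
                     granularity = 1e-4, filter_direction = c("le", "ge"),
                     both_strands = TRUE) {
  filter_direction <- match.arg(filter_direction)
  stop_if(!inherits(pwm, "pwm_motif"), "pwm must be a pwm_motif")
  dss <- as_dss(regions)
  S <- pwm_score_table(pwm, granularity)
  pval <- pwm_pvalue_fn(pwm, granularity)
  w <- pwm$width
  scan_one <- function(seqchar) {
    n <- nchar(seqchar)
    if (n < w) return(NULL)
    idx <- match(strsplit(seqchar, "")[[1]], c("A", "C", "G", "T"))
    total <- rep(0L, n - w + 1)
    bad <- rep(FALSE, n - w + 1)
    for (j in seq_len(w)) {
      cell <- S[cbind(idx[j:(j + n - w)], j)]
      bad <- bad | is.na(cell)
      total <- total + ifelse(is.na(cell), 0L, cell)
    }
    total[bad] <- NA_integer_
    total
  }
  out <- lapply(seq_along(dss), function(r) {
    fwd <- as.character(dss[r])
    res <- list()
    sc <- scan_one(fwd)
    if (!is.null(sc)) {
      res$fwd <- data.frame(offset = seq_along(sc), strand = "+",
                            score_int = sc, stringsAsFactors = FALSE)
    }
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(dss[[r]]))
      sc2 <- scan_one(rc)
      if (!is.null(sc2)) {
        n <- nchar(fwd)
        res$rev <- data.frame(offset = n - w + 2 - seq_along(sc2) - 0L,
                              strand = "-", score_int = sc2,
                              stringsAsFactors = FALSE)
      }
    }
    if (!length(res)) return(NULL)
    df <- do.call(rbind, res)
    df$region_id <- names(dss)[r]
    df
  })
  df <- do.call(rbind, out)
  if (is.null(df) || !nrow(df)) return(empty_match_df(pwm$motif_id))
  df$p_value <- pval(df$score_int)
  keep <- if (filter_direction == "le") df$p_value * w <= filter_constant
          else df$p_value * w >= filter_constant
  keep <- keep & !is.na(df$score_int)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) return(empty_match_df())
  data.frame(motif_id = pwm$motif_id, region_id = df$region_id,
             offset = df$offset, strand = df$strand,
             score = df$score_int * granularity, p_value = df$p_value,
             row.names = NULL, stringsAsFactors = FALSE)
}

empty_match_df <- function(motif_id = character(0)) {
  data.frame(motif_id = character(0), region_id = character(0),
             offset = integer(0), strand = character(0), score = numeric(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}

#' Flanking sequence coordinates for a set of spans
#'
#' For each span and flank width, returns the left and right flanking
#' intervals immediately outside the span, clipped at the chromosome ends;
#' flanks never overlap their focal span.
#'
#' @param spans Data frame with `start`, `end` (1-based inclusive) and
#'   optionally `region_id`.
#' @param widths Flank widths in bp.
#' @param chromosome_length Chromosome length for clipping.
#' @return Data frame with `region_id`, `width`, `side`, `start`, `end`;
#'   flanks clipped to nothing are dropped (with a warning).
#' @export
flank_coordinates <- function(spans, widths = c(1000, 5000, 10000),
                              chromosome_length) {
  ids <- spans$region_id %||% paste0("region", seq_len(nrow(spans)))
  out <- do.call(rbind, lapply(widths, function(w) {
    left <- data.frame(region_id = ids, width = w, side = "left",
                       start = pmax(spans$start - w, 1),
                       end = spans$start - 1, stringsAsFactors = FALSE)
    right <- data.frame(region_id = ids, width = w, side = "right",
                        start = spans$end + 1,
                        end = pmin(spans$end + w, chromosome_length),
                        stringsAsFactors = FALSE)
    rbind(left, right)
  }))
  empty <- out$end < out$start
  if (any(empty)) {
    warning(sum(empty), " flank(s) clipped to zero length and dropped")
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Motif enrichment in spans versus flanking sequence
#'
#' For each motif and flank width, a Fisher exact test compares match
#' counts between the pooled spans and the pooled flanks of that width,
#' with totals given by the number of non-overlapping match-width
#' positions; P-values are Benjamini-Hochberg adjusted across motifs
#' within each flank width.
#'
#' @param span_counts Named vector of match counts per motif in the spans.
#' @param span_length Total span length in bp.
#' @param flank_counts Matrix of match counts, motifs x flank widths
#'   (columns named by width).
#' @param flank_lengths Vector of total flank lengths per width.
#' @param width Match width in bp (vector per motif or scalar).
#' @param alpha Significance level applied to adjusted P-values.
#' @return Data frame with one row per motif and flank width: `motif`,
#'   `flank`, `p`, `p_adj`, `direction` (`"over"`/`"under"`) and
#'   `significant`.
#' @export
flank_enrichment <- function(span_counts, span_length, flank_counts,
                             flank_lengths, width = 7, alpha = 0.05) {
  flank_counts <- as.matrix(flank_counts)
  stop_if(length(span_counts) != nrow(flank_counts),
          "span_counts and flank_counts disagree on the number of motifs")
  stop_if(ncol(flank_counts) != length(flank_lengths),
          "flank_counts and flank_lengths disagree on the number of widths")
  motifs <- names(span_counts) %||% paste0("motif", seq_along(span_counts))
  width <- rep_len(width, length(span_counts))
  out <- do.call(rbind, lapply(seq_len(ncol(flank_counts)), function(fw) {
    p <- numeric(length(motifs)); dir <- character(length(motifs))
    for (m in seq_along(motifs)) {
      ft <- word_count_fisher(span_counts[m], span_length,
                              flank_counts[m, fw], flank_lengths[fw],
                              word_length = width[m])
      p[m] <- ft$p.value
      dens_span <- span_counts[m] / span_length
      dens_flank <- flank_counts[m, fw] / flank_lengths[fw]
      dir[m] <- if (dens_span >= dens_flank) "over" else "under"
    }
    data.frame(motif = motifs,
               flank = colnames(flank_counts)[fw] %||% as.character(fw),
               p = p, p_adj = p.adjust(p, method = "BH"),
               direction = dir, stringsAsFactors = FALSE)
  }))
  out$significant <- out$p_adj <= alpha
  rownames(out) <- NULL
  out
}

#' Metamotif clustering of a motif similarity matrix
#'
#' Motifs discovered across repeated runs are merged into "metamotifs":
#' connected components of the graph whose edges join motif pairs with
#' alignment `p_value * aln_length` at or below `threshold_constant`.
#' Components are ranked by size, and each reports how many distinct
#' discovery runs contributed a member, the statistic used to judge
#' whether a metamotif is found robustly.
#'
#' @param similarity Data frame with `motif_a`, `motif_b`, `p_value`,
#'   `aln_length` (undirected; a pair listed in both orders must agree),
#'   or a symmetric numeric matrix of `p_value * aln_length` products.
#' @param threshold_constant Edge threshold.
#' @param motifs Optional complete motif list, so motifs without any
#'   similar partner appear as singleton components.
#' @param runs Optional named vector mapping motif id to discovery run id;
#'   defaults to the prefix of the motif id before the last `.`.
#' @return A list of class `metamotifs`: `components` (list of motif-id
#'   vectors, largest first) and `summary` (data frame with `component`,
#'   `size`, `n_runs`).
#' @export
metamotif_components <- function(similarity, threshold_constant = 0.001,
                                 motifs = NULL, runs = NULL) {
  if (is.matrix(similarity)) {
    stop_if(!isSymmetric(unname(similarity)), "similarity matrix must be symmetric")
    ids <- rownames(similarity) %||% paste0("motif", seq_len(nrow(similarity)))
    idx <- which(similarity <= threshold_constant & upper.tri(similarity),
                 arr.ind = TRUE)
    edges <- data.frame(motif_a = ids[idx[, 1]], motif_b = ids[idx[, 2]],
                        stringsAsFactors = FALSE)
    motifs <- motifs %||% ids
  } else {
    sim <- similarity
    key <- paste(pmin(sim$motif_a, sim$motif_b), pmax(sim$motif_a, sim$motif_b))
    prod <- sim$p_value * sim$aln_length
    agree <- tapply(prod, key, function(v) max(v) - min(v) < 1e-12)
    stop_if(!all(agree), "similarity table is asymmetric")
    hit <- prod <= threshold_constant & sim$motif_a != sim$motif_b
    edges <- data.frame(motif_a = sim$motif_a[hit], motif_b = sim$motif_b[hit],
                        stringsAsFactors = FALSE)
    motifs <- motifs %||% unique(c(sim$motif_a, sim$motif_b))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = motifs))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  names(groups) <- paste0("MM", seq_along(groups))
  run_of <- function(m) {
    if (!is.null(runs)) return(unname(runs[m]))
    sub("\\.[^.]*$", "", m)
  }
  summary <- data.frame(
    component = names(groups),
    size = vapply(groups, length, integer(1)),
    n_runs = vapply(groups, function(g) length(unique(run_of(g))), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(components = groups, summary = summary), class = "metamotifs")
}

#' @export
print.metamotifs <- function(x, ...) {
  cat(sprintf("Metamotifs: %d components from %d motifs\n",
              nrow(x$summary), sum(x$summary$size)))
  print(head(x$summary, 10))
  invisible(x)
}

#' Empirical null over random region sets
#'
#' Repeats a region-set statistic on `n_sets` random sets of regions drawn
#' from a chromosome sequence with the same size distribution as the
#' observed set, and reports the fraction of null sets with statistic at
#' least as large as the observed one.
#'
#' @param stat_fn Function taking a `DNAStringSet` and returning a scalar.
#' @param regions Observed regions (`DNAStringSet` or character).
#' @param chromosome_seq Source sequence (`DNAString` or character).
#' @param n_sets Number of random sets.
#' @param seed Integer seed.
#' @return A list with `observed`, `null_stats` and `empirical_P`.
#' @export
empirical_region_null <- function(stat_fn, regions, chromosome_seq,
                                  n_sets = 100, seed = 1) {
  dss <- as_dss(regions)
  chrom <- if (inherits(chromosome_seq, "DNAString")) chromosome_seq
           else Biostrings::DNAString(toupper(as.character(chromosome_seq)))
  L <- length(chrom)
  lens <- Biostrings::width(dss)
  stop_if(any(lens > L), "region longer than the source sequence")
  observed <- stat_fn(dss)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_sets), function(s) {
    starts <- floor(runif(length(lens), 0, L - lens + 1)) + 1
    rand <- Biostrings::DNAStringSet(lapply(seq_along(lens), function(i)
      Biostrings::subseq(chrom, starts[i], width = lens[i])))
    names(rand) <- names(dss)
    stat_fn(rand)
  }, numeric(1))
  list(observed = observed, null_stats = null_stats,
       empirical_P = mean(null_stats >= observed))
}

#' Random DNA sequence
#'
#' Convenience generator for synthetic chromosomes and test fixtures.
#'
#' @param n Sequence length.
#' @param gc GC content.
#' @param seed Integer seed.
#' @return A `DNAString`.
#' @export
random_dna <- function(n, gc = 0.5, seed = 1) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  Biostrings::DNAString(paste(sample(names(p), n, replace = TRUE, prob = p),
                              collapse = ""))
}
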