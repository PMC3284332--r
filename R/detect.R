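#' Segment a call vector into parental haplotype runs
#'
#' Missing calls are ignored; maximal runs of identical parental origin over
#' the called markers are returned in positional order.
#'
#' @param calls An `observed_calls` object or a character vector of
#'   `"P1"`/`"P2"`/`NA` calls.
#' @return A data frame with one row per run: `start_idx`/`end_idx` (indices
#'   into the full marker vector), `parent` and `n_markers` (number of
#'   called markers in the run).
#' @export
segment_haplotype <- function(calls) {
  v <- if (inherits(calls, "observed_calls")) calls$calls else calls
  idx <- which(!is.na(v))
  stop_if(length(idx) == 0, "all calls are missing")
  r <- rle(v[idx])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    start_idx = idx[starts],
    end_idx = idx[ends],
    parent = r$values,
    n_markers = r$lengths,
    stringsAsFactors = FALSE
  )
}

empty_co_df <- function() {
  data.frame(progeny_id = character(0), distal_flank_pos = numeric(0),
              proximal_flank_pos = numeric(0), span = numeric(0),
              co_class = character(0), stringsAsFactors = FALSE)
}

empty_gc_df <- function() {
  data.frame(progeny_id = character(0), distal_flank_pos = numeric(0),
              first_converted_pos = numeric(0), last_converted_pos = numeric(0),
              proximal_flank_pos = numeric(0), n_converted = integer(0),
              min_tract = numeric(0), max_tract = numeric(0),
              donor_parent = character(0), stringsAsFactors = FALSE)
}

#' Classify crossover and gene-conversion events from haplotype runs
#'
#' An internal run flanked on both sides by the opposite parent whose
#' outer-flank extent (distance between nearest non-converted called
#' markers) is at most `max_gc_extent` is a gene-conversion event; any other
#' boundary between runs is a crossover, with flanks taken from the
#' adjacent called markers.  Runs with fewer than `min_gc_markers` markers
#' are not trusted as events: they are emitted as low-confidence candidates
#' and their calls are reverted to the flanking parent before crossover
#' calling, the in-silico analogue of the Sanger triage that sequencing
#' studies apply to candidate conversions (isolated discordant calls are
#' overwhelmingly false positives).  Chromatids are labelled SCO/DCO by
#' their final crossover count.
#'
#' @param calls An `observed_calls` object (or character vector).
#' @param map The [marker_map()] the calls are indexed against.
#' @param min_flank_markers Minimum called markers required in both runs
#'   flanking a conversion event.
#' @param max_gc_extent Maximum outer-flank extent (bp) for a conversion
#'   interpretation; wider internal runs are treated as two crossovers.
#' @param min_gc_markers Minimum converted markers for a trusted conversion
#'   event.
#' @param progeny_id Identifier used in the event tables.
#' @return A list with `crossovers`, `conversions` and `candidates` data
#'   frames (see Details for columns) and `calls_used`, the call vector
#'   after low-confidence candidates were reverted (the vector that
#'   [span_histogram()] should see).
#' @details `crossovers` has columns `progeny_id`, `distal_flank_pos`,
#'   `proximal_flank_pos`, `span` (the difference of the two) and
#'   `co_class`; `conversions` has flanking and outermost-converted marker
#'   positions, the converted-marker count, `min_tract` (distance between
#'   outermost converted markers), `max_tract` (distance between flanking
#'   non-converted markers) and `donor_parent`.
#' @export
classify_events <- function(calls, map, min_flank_markers = 2,
                            max_gc_extent = 10000, min_gc_markers = 2,
                            progeny_id = NULL) {
  obs <- if (inherits(calls, "observed_calls")) calls else
    structure(list(progeny_id = progeny_id %||% "progeny", calls = calls),
              class = "observed_calls")
  id <- progeny_id %||% obs$progeny_id
  pos <- map$markers$pos
  v <- obs$calls
  stop_if(length(v) != length(pos), "calls do not match the marker map")

  flip <- function(p) ifelse(p == "P1", "P2", "P1")
  candidates <- empty_gc_df()

  # triage pass: revert untrusted small runs (interior or terminal) so an
  # isolated false call does not masquerade as a crossover pair
  repeat {
    runs <- segment_haplotype(v)
    small <- which(runs$n_markers < min_gc_markers)
    if (length(small) == 0 || nrow(runs) == 1) break
    # revert the smallest first; re-segment because neighbours merge
    j <- small[which.min(runs$n_markers[small])]
    sel <- seq(runs$start_idx[j], runs$end_idx[j])
    sel <- sel[!is.na(v[sel])]
    neighbour <- if (j > 1) runs$parent[j - 1] else runs$parent[j + 1]
    dfp <- if (j > 1) pos[max(which(!is.na(v[1:(runs$start_idx[j] - 1)]))) ] else NA_real_
    after <- which(!is.na(v)) ; after <- after[after > runs$end_idx[j]]
    pfp <- if (length(after)) pos[min(after)] else NA_real_
    candidates <- rbind(candidates, data.frame(
      progeny_id = id, distal_flank_pos = dfp,
      first_converted_pos = pos[min(sel)], last_converted_pos = pos[max(sel)],
      proximal_flank_pos = pfp, n_converted = length(sel),
      min_tract = pos[max(sel)] - pos[min(sel)],
      max_tract = if (is.na(dfp) || is.na(pfp)) NA_real_ else pfp - dfp,
      donor_parent = runs$parent[j], stringsAsFactors = FALSE
    ))
    v[sel] <- neighbour
  }

  runs <- segment_haplotype(v)
  n <- nrow(runs)
  conversions <- empty_gc_df()
  is_gc <- rep(FALSE, n)
  if (n >= 3) {
    for (j in 2:(n - 1)) {
      dfp <- pos[runs$end_idx[j - 1]]
      pfp <- pos[runs$start_idx[j + 1]]
      ok_flanks <- runs$n_markers[j - 1] >= min_flank_markers &&
        runs$n_markers[j + 1] >= min_flank_markers
      if (pfp - dfp <= max_gc_extent && ok_flanks) {
        is_gc[j] <- TRUE
        conversions <- rbind(conversions, data.frame(
          progeny_id = id, distal_flank_pos = dfp,
          first_converted_pos = pos[runs$start_idx[j]],
          last_converted_pos = pos[runs$end_idx[j]],
          proximal_flank_pos = pfp, n_converted = runs$n_markers[j],
          min_tract = pos[runs$end_idx[j]] - pos[runs$start_idx[j]],
          max_tract = pfp - dfp,
          donor_parent = runs$parent[j], stringsAsFactors = FALSE
        ))
      }
    }
  }

  # crossovers: boundaries between consecutive non-conversion runs
  keep <- which(!is_gc)
  crossovers <- empty_co_df()
  if (length(keep) >= 2) {
    for (m in seq_len(length(keep) - 1)) {
      j1 <- keep[m]; j2 <- keep[m + 1]
      if (runs$parent[j1] == runs$parent[j2]) next  # merged across a conversion
      dfp <- pos[runs$end_idx[j1]]
      pfp <- pos[runs$start_idx[j2]]
      crossovers <- rbind(crossovers, data.frame(
        progeny_id = id, distal_flank_pos = dfp, proximal_flank_pos = pfp,
        span = pfp - dfp, co_class = NA_character_, stringsAsFactors = FALSE
      ))
    }
  }
  nco <- nrow(crossovers)
  if (nco > 0) {
    crossovers$co_class <- if (nco == 1) "SCO" else if (nco == 2) "DCO" else "MCO"
  }

  list(crossovers = crossovers, conversions = conversions,
       candidates = candidates, calls_used = v)
}

#' Detect events across a dataset of progeny call vectors
#'
#' Applies [classify_events()] to each progeny and aggregates the event
#' tables, the triaged call vectors and the inter-marker span histogram.
#'
#' @param map A [marker_map()].
#' @param calls List of `observed_calls` (e.g. `simulate_meiosis(...)$calls`).
#' @param b Maximum span length (bp) retained in the histogram.
#' @inheritParams classify_events
#' @return An object of class `recomb_events`: a list with `crossovers`,
#'   `conversions`, `candidates`, `calls_used` (list of triaged call
#'   vectors) and `spans` (a [span_histogram()]).
#' @export
detect_events <- function(map, calls, min_flank_markers = 2,
                          max_gc_extent = 10000, min_gc_markers = 2,
                          b = 10000) {
  res <- lapply(calls, classify_events, map = map,
                min_flank_markers = min_flank_markers,
                max_gc_extent = max_gc_extent, min_gc_markers = min_gc_markers)
  out <- list(
    crossovers = do.call(rbind, c(lapply(res, `[[`, "crossovers"),
                                  list(empty_co_df()))),
    conversions = do.call(rbind, c(lapply(res, `[[`, "conversions"),
                                   list(empty_gc_df()))),
    candidates = do.call(rbind, c(lapply(res, `[[`, "candidates"),
                                  list(empty_gc_df()))),
    calls_used = lapply(res, `[[`, "calls_used")
  )
  rownames(out$crossovers) <- rownames(out$conversions) <-
    rownames(out$candidates) <- NULL
  # spans overlapping either a trusted conversion tract or a triaged
  # candidate are ambiguous about the no-conversion outcome and are
  # excluded from the histogram entirely
  out$spans <- span_histogram(map, out$calls_used,
                              rbind(out$conversions, out$candidates), b = b)
  class(out) <- "recomb_events"
  out
}

#' @export
print.recomb_events <- function(x, ...) {
  cat(sprintf("Recombination events: %d crossovers, %d conversions, %d low-confidence candidates\n",
              nrow(x$crossovers), nrow(x$conversions), nrow(x$candidates)))
  if (nrow(x$crossovers)) {
    cls <- table(tapply(x$crossovers$co_class, x$crossovers$progeny_id, `[`, 1))
    cat("  chromatids by class: ",
        paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  span histogram: %d spans (b = %d)\n",
              sum(x$spans$counts$count), attr(x$spans, "b")))
  invisible(x)
}

#' Histogram of no-conversion inter-marker spans
#'
#' For every progeny, each gap between adjacent called markers that does not
#' overlap a detected conversion tract contributes one count at its length;
#' gaps longer than `b` are excluded (long spans carry almost no information
#' about the conversion process).  The result is the sufficient statistic
#' for the "non-event" part of the [gcml()] likelihood.
#'
#' @param map A [marker_map()].
#' @param calls List of call vectors or `observed_calls` (use the triaged
#'   `calls_used` from [detect_events()] so reverted candidates count as
#'   ordinary markers).
#' @param conversions Conversion-event data frame; gaps within
#'   `[distal_flank, proximal_flank]` of an event for the same progeny are
#'   excluded entirely.  [detect_events()] passes both trusted conversions
#'   and triaged low-confidence candidates here, since a span containing
#'   either did not cleanly witness "no conversion".
#' @param b Maximum span length retained.
#' @return An object of class `span_histogram`: a list with `counts`, a data
#'   frame of distinct span `length`s and their `count`s, with attribute
#'   `b`.
#' @export
span_histogram <- function(map, calls, conversions = empty_gc_df(), b = 10000) {
  pos <- map$markers$pos
  all_lens <- lapply(seq_along(calls), function(j) {
    obs <- calls[[j]]
    v <- if (inherits(obs, "observed_calls")) obs$calls else obs
    id <- if (inherits(obs, "observed_calls")) obs$progeny_id else names(calls)[j]
    p <- pos[!is.na(v)]
    if (length(p) < 2) return(numeric(0))
    g_start <- p[-length(p)]
    g_end <- p[-1]
    ev <- conversions[conversions$progeny_id %in% id, , drop = FALSE]
    # candidates at chromosome ends can lack a flank; fall back to the
    # converted markers themselves for the exclusion window
    dfp <- ifelse(is.na(ev$distal_flank_pos), ev$first_converted_pos,
                  ev$distal_flank_pos)
    pfp <- ifelse(is.na(ev$proximal_flank_pos), ev$last_converted_pos,
                  ev$proximal_flank_pos)
    keep <- rep(TRUE, length(g_start))
    for (e in seq_len(nrow(ev))) {
      keep <- keep & !(g_start < pfp[e] & g_end > dfp[e])
    }
    len <- (g_end - g_start)[keep]
    len[len <= b]
  })
  lens <- unlist(all_lens, use.names = FALSE)
  tab <- table(lens)
  counts <- data.frame(length = as.integer(names(tab)),
                       count = as.integer(tab))
  structure(list(counts = counts), b = b, class = "span_histogram")
}

#' @export
print.span_histogram <- function(x, ...) {
  cat(sprintf("Span histogram: %d spans over %d distinct lengths (b = %d)\n",
              sum(x$counts$count), nrow(x$counts), attr(x, "b")))
  invisible(x)
}

#' Summarize detected events
#'
#' Computes the span and tract bookkeeping used to describe a dataset:
#' mean and total crossover span (over localized events), total conversion
#' maximum-tract length, exonic base counts and proportions when an
#' annotation is supplied, per-chromatid crossover class tallies, and the
#' single-crossover pairwise-distance and double-crossover separation
#' summaries of [pairwise_distance_summary()].
#'
#' @param crossovers,conversions Event data frames from [detect_events()]
#'   (or assembled by hand, e.g. from a published event table).
#' @param annotation Optional annotation data frame with 1-based inclusive
#'   `start`, `end` and `class` columns; rows with class `"exon"` are used
#'   for exonic overlap.
#' @param max_localized_span Crossovers with spans above this are treated as
#'   non-localized and excluded from span statistics (they remain in the
#'   class tallies).
#' @return A list of summary quantities; fields that need at least two
#'   events are `NA` with an `undefined` flag when the input is degenerate.
#' @export
summarize_events <- function(crossovers, conversions = empty_gc_df(),
                             annotation = NULL, max_localized_span = 10000) {
  loc <- crossovers[crossovers$span <= max_localized_span, , drop = FALSE]
  out <- list(
    n_crossovers = nrow(crossovers),
    n_localized = nrow(loc),
    total_co_span = if (nrow(loc)) sum(loc$span) else NA_real_,
    mean_co_span = if (nrow(loc)) mean(loc$span) else NA_real_,
    n_conversions = nrow(conversions),
    total_gc_min_tract = if (nrow(conversions)) sum(conversions$min_tract) else NA_real_,
    total_gc_max_tract = if (nrow(conversions)) sum(conversions$max_tract) else NA_real_,
    co_class_tally = if (nrow(crossovers))
      table(tapply(crossovers$co_class, crossovers$progeny_id, `[`, 1)) else table(character(0)),
    undefined = character(0)
  )
  if (!nrow(loc)) out$undefined <- c(out$undefined, "co_span")
  if (!is.null(annotation)) {
    exons <- annotation[annotation$class == "exon", , drop = FALSE]
    co_ex <- exonic_overlap_bp(loc$distal_flank_pos, loc$proximal_flank_pos, exons)
    gc_ex <- exonic_overlap_bp(conversions$distal_flank_pos,
                               conversions$proximal_flank_pos, exons)
    out$co_exonic_bp <- sum(co_ex)
    out$co_exonic_fraction <- if (nrow(loc)) sum(co_ex) / sum(loc$span) else NA_real_
    out$gc_exonic_bp <- sum(gc_ex)
    out$gc_exonic_fraction <- if (nrow(conversions))
      sum(gc_ex) / sum(conversions$max_tract) else NA_real_
  }
  dist_sum <- pairwise_distance_summary(crossovers)
  out[names(dist_sum)] <- dist_sum
  out
}

# exonic bp inside (start, end) open intervals (span semantics: the bp
# strictly between the flanking markers)
exonic_overlap_bp <- function(start, end, exons) {
  if (length(start) == 0) return(numeric(0))
  if (nrow(exons) == 0) return(numeric(length(start)))
  sp <- IRanges::IRanges(start = start + 1, end = end - 1)
  ex <- IRanges::reduce(IRanges::IRanges(start = exons$start, end = exons$end))
  ov <- IRanges::findOverlaps(sp, ex)
  w <- IRanges::width(IRanges::pintersect(sp[S4Vectors::queryHits(ov)],
                                          ex[S4Vectors::subjectHits(ov)]))
  as.numeric(tapply(c(w, numeric(0)), factor(S4Vectors::queryHits(ov),
                                             levels = seq_along(sp)), sum, default = 0))
}
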