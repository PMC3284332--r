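#' Simulation parameters for the meiosis generator
#'
#' Bundles the stochastic model for one transmitted (hemizygous) chromatid:
#' a crossover (CO) process with 0--2 COs per chromatid, a distal position
#' bias and hard interference, and a noncrossover gene-conversion (GC)
#' process placing double-strand breaks (DSBs) as a Poisson process at rate
#' `nco_dsb_rate` per bp, each extending a conversion tract independently
#' leftward and rightward by geometric lengths with cessation probability
#' `tract_p`.  The observation model drops each marker call independently
#' (probability `1 - call_rate`) and flips isolated calls to the opposite
#' parent (probability `false_call_rate`), emulating incomplete genotyping
#' and the false single-marker conversion candidates that sequencing studies
#' must triage away.
#'
#' Defaults reproduce the design of a 30-chromatid whole-X study: about 15
#' COs among 30 chromatids (9 single-CO and 3 double-CO chromatids), a GC
#' DSB rate of 1.8e-8 per bp per chromatid (0.40 events per 22.4-Mb arm),
#' mean one-sided tract extension 238 bp, 70\% marker call rate and a false
#' call rate calibrated to produce on the order of 23 isolated false
#' conversion candidates per 30 chromatids.
#'
#' @param n_progeny Number of chromatids per simulated dataset.
#' @param co_count_probs Probabilities of 0, 1 and 2 COs per chromatid;
#'   must sum to 1.
#' @param co_position_density Data frame with columns `start`, `end`,
#'   `weight`: piecewise-constant relative CO density along the chromosome.
#'   `NULL` gives the default distal bias (weight 3 on the distal
#'   two-thirds, 1 on the proximal third).
#' @param interference_min_separation Minimum separation (bp) between the
#'   two COs of a double-CO chromatid.
#' @param nco_dsb_rate GC DSB rate per bp per transmitted chromatid.
#' @param tract_p Geometric tract-extension cessation probability in (0, 1].
#' @param call_rate Probability a marker is genotyped in a progeny.
#' @param false_call_rate Probability a genotyped marker is flipped to the
#'   opposite parent.
#' @param seed Integer seed for the dataset; per-chromatid substreams are
#'   derived deterministically from it.
#' @return An object of class `meiosis_params`.
#' @export
meiosis_params <- function(n_progeny = 30,
                           co_count_probs = c(0.6, 0.3, 0.1),
                           co_position_density = NULL,
                           interference_min_separation = 4e6,
                           nco_dsb_rate = 1.8e-8,
                           tract_p = 1 / 239,
                           call_rate = 0.7,
                           false_call_rate = 1.2e-5,
                           seed = 1) {
  stop_if(abs(sum(co_count_probs) - 1) > 1e-8, "co_count_probs must sum to 1")
  stop_if(any(co_count_probs < 0), "co_count_probs must be non-negative")
  stop_if(nco_dsb_rate < 0, "nco_dsb_rate must be >= 0")
  stop_if(tract_p <= 0 || tract_p > 1, "tract_p must be in (0, 1]")
  stop_if(call_rate < 0 || call_rate > 1 || false_call_rate < 0 || false_call_rate > 1,
          "call_rate and false_call_rate must be in [0, 1]")
  stop_if(interference_min_separation < 0, "interference_min_separation must be >= 0")
  structure(list(
    n_progeny = as.integer(n_progeny),
    co_count_probs = co_count_probs,
    co_position_density = co_position_density,
    interference_min_separation = interference_min_separation,
    nco_dsb_rate = nco_dsb_rate,
    tract_p = tract_p,
    call_rate = call_rate,
    false_call_rate = false_call_rate,
    seed = as.integer(seed)
  ), class = "meiosis_params")
}

#' @export
print.meiosis_params <- function(x, ...) {
  cat("Meiosis simulation parameters\n")
  cat(sprintf("  progeny: %d;  P(0/1/2 COs) = %s\n", x$n_progeny,
              paste(format(x$co_count_probs), collapse = "/")))
  cat(sprintf("  GC DSB rate: %.3g per bp;  tract p: %.4g (mean one-sided %.0f bp)\n",
              x$nco_dsb_rate, x$tract_p, (1 - x$tract_p) / x$tract_p))
  cat(sprintf("  call rate: %.2f;  false call rate: %.2g\n",
              x$call_rate, x$false_call_rate))
  invisible(x)
}

default_co_density <- function(L) {
  data.frame(start = c(0, 2 / 3 * L), end = c(2 / 3 * L, L), weight = c(3, 1))
}

draw_co_positions <- function(n, L, density, min_sep) {
  if (n == 0) return(numeric(0))
  dens <- density %||% default_co_density(L)
  w <- dens$weight * (dens$end - dens$start)
  draw_one <- function(k) {
    seg <- sample.int(nrow(dens), k, replace = TRUE, prob = w)
    floor(runif(k, dens$start[seg], dens$end[seg])) + 1
  }
  pos <- draw_one(n)
  if (n > 1) {
    tries <- 0
    while (min(diff(sort(pos))) < min_sep) {
      pos <- draw_one(n)
      tries <- tries + 1
      if (tries > 10000) stop("cannot satisfy interference constraint", call. = FALSE)
    }
  }
  sort(pos)
}

#' Simulate one recombinant chromatid
#'
#' Draws the CO count from `co_count_probs` and CO breakpoints from the
#' position density (respecting the interference minimum separation), places
#' GC DSBs as Poisson(`nco_dsb_rate` x chromosome length) uniform positions,
#' and extends each conversion tract left and right by independent geometric
#' lengths, the DSB nucleotide itself always being converted.  The parental
#' origin at each marker is the background haplotype flipped across CO
#' breakpoints, with converted intervals overwritten by the opposite parent.
#'
#' @param map A [marker_map()].
#' @param params A [meiosis_params()].
#' @param seed Integer seed for this chromatid.
#' @param progeny_id Identifier stored with the result.
#' @return A list with elements `truth` (class `chromatid_truth`: CO
#'   breakpoints, GC events with DSB position and left/right extensions, and
#'   the starting parent) and `origin` (character vector, `"P1"`/`"P2"`, the
#'   true parental origin at each marker).
#' @export
simulate_chromatid <- function(map, params, seed = params$seed,
                               progeny_id = "chromatid") {
  validate_marker_map(map)
  set.seed(seed)
  L <- map$chromosome_length
  pos <- map$markers$pos

  n_co <- sample(0:2, 1, prob = params$co_count_probs)
  co <- draw_co_positions(n_co, L, params$co_position_density,
                          params$interference_min_separation)

  n_gc <- rpois(1, params$nco_dsb_rate * L)
  gc <- data.frame(
    dsb = if (n_gc) floor(runif(n_gc, 0, L)) + 1 else integer(0),
    left = if (n_gc) rgeom(n_gc, params$tract_p) else integer(0),
    right = if (n_gc) rgeom(n_gc, params$tract_p) else integer(0)
  )

  start_parent <- sample(c("P1", "P2"), 1)
  # haplotype flips at each CO breakpoint
  n_flips <- findInterval(pos, co)
  origin_idx <- (match(start_parent, c("P1", "P2")) - 1L + n_flips) %% 2L
  origin <- c("P1", "P2")[origin_idx + 1L]
  # converted intervals copy from the homolog: flip markers inside
  if (n_gc > 0) {
    for (g in seq_len(n_gc)) {
      lo <- gc$dsb[g] - gc$left[g]
      hi <- gc$dsb[g] + gc$right[g]
      inside <- pos >= lo & pos <= hi
      origin[inside] <- ifelse(origin[inside] == "P1", "P2", "P1")
    }
  }

  truth <- structure(list(
    progeny_id = progeny_id,
    start_parent = start_parent,
    co_breakpoints = co,
    gc_events = gc
  ), class = "chromatid_truth")
  list(truth = truth, origin = origin)
}

#' Degrade a true origin vector with the observation model
#'
#' Each marker is independently missing with probability `1 - call_rate`;
#' each called marker is independently flipped to the opposite parent with
#' probability `false_call_rate`.  Flips are isolated single-marker errors,
#' the in-silico analogue of the false conversion candidates produced by
#' alignment artefacts in sequencing studies.
#'
#' @param origin Character vector of true origins (`"P1"`/`"P2"`).
#' @param call_rate,false_call_rate Observation probabilities in [0, 1].
#' @param seed Integer seed.
#' @param progeny_id Identifier stored with the result.
#' @return An object of class `observed_calls`: a list with `progeny_id` and
#'   `calls` (character vector with `NA` for missing markers).
#' @export
apply_observation_model <- function(origin, call_rate = 0.7,
                                    false_call_rate = 1.2e-5, seed = 1,
                                    progeny_id = "chromatid") {
  stop_if(call_rate < 0 || call_rate > 1 || false_call_rate < 0 || false_call_rate > 1,
          "rates must be in [0, 1]")
  set.seed(seed)
  n <- length(origin)
  calls <- origin
  calls[runif(n) >= call_rate] <- NA
  flip <- !is.na(calls) & runif(n) < false_call_rate
  calls[flip] <- ifelse(calls[flip] == "P1", "P2", "P1")
  structure(list(progeny_id = progeny_id, calls = calls),
            class = "observed_calls")
}

#' Simulate a full meiosis dataset
#'
#' Generates `params$n_progeny` chromatids from a marker map, each with its
#' own deterministic RNG substream derived from `params$seed`, and applies
#' the observation model to every chromatid.
#'
#' @param map A [marker_map()].
#' @param params A [meiosis_params()].
#' @return An object of class `meiosis_sim`: a list with the `map`, `params`,
#'   `truths` (list of `chromatid_truth`) and `calls` (list of
#'   `observed_calls`), one per progeny.
#' @examples
#' map <- generate_marker_map(2000, 1e6, clustering = 0, seed = 1)
#' sim <- simulate_meiosis(map, meiosis_params(n_progeny = 4, seed = 7))
#' sim$truths[[1]]$co_breakpoints
#' @export
simulate_meiosis <- function(map, params = meiosis_params()) {
  ids <- sprintf("p%02d", seq_len(params$n_progeny))
  truths <- vector("list", params$n_progeny)
  calls <- vector("list", params$n_progeny)
  for (j in seq_len(params$n_progeny)) {
    sim <- simulate_chromatid(map, params, seed = substream_seed(params$seed, j),
                              progeny_id = ids[j])
    obs <- apply_observation_model(sim$origin, params$call_rate,
                                   params$false_call_rate,
                                   seed = substream_seed(params$seed, j + params$n_progeny),
                                   progeny_id = ids[j])
    truths[[j]] <- sim$truth
    calls[[j]] <- obs
  }
  structure(list(map = map, params = params,
                 truths = setNames(truths, ids), calls = setNames(calls, ids)),
            class = "meiosis_sim")
}

#' @export
print.meiosis_sim <- function(x, ...) {
  n_co <- vapply(x$truths, function(t) length(t$co_breakpoints), integer(1))
  n_gc <- vapply(x$truths, function(t) nrow(t$gc_events), integer(1))
  cat(sprintf("Simulated meiosis dataset: %d chromatids on %d markers\n",
              length(x$truths), nrow(x$map$markers)))
  cat(sprintf("  true COs: %d (%s chromatid counts)\n", sum(n_co),
              paste(table(factor(n_co, 0:2)), collapse = "/")))
  cat(sprintf("  true GC events: %d\n", sum(n_gc)))
  invisible(x)
}

# converted intervals implied by a chromatid truth, 1-based inclusive
converted_intervals <- function(truth) {
  g <- truth$gc_events
  if (nrow(g) == 0) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = g$dsb - g$left, end = g$dsb + g$right)
}
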