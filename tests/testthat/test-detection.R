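test_that("segmentation skips missing calls and round-trips", {
  r <- segment_haplotype(c("P1", "P1", NA, "P1"))
  expect_equal(nrow(r), 1)
  expect_equal(r$n_markers, 3)
  r2 <- segment_haplotype(c("P1", "P1", "P2", "P2"))
  expect_equal(nrow(r2), 2)
  expect_equal(r2$parent, c("P1", "P2"))
  expect_error(segment_haplotype(c(NA_character_, NA)), "missing")

  # reconstruction oracle on random calls
  set.seed(3)
  v <- sample(c("P1", "P2", NA), 10000, replace = TRUE, prob = c(.45, .45, .1))
  runs <- segment_haplotype(v)
  rebuilt <- rep(NA_character_, length(v))
  for (j in seq_len(nrow(runs))) {
    idx <- runs$start_idx[j]:runs$end_idx[j]
    idx <- idx[!is.na(v[idx])]
    rebuilt[idx] <- runs$parent[j]
  }
  expect_identical(rebuilt, v)
  expect_true(all(runs$parent[-1] != runs$parent[-nrow(runs)]))
})

test_that("classification reproduces published event arithmetic", {
  # crossover: w1118 haplotype through 2,413,159, Canton-S from 2,413,912
  pos <- c(2410000, 2411500, 2413159, 2413912, 2415000, 2416000)
  map <- marker_map("X", 3e6, pos)
  calls <- c("P1", "P1", "P1", "P2", "P2", "P2")
  r <- classify_events(calls, map, progeny_id = "2d")
  expect_equal(nrow(r$crossovers), 1)
  expect_equal(r$crossovers$span, 753)
  expect_equal(r$crossovers$distal_flank_pos, 2413159)
  expect_equal(r$crossovers$co_class, "SCO")

  # conversion: 4 converted markers between flanks 6,633,119 / 6,633,865
  pos2 <- c(6632000, 6633119, 6633448, 6633500, 6633550, 6633592, 6633865, 6634500)
  map2 <- marker_map("X", 7e6, pos2)
  calls2 <- c("P1", "P1", "P2", "P2", "P2", "P2", "P1", "P1")
  r2 <- classify_events(calls2, map2, progeny_id = "1e")
  expect_equal(nrow(r2$crossovers), 0)
  expect_equal(nrow(r2$conversions), 1)
  expect_equal(r2$conversions$min_tract, 144)
  expect_equal(r2$conversions$max_tract, 746)
  expect_equal(r2$conversions$n_converted, 4)
  expect_equal(r2$conversions$donor_parent, "P2")

  # constant chromatid: no events
  r3 <- classify_events(rep("P1", 6), map, progeny_id = "null")
  expect_equal(nrow(r3$crossovers) + nrow(r3$conversions), 0)
})

test_that("single-marker discordant calls are triaged, not called as events", {
  pos <- seq(1000, 50000, by = 1000)
  map <- marker_map("X", 1e5, pos)
  calls <- rep("P1", length(pos))
  calls[20] <- "P2"
  r <- classify_events(calls, map)
  expect_equal(nrow(r$crossovers), 0)
  expect_equal(nrow(r$conversions), 0)
  expect_equal(nrow(r$candidates), 1)
  expect_equal(r$candidates$n_converted, 1)
  expect_identical(r$calls_used, rep("P1", length(pos)))
})

test_that("noise-free simulations are detected event-for-event", {
  map <- tiny_map(4000, 1e6)
  params <- meiosis_params(n_progeny = 12, seed = 21, call_rate = 1,
                           false_call_rate = 0, nco_dsb_rate = 2e-6,
                           tract_p = 1 / 150,
                           interference_min_separation = 2e5)
  sim <- simulate_meiosis(map, params)
  ev <- detect_events(map, sim$calls)
  pos <- map$markers$pos
  for (id in names(sim$truths)) {
    truth <- sim$truths[[id]]
    co_det <- ev$crossovers[ev$crossovers$progeny_id == id, ]
    # every true CO with a marker on each side is bracketed by a detected span
    for (x in truth$co_breakpoints) {
      if (x <= min(pos) || x > max(pos)) next
      expect_true(any(co_det$distal_flank_pos < x &
                        co_det$proximal_flank_pos >= x))
    }
    # every true conversion covering >= 2 markers is recovered with
    # min_tract <= true extent <= max_tract
    g <- truth$gc_events
    conv <- ev$conversions[ev$conversions$progeny_id == id, ]
    for (i in seq_len(nrow(g))) {
      lo <- g$dsb[i] - g$left[i]; hi <- g$dsb[i] + g$right[i]
      n_mark <- sum(pos >= lo & pos <= hi)
      covers_all <- lo > min(pos) && hi < max(pos)
      if (n_mark < 2 || !covers_all) next
      hit <- which(conv$first_converted_pos >= lo & conv$last_converted_pos <= hi)
      if (length(hit) != 1) next  # merged with a neighbouring event
      expect_lte(conv$min_tract[hit], hi - lo)
      expect_gte(conv$max_tract[hit], hi - lo)
    }
  }
})

test_that("span histograms count exactly the qualifying gaps", {
  # single span of 5 bp
  map <- marker_map("X", 100, c(10, 15))
  h <- span_histogram(map, list(c("P1", "P1")))
  expect_equal(h$counts, data.frame(length = 5L, count = 1L))

  # spans above b are excluded
  map2 <- marker_map("X", 1e5, c(10, 12010, 13000))
  h2 <- span_histogram(map2, list(c("P1", "P1", "P1")), b = 10000)
  expect_equal(h2$counts, data.frame(length = 990L, count = 1L))

  # total equals a brute-force count of qualifying adjacent pairs
  map3 <- tiny_map(2000, 5e5, seed = 31)
  sim <- simulate_meiosis(map3, meiosis_params(n_progeny = 6, seed = 13,
                                               nco_dsb_rate = 1e-6,
                                               interference_min_separation = 1e5))
  ev <- detect_events(map3, sim$calls, b = 2000)
  brute <- 0
  for (id in names(ev$calls_used)) {
    p <- map3$markers$pos[!is.na(ev$calls_used[[id]])]
    gaps <- diff(p)
    gs <- p[-length(p)]; ge <- p[-1]
    # both trusted conversions and triaged candidates exclude their windows
    conv <- rbind(ev$conversions[ev$conversions$progeny_id == id, ],
                  ev$candidates[ev$candidates$progeny_id == id, ])
    lo <- ifelse(is.na(conv$distal_flank_pos), conv$first_converted_pos,
                 conv$distal_flank_pos)
    hi <- ifelse(is.na(conv$proximal_flank_pos), conv$last_converted_pos,
                 conv$proximal_flank_pos)
    excl <- rep(FALSE, length(gaps))
    for (e in seq_len(nrow(conv))) {
      excl <- excl | (gs < hi[e] & ge > lo[e])
    }
    brute <- brute + sum(gaps[!excl] <= 2000)
  }
  expect_equal(sum(ev$spans$counts$count), brute)
})

test_that("event summaries reproduce the published bookkeeping", {
  co <- xchrom_co_spans()
  gc <- xchrom_gc_tracts()
  s <- summarize_events(co, gc)
  expect_equal(s$n_crossovers, 15)
  expect_equal(s$n_localized, 14)
  expect_equal(s$total_co_span, 12925)
  expect_equal(round(s$mean_co_span), 923)
  expect_equal(s$total_gc_max_tract, 8151)
  expect_equal(as.vector(s$co_class_tally[c("SCO", "DCO")]), c(9, 3))

  # degenerate input flags undefined fields
  one <- co[3, ]
  s1 <- summarize_events(one)
  expect_true("sco_mean_pairwise_distance" %in% s1$undefined)
})

test_that("exonic fractions agree with an interval-arithmetic oracle", {
  set.seed(5)
  ann <- generate_annotation(1e5, exon_fraction = 0.3, seed = 8)
  co <- data.frame(progeny_id = "p", distal_flank_pos = c(5000, 42000),
                   proximal_flank_pos = c(9000, 55000),
                   span = c(4000, 13000),
                   co_class = "SCO", stringsAsFactors = FALSE)
  s <- summarize_events(co, annotation = ann, max_localized_span = 2e4)
  # oracle: per-bp membership test
  exons <- ann[ann$class == "exon", ]
  in_exon <- logical(1e5)
  for (r in seq_len(nrow(exons))) in_exon[exons$start[r]:exons$end[r]] <- TRUE
  brute <- sum(in_exon[5001:8999]) + sum(in_exon[42001:54999])
  expect_equal(s$co_exonic_bp, brute)
  expect_equal(s$co_exonic_fraction, brute / 17000)
})
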