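test_that("minimum-distance null matches its closed form and bounds", {
  expect_error(min_distance_null(n_events = 1), "at least 2")
  # two events, threshold the whole region: always below
  r2 <- min_distance_null(n_events = 2, region_length = 1e5, n_trials = 200,
                          threshold = 1e5, seed = 1)
  expect_equal(r2$fraction_below_threshold, 1)

  r <- min_distance_null(n_trials = 4000, seed = 7)
  closed <- 1 - (1 - 14 * 25000 / 1.4e7)^15
  se <- sqrt(closed * (1 - closed) / 4000)
  expect_lt(abs(r$fraction_below_threshold - closed), 3 * se)
  # mean minimum distance: continuous order-statistics expectation
  # L / ((n-1)(n+1)) = 62,500
  expect_lt(abs(r$mean_min_distance - 62500),
            3 * sd(r$min_distances) / sqrt(r$n_trials))
  # bit-exact reproducibility for a fixed seed
  expect_identical(r$min_distances,
                   min_distance_null(n_trials = 4000, seed = 7)$min_distances)
  expect_false(identical(r$min_distances,
                         min_distance_null(n_trials = 4000, seed = 8)$min_distances))
})

test_that("interval placement null has the correct expectation and bounds", {
  ann <- generate_annotation(2e5, exon_fraction = 0.237, seed = 4)
  exon_frac <- with(ann[ann$class == "exon", ], sum(end - start + 1)) / 2e5

  # spans tiling the whole chromosome reproduce the global fraction exactly
  r_all <- interval_placement_null(2e5, ann, 2e5, n_trials = 20, seed = 1)
  expect_true(all(abs(r_all$null_stats - exon_frac) < 1e-12))

  # expectation oracle at the published span-size distribution
  spans <- xchrom_co_spans()$span
  spans <- spans[spans <= 10000]
  r <- interval_placement_null(spans, ann, 2e5, n_trials = 600, seed = 2)
  se <- sd(r$null_stats) / sqrt(r$n_trials)
  expect_lt(abs(r$null_mean - exon_frac), 3 * se + 0.01)

  # saturated observation gives empirical P = 1 under "avoidance"
  r1 <- interval_placement_null(spans, ann, 2e5, n_trials = 100,
                                observed_stat = 1, alternative = "avoidance",
                                seed = 3)
  expect_equal(r1$empirical_P, 1)
  expect_error(interval_placement_null(3e5, ann, 2e5), "longer")
})

test_that("placement-null empirical P is uniform under the null", {
  ann <- generate_annotation(1e5, exon_fraction = 0.3, seed = 9)
  spans <- c(400, 900, 1500, 2600)
  base <- interval_placement_null(spans, ann, 1e5, n_trials = 60, seed = 100)
  ps <- vapply(1:150, function(r) {
    obs <- base$null_stats[((r - 1) %% 60) + 1]
    mean(interval_placement_null(spans, ann, 1e5, n_trials = 60,
                                 seed = 200 + r)$null_stats <= obs)
  }, numeric(1))
  # uniform on {0, 1/60, ..., 1}: mean 1/2 within 3 s.e.
  expect_lt(abs(mean(ps) - 0.5), 3 * sqrt(1 / 12 / 150) + 1 / 60)
})

test_that("word-count Fisher test equals the hypergeometric oracle", {
  expect_equal(word_count_fisher(0, 700, 0, 350)$p.value, 1)
  expect_equal(word_count_fisher(0, 70, 0, 35)$p.value, 1)

  cases <- list(c(5, 210, 1, 140), c(12, 700, 3, 350), c(2, 70, 9, 77),
                c(25, 12925, 7, 8151))
  for (cs in cases) {
    got <- word_count_fisher(cs[1], cs[2], cs[3], cs[4])$p.value
    na <- floor(cs[2] / 7); nb <- floor(cs[4] / 7)
    want <- fisher_oracle(cs[1], na - cs[1], cs[3], nb - cs[3])
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(word_count_fisher(50, 70, 0, 35), "exceed")
})

test_that("crossover distance summaries match the published values", {
  co <- xchrom_co_spans()
  d <- pairwise_distance_summary(co)
  # 9 single-CO midpoints: mean pairwise distance about 4.8 Mb
  expect_equal(d$sco_mean_pairwise_distance / 1e6, 4.75, tolerance = 0.01)
  # 3 double-CO chromatids: mean separation 8.6 Mb
  expect_equal(d$dco_mean_separation / 1e6, 8.62, tolerance = 0.01)
  expect_length(d$dco_separations, 3)

  same <- data.frame(progeny_id = c("a", "a"), distal_flank_pos = c(100, 100),
                     proximal_flank_pos = c(200, 200),
                     co_class = c("DCO", "DCO"))
  expect_equal(pairwise_distance_summary(same)$dco_separations[["a"]], 0)
  one <- co[1, ]
  expect_true("sco_mean_pairwise_distance" %in%
                pairwise_distance_summary(one)$undefined)
})
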