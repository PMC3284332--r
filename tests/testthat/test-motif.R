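indicator_pwm <- function(word, id = "ind") {
  bases <- c("A", "C", "G", "T")
  probs <- vapply(strsplit(word, "")[[1]], function(b) as.numeric(bases == b),
                  numeric(4))
  pwm_motif(id, probs)
}

test_that("word counting matches a sliding-window oracle", {
  expect_equal(count_words(strrep("A", 50), "GTGGAAA")$total, 0)
  expect_equal(count_words("GTGGAAA", "GTGGAAA")$total, 1)
  # overlapping occurrences are counted
  expect_equal(count_words("AAAA", "AA")$total, 3)
  # palindrome on both strands double-counts symmetrically
  expect_equal(count_words("ACGT", "ACGT", both_strands = TRUE)$total, 2)

  set.seed(21)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""),
    character(1))
  expect_equal(count_words(seqs, "GTGCA")$total, brute_word_count(seqs, "GTGCA"))
  expect_equal(count_words(seqs, "TT")$total, brute_word_count(seqs, "TT"))
  # region order does not matter
  expect_equal(count_words(rev(seqs), "GTGCA")$total,
               count_words(seqs, "GTGCA")$total)
  expect_error(count_words(seqs, "GTXGA"), "A/C/G/T")
})

test_that("expected counts follow the composition closed form", {
  s <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")  # 1000 bp, 25% each
  e <- expected_word_count(s, "GTGGAAA")
  expect_equal(e$expected, (1000 - 6) * 4^-7, tolerance = 1e-12)

  # O/E near 1 on a large random equal-composition sequence
  r <- expected_word_count(as.character(random_dna(1e6, seed = 3)), "GTGGAAA")
  expect_lt(abs(r$oe_ratio - 1), 3 / sqrt(r$expected))

  g <- expected_word_count(strrep("G", 100), "GTGGAAA")
  expect_true(g$undefined)
  expect_true(is.na(g$oe_ratio))
})

test_that("an indicator PWM scan reduces to word counting", {
  set.seed(8)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                 prob = c(.3, .2, .2, .3)), collapse = ""), character(1))
  seqs[2] <- paste0(substr(seqs[2], 1, 100), "GTGGAAA", substr(seqs[2], 108, 400))
  pwm <- indicator_pwm("GTGGAAA")
  hits <- pwm_scan(seqs, pwm, both_strands = FALSE)
  expect_equal(nrow(hits), count_words(seqs, "GTGGAAA")$total)
  expect_true(all(hits$p_value == 4^-7))
  # filter constant 0 keeps nothing
  expect_equal(nrow(pwm_scan(seqs, pwm, filter_constant = 0)), 0)
  # a region shorter than the motif yields no matches, silently
  expect_equal(nrow(pwm_scan("ACG", pwm)), 0)
})

test_that("DP p-values equal exhaustive enumeration for small widths", {
  set.seed(30)
  for (w in c(3, 5)) {
    probs <- matrix(rgamma(4 * w, 1), 4)
    probs <- sweep(probs, 2, colSums(probs), "/")
    bg <- c(.3, .2, .2, .3)
    pwm <- pwm_motif("m", probs, bg)
    # enumerate all 4^w words: exact integer-score tail under the background
    S <- meiorec:::pwm_score_table(pwm, 1e-4)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- rowSums(matrix(S[cbind(as.vector(words), rep(1:w, each = 4^w))],
                             ncol = w))
    wprob <- apply(matrix(bg[as.vector(words)], ncol = w), 1, prod)
    pfun <- meiorec:::pwm_pvalue_fn(pwm, 1e-4)
    for (q in quantile(scores, c(0, .25, .5, .75, 1), type = 1)) {
      expect_equal(pfun(q), sum(wprob[scores >= q]), tolerance = 1e-9)
    }
    # monotone non-increasing in score
    ss <- sort(unique(scores))
    expect_true(all(diff(pfun(ss)) <= 1e-15))
  }
})

test_that("flank enrichment finds planted excess and matches the BH oracle", {
  # identical densities: P = 1
  r <- flank_enrichment(span_counts = c(m1 = 10), span_length = 7000,
                        flank_counts = matrix(10, 1, 1,
                                              dimnames = list(NULL, "1k")),
                        flank_lengths = 7000, width = 7)
  expect_equal(r$p, 1)

  # planted tenfold density excess across 14 regions' pooled spans
  r2 <- flank_enrichment(span_counts = c(hot = 60, cold = 3),
                         span_length = 14000,
                         flank_counts = cbind(`1k` = c(6, 3)),
                         flank_lengths = 14000, width = 7)
  hot <- r2[r2$motif == "hot", ]
  expect_true(hot$significant && hot$direction == "over")

  # BH adjustment equals the direct step-up formula on a fixed 260-vector
  set.seed(12)
  pv <- c(runif(250), runif(10, 0, 1e-3))
  expect_equal(p.adjust(pv, "BH"), bh_oracle(pv), tolerance = 1e-12)
  counts <- rpois(260, 4)
  r3 <- flank_enrichment(setNames(counts, paste0("m", 1:260)), 5e4,
                         cbind(`1k` = rpois(260, 4)), 5e4)
  expect_equal(r3$p_adj, bh_oracle(r3$p), tolerance = 1e-12)
})

test_that("metamotif components match a union-find oracle", {
  ids <- paste0("run", rep(1:13, each = 20), ".m", rep(1:20, 13))
  # no off-diagonal edges: 260 singletons
  sim0 <- data.frame(motif_a = ids, motif_b = ids, p_value = 1e-9,
                     aln_length = 7)
  mm0 <- metamotif_components(sim0, motifs = ids)
  expect_equal(nrow(mm0$summary), 260)
  expect_true(all(mm0$summary$size == 1))

  # fully connected (via a connecting chain): one component of 260 with
  # members from all 13 runs
  chain <- data.frame(motif_a = ids[-length(ids)], motif_b = ids[-1],
                      p_value = 1e-9, aln_length = 7)
  mm1 <- metamotif_components(chain, motifs = ids)
  expect_equal(mm1$summary$size[1], 260)
  expect_equal(mm1$summary$n_runs[1], 13)

  # random sparse graph vs oracle
  set.seed(77)
  n <- 60
  verts <- paste0("r", sample(1:6, n, replace = TRUE), ".", seq_len(n))
  a <- sample(verts, 120, replace = TRUE)
  b <- sample(verts, 120, replace = TRUE)
  sim <- data.frame(motif_a = a, motif_b = b,
                    p_value = sample(c(1e-9, 0.5), 120, replace = TRUE),
                    aln_length = 10)
  sim <- sim[!duplicated(paste(pmin(sim$motif_a, sim$motif_b),
                               pmax(sim$motif_a, sim$motif_b))), ]
  mm <- metamotif_components(sim, motifs = verts)
  edge <- sim$p_value * sim$aln_length <= 0.001 & sim$motif_a != sim$motif_b
  oracle <- union_find_components(verts, sim$motif_a[edge], sim$motif_b[edge])
  got <- lapply(mm$components, sort)
  want <- lapply(oracle, sort)
  expect_setequal(unname(lapply(got, paste, collapse = ",")),
                  unname(lapply(want, paste, collapse = ",")))

  # asymmetric tables are rejected
  bad <- data.frame(motif_a = c("x", "y"), motif_b = c("y", "x"),
                    p_value = c(1e-9, 0.9), aln_length = 7)
  expect_error(metamotif_components(bad), "asymmetric")
})

test_that("empirical region nulls behave at the boundaries", {
  chrom <- random_dna(20000, seed = 14)
  regions <- Biostrings::DNAStringSet(c(r1 = paste(rep("GTGGAAA", 30), collapse = ""),
                                        r2 = as.character(random_dna(300, seed = 15))))
  # constant statistic: empirical P = 1
  r0 <- empirical_region_null(function(x) 7, regions, chrom, n_sets = 30,
                              seed = 2)
  expect_equal(r0$empirical_P, 1)
  # planted word enriched only in the real regions
  stat <- function(x) count_words(x, "GTGGAAA")$total
  r1 <- empirical_region_null(stat, regions, chrom, n_sets = 60, seed = 3)
  expect_lte(r1$empirical_P, 0.05)
  expect_error(empirical_region_null(stat, strrep("A", 30001), chrom),
               "longer")
})

test_that("MEME-minimal motif files parse to valid PWMs", {
  path <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.30 C 0.20 G 0.20 T 0.30", "",
    "MOTIF MM2.1 GTGGAAA",
    "letter-probability matrix: alength= 4 w= 3 nsites= 14 E= 1e-5",
    " 0.10 0.10 0.70 0.10",
    " 0.05 0.05 0.05 0.85",
    " 0.25 0.25 0.25 0.25",
    "",
    "MOTIF MM2.2",
    "letter-probability matrix: alength= 4 w= 2 nsites= 10 E= 1e-3",
    " 1.00 0.00 0.00 0.00",
    " 0.00 0.00 1.00 0.00"
  ), path)
  motifs <- read_meme_motifs(path)
  expect_length(motifs, 2)
  expect_equal(motifs[[1]]$motif_id, "MM2.1")
  expect_equal(motifs[[1]]$width, 3)
  expect_equal(motifs[[1]]$background, c(0.3, 0.2, 0.2, 0.3))
  expect_equal(motifs[[1]]$probs["G", 1], 0.7)
  expect_equal(motifs[[2]]$probs["A", 1], 1)
  expect_equal(colSums(motifs[[1]]$probs), rep(1, 3), ignore_attr = TRUE)
})
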