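test_that("pair-level null probability follows the closed form", {
  expect_equal(pair_null_prob(0), 0)
  expect_equal(pair_null_prob(1), 1)
  expect_equal(pair_null_prob(0.5), 0.75)
  expect_error(pair_null_prob(-0.1), "\\[0, 1\\]")
  expect_error(pair_null_prob(1.1), "\\[0, 1\\]")
})

test_that("closed-form q matches Monte-Carlo placement of uniform position pairs", {
  g <- tair10_genome()
  st <- subtelomere_stats(g, 1e5)
  n_mc <- 1e6
  hit <- withr::with_seed(2024, {
    draw <- function() {
      idx <- sample.int(nrow(g), n_mc, replace = TRUE, prob = g$length)
      pos <- floor(runif(n_mc) * g$length[idx])
      L <- g$length[idx]
      pos < pmin(1e5, L) | pos >= pmax(L - 1e5, 0)
    }
    draw() | draw()
  })
  se <- sqrt(st$null_prob * (1 - st$null_prob) / n_mc)
  expect_lt(abs(mean(hit) - st$null_prob), 3 * se)
})

test_that("binomial upper tail equals direct pmf enumeration", {
  # toy genomes give a spread of q values without bypassing the geometry
  geoms <- list(list(g = toy_genome(rep(1e5, 10)), w = 500),    # q ~ 0.02
                list(g = toy_genome(rep(1e5, 10)), w = 5000),   # q ~ 0.19
                list(g = toy_genome(rep(1e5, 10)), w = 25000))  # q = 0.75
  for (gm in geoms) {
    q <- subtelomere_stats(gm$g, gm$w)$null_prob
    for (n in c(1, 5, 10, 20)) {
      for (k in 0:n) {
        got <- enrichment_test(fusion_counts(n, k), gm$g, gm$w)
        expect_equal(got$p.value, enum_binom_upper(k, n, q), tolerance = 1e-12)
      }
    }
  }
})

test_that("k = 0 gives p = 1 and p decreases as k grows", {
  g <- toy_genome(rep(1e6, 5))
  t0 <- enrichment_test(fusion_counts(100, 0), g, 5e4)
  expect_equal(t0$p.value, 1)
  p_seq <- vapply(0:100, function(k) {
    enrichment_test(fusion_counts(100, k), g, 5e4)$log10_p
  }, numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))
})

test_that("extreme significance is preserved in log space", {
  t <- enrichment_test(fusion_counts(28748, 1735), tair10_genome(), 1e5)
  expect_lt(t$log10_p, -400)
  expect_gte(t$p.value, 0)
  expect_match(format(t$log10_p), "-4")
  out <- capture.output(print(t))
  expect_true(any(grepl("< 1e-300", out)))
})

test_that("pair-binomial and mate-hypergeometric variants agree within 10x", {
  # simulated uniform-background libraries on a 2e7 bp toy genome: the
  # sampling-without-replacement correction is negligible at this scale
  for (seed in 1:3) {
    cfg <- sim_config(chrom_lengths = rep(2e6, 10), n_pairs = 4000,
                      discordant_frac = 0.5, theta = 0, fusion_zone = 1e5,
                      seed = seed)
    counts <- glance(scan_pairs(simulate_library(cfg)$alignments, cfg$genome,
                                window = 1e5))
    pb <- enrichment_test(counts, cfg$genome, 1e5)$log10_p
    ph <- enrichment_test(counts, cfg$genome, 1e5,
                          method = "hypergeometric")$log10_p
    expect_lt(abs(pb - ph), 1)
  }
})

test_that("enrichment preconditions are enforced", {
  g <- toy_genome(rep(1e6, 2))
  expect_error(enrichment_test(fusion_counts(10, 5), g, 1e5,
                               method = "hypergeometric", m = 11),
               "k <= m <= 2k")
  expect_error(fusion_counts(10, 11), "k_subtel <= n_inter")
  expect_error(fusion_counts(10, 5, 4), "m_subtel_mates")
})

test_that("fold enrichment is plain arithmetic on the proportions", {
  expect_equal(fold_enrichment(fusion_counts(100, 20), fusion_counts(100, 10)), 2)
  expect_equal(fold_enrichment(fusion_counts(500, 37), fusion_counts(500, 37)), 1)
  expect_equal(fold_enrichment(fusion_counts(28748, 1735), fusion_counts(23808, 449)),
               (1735 / 28748) / (449 / 23808))
  # invariant under common scaling of all four counts
  expect_equal(fold_enrichment(fusion_counts(700, 210), fusion_counts(1400, 140)),
               fold_enrichment(fusion_counts(70, 21), fusion_counts(140, 14)))
  expect_error(fold_enrichment(fusion_counts(100, 5), fusion_counts(100, 0)),
               "compare_libraries")
})

test_that("chi-square equals the closed-form 2x2 expression", {
  cmp <- compare_libraries(fusion_counts(28748, 1735), fusion_counts(23808, 449))
  expect_equal(cmp$statistic, chisq_closed_form(1735, 27013, 449, 23359),
               tolerance = 1e-12)
  expect_equal(cmp$statistic, 562.9332, tolerance = 1e-6)
  expect_lt(cmp$log10_p, -15)

  # equal proportions: statistic 0, p 1
  eq <- compare_libraries(fusion_counts(100, 10), fusion_counts(100, 10))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  # Yates correction shrinks the statistic
  yates <- compare_libraries(fusion_counts(100, 20), fusion_counts(100, 10),
                             correct = TRUE)
  plain <- compare_libraries(fusion_counts(100, 20), fusion_counts(100, 10))
  expect_lt(yates$statistic, plain$statistic)

  expect_error(compare_libraries(fusion_counts(100, 0), fusion_counts(100, 0)),
               "zero margin")
})

test_that("the telomeric-fraction estimator inverts the mixture exactly", {
  g <- toy_genome(rep(1e6, 5))
  q <- subtelomere_stats(g, 5e4)$null_prob
  for (theta in c(0, 0.3, 0.9)) {
    kn <- theta + (1 - theta) * q      # noiseless mixture proportion
    n <- 100000
    est <- estimate_telomeric_fraction(fusion_counts(n, round(kn * n)), g, 5e4)
    expect_equal(est, theta, tolerance = 1e-4)
  }
})

test_that("tidy and glance return one-row tibbles for test objects", {
  t <- enrichment_test(fusion_counts(100, 10), toy_genome(rep(1e6, 3)), 1e5)
  expect_s3_class(tidy(t), "tbl_df")
  expect_equal(nrow(tidy(t)), 1L)
  expect_equal(tidy(t), glance(t))
  cmp <- compare_libraries(fusion_counts(100, 20), fusion_counts(100, 10))
  td <- tidy(cmp)
  expect_equal(td[, c("k1", "n1", "k2", "n2")],
               tibble::tibble(k1 = 20, n1 = 100, k2 = 10, n2 = 100))
})
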