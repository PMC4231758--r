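base_cfg <- function(...) {
  args <- utils::modifyList(
    list(chrom_lengths = rep(1e6, 5), n_pairs = 1000L,
         discordant_frac = 0.2, theta = 0.5, fusion_zone = 5e4,
         insert_mean = 400, insert_sd = 50, read_length = 100,
         seed = 99),
    list(...))
  do.call(sim_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(rep(1e6, 2), theta = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(rep(1e6, 2), fusion_zone = 50, read_length = 100),
               "fusion_zone")
  expect_error(sim_config(rep(1e6, 2), insert_mean = 150, read_length = 100),
               "insert_mean")
  expect_error(sim_config(c(1e6, -5)), "positive")
  expect_error(simulate_junctions(sim_config(1e6), 10), "2 chromosomes")
})

test_that("identical configurations reproduce byte-identical output", {
  cfg <- base_cfg()
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a$alignments, b$alignments)
  expect_identical(a$truth, b$truth)
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, s1); write_sam(b, s2)
  expect_identical(readLines(s1), readLines(s2))
  # and a different seed changes it
  expect_false(identical(
    simulate_library(base_cfg(seed = 100))$truth, a$truth))
})

test_that("junction types honour their geometric definitions", {
  cfg <- base_cfg(theta = 1, fusion_zone = 1000, read_length = 50,
                  insert_mean = 300)
  jn <- simulate_junctions(cfg, 500)
  expect_true(all(jn$type == "telomeric"))
  expect_true(all(jn$chromA != jn$chromB))
  near_end <- function(chrom, pos, zone) {
    L <- cfg$genome$length[match(chrom, cfg$genome$chrom)]
    pos < zone | pos >= L - zone
  }
  expect_true(all(near_end(jn$chromA, jn$posA, 1000)))
  expect_true(all(near_end(jn$chromB, jn$posB, 1000)))

  expect_equal(nrow(simulate_junctions(cfg, 0)), 0L)
})

test_that("uniform junctions hit subtelomeres at the closed-form null rate", {
  cfg <- base_cfg(theta = 0)
  n_j <- 10000
  jn <- simulate_junctions(cfg, n_j)
  q <- subtelomere_stats(cfg$genome, 5e4)$null_prob
  sub <- flag_subtelomeric(jn, cfg$genome, 5e4, chrom = "chromA", pos = "posA")$subtelomeric |
    flag_subtelomeric(jn, cfg$genome, 5e4, chrom = "chromB", pos = "posB")$subtelomeric
  se <- sqrt(q * (1 - q) / n_j)
  expect_lt(abs(mean(sub) - q), 3 * se)
})

test_that("a library with no discordant pairs scans to zero interchromosomal", {
  lib <- simulate_library(base_cfg(discordant_frac = 0))
  counts <- glance(scan_pairs(lib$alignments, lib$genome, window = 5e4))
  expect_equal(counts$n_inter, 0L)
  expect_equal(counts$pairs_passing, 1000L)
})

test_that("scanner counts equal the truth-table tallies on clean output", {
  cfg <- sim_config(chrom_lengths = rep(1e6, 5), n_pairs = 10000,
                    discordant_frac = 0.1, theta = 0.8, fusion_zone = 5e4,
                    insert_mean = 400, insert_sd = 50, low_mapq_fraction = 0,
                    seed = 31)
  lib <- simulate_library(cfg)
  counts <- glance(scan_pairs(lib$alignments, lib$genome, window = 5e4))
  truth <- lib$truth
  disc <- truth[truth$class == "discordant", ]
  s1 <- flag_subtelomeric(disc, lib$genome, 5e4, chrom = "chrom1", pos = "pos1")$subtelomeric
  s2 <- flag_subtelomeric(disc, lib$genome, 5e4, chrom = "chrom2", pos = "pos2")$subtelomeric
  expect_equal(counts$n_inter, nrow(disc))
  expect_equal(counts$n_inter, 1000L)
  expect_equal(counts$k_subtel, sum(s1 | s2))
  expect_equal(counts$m_subtel_mates, sum(s1) + sum(s2))
})

test_that("emitted SAM is valid and mate fields are mutually consistent", {
  lib <- simulate_library(base_cfg())
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(lib, sam)
  # Rsamtools SAM->BAM conversion enforces header/flag/coordinate validity
  back <- read_alignments(sam, genome = lib$genome)
  expect_equal(nrow(back), 2L * 1000L)
  r1 <- back[bitwAnd(back$flag, 0x40L) != 0L, ]
  r2 <- back[bitwAnd(back$flag, 0x80L) != 0L, ]
  r2 <- r2[match(r1$qname, r2$qname), ]
  expect_equal(r1$mate_chrom, r2$chrom)
  expect_equal(r1$mate_pos, r2$pos)
  expect_equal(r2$mate_chrom, r1$chrom)
  expect_equal(r2$mate_pos, r1$pos)
  # positions within chromosome bounds
  L <- lib$genome$length[match(back$chrom, lib$genome$chrom)]
  expect_true(all(back$pos >= 0 & back$pos < L))
  # scanning the file agrees with scanning the in-memory table
  expect_equal(glance(scan_pairs(sam, lib$genome, window = 5e4)),
               glance(scan_pairs(lib$alignments, lib$genome, window = 5e4)))
})

test_that("low-MAPQ records are filtered out of passing pairs", {
  lib <- simulate_library(base_cfg(low_mapq_fraction = 0.3))
  counts <- glance(scan_pairs(lib$alignments, lib$genome, window = 5e4))
  expect_lt(counts$pairs_passing, 1000L)
  expect_equal(counts$pairs_seen, 1000L)
  # with the threshold below mapq_low everything passes again
  all_in <- glance(scan_pairs(lib$alignments, lib$genome, window = 5e4,
                              mapq_min = 0))
  expect_equal(all_in$pairs_passing, 1000L)
})

test_that("a fusion-rich library separates from a background library", {
  run <- function(theta, seed) {
    cfg <- sim_config(chrom_lengths = rep(1e6, 5), n_pairs = 2000,
                      discordant_frac = 0.5, theta = theta, fusion_zone = 5e4,
                      insert_mean = 400, insert_sd = 50, seed = seed)
    glance(scan_pairs(simulate_library(cfg)$alignments, cfg$genome, window = 5e4))
  }
  hits <- vapply(1:6, function(seed) {
    cmp <- compare_libraries(run(0.8, seed), run(0.05, seed + 1000))
    cmp$fold > 1 && cmp$p.value < 0.01
  }, logical(1))
  expect_gte(sum(hits), 5L)
})

test_that("truth tables round-trip through the TSV writer", {
  lib <- simulate_library(base_cfg(n_pairs = 200))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_truth(lib, p)
  expect_match(readLines(p, n = 1), "seed=99")
  back <- readr::read_tsv(p, comment = "#", show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(lib$truth))
})
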