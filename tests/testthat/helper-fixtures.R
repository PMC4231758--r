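# Fixture builders shared across test files. All coordinates are 0-based.

toy_genome <- function(lengths = c(1e6, 1e6), names = NULL) {
  if (is.null(names)) names <- paste0("chr", seq_along(lengths))
  tibble::tibble(chrom = names, length = as.numeric(lengths))
}

# one primary alignment record in the internal schema
aln_record <- function(qname, chrom, pos, mate_chrom, mate_pos,
                       mapq = 42, read1 = TRUE, flag_extra = 0L) {
  flag <- 0x1 + (if (read1) 0x40 else 0x80) + flag_extra
  tibble::tibble(qname = qname, flag = as.integer(flag), chrom = chrom,
                 pos = pos, mapq = as.integer(mapq),
                 mate_chrom = mate_chrom, mate_pos = mate_pos)
}

# both primary records of a mate pair
aln_pair <- function(qname, chrom1, pos1, chrom2, pos2,
                     mapq1 = 42, mapq2 = 42) {
  dplyr::bind_rows(
    aln_record(qname, chrom1, pos1, chrom2, pos2, mapq = mapq1, read1 = TRUE),
    aln_record(qname, chrom2, pos2, chrom1, pos1, mapq = mapq2, read1 = FALSE)
  )
}

# Hand-enumerated scan fixture on a 2 x 1 Mb genome, window 100 kb.
# Expected (by manual enumeration, see comments):
#   pairs_seen = 7, pairs_passing = 6, n_inter = 3, n_intra = 3,
#   k_subtel = 2, m_subtel_mates = 2
scan_fixture <- function() {
  dplyr::bind_rows(
    aln_pair("intra1", "chr1", 400000, "chr1", 400450),  # proper, mid
    aln_pair("intra2", "chr1", 250000, "chr1", 250450),  # proper, mid
    aln_pair("intra3", "chr2", 600000, "chr2", 600450),  # proper, mid
    aln_pair("inter1", "chr1", 50000, "chr2", 500000),   # inter, mate1 subtel
    aln_pair("inter2", "chr1", 500000, "chr2", 50000),   # inter, mate2 subtel
    aln_pair("inter3", "chr1", 500000, "chr2", 500000),  # inter, no subtel
    aln_pair("lowq1", "chr1", 50000, "chr2", 500000, mapq2 = 5) # fails MAPQ
  )
}

scan_fixture_expected <- tibble::tibble(
  pairs_seen = 7L, pairs_passing = 6L, n_inter = 3L, n_intra = 3L,
  k_subtel = 2L, m_subtel_mates = 2L, skipped = 0L
)

# independent closed-form Pearson chi-square for a 2x2 table given as
# (a, b) = row 1 and (c, d) = row 2
chisq_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force subtelomere membership: linear scan over explicit intervals
brute_force_subtel <- function(chrom, pos, intervals) {
  vapply(seq_along(chrom), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start <= pos[i] & pos[i] < intervals$end)
  }, logical(1))
}

# independent upper-tail binomial probability by direct pmf enumeration
enum_binom_upper <- function(k, n, q) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * q^(k:n) * (1 - q)^(n - (k:n)))
}
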