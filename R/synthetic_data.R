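#' Simulation configuration
#'
#' Bundles the parameters of the paired-end library simulator. The
#' generative model targets the alignment level directly (coordinates,
#' flags, MAPQ): concordant background pairs are placed uniformly along the
#' genome, and a configurable fraction of pairs span interchromosomal
#' fusion junctions. Junctions are of two kinds: "telomeric" (both partner
#' positions within `fusion_zone` bp of a chromosome end, emulating
#' end-to-end fusions of eroded telomeres) and "uniform" (positions uniform
#' along the genome, chromosomes forced distinct).
#'
#' @param chrom_lengths Numeric vector of chromosome lengths in bp.
#' @param chrom_names Optional chromosome names (default `chr1`, `chr2`, ...).
#' @param n_pairs Total read pairs to simulate.
#' @param discordant_frac Fraction of pairs that span a fusion junction.
#' @param theta Fraction of junctions that are telomeric-type, in \[0, 1\].
#' @param fusion_zone Width D in bp of the terminal zone within which a
#'   telomeric junction partner lies (erosion-like uniform offset in
#'   \[0, D) from the chromosome end). Defaults to 100 kb so truth labels
#'   and the default analysis window coincide; the two are independent
#'   knobs.
#' @param insert_mean,insert_sd Insert-size model, bp; draws are truncated
#'   at twice the read length.
#' @param read_length Read length in bp.
#' @param mapq_high MAPQ assigned to well-mapped records.
#' @param mapq_low,low_mapq_fraction A `low_mapq_fraction` of records is
#'   assigned `mapq_low` (below the default scan filter) instead.
#' @param seed RNG seed; identical configurations produce byte-identical
#'   SAM and truth output.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(chrom_lengths = rep(1e6, 5), n_pairs = 1000, theta = 0.8)
#' @export
sim_config <- function(chrom_lengths, chrom_names = NULL,
                       n_pairs = 10000, discordant_frac = 0.1, theta = 0.8,
                       fusion_zone = 1e5, insert_mean = 500, insert_sd = 50,
                       read_length = 100, mapq_high = 42, mapq_low = 3,
                       low_mapq_fraction = 0, seed = 1) {
  if (length(chrom_lengths) < 1L || any(chrom_lengths <= 0)) {
    abort("chrom_lengths must be positive")
  }
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_along(chrom_lengths))
  if (anyDuplicated(chrom_names)) abort("chromosome names must be unique")
  for (p in c(discordant_frac = discordant_frac, theta = theta,
              low_mapq_fraction = low_mapq_fraction)) {
    if (p < 0 || p > 1) abort("fractions must lie in [0, 1]")
  }
  if (fusion_zone < read_length) abort("fusion_zone must be >= read_length")
  if (insert_mean <= 2 * read_length) abort("insert_mean must exceed 2 * read_length")
  if (mapq_low >= mapq_high) abort("mapq_low must be below mapq_high")
  structure(
    list(genome = tibble::tibble(chrom = chrom_names,
                                 length = as.numeric(chrom_lengths)),
         n_pairs = as.integer(n_pairs),
         discordant_frac = discordant_frac, theta = theta,
         fusion_zone = fusion_zone,
         insert_mean = insert_mean, insert_sd = insert_sd,
         read_length = as.integer(read_length),
         mapq_high = as.integer(mapq_high), mapq_low = as.integer(mapq_low),
         low_mapq_fraction = low_mapq_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Paired-end fusion simulator configuration\n")
  cat(sprintf("  genome: %d chromosomes, %s bp\n", nrow(x$genome),
              format(sum(x$genome$length), big.mark = ",")))
  cat(sprintf("  pairs:  %s (discordant fraction %.3g, theta %.3g)\n",
              format(x$n_pairs, big.mark = ","), x$discordant_frac, x$theta))
  cat(sprintf("  reads:  %d bp, insert %g +/- %g, fusion zone %s bp, seed %d\n",
              x$read_length, x$insert_mean, x$insert_sd,
              format(x$fusion_zone, scientific = FALSE, big.mark = ","), x$seed))
  invisible(x)
}

# uniform genome positions: chromosome weighted by length, then uniform bp
draw_uniform_positions <- function(genome, n) {
  idx <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  tibble::tibble(idx = idx, chrom = genome$chrom[idx],
                 pos = floor(runif(n) * genome$length[idx]))
}

sim_junctions_impl <- function(genome, count, theta, zone) {
  if (nrow(genome) < 2L) abort("junction simulation needs at least 2 chromosomes")
  if (count == 0L) {
    return(tibble::tibble(junction_id = integer(), type = character(),
                          chromA = character(), posA = numeric(),
                          endA = character(), chromB = character(),
                          posB = numeric(), endB = character()))
  }
  telomeric <- runif(count) < theta
  n_chrom <- nrow(genome)
  out <- tibble::tibble(junction_id = seq_len(count),
                        type = ifelse(telomeric, "telomeric", "uniform"),
                        chromA = NA_character_, posA = NA_real_,
                        endA = NA_character_, chromB = NA_character_,
                        posB = NA_real_, endB = NA_character_)

  draw_end <- function(n) {
    # an "end" is (chromosome index, L or R terminus), uniform over all ends
    e <- sample.int(2L * n_chrom, n, replace = TRUE)
    list(idx = (e - 1L) %/% 2L + 1L, side = c("L", "R")[(e - 1L) %% 2L + 1L])
  }
  end_pos <- function(idx, side, zone) {
    L <- genome$length[idx]
    off <- floor(runif(length(idx)) * pmin(zone, L))
    ifelse(side == "L", off, L - 1 - off)
  }

  n_tel <- sum(telomeric)
  if (n_tel > 0L) {
    a <- draw_end(n_tel)
    b <- draw_end(n_tel)
    while (any(clash <- b$idx == a$idx)) {
      redo <- draw_end(sum(clash))
      b$idx[clash] <- redo$idx
      b$side[clash] <- redo$side
    }
    out$chromA[telomeric] <- genome$chrom[a$idx]
    out$posA[telomeric] <- end_pos(a$idx, a$side, zone)
    out$endA[telomeric] <- a$side
    out$chromB[telomeric] <- genome$chrom[b$idx]
    out$posB[telomeric] <- end_pos(b$idx, b$side, zone)
    out$endB[telomeric] <- b$side
  }
  n_uni <- count - n_tel
  if (n_uni > 0L) {
    a <- draw_uniform_positions(genome, n_uni)
    b <- draw_uniform_positions(genome, n_uni)
    while (any(clash <- b$idx == a$idx)) {
      redo <- draw_uniform_positions(genome, sum(clash))
      b[clash, ] <- redo
    }
    out$chromA[!telomeric] <- a$chrom
    out$posA[!telomeric] <- a$pos
    out$chromB[!telomeric] <- b$chrom
    out$posB[!telomeric] <- b$pos
  }
  out
}

#' Simulate interchromosomal fusion junctions
#'
#' Draws `count` junctions from the configured generative model: with
#' probability `theta` a junction is telomeric (each partner is a uniformly
#' chosen chromosome end, eroded inward by a uniform offset within the
#' fusion zone), otherwise both partners are uniform genome positions;
#' partner chromosomes are always distinct.
#'
#' @param config A [sim_config()].
#' @param count Number of junctions.
#' @return A tibble with columns `junction_id`, `type` (`"telomeric"` or
#'   `"uniform"`), `chromA`, `posA`, `endA`, `chromB`, `posB`, `endB`
#'   (`endA`/`endB` give the fused terminus, `NA` for uniform junctions).
#' @export
simulate_junctions <- function(config, count) {
  stopifnot(inherits(config, "sim_config"), count >= 0)
  withr::with_seed(config$seed,
                   sim_junctions_impl(config$genome, as.integer(count),
                                      config$theta, config$fusion_zone))
}

#' Simulate a paired-end alignment library with junction truth
#'
#' Generates a full library at the alignment level: background concordant
#' pairs placed uniformly (proper-pair flags, truncated-normal insert), and
#' junction-spanning discordant pairs whose two mates map to the two
#' partner chromosomes of a fusion junction, flanking the junction point at
#' insert-model distances. No bases are simulated beyond placeholder
#' sequence; the model targets coordinates, flags, and MAPQ.
#'
#' When `junctions` is `NULL` (default) one junction is drawn per
#' discordant pair, so pair-level truth tallies are independent draws from
#' the junction model. Supplying a junction table instead assigns each
#' discordant pair a junction uniformly at random from it.
#'
#' @inheritParams simulate_junctions
#' @param junctions Optional junction tibble from [simulate_junctions()];
#'   must be non-empty when the configuration has discordant pairs.
#' @return An object of class `fusion_sim`: a list with `genome`,
#'   `config`, `junctions`, `alignments` (one row per read, same schema as
#'   [read_alignments()] plus `cigar`/`seq`/`qual`/`tlen`), and `truth`
#'   (one row per pair: `pair_id`, `class`, `junction_id`, `junction_type`,
#'   `chrom1`, `pos1`, `chrom2`, `pos2` — mapped mate positions, 0-based).
#' @examples
#' cfg <- sim_config(chrom_lengths = rep(1e6, 3), n_pairs = 100, seed = 42)
#' lib <- simulate_library(cfg)
#' dplyr::count(lib$truth, class)
#' @export
simulate_library <- function(config, junctions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- config$genome
  rl <- config$read_length
  if (any(genome$length < 2 * rl)) {
    abort("every chromosome must be at least twice the read length")
  }
  if (any(genome$length < config$insert_mean + 3 * config$insert_sd)) {
    warn("some chromosomes are shorter than insert_mean + 3 sd; inserts are clipped")
  }
  n_disc <- as.integer(round(config$discordant_frac * config$n_pairs))
  n_conc <- config$n_pairs - n_disc
  if (!is.null(junctions) && n_disc > 0L && nrow(junctions) == 0L) {
    abort("junction table is empty but the configuration has discordant pairs")
  }

  withr::with_seed(config$seed, {
    if (is.null(junctions)) {
      jn <- sim_junctions_impl(genome, n_disc, config$theta, config$fusion_zone)
      assign_id <- seq_len(n_disc)
    } else {
      jn <- junctions
      assign_id <- if (n_disc > 0L) sample.int(nrow(jn), n_disc, replace = TRUE)
                   else integer()
    }

    draw_insert <- function(n, L) {
      ins <- round(rnorm(n, config$insert_mean, config$insert_sd))
      pmin(pmax(ins, 2 * rl), L)
    }

    # concordant background
    conc <- draw_uniform_positions(genome, n_conc)
    Lc <- genome$length[conc$idx]
    ins <- draw_insert(n_conc, Lc)
    start <- floor(runif(n_conc) * (Lc - ins + 1))
    conc_p1 <- start
    conc_p2 <- start + ins - rl

    # discordant, junction-spanning
    j <- jn[assign_id, , drop = FALSE]
    place_mate <- function(chrom, pos, end_side, slack_side) {
      L <- genome$length[match(chrom, genome$chrom)]
      # inward from a fused terminus; random direction for uniform junctions
      dir <- ifelse(is.na(end_side),
                    ifelse(runif(length(chrom)) < 0.5, 1, -1),
                    ifelse(end_side == "L", 1, -1))
      left <- ifelse(dir > 0, pos + slack_side, pos - slack_side - rl)
      pmin(pmax(left, 0), L - rl)
    }
    ins_d <- draw_insert(n_disc, Inf)
    slack <- ins_d - 2 * rl
    d1 <- floor(runif(n_disc) * (slack + 1))
    d2 <- slack - d1
    disc_p1 <- place_mate(j$chromA, j$posA, j$endA, d1)
    disc_p2 <- place_mate(j$chromB, j$posB, j$endB, d2)

    pair_id <- sprintf("pair%07d", seq_len(config$n_pairs))
    truth <- tibble::tibble(
      pair_id = pair_id,
      class = rep(c("concordant", "discordant"), c(n_conc, n_disc)),
      junction_id = c(rep(NA_integer_, n_conc), j$junction_id),
      junction_type = c(rep(NA_character_, n_conc), j$type),
      chrom1 = c(conc$chrom, j$chromA), pos1 = c(conc_p1, disc_p1),
      chrom2 = c(conc$chrom, j$chromB), pos2 = c(conc_p2, disc_p2)
    )

    n_rec <- 2L * config$n_pairs
    mapq <- ifelse(runif(n_rec) < config$low_mapq_fraction,
                   config$mapq_low, config$mapq_high)
    flag1 <- rep(c(99L, 97L), c(n_conc, n_disc))
    flag2 <- rep(c(147L, 145L), c(n_conc, n_disc))
    same <- truth$chrom1 == truth$chrom2
    tlen1 <- ifelse(same, truth$pos2 + rl - truth$pos1, 0)
    alignments <- tibble::tibble(
      qname = rep(truth$pair_id, 2L),
      flag = c(flag1, flag2),
      chrom = c(truth$chrom1, truth$chrom2),
      pos = c(truth$pos1, truth$pos2),
      mapq = as.integer(mapq),
      mate_chrom = c(truth$chrom2, truth$chrom1),
      mate_pos = c(truth$pos2, truth$pos1),
      cigar = paste0(rl, "M"),
      seq = strrep("N", rl),
      qual = strrep("I", rl),
      tlen = c(tlen1, -tlen1)
    ) |>
      dplyr::arrange(.data$qname, .data$flag)

    structure(list(genome = genome, config = config, junctions = jn,
                   alignments = alignments, truth = truth),
              class = "fusion_sim")
  })
}

#' @export
print.fusion_sim <- function(x, ...) {
  cat("Simulated paired-end library\n")
  cat(sprintf("  %s pairs (%s discordant), %d chromosomes, seed %d\n",
              format(x$config$n_pairs, big.mark = ","),
              format(sum(x$truth$class == "discordant"), big.mark = ","),
              nrow(x$genome), x$config$seed))
  invisible(x)
}

#' Write a simulated library (or any alignment table) as SAM
#'
#' Emits a valid SAM text file: `@HD`/`@SQ` header from the genome table,
#' then one line per record. Positions are converted back to SAM's 1-based
#' convention.
#'
#' @param x A `fusion_sim` object or an alignment tibble.
#' @param path Output path (conventionally `.sam`).
#' @param genome Chromosome-size tibble for the header; taken from `x` when
#'   it is a `fusion_sim`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path, genome = NULL) {
  if (inherits(x, "fusion_sim")) {
    genome <- x$genome
    aln <- x$alignments
  } else {
    aln <- tibble::as_tibble(x)
  }
  check_genome(genome)
  col_or <- function(name, default) {
    if (name %in% names(aln)) aln[[name]] else rep(default, nrow(aln))
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%s", genome$chrom,
            format(genome$length, scientific = FALSE, trim = TRUE))
  )
  rnext <- ifelse(aln$mate_chrom == aln$chrom, "=", aln$mate_chrom)
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
    aln$qname, aln$flag, aln$chrom,
    format(aln$pos + 1, scientific = FALSE, trim = TRUE),
    # a CIGAR-less mapped record is demoted to unmapped by BAM converters,
    # so default to a minimal 1M placeholder (leftmost position is all the
    # scan uses)
    as.integer(aln$mapq), col_or("cigar", "1M"), rnext,
    format(aln$mate_pos + 1, scientific = FALSE, trim = TRUE),
    format(col_or("tlen", 0), scientific = FALSE, trim = TRUE),
    col_or("seq", "*"), col_or("qual", "*")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the truth table of a simulated library
#'
#' Tab-separated truth table, one row per pair, with the simulation seed
#' recorded in a comment header line.
#'
#' @param sim A `fusion_sim` object.
#' @param path Output path (conventionally `.truth.tsv`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "fusion_sim"))
  writeLines(sprintf("# telofuse truth table; seed=%d", sim$config$seed), path)
  readr::write_tsv(sim$truth, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Emit placeholder FASTQ for a simulated library
#'
#' Interoperability demo only: writes the simulated reads as FASTQ with
#' random bases and uniform quality, for feeding an external aligner. The
#' bases carry no signal (the simulator is alignment-level), so this
#' emitter is not part of the validated pipeline.
#'
#' @param sim A `fusion_sim` object.
#' @param prefix Output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(sim, prefix) {
  stopifnot(inherits(sim, "fusion_sim"))
  rl <- sim$config$read_length
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (i in 1:2) {
    aln <- sim$alignments[has_flag(sim$alignments$flag, if (i == 1) FLAG_READ1 else FLAG_READ2), ]
    bases <- vapply(seq_len(nrow(aln)), function(j) {
      paste(sample(c("A", "C", "G", "T"), rl, replace = TRUE), collapse = "")
    }, character(1))
    writeLines(c(rbind(paste0("@", aln$qname, "/", i), bases, "+",
                       strrep("I", rl))), paths[i])
  }
  invisible(paths)
}
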