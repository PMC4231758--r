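#' Read a chromosome-size table
#'
#' Reads reference geometry from a UCSC-style `chrom.sizes` file (name and
#' length in the first two whitespace-separated columns) or a samtools
#' `.fai` index (extra columns are ignored).
#'
#' @param path Path to a `chrom.sizes` or `.fai` file.
#' @return A tibble with columns `chrom` (character) and `length` (double,
#'   bp), one row per chromosome in file order.
#' @examples
#' genome <- tair10_genome()
#' genome_size(genome)
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("chromosome-size file not found: ", path))
  }
  raw <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character", fill = TRUE),
    error = function(e) abort(paste0("cannot parse '", path, "': ", conditionMessage(e)))
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort(paste0("'", path, "' has no name/length rows"))
  }
  genome <- tibble::tibble(
    chrom  = as.character(raw[[1L]]),
    length = suppressWarnings(as.numeric(raw[[2L]]))
  )
  bad <- which(is.na(genome$length) | genome$length <= 0 |
                 genome$length != floor(genome$length))
  if (length(bad) > 0L) {
    abort(sprintf("row %d ('%s'): length must be a positive integer, got '%s'",
                  bad[1L], genome$chrom[bad[1L]], raw[[2L]][bad[1L]]))
  }
  dup <- genome$chrom[duplicated(genome$chrom)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate chromosome name(s): ", paste(unique(dup), collapse = ", ")))
  }
  genome
}

#' Arabidopsis TAIR10 nuclear chromosome lengths
#'
#' The five nuclear chromosome lengths of the TAIR10 assembly, shipped with
#' the package so the uniform-recombination null for this genome can be
#' built without downloads.
#'
#' @return A tibble with columns `chrom` and `length` (bp).
#' @export
tair10_genome <- function() {
  read_chrom_sizes(system.file("extdata", "tair10.chrom.sizes",
                               package = "telofuse", mustWork = TRUE))
}

#' Total genome size
#'
#' @param genome A chromosome-size tibble from [read_chrom_sizes()].
#' @return Total length in bp.
#' @export
genome_size <- function(genome) {
  check_genome(genome)
  sum(genome$length)
}

#' Subtelomeric intervals
#'
#' The subtelomere of a chromosome is operationalised as the sequence within
#' `window` bp of either end of the assembled chromosome. Coordinates are
#' 0-based, half-open. When a chromosome is shorter than twice the window
#' the two terminal windows merge into a single interval covering it.
#'
#' @inheritParams genome_size
#' @param window Window width in bp (default 100,000, i.e. 100 kb).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based,
#'   half-open); zero rows when `window = 0`.
#' @examples
#' subtelomere_intervals(tair10_genome())
#' @export
subtelomere_intervals <- function(genome, window = 1e5) {
  check_genome(genome)
  check_window(window)
  if (window == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  purrr::pmap_dfr(genome, function(chrom, length) {
    if (length < 2 * window) {
      tibble::tibble(chrom = chrom, start = 0, end = length)
    } else {
      tibble::tibble(chrom = chrom,
                     start = c(0, length - window),
                     end   = c(window, length))
    }
  })
}

#' Subtelomeric span, fraction, and pair-level null probability
#'
#' Summarises the genome geometry at a given window width: total
#' subtelomeric span S = sum over chromosomes of min(2*window, length),
#' fraction f = S / G, and the pair-level null probability
#' q = 1 - (1 - f)^2 that at least one of two independent uniform genome
#' positions is subtelomeric.
#'
#' @inheritParams subtelomere_intervals
#' @return A one-row tibble with columns `n_chrom`, `genome_bp`, `window`,
#'   `subtel_bp`, `fraction`, `null_prob`.
#' @examples
#' subtelomere_stats(tair10_genome(), window = 1e5)
#' @export
subtelomere_stats <- function(genome, window = 1e5) {
  check_genome(genome)
  check_window(window)
  G <- sum(genome$length)
  S <- sum(pmin(2 * window, genome$length))
  f <- S / G
  tibble::tibble(n_chrom = nrow(genome), genome_bp = G, window = window,
                 subtel_bp = S, fraction = f, null_prob = pair_null_prob(f))
}

#' Flag subtelomeric positions
#'
#' Adds a logical `subtelomeric` column to a table of genomic positions,
#' true where the position lies within `window` bp of its chromosome's
#' nearer end (0-based, half-open test).
#'
#' @param x A data frame with a chromosome-name column and a 0-based
#'   position column.
#' @inheritParams subtelomere_intervals
#' @param chrom,pos Column names in `x` holding chromosome and position
#'   (defaults `"chrom"`, `"pos"`).
#' @return `x` as a tibble with an added logical column `subtelomeric`.
#' @examples
#' pts <- tibble::tibble(chrom = "Chr1", pos = c(0, 99999, 100000))
#' flag_subtelomeric(pts, tair10_genome())
#' @export
flag_subtelomeric <- function(x, genome, window = 1e5,
                              chrom = "chrom", pos = "pos") {
  check_genome(genome)
  check_window(window)
  x <- tibble::as_tibble(x)
  cv <- x[[chrom]]
  pv <- x[[pos]]
  if (is.null(cv) || is.null(pv)) {
    abort(sprintf("columns '%s' and '%s' are required", chrom, pos))
  }
  idx <- match(cv, genome$chrom)
  if (anyNA(idx)) {
    abort(paste0("unknown chromosome(s): ",
                 paste(unique(cv[is.na(idx)]), collapse = ", ")))
  }
  L <- genome$length[idx]
  if (any(pv < 0 | pv >= L)) {
    bad <- which(pv < 0 | pv >= L)[1L]
    abort(sprintf("position %s out of range [0, %s) on %s",
                  format(pv[bad], scientific = FALSE),
                  format(L[bad], scientific = FALSE), cv[bad]))
  }
  x$subtelomeric <- pv < pmin(window, L) | pv >= pmax(L - window, 0)
  x
}

#' Write subtelomeric intervals as BED
#'
#' @param intervals Interval tibble from [subtelomere_intervals()].
#' @param path Output path; 3-column BED, 0-based half-open, no header.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  out <- intervals[, c("chrom", "start", "end")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

# -- internal validation ------------------------------------------------

check_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort("genome must be a data frame with columns 'chrom' and 'length'")
  }
  if (nrow(genome) == 0L) abort("genome has no chromosomes")
  if (anyDuplicated(genome$chrom)) abort("genome has duplicate chromosome names")
  if (any(is.na(genome$length) | genome$length <= 0)) {
    abort("all chromosome lengths must be positive")
  }
  invisible(genome)
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) || window < 0) {
    abort("window must be a single non-negative number of bp")
  }
  invisible(window)
}
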