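#' Build an analysis report from pair-count summaries
#'
#' Pure formatting-and-testing layer: given one or two count summaries (no
#' raw alignments), computes the uniform-null enrichment test per library
#' and, for two libraries, the fold enrichment and chi-square comparison.
#' Re-running on the same counts, genome, and parameters reproduces the
#' report exactly.
#'
#' @param counts_a Count summary for the focal library (`fusion_scan`,
#'   [glance()] tibble, [fusion_counts()], or a path to a counts JSON
#'   written by [write_counts()]).
#' @param counts_b Optional count summary for the reference library.
#' @inheritParams enrichment_test
#' @param correct Yates continuity correction for the comparison.
#' @return An object of class `fusion_report` with elements `params`,
#'   `counts` (tibble, one row per library), `tests` (list of
#'   `fusion_test`), and `comparison` (`fusion_compare` or `NULL`).
#'   [tidy()] returns the per-library test results as a tibble.
#' @examples
#' build_report(fusion_counts(28748, 1735), fusion_counts(23808, 449),
#'              genome = tair10_genome())
#' @export
build_report <- function(counts_a, counts_b = NULL, genome, window = 1e5,
                         method = c("binomial", "hypergeometric"),
                         correct = FALSE) {
  method <- match.arg(method)
  load_one <- function(x) {
    if (is.character(x) && length(x) == 1L) x <- read_counts(x)
    resolve_counts(x)
  }
  counts_a <- load_one(counts_a)
  two <- !is.null(counts_b)
  if (two) counts_b <- load_one(counts_b)

  st <- subtelomere_stats(genome, window)
  libs <- if (two) list(A = counts_a, B = counts_b) else list(A = counts_a)
  tests <- purrr::map(libs, enrichment_test, genome = genome, window = window,
                      method = method)
  counts_tbl <- dplyr::bind_rows(purrr::map(libs, ~ tibble::as_tibble(.x)),
                                 .id = "library")
  comparison <- if (two) compare_libraries(counts_a, counts_b, correct = correct)
                else NULL
  structure(
    list(params = list(window = window, method = method, correct = correct,
                       geometry = st),
         counts = counts_tbl, tests = tests, comparison = comparison),
    class = "fusion_report"
  )
}

#' Run the full fusion-detection pipeline
#'
#' Scans one or two alignment files (or tibbles) against the same genome,
#' then builds the analysis report: per-library interchromosomal and
#' subtelomeric pair counts, the uniform-null enrichment test, and — when
#' two libraries are given — the fold enrichment and chi-square comparison.
#'
#' @param alignments_a Alignment tibble or SAM/BAM path for the focal
#'   library.
#' @param genome Chromosome-size tibble shared by both libraries (each SAM
#'   header is cross-checked against it).
#' @param alignments_b Optional second library (the reference).
#' @inheritParams build_report
#' @inheritParams scan_pairs
#' @return A `fusion_report` (see [build_report()]).
#' @export
run_pipeline <- function(alignments_a, genome, alignments_b = NULL,
                         window = 1e5, mapq_min = 20,
                         method = c("binomial", "hypergeometric"),
                         correct = FALSE) {
  method <- match.arg(method)
  scan_a <- scan_pairs(alignments_a, genome, window = window, mapq_min = mapq_min)
  scan_b <- if (!is.null(alignments_b)) {
    scan_pairs(alignments_b, genome, window = window, mapq_min = mapq_min)
  }
  rep <- build_report(scan_a, scan_b, genome = genome, window = window,
                      method = method, correct = correct)
  rep$params$mapq_min <- mapq_min
  rep
}

#' @exportS3Method generics::tidy
tidy.fusion_report <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$tests, tidy), .id = "library")
}

#' @exportS3Method generics::glance
glance.fusion_report <- function(x, ...) x$counts

#' @export
format.fusion_report <- function(x, ...) {
  st <- x$params$geometry
  out <- c(
    "== telofuse analysis report ==",
    sprintf("genome: %d chromosomes, %s bp; window %s bp; f = %.6f; q = %.6f",
            st$n_chrom, format(st$genome_bp, big.mark = ",", scientific = FALSE),
            format(st$window, scientific = FALSE, big.mark = ","),
            st$fraction, st$null_prob),
    sprintf("parameters: method = %s%s%s", x$params$method,
            if (isTRUE(x$params$correct)) ", Yates correction" else "",
            if (!is.null(x$params$mapq_min))
              sprintf(", MAPQ >= %d", x$params$mapq_min) else ""),
    ""
  )
  for (lib in names(x$tests)) {
    t <- x$tests[[lib]]
    out <- c(out,
      sprintf("library %s: n = %s interchromosomal pairs, k = %s subtelomeric (%.4f)",
              lib, format(t$n, big.mark = ","), format(t$k, big.mark = ","),
              t$k / max(t$n, 1)),
      sprintf("  enrichment: %.2f-fold over uniform null; p %s",
              t$effect, format_p(t$p.value, t$log10_p)))
  }
  if (!is.null(x$comparison)) {
    cmp <- x$comparison
    out <- c(out, "",
      sprintf("A vs B: fold enrichment = %.2f; X-squared = %.4g (df = 1), p %s",
              cmp$fold, cmp$statistic, format_p(cmp$p.value, cmp$log10_p)))
  }
  out
}

#' @export
print.fusion_report <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}
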