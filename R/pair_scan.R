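# SAM flag bits used by the unique-pair filter
FLAG_PAIRED <- 0x1
FLAG_PROPER <- 0x2
FLAG_UNMAPPED <- 0x4
FLAG_MATE_UNMAPPED <- 0x8
FLAG_REVERSE <- 0x10
FLAG_MATE_REVERSE <- 0x20
FLAG_READ1 <- 0x40
FLAG_READ2 <- 0x80
FLAG_SECONDARY <- 0x100
FLAG_DUP <- 0x400
FLAG_SUPPLEMENTARY <- 0x800

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), as.integer(bit)) != 0L

#' Read paired-end alignments into a tibble
#'
#' Loads alignment records from a SAM (text) or BAM file. SAM input is
#' converted to BAM internally via [Rsamtools::asBam()], so the file must
#' carry `@SQ` header lines. Positions are converted from SAM's 1-based
#' convention to 0-based at read time; all downstream coordinates are
#' 0-based, half-open.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param genome Optional chromosome-size tibble; when given, the file's
#'   `@SQ` header is cross-checked against it and mismatches are an error.
#' @return A tibble with columns `qname`, `flag`, `chrom`, `pos` (0-based
#'   leftmost), `mapq`, `mate_chrom`, `mate_pos` (0-based).
#' @export
read_alignments <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE, indexDestination = FALSE))
  }
  if (!is.null(genome)) {
    check_genome(genome)
    targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    bad <- setdiff(names(targets), genome$chrom)
    miss <- setdiff(genome$chrom, names(targets))
    shared <- intersect(names(targets), genome$chrom)
    neq <- shared[targets[shared] != genome$length[match(shared, genome$chrom)]]
    if (length(bad) + length(miss) + length(neq) > 0L) {
      abort(paste0(
        "alignment header disagrees with genome table:",
        if (length(bad)) paste0("\n  only in header: ", paste(bad, collapse = ", ")) else "",
        if (length(miss)) paste0("\n  only in genome: ", paste(miss, collapse = ", ")) else "",
        if (length(neq)) paste0("\n  length mismatch: ", paste(neq, collapse = ", ")) else ""
      ))
    }
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "mrnm", "mpos")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  tibble::tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    chrom = as.character(res$rname),
    pos = as.numeric(res$pos) - 1,
    mapq = as.integer(res$mapq),
    mate_chrom = as.character(res$mrnm),
    mate_pos = as.numeric(res$mpos) - 1
  )
}

#' Unique-pair alignment filter
#'
#' The operational proxy for "uniquely mapped" used throughout the package:
#' a record passes when it is paired, both mates are mapped, it is a
#' primary alignment (not secondary, not supplementary), it is not flagged
#' as a duplicate, and its mapping quality is at least `mapq_min`.
#'
#' @param alignments Alignment tibble from [read_alignments()].
#' @param mapq_min Minimum MAPQ (default 20).
#' @return A logical vector, one element per record.
#' @export
passes_unique_filter <- function(alignments, mapq_min = 20) {
  flag <- alignments$flag
  has_flag(flag, FLAG_PAIRED) &
    !has_flag(flag, FLAG_UNMAPPED) &
    !has_flag(flag, FLAG_MATE_UNMAPPED) &
    !has_flag(flag, FLAG_SECONDARY) &
    !has_flag(flag, FLAG_SUPPLEMENTARY) &
    !has_flag(flag, FLAG_DUP) &
    !is.na(alignments$mapq) & alignments$mapq >= mapq_min
}

#' Scan alignments for interchromosomal and subtelomeric mate pairs
#'
#' Collates primary alignment records by read name, keeps pairs in which
#' both mates pass [passes_unique_filter()], and classifies each pair as
#' interchromosomal (mates on different chromosomes) and as subtelomeric
#' (at least one mate's leftmost position within `window` bp of a
#' chromosome end). Record order in the input is irrelevant.
#'
#' @param alignments Alignment tibble (from [read_alignments()]) or a path
#'   to a SAM/BAM file.
#' @inheritParams subtelomere_intervals
#' @inheritParams passes_unique_filter
#' @param keep_pairs Keep the per-pair table (read name, both endpoints,
#'   subtelomeric mate count) in the result? Default `FALSE`.
#' @return An object of class `fusion_scan`. [glance()] returns the count
#'   summary as a one-row tibble with `pairs_seen`, `pairs_passing`,
#'   `n_inter`, `n_intra`, `k_subtel` (interchromosomal pairs with >= 1
#'   subtelomeric mate), `m_subtel_mates` (subtelomeric mates among
#'   interchromosomal pairs) and `skipped`; [tidy()] returns the per-pair
#'   table when kept.
#' @examples
#' cfg <- sim_config(chrom_lengths = rep(1e6, 3), n_pairs = 200, seed = 7)
#' lib <- simulate_library(cfg)
#' scan <- scan_pairs(lib$alignments, lib$genome, window = 5e4)
#' glance(scan)
#' @export
scan_pairs <- function(alignments, genome, window = 1e5, mapq_min = 20,
                       keep_pairs = FALSE) {
  check_genome(genome)
  check_window(window)
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignments(alignments, genome = genome)
  }
  need <- c("qname", "flag", "chrom", "pos", "mapq")
  if (!all(need %in% names(alignments))) {
    abort(paste0("alignments must have columns: ", paste(need, collapse = ", ")))
  }
  aln <- tibble::as_tibble(alignments)

  # malformed records: missing name/flag, or mapped but with an unusable
  # or out-of-range coordinate -> warn and skip
  mapped <- !has_flag(ifelse(is.na(aln$flag), 0L, aln$flag), FLAG_UNMAPPED)
  L <- genome$length[match(aln$chrom, genome$chrom)]
  malformed <- is.na(aln$qname) | is.na(aln$flag) |
    (mapped & (is.na(aln$chrom) | is.na(aln$pos) | is.na(L) |
                 aln$pos < 0 | aln$pos >= L))
  n_skipped <- sum(malformed)
  if (n_skipped > 0L) {
    warn(sprintf("skipping %d malformed alignment record(s)", n_skipped))
    aln <- aln[!malformed, , drop = FALSE]
  }

  primary <- has_flag(aln$flag, FLAG_PAIRED) &
    !has_flag(aln$flag, FLAG_SECONDARY) &
    !has_flag(aln$flag, FLAG_SUPPLEMENTARY)
  pairs_seen <- dplyr::n_distinct(aln$qname[primary])

  pass <- aln[primary & passes_unique_filter(aln, mapq_min), , drop = FALSE]
  per_name <- table(pass$qname)
  if (any(per_name > 2L)) {
    abort(paste0("corrupt input: read name(s) with more than two passing ",
                 "primary records: ",
                 paste(utils::head(names(per_name)[per_name > 2L], 5L), collapse = ", ")))
  }

  complete <- pass |>
    dplyr::filter(.data$qname %in% names(per_name)[per_name == 2L]) |>
    flag_subtelomeric(genome, window) |>
    dplyr::arrange(.data$qname, dplyr::desc(has_flag(.data$flag, FLAG_READ1)),
                   .data$chrom, .data$pos)
  pairs <- complete |>
    dplyr::group_by(.data$qname) |>
    dplyr::summarise(
      chrom1 = .data$chrom[1L], pos1 = .data$pos[1L],
      chrom2 = .data$chrom[2L], pos2 = .data$pos[2L],
      subtel_mates = sum(.data$subtelomeric),
      .groups = "drop"
    ) |>
    dplyr::mutate(interchromosomal = .data$chrom1 != .data$chrom2,
                  subtelomeric = .data$subtel_mates >= 1L)

  inter <- pairs[pairs$interchromosomal, , drop = FALSE]
  counts <- tibble::tibble(
    pairs_seen = pairs_seen,
    pairs_passing = nrow(pairs),
    n_inter = nrow(inter),
    n_intra = nrow(pairs) - nrow(inter),
    k_subtel = sum(inter$subtelomeric),
    m_subtel_mates = sum(inter$subtel_mates),
    skipped = n_skipped
  )
  structure(
    list(counts = counts,
         pairs = if (keep_pairs) pairs else NULL,
         params = list(window = window, mapq_min = mapq_min,
                       genome = genome)),
    class = "fusion_scan"
  )
}

#' Build a pair-count table by hand
#'
#' Convenience constructor for the count summary consumed by
#' [enrichment_test()] and [compare_libraries()], for use when the counts
#' come from a publication or an external pipeline rather than from
#' [scan_pairs()].
#'
#' @param n_inter Interchromosomal pair count n.
#' @param k_subtel Interchromosomal pairs with at least one subtelomeric
#'   mate, k.
#' @param m_subtel_mates Subtelomeric mate positions among interchromosomal
#'   pairs, m (defaults to `k_subtel`, its lower bound; k <= m <= 2k).
#' @return A one-row tibble.
#' @examples
#' fusion_counts(n_inter = 28748, k_subtel = 1735)
#' @export
fusion_counts <- function(n_inter, k_subtel, m_subtel_mates = k_subtel) {
  if (k_subtel < 0 || n_inter < k_subtel) abort("need 0 <= k_subtel <= n_inter")
  if (m_subtel_mates < k_subtel || m_subtel_mates > 2 * k_subtel) {
    abort("need k_subtel <= m_subtel_mates <= 2 * k_subtel")
  }
  tibble::tibble(n_inter = n_inter, k_subtel = k_subtel,
                 m_subtel_mates = m_subtel_mates)
}

#' @exportS3Method generics::glance
glance.fusion_scan <- function(x, ...) x$counts

#' @exportS3Method generics::tidy
tidy.fusion_scan <- function(x, ...) {
  if (is.null(x$pairs)) {
    abort("scan was run with keep_pairs = FALSE; no per-pair table to tidy")
  }
  x$pairs
}

#' @export
print.fusion_scan <- function(x, ...) {
  c0 <- x$counts
  cat("Fusion read-pair scan (window =",
      format(x$params$window, scientific = FALSE, big.mark = ","),
      "bp, MAPQ >=", x$params$mapq_min, ")\n")
  cat(sprintf("  pairs seen / passing:   %s / %s\n",
              format(c0$pairs_seen, big.mark = ","),
              format(c0$pairs_passing, big.mark = ",")))
  cat(sprintf("  interchromosomal (n):   %s\n", format(c0$n_inter, big.mark = ",")))
  cat(sprintf("  subtelomeric pairs (k): %s\n", format(c0$k_subtel, big.mark = ",")))
  cat(sprintf("  subtelomeric mates (m): %s\n", format(c0$m_subtel_mates, big.mark = ",")))
  if (c0$skipped > 0) cat(sprintf("  skipped records:        %s\n", c0$skipped))
  invisible(x)
}

#' Write / read a pair-count summary as JSON
#'
#' @param x A `fusion_scan` object or a counts tibble ([glance()] output or
#'   [fusion_counts()]).
#' @param path Output / input path.
#' @return `write_counts()` returns `path` invisibly; `read_counts()`
#'   returns a one-row tibble.
#' @export
write_counts <- function(x, path) {
  if (inherits(x, "fusion_scan")) x <- glance(x)
  jsonlite::write_json(list(schema = "telofuse-counts-1",
                            counts = as.list(x[1L, , drop = FALSE])),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::as_tibble(obj$counts)
}

#' Per-pair bar summary of a scan
#'
#' @param object A `fusion_scan` object.
#' @param ... Ignored.
#' @return A ggplot of pair-category counts.
#' @exportS3Method ggplot2::autoplot
autoplot.fusion_scan <- function(object, ...) {
  c0 <- object$counts
  df <- tibble::tibble(
    category = factor(c("intrachromosomal", "interchromosomal",
                        "interchromosomal\nsubtelomeric"),
                      levels = c("intrachromosomal", "interchromosomal",
                                 "interchromosomal\nsubtelomeric")),
    pairs = c(c0$n_intra, c0$n_inter, c0$k_subtel)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pairs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mate pairs (log scale)",
                  title = "Read-pair classification") +
    ggplot2::theme_minimal()
}
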