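#' Pair-level null probability of subtelomere involvement
#'
#' Under a uniform-recombination null, a junction's two positions are
#' independent uniform draws along the genome, so the probability that at
#' least one falls in subtelomeric sequence of genome fraction `f` is
#' q = 1 - (1 - f)^2.
#'
#' @param f Subtelomeric genome fraction, in \[0, 1\].
#' @return q, in \[0, 1\].
#' @examples
#' pair_null_prob(0.5)
#' @export
pair_null_prob <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    abort("f must lie in [0, 1]")
  }
  1 - (1 - f)^2
}

resolve_counts <- function(counts) {
  if (inherits(counts, "fusion_scan")) counts <- glance(counts)
  if (!is.data.frame(counts) || nrow(counts) != 1L ||
      !all(c("n_inter", "k_subtel") %in% names(counts))) {
    abort(paste0("counts must be a fusion_scan object or a one-row data ",
                 "frame with columns n_inter and k_subtel (see fusion_counts())"))
  }
  counts
}

#' Test subtelomere enrichment against the uniform-recombination null
#'
#' Tests whether interchromosomal mate pairs involve subtelomeric sequence
#' more often than expected if junctions were placed uniformly along the
#' genome. Two variants are provided:
#'
#' * `"binomial"` (default, pair-level): the number of pairs with at least
#'   one subtelomeric mate, k, is compared with Binomial(n, q), where
#'   q = 1 - (1 - f)^2 and f is the subtelomeric genome fraction; the
#'   p-value is the upper tail P(X >= k).
#' * `"hypergeometric"` (mate-level): the number of subtelomeric mate
#'   positions m among the 2n mates of interchromosomal pairs is compared
#'   with Hypergeometric(population G bp, successes S subtelomeric bp,
#'   draws 2n); the p-value is the upper tail P(Y >= m).
#'
#' At the genome sizes and pair counts this assay targets, the two agree
#' closely; both are reported with an explicit method label. Tail
#' probabilities are computed in log space, so extreme significance is
#' preserved in `log10_p` even when the p-value itself underflows to zero
#' in double precision (such values print as a "< 1e-300" style bound).
#'
#' @param counts A `fusion_scan` object, its [glance()] tibble, or a
#'   [fusion_counts()] row with `n_inter`, `k_subtel` and (for the
#'   mate-level variant) `m_subtel_mates`.
#' @inheritParams subtelomere_intervals
#' @param method `"binomial"` (pair-level) or `"hypergeometric"`
#'   (mate-level).
#' @param m Optional override for the subtelomeric mate count m used by the
#'   mate-level variant; must satisfy k <= m <= 2k.
#' @return An object of class `fusion_test`; [tidy()] returns a one-row
#'   tibble with `method`, `statistic`, `p.value`, `log10_p`, `effect`
#'   (observed/expected fold enrichment (k/n)/q), and the null parameters.
#' @examples
#' fusion_counts(n_inter = 28748, k_subtel = 1735) |>
#'   enrichment_test(tair10_genome(), window = 1e5)
#' @export
enrichment_test <- function(counts, genome, window = 1e5,
                            method = c("binomial", "hypergeometric"),
                            m = NULL) {
  method <- match.arg(method)
  counts <- resolve_counts(counts)
  st <- subtelomere_stats(genome, window)
  n <- counts$n_inter
  k <- counts$k_subtel
  if (k < 0 || n < k) abort("need 0 <= k_subtel <= n_inter")
  q <- st$null_prob

  if (method == "binomial") {
    log_p <- pbinom(k - 1, size = n, prob = q, lower.tail = FALSE, log.p = TRUE)
    statistic <- k
  } else {
    if (is.null(m)) {
      m <- if ("m_subtel_mates" %in% names(counts)) counts$m_subtel_mates else k
    }
    if (m < k || m > 2 * k || m > 2 * n) abort("need k <= m <= 2k (and m <= 2n)")
    log_p <- phyper(m - 1, m = st$subtel_bp, n = st$genome_bp - st$subtel_bp,
                    k = 2 * n, lower.tail = FALSE, log.p = TRUE)
    statistic <- m
  }
  new_fusion_test(
    method = paste0(if (method == "binomial") "pair-level binomial"
                    else "mate-level hypergeometric",
                    " upper tail, uniform-recombination null"),
    statistic = statistic, log_p = log_p,
    effect = if (n > 0 && q > 0) (k / n) / q else NA_real_,
    extra = list(n = n, k = k,
                 m = if (method == "hypergeometric") m else NA_real_,
                 fraction = st$fraction, null_prob = q,
                 genome_bp = st$genome_bp, subtel_bp = st$subtel_bp,
                 window = window)
  )
}

#' Fold enrichment between two libraries
#'
#' Ratio of subtelomeric proportions among interchromosomal pairs,
#' (k1/n1) / (k2/n2).
#'
#' @param counts_a,counts_b Count summaries for the two libraries
#'   (`fusion_scan`, [glance()] tibble, or [fusion_counts()]).
#' @return The fold-enrichment ratio (a single number).
#' @examples
#' fold_enrichment(fusion_counts(28748, 1735), fusion_counts(23808, 449))
#' @export
fold_enrichment <- function(counts_a, counts_b) {
  a <- resolve_counts(counts_a)
  b <- resolve_counts(counts_b)
  if (a$n_inter <= 0 || b$n_inter <= 0) abort("both libraries need n_inter > 0")
  if (b$k_subtel == 0) {
    abort(paste0("fold enrichment is undefined when the reference library ",
                 "has k_subtel = 0; use compare_libraries() instead"))
  }
  (a$k_subtel / a$n_inter) / (b$k_subtel / b$n_inter)
}

#' Compare subtelomere involvement between two libraries
#'
#' Pearson chi-square test on the 2x2 table (subtelomeric vs other
#' interchromosomal pairs, library A vs library B), without Yates
#' continuity correction by default. Also reports the fold enrichment of
#' library A over library B.
#'
#' @inheritParams fold_enrichment
#' @param correct Apply the Yates continuity correction? Default `FALSE`
#'   (expected cell counts are large in the motivating data).
#' @return An object of class `fusion_compare`; [tidy()] returns a one-row
#'   tibble with `statistic`, `df`, `p.value`, `log10_p`, `fold` and the
#'   four cell counts.
#' @examples
#' compare_libraries(fusion_counts(28748, 1735), fusion_counts(23808, 449))
#' @export
compare_libraries <- function(counts_a, counts_b, correct = FALSE) {
  a <- resolve_counts(counts_a)
  b <- resolve_counts(counts_b)
  tab <- matrix(c(a$k_subtel, a$n_inter - a$k_subtel,
                  b$k_subtel, b$n_inter - b$k_subtel),
                nrow = 2, byrow = TRUE,
                dimnames = list(library = c("A", "B"),
                                pairs = c("subtelomeric", "other")))
  if (any(tab < 0)) abort("all 2x2 cells must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("chi-square test undefined: the 2x2 table has a zero margin")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  log_p <- pchisq(unname(ct$statistic), df = 1, lower.tail = FALSE, log.p = TRUE)
  fold <- if (b$k_subtel > 0) fold_enrichment(a, b) else NA_real_
  structure(
    list(statistic = unname(ct$statistic), df = 1L,
         p.value = exp(log_p), log10_p = log_p / log(10),
         fold = fold, table = tab, correct = correct,
         method = paste0("Pearson chi-square on 2x2",
                         if (correct) " (Yates-corrected)" else "")),
    class = "fusion_compare"
  )
}

#' Estimate the telomeric-junction fraction from scan counts
#'
#' Method-of-moments estimate of the fraction of interchromosomal junctions
#' that are telomeric-type: with observed subtelomeric pair proportion k/n
#' and null probability q at the given window,
#' theta-hat = (k/n - q) / (1 - q). Values near 0 indicate a uniform
#' background; sampling noise can push the raw estimate slightly below 0.
#'
#' @inheritParams enrichment_test
#' @return The estimate (a single number).
#' @export
estimate_telomeric_fraction <- function(counts, genome, window = 1e5) {
  counts <- resolve_counts(counts)
  q <- subtelomere_stats(genome, window)$null_prob
  if (counts$n_inter <= 0) abort("need n_inter > 0")
  if (q >= 1) abort("null probability is 1; estimate undefined")
  (counts$k_subtel / counts$n_inter - q) / (1 - q)
}

# -- result class -------------------------------------------------------

new_fusion_test <- function(method, statistic, log_p, effect, extra) {
  log_p <- min(log_p, 0)
  structure(
    c(list(method = method, statistic = statistic,
           p.value = exp(log_p), log10_p = log_p / log(10),
           effect = effect), extra),
    class = "fusion_test"
  )
}

format_p <- function(p, log10_p) {
  if (p == 0 || log10_p < -300) sprintf("< 1e-300 (log10 p = %.1f)", log10_p)
  else format(p, digits = 4)
}

#' @exportS3Method generics::tidy
tidy.fusion_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p.value, log10_p = x$log10_p, effect = x$effect,
                 n = x$n, k = x$k, m = x$m,
                 fraction = x$fraction, null_prob = x$null_prob)
}

#' @exportS3Method generics::glance
glance.fusion_test <- function(x, ...) tidy(x, ...)

#' @export
print.fusion_test <- function(x, ...) {
  cat("Subtelomere enrichment test\n")
  cat("  method:   ", x$method, "\n")
  cat(sprintf("  counts:    n = %s, k = %s%s\n",
              format(x$n, big.mark = ","), format(x$k, big.mark = ","),
              if (!is.na(x$m)) paste0(", m = ", format(x$m, big.mark = ",")) else ""))
  cat(sprintf("  null:      f = %.6f, q = %.6f (window %s bp)\n",
              x$fraction, x$null_prob,
              format(x$window, scientific = FALSE, big.mark = ",")))
  cat(sprintf("  effect:    %.2f-fold over expectation\n", x$effect))
  cat("  p-value:  ", format_p(x$p.value, x$log10_p), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fusion_compare <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p.value = x$p.value, log10_p = x$log10_p, fold = x$fold,
                 k1 = x$table[1, 1], n1 = sum(x$table[1, ]),
                 k2 = x$table[2, 1], n2 = sum(x$table[2, ]))
}

#' @exportS3Method generics::glance
glance.fusion_compare <- function(x, ...) tidy(x, ...)

#' @export
print.fusion_compare <- function(x, ...) {
  cat("Two-library comparison of subtelomeric interchromosomal pairs\n")
  cat("  method:   ", x$method, "\n")
  cat(sprintf("  A: %s / %s   B: %s / %s\n",
              format(x$table[1, 1], big.mark = ","), format(sum(x$table[1, ]), big.mark = ","),
              format(x$table[2, 1], big.mark = ","), format(sum(x$table[2, ]), big.mark = ",")))
  cat(sprintf("  fold (A/B): %.2f\n", x$fold))
  cat(sprintf("  X-squared = %.4g, df = 1, p = %s\n",
              x$statistic, format_p(x$p.value, x$log10_p)))
  invisible(x)
}

#' Observed vs expected subtelomeric proportions for two libraries
#'
#' @param object A `fusion_compare` object.
#' @param ... Ignored.
#' @return A ggplot comparing the subtelomeric proportion of
#'   interchromosomal pairs in the two libraries.
#' @exportS3Method ggplot2::autoplot
autoplot.fusion_compare <- function(object, ...) {
  df <- tibble::tibble(
    library = rownames(object$table),
    proportion = object$table[, 1] / rowSums(object$table)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$library, y = .data$proportion)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "library",
                  y = "subtelomeric fraction of interchromosomal pairs",
                  title = "Subtelomere involvement by library") +
    ggplot2::theme_minimal()
}
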