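# Pathway over-representation analysis of enzymes with corrected turnover
# numbers (one-sided hypergeometric test, Benjamini-Hochberg correction).

#' One-sided hypergeometric enrichment p-value
#'
#' Standard mode is the upper tail `P(X >= x)` for `x` corrected enzymes
#' annotated to a term out of `N` corrected, with `K` of the `M_total`
#' background enzymes annotated to the term. The `"as_printed"` mode
#' evaluates the literal form `1 - sum_{i=1}^{x-1} pmf(i)`, whose sum
#' starts at 1 and therefore also retains the probability of zero draws.
#'
#' @param x annotated corrected enzymes (integer).
#' @param K annotated background enzymes.
#' @param N corrected enzymes (draws).
#' @param M_total background size (enzymes measured in all conditions).
#' @param mode `"standard"` (default) or `"as_printed"`.
#' @return the p-value.
#' @export
hypergeom_pvalue <- function(x, K, N, M_total,
                             mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(x == round(x), K == round(K), N == round(N),
            M_total == round(M_total))
  if (K > M_total || N > M_total || x < 0)
    stop("inconsistent hypergeometric arguments")
  if (x > min(K, N))
    stop("x (", x, ") exceeds min(K, N) = ", min(K, N))
  if (mode == "standard")
    return(stats::phyper(x - 1, K, M_total - K, N, lower.tail = FALSE))
  ix <- seq_len(max(x - 1, 0))
  1 - sum(stats::dhyper(ix, K, M_total - K, N))
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up adjusted q-values (via [stats::p.adjust()]) and flags at the
#' requested false discovery rate.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param fdr false discovery rate (default 0.05).
#' @return tibble (p, q, significant).
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = q <= fdr)
}

#' Pathway enrichment of corrected enzymes
#'
#' Tests each pathway term for over-representation among the corrected
#' enzymes relative to the background of enzymes measured in all
#' conditions. Terms associated with fewer than two corrected enzymes are
#' excluded before testing; the multiple-testing correction is applied
#' over the tested terms only.
#'
#' @param corrected character vector of corrected enzyme identifiers.
#' @param annotation data frame (`enzyme`, `term`), one pair per row.
#' @param background character vector of background enzymes (those
#'   measured in every condition); annotation rows outside it are
#'   dropped.
#' @param fdr false discovery rate (default 0.05).
#' @param mode p-value mode, see [hypergeom_pvalue()].
#' @param min_corrected minimum corrected enzymes per term (default 2).
#' @return an `enrichment_table` tibble (term, x, K, N, M_total, p, q,
#'   significant), sorted by q.
#' @export
enrich_pathways <- function(corrected, annotation, background, fdr = 0.05,
                            mode = c("standard", "as_printed"),
                            min_corrected = 2) {
  mode <- match.arg(mode)
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("enzyme", "term") %in% names(annotation)))
  annotation <- annotation[annotation$enzyme %in% background, ]
  corrected <- intersect(corrected, background)
  M_total <- length(unique(background))
  N <- length(corrected)
  empty <- tibble::tibble(term = character(0), x = integer(0),
                          K = integer(0), N = integer(0),
                          M_total = integer(0), p = numeric(0),
                          q = numeric(0), significant = logical(0))
  if (N == 0 || nrow(annotation) == 0)
    return(structure(empty, class = c("enrichment_table", class(empty))))
  counts <- annotation |>
    dplyr::distinct(.data$enzyme, .data$term) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(K = dplyr::n(),
                     x = sum(.data$enzyme %in% corrected)) |>
    dplyr::filter(.data$x >= min_corrected)
  if (nrow(counts) == 0)
    return(structure(empty, class = c("enrichment_table", class(empty))))
  counts$p <- vapply(seq_len(nrow(counts)), function(i)
    hypergeom_pvalue(counts$x[i], counts$K[i], N, M_total, mode = mode), 0)
  adj <- bh_adjust(counts$p, fdr = fdr)
  out <- tibble::tibble(term = counts$term, x = as.integer(counts$x),
                        K = as.integer(counts$K), N = as.integer(N),
                        M_total = as.integer(M_total), p = counts$p,
                        q = adj$q, significant = adj$significant) |>
    dplyr::arrange(.data$q, .data$p, .data$term)
  structure(out, class = c("enrichment_table", class(out)))
}
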