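#' Categorical annotation enrichment by Fisher's exact test
#'
#' For each annotation category with at least `min_category_size` members
#' in the background, tests the 2x2 table (in/out foreground x in/out
#' category) with the two-sided Fisher's exact test (the usual convention:
#' summing probabilities of tables as or less probable than the observed
#' one), adjusts across categories by Benjamini-Hochberg, and reports the
#' sample odds ratio.
#'
#' @param foreground Character vector of protein ids (must be a subset of
#'   `background`).
#' @param background Character vector: the tested universe.
#' @param annotations Named list category -> protein ids.
#' @param min_category_size Minimum members in background (default 4).
#' @param fdr_threshold BH threshold for the `significant` flag
#'   (default 0.02).
#' @return `data.frame(category, n_category, n_overlap, odds_ratio, p, q,
#'   significant)` sorted by p.
#' @export
fisher_enrichment <- function(foreground, background, annotations,
                              min_category_size = 4, fdr_threshold = 0.02) {
  if (length(foreground) == 0) stopf("empty foreground set")
  if (!all(foreground %in% background))
    stopf("foreground must be a subset of background")
  foreground <- unique(foreground); background <- unique(background)
  rows <- lapply(names(annotations), function(nm) {
    members <- intersect(annotations[[nm]], background)
    if (length(members) < min_category_size) return(NULL)
    a <- sum(foreground %in% members)
    b <- length(foreground) - a
    cc <- length(members) - a
    d <- length(background) - length(foreground) - cc
    p <- min(1, stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                          byrow = TRUE))$p.value)
    or <- (a * d) / (b * cc)
    data.frame(category = nm, n_category = length(members), n_overlap = a,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(category = character(0), n_category = integer(0),
                      n_overlap = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q <= fdr_threshold
  out[order(out$p), , drop = FALSE]
}

#' One-dimensional annotation enrichment on a numeric protein score
#'
#' Rank-based test asking whether the proteins of a category concentrate at
#' high or low values of a numeric score (e.g. a log2 fold change between
#' two clusters). All n proteins are ranked (average ranks on ties) and
#' each category receives a position score
#' `s = 2 * (mean rank of members - mean rank of non-members) / n`,
#' which lies in `[-1, 1]`: +1 when the members occupy the top ranks, -1 at
#' the bottom, 0 when they are spread like the rest. Significance comes
#' from the two-sided Mann-Whitney U test, adjusted across categories by
#' Benjamini-Hochberg.
#'
#' @param values Named numeric vector: protein -> score (complete for all
#'   tested proteins).
#' @param annotations Named list category -> protein ids.
#' @param min_category_size Minimum members among the scored proteins
#'   (default 4). Categories covering all proteins are skipped.
#' @param fdr_threshold BH threshold for the `significant` flag
#'   (default 0.02).
#' @return `data.frame(category, n_category, score, p, q, significant)`
#'   sorted by p.
#' @export
enrichment_1d <- function(values, annotations, min_category_size = 4,
                          fdr_threshold = 0.02) {
  if (is.null(names(values))) stopf("`values` must be named by protein id")
  if (anyNA(values)) stopf("`values` must be complete for tested proteins")
  n <- length(values)
  rk <- rank(values)
  rows <- lapply(names(annotations), function(nm) {
    inset <- names(values) %in% annotations[[nm]]
    m <- sum(inset)
    if (m < min_category_size || m == n) return(NULL)
    score <- 2 * (mean(rk[inset]) - mean(rk[!inset])) / n
    p <- min(1, suppressWarnings(
      stats::wilcox.test(values[inset], values[!inset])$p.value))
    data.frame(category = nm, n_category = m, score = score, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(category = character(0), n_category = integer(0),
                      score = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q <= fdr_threshold
  out[order(out$p), , drop = FALSE]
}
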