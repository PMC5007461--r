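#' SAM-type s0-moderated two-sample t statistic
#'
#' The ordinary two-sample t statistic damped by a constant `s0` added to
#' the standard error: `statistic = (mean_a - mean_b) / (se + s0)`. The
#' constant suppresses the significance of small-effect features whose
#' tiny variance would otherwise inflate the statistic. `s0 = 0` recovers
#' the ordinary t statistic. The p-value evaluates the moderated statistic
#' against the Student reference distribution of the unmoderated one
#' (two-sided); permutation-based calibration is available through
#' [permutation_fdr()].
#'
#' @param values_a,values_b Numeric vectors (one protein) or matrices
#'   (proteins x samples per group, same rownames).
#' @param s0 Nonnegative damping constant (conventionally 4 for signature
#'   ranking, 2 for volcano analyses).
#' @param var `"pooled"` (default, the SAM convention) or `"welch"`.
#' @return `data.frame(protein, difference, statistic, se, df, p)`; rows
#'   with fewer than two valid values on either side get `NA` statistics.
#' @export
moderated_t <- function(values_a, values_b, s0 = 0,
                        var = c("pooled", "welch")) {
  var <- match.arg(var)
  if (s0 < 0) stopf("`s0` must be >= 0")
  if (!is.matrix(values_a)) values_a <- matrix(values_a, nrow = 1)
  if (!is.matrix(values_b)) values_b <- matrix(values_b, nrow = 1)
  stopifnot(nrow(values_a) == nrow(values_b))
  ids <- rownames(values_a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values_a)))

  sa <- row_stats(values_a); sb <- row_stats(values_b)
  ok <- sa$n >= 2 & sb$n >= 2
  d <- sa$mean - sb$mean
  if (var == "pooled") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$var + (sb$n - 1) * sb$var) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    va <- sa$var / sa$n; vb <- sb$var / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  stat <- d / (se + s0)
  # zero-variance, zero-difference rows: define statistic 0 (p = 1)
  degen <- ok & se == 0 & s0 == 0
  stat[degen & d == 0] <- 0
  p <- 2 * stats::pt(-abs(stat), df)
  p[ok & is.infinite(stat)] <- 0
  d[!ok] <- NA_real_; stat[!ok] <- NA_real_; p[!ok] <- NA_real_
  if (any(!ok))
    message(sprintf("%d proteins skipped (fewer than 2 valid values per side)",
                    sum(!ok)))
  data.frame(protein = ids, difference = d, statistic = stat, se = se,
             df = df, p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group differential test with permutation-based FDR
#'
#' Computes the s0-moderated statistic for every protein, then estimates
#' the false-discovery rate at each candidate cutoff by comparing the
#' observed absolute statistics to their distribution under random label
#' permutations: `FDR(c) = mean permuted count >= c / observed count >= c`.
#' A protein's q-value is the smallest estimated FDR over cutoffs at or
#' below its own statistic, so the significant set at a threshold is the
#' largest set whose estimated FDR stays below it.
#'
#' When the number of distinct label arrangements is small, all of them
#' are enumerated exactly; otherwise `n_permutations` random permutations
#' are drawn under the seed.
#'
#' @param x Numeric matrix (proteins x samples) or [protein_matrix()].
#' @param labels Two-level factor/character vector over the columns.
#' @param s0 Damping constant (default 2, the volcano-analysis convention).
#' @param n_permutations Number of label permutations (default 250).
#' @param fdr_threshold Target FDR (default 0.05).
#' @param seed Integer seed.
#' @return List with `results` (the [moderated_t()] table plus `q` and
#'   `significant`), `n_permutations_used`, and `exact` (whether all
#'   arrangements were enumerated).
#' @export
permutation_fdr <- function(x, labels, s0 = 2, n_permutations = 250,
                            fdr_threshold = 0.05, seed = 1L) {
  if (inherits(x, "protein_matrix")) x <- x$values
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stopf("`labels` must have exactly two levels")
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives a coarse FDR estimate",
            call. = FALSE)
  a_cols <- labels == lv[1]
  obs <- moderated_t(x[, a_cols, drop = FALSE], x[, !a_cols, drop = FALSE],
                     s0 = s0)
  t_obs <- abs(obs$statistic)
  valid <- !is.na(t_obs)

  n <- ncol(x); na <- sum(a_cols)
  n_arrange <- choose(n, na)
  exact <- n_arrange <= n_permutations
  perm_sets <- if (exact) {
    cmb <- utils::combn(n, na)
    lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  } else {
    with_seed(seed, lapply(seq_len(n_permutations),
                           function(k) sample(n, na)))
  }
  perm_stats <- vapply(perm_sets, function(idx) {
    sel <- logical(n); sel[idx] <- TRUE
    abs(suppressMessages(
      moderated_t(x[, sel, drop = FALSE], x[, !sel, drop = FALSE],
                  s0 = s0))$statistic)
  }, numeric(nrow(x)))
  B <- length(perm_sets)

  # FDR at each observed cutoff, then monotone q by running minimum
  pooled <- sort(perm_stats[!is.na(perm_stats)])
  ord <- order(t_obs[valid], decreasing = TRUE)
  cuts <- t_obs[valid][ord]
  n_obs_ge <- seq_along(cuts)
  n_perm_ge <- length(pooled) - findInterval(cuts - 1e-12, pooled)
  fdr <- pmin(1, (n_perm_ge / B) / n_obs_ge)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- rep(NA_real_, nrow(x))
  q[which(valid)[ord]] <- q_sorted

  res <- obs
  res$q <- q
  res$significant <- !is.na(q) & q <= fdr_threshold
  list(results = res, n_permutations_used = B, exact = exact,
       significant = res$protein[res$significant])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment controlling the false-discovery rate.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
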