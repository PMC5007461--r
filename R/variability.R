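#' Per-protein expression variability across cell lines
#'
#' For each protein quantified in at least `min_valid` lines, the standard
#' deviation of its log LFQ intensity across lines (expression variability)
#' and its estimated absolute abundance, log10 of the summed iBAQ values.
#' Housekeeping proteins sit at low SD; subtype markers and frequently
#' amplified or lost proteins show high SD.
#'
#' @param x A line-averaged [protein_matrix()] (log2 values).
#' @param ibaq Optional proteins x lines matrix of linear iBAQ values;
#'   defaults to `x$ibaq`.
#' @param min_valid Minimum quantified lines per protein (default 10).
#' @param log_base Base on which the SD is expressed (default 10, matching
#'   the conventional log10 variability axis; use 2 for log2 units).
#' @return `data.frame(protein, sd, abundance, n_valid)`, one row per
#'   retained protein; `abundance` is `NA` when no iBAQ values are given.
#' @export
protein_variability <- function(x, ibaq = NULL, min_valid = 10,
                                log_base = 10) {
  stopifnot(inherits(x, "protein_matrix"))
  if (is.null(ibaq)) ibaq <- x$ibaq
  st <- row_stats(x$values)
  keep <- st$n >= min_valid
  scale <- log(x$log_base) / log(log_base)  # log2 SD -> chosen-base SD
  sdv <- sqrt(st$var[keep]) * scale
  abundance <- rep(NA_real_, sum(keep))
  if (!is.null(ibaq)) {
    tot <- rowSums(ibaq[keep, , drop = FALSE], na.rm = TRUE)
    abundance <- ifelse(tot > 0, log10(tot), NA_real_)
  }
  data.frame(protein = rownames(x$values)[keep], sd = sdv,
             abundance = abundance, n_valid = st$n[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' High-variability protein subset
#'
#' Proteins whose cross-line SD strictly exceeds the cutoff (default 0.5 on
#' log10 scale), the conventional threshold separating the most variably
#' expressed proteins from the stable bulk.
#'
#' @param records Output of [protein_variability()].
#' @param cutoff SD cutoff; strict inequality (default 0.5).
#' @return Character vector of protein ids.
#' @export
high_variability_set <- function(records, cutoff = 0.5) {
  records$protein[records$sd > cutoff]
}
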