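#' Remove decoy, site-only and contaminant protein rows
#'
#' Proteins matching the reversed decoy database or identified only by a
#' modified site are artefacts of the search and are never analysed.
#' Potential contaminants are removed by default but can be kept, since
#' contaminant filtering is a separable choice.
#'
#' @param x A [protein_matrix()].
#' @param contaminants Also drop contaminant-flagged rows (default `TRUE`).
#' @return Filtered [protein_matrix()].
#' @export
remove_flagged <- function(x, contaminants = TRUE) {
  stopifnot(inherits(x, "protein_matrix"))
  drop <- x$flags$reverse | x$flags$only_by_site
  if (contaminants) drop <- drop | x$flags$contaminant
  x[!drop, ]
}

#' Filter proteins by per-line replicate support
#'
#' Within each cell line, a protein's replicate quantifications are kept
#' only when at least `min_quantified` of them are valid; otherwise the
#' protein is set missing for that line. Proteins left with no valid value
#' anywhere are dropped.
#'
#' @param x A [protein_matrix()] whose metadata has a `line` column.
#' @param min_quantified Minimum valid replicates per line (default 2,
#'   i.e. two of three consecutive-passage replicates).
#' @return Filtered [protein_matrix()].
#' @export
filter_replicates <- function(x, min_quantified = 2) {
  stopifnot(inherits(x, "protein_matrix"))
  if (!"line" %in% names(x$meta))
    stopf("sample metadata needs a `line` column for the replicate filter")
  vals <- x$values
  for (ln in unique(x$meta$line)) {
    cols <- which(x$meta$line == ln)
    if (length(cols) < min_quantified)
      message(sprintf("line %s has %d replicates < min_quantified=%d; all values kept need full support",
                      ln, length(cols), min_quantified))
    nvalid <- rowSums(!is.na(vals[, cols, drop = FALSE]))
    fail <- nvalid < min(min_quantified, length(cols))
    vals[fail, cols] <- NA_real_
  }
  out <- x
  out$values <- vals
  if (!is.null(out$ibaq)) out$ibaq[is.na(vals)] <- NA_real_
  keep <- rowSums(!is.na(vals)) > 0
  out[keep, ]
}

#' Average replicate columns into one column per cell line
#'
#' The mean of the valid (non-missing) replicate log intensities per line;
#' missing when all replicates are missing. iBAQ values, when present, are
#' averaged on linear scale.
#'
#' @param x A [protein_matrix()] with `line` metadata.
#' @return A [protein_matrix()] with one column per line.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "protein_matrix"))
  if (!"line" %in% names(x$meta)) stopf("sample metadata needs a `line` column")
  lines <- unique(x$meta$line)
  avg <- function(mat) {
    out <- sapply(lines, function(ln) {
      cols <- x$meta$line == ln
      rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
    })
    out[is.nan(out)] <- NA_real_
    out
  }
  vals <- avg(x$values)
  dimnames(vals) <- list(rownames(x$values), lines)
  meta_cols <- intersect(c("entity", "group", "cohort"), names(x$meta))
  meta <- unique(data.frame(sample = x$meta$line,
                            x$meta[meta_cols], stringsAsFactors = FALSE))
  ibaq <- NULL
  if (!is.null(x$ibaq)) {
    ibaq <- avg(x$ibaq)
    dimnames(ibaq) <- dimnames(vals)
  }
  protein_matrix(vals, meta = meta, flags = x$flags, ibaq = ibaq,
                 log_base = x$log_base)
}

#' Filter proteins by minimum number of valid values
#'
#' @param x A [protein_matrix()].
#' @param n Minimum count of non-missing values per row (e.g. 10 of 30
#'   samples for whole-panel clustering, 30 of 41 for an integrated PCA).
#' @return Filtered [protein_matrix()].
#' @export
filter_min_valid <- function(x, n) {
  stopifnot(inherits(x, "protein_matrix"))
  if (n > ncol(x$values))
    stopf("invalid config: min valid %d exceeds %d samples", n, ncol(x$values))
  x[rowSums(!is.na(x$values)) >= n, ]
}

#' Remove abundant plasma proteins
#'
#' Tumour tissue carries blood contamination; the most abundant plasma
#' proteins are removed before integrated tissue/cell-line analyses.
#' The packaged list (`plasma_proteins()`) is a synthetic stand-in of ~200
#' common plasma protein gene symbols.
#'
#' @param x A [protein_matrix()].
#' @param plasma_ids Character vector of protein ids to drop; defaults to
#'   the packaged list.
#' @return Filtered [protein_matrix()].
#' @export
remove_plasma_proteins <- function(x, plasma_ids = plasma_proteins()) {
  stopifnot(inherits(x, "protein_matrix"))
  x[!rownames(x$values) %in% plasma_ids, ]
}

#' Packaged plasma-protein identifier list
#'
#' A synthetic stand-in list of common high-abundance plasma protein gene
#' symbols (albumin, immunoglobulin chains, apolipoproteins, complement and
#' coagulation factors, etc.), for use with [remove_plasma_proteins()].
#'
#' @return Character vector of protein ids.
#' @export
plasma_proteins <- function() {
  path <- system.file("extdata", "plasma_proteins_synthetic.txt",
                      package = "protsig")
  if (!nzchar(path)) stopf("packaged plasma protein list not found")
  readLines(path)
}

#' Z-score a protein matrix
#'
#' Standardizes each row (protein, default) or column (sample) to mean 0 and
#' standard deviation 1 over its non-missing entries, using the sample
#' (n - 1) standard deviation. With `groupwise`, standardization is done
#' separately within each cohort (e.g. label-free vs isobaric-tag data), so
#' that technology-specific location and scale do not dominate a joint
#' clustering.
#'
#' @param x A [protein_matrix()].
#' @param by `"rows"` (default) or `"columns"`.
#' @param groupwise If `TRUE`, standardize within each level of
#'   `meta$cohort` separately (rows mode only).
#' @return A z-scored [protein_matrix()].
#' @export
zscore_matrix <- function(x, by = c("rows", "columns"), groupwise = FALSE) {
  stopifnot(inherits(x, "protein_matrix"))
  by <- match.arg(by)
  vals <- x$values
  zrows <- function(m) {
    st <- row_stats(m)
    sd <- sqrt(st$var)
    z <- (m - st$mean) / sd
    const <- !is.na(sd) & sd == 0
    if (any(const)) {
      warning(sprintf("%d zero-variance rows set to 0", sum(const)),
              call. = FALSE)
      z[const, ] <- ifelse(is.na(m[const, , drop = FALSE]), NA_real_, 0)
    }
    z
  }
  if (by == "rows") {
    if (groupwise) {
      if (!"cohort" %in% names(x$meta))
        stopf("groupwise z-scoring needs a `cohort` metadata column")
      for (ch in unique(x$meta$cohort)) {
        cols <- x$meta$cohort == ch
        vals[, cols] <- zrows(vals[, cols, drop = FALSE])
      }
    } else {
      vals <- zrows(vals)
    }
  } else {
    vals <- t(zrows(t(vals)))
  }
  out <- x
  out$values <- vals
  out$ibaq <- NULL  # iBAQ is meaningless after standardization
  out
}

#' Normalize isobaric-tag reporter intensities against a control channel
#'
#' Log reporter intensities minus the same-run control-channel (pooled
#' reference) log intensity, followed by shifting every sample column to
#' median zero.
#'
#' @param x A [protein_matrix()] of log reporter intensities; control
#'   channels included as columns.
#' @param control_channel Column (sample) name of the control channel, or a
#'   named vector run -> control channel when `runs` is given.
#' @param runs Optional character vector assigning each column to a run;
#'   default: all columns one run.
#' @return A [protein_matrix()] of normalized log ratios with control
#'   channels removed.
#' @export
normalize_itraq <- function(x, control_channel, runs = NULL) {
  stopifnot(inherits(x, "protein_matrix"))
  vals <- x$values
  if (is.null(runs)) runs <- rep("run1", ncol(vals))
  ctrl <- if (length(control_channel) == 1)
    stats::setNames(rep(control_channel, length(unique(runs))), unique(runs))
  else control_channel
  for (r in unique(runs)) {
    if (!ctrl[[r]] %in% colnames(vals)[runs == r])
      stopf("control channel '%s' absent from run '%s'", ctrl[[r]], r)
    cols <- which(runs == r)
    vals[, cols] <- vals[, cols] - vals[, ctrl[[r]]]
  }
  keep <- !colnames(vals) %in% unname(ctrl)
  vals <- vals[, keep, drop = FALSE]
  meds <- apply(vals, 2, stats::median, na.rm = TRUE)
  vals <- sweep(vals, 2, meds)
  protein_matrix(vals, meta = x$meta[keep, , drop = FALSE], flags = x$flags,
                 log_base = x$log_base)
}

#' Impute missing values from a down-shifted normal distribution
#'
#' Models left-censored missingness: each missing entry in sample column j
#' is drawn from `Normal(mean_j - down_shift * sd_j, (width * sd_j)^2)`,
#' with `mean_j` and `sd_j` computed over the observed values of that
#' column. Defaults `width = 0.15`, `down_shift = 1.8` place imputed values
#' in the low-intensity tail, where below-detection-limit values are
#' expected to lie. Observed entries are never altered; the result records
#' which entries were imputed in `$imputed`.
#'
#' @param x A [protein_matrix()].
#' @param width Imputation spread as a fraction of the column SD.
#' @param down_shift Location shift in column-SD multiples.
#' @param seed Integer seed (imputation is deterministic given the seed).
#' @param per_column If `FALSE`, use the whole-matrix mean and SD instead
#'   of per-sample ones.
#' @return A complete [protein_matrix()] (columns with under two observed
#'   values are skipped with a warning).
#' @export
impute_downshifted <- function(x, width = 0.15, down_shift = 1.8, seed = 1L,
                               per_column = TRUE) {
  stopifnot(inherits(x, "protein_matrix"))
  if (width <= 0) stopf("invalid config: `width` must be > 0")
  if (down_shift < 0) stopf("invalid config: `down_shift` must be >= 0")
  vals <- x$values
  imputed <- is.na(vals)
  with_seed(seed, {
    if (per_column) {
      for (j in seq_len(ncol(vals))) {
        obs <- vals[!is.na(vals[, j]), j]
        k <- sum(is.na(vals[, j]))
        if (k == 0) next
        if (length(obs) < 2) {
          warning(sprintf("column %s has < 2 observed values; skipped",
                          colnames(vals)[j]), call. = FALSE)
          next
        }
        mu <- mean(obs); sd_j <- stats::sd(obs)
        vals[is.na(vals[, j]), j] <-
          stats::rnorm(k, mu - down_shift * sd_j, width * sd_j)
      }
    } else {
      obs <- vals[!is.na(vals)]
      k <- sum(is.na(vals))
      if (k > 0) {
        mu <- mean(obs); sd_g <- stats::sd(obs)
        vals[is.na(vals)] <- stats::rnorm(k, mu - down_shift * sd_g,
                                          width * sd_g)
      }
    }
  })
  out <- x
  out$values <- vals
  out$imputed <- imputed
  out
}
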