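#' Protein expression matrix with missingness mask and sample metadata
#'
#' The central container of the pipeline: a proteins x samples matrix of
#' log2 intensities in which `NA` marks a missing (not-quantified) value.
#' Per-row identification flags (decoy/reverse hits, proteins identified only
#' by a modified site, potential contaminants) and per-sample metadata travel
#' with the matrix through every filtering step.
#'
#' @param values Numeric matrix, rows = proteins (unique rownames), columns =
#'   samples (colnames). `NA` encodes a missing quantification. Values are
#'   log2 intensities unless `log_base` says otherwise.
#' @param meta Optional `data.frame` of per-sample metadata with a `sample`
#'   column matching `colnames(values)`; typical columns are `entity`
#'   (cell line / tumour / primary cell), `line`, `replicate`, `group`,
#'   `cohort` (e.g. LFQ vs ITRAQ).
#' @param flags Optional `data.frame` with logical columns `reverse`,
#'   `only_by_site`, `contaminant`, one row per protein.
#' @param ibaq Optional numeric matrix of linear-scale iBAQ values with the
#'   same dimnames as `values`.
#' @param log_base Base of the stored log intensities (default 2).
#'
#' @return An object of class `protein_matrix`: a list with elements
#'   `values`, `meta`, `flags`, `ibaq`, `log_base` and (after imputation)
#'   `imputed`, a logical matrix marking entries that were filled in.
#' @export
protein_matrix <- function(values, meta = NULL, flags = NULL, ibaq = NULL,
                           log_base = 2) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%05d", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stopf("protein (row) ids must be unique")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  if (is.null(meta)) {
    meta <- data.frame(sample = colnames(values), stringsAsFactors = FALSE)
  }
  if (!"sample" %in% names(meta)) stopf("`meta` needs a `sample` column")
  if (!setequal(meta$sample, colnames(values)))
    stopf("`meta$sample` must match the matrix column names")
  meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(flags)) {
    flags <- data.frame(reverse = logical(nrow(values)),
                        only_by_site = logical(nrow(values)),
                        contaminant = logical(nrow(values)))
  }
  rownames(flags) <- rownames(values)
  if (!is.null(ibaq)) {
    stopifnot(identical(dim(ibaq), dim(values)))
    dimnames(ibaq) <- dimnames(values)
  }
  structure(list(values = values, meta = meta, flags = flags, ibaq = ibaq,
                 log_base = log_base),
            class = "protein_matrix")
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples (log%g scale)\n",
              nrow(x$values), ncol(x$values), x$log_base))
  cat(sprintf("  missing: %.1f%%", 100 * mean(is.na(x$values))))
  if (any(x$flags$reverse | x$flags$only_by_site | x$flags$contaminant))
    cat(sprintf(" | flagged rows: %d",
                sum(x$flags$reverse | x$flags$only_by_site | x$flags$contaminant)))
  if (!is.null(x$imputed)) cat(" | imputed")
  cat("\n")
  invisible(x)
}

#' Subset a protein matrix by proteins and/or samples
#'
#' Keeps flags, metadata, iBAQ values and the imputation mask aligned.
#'
#' @param x A [protein_matrix()].
#' @param i,j Row (protein) and column (sample) indices.
#' @param ... Unused.
#' @export
`[.protein_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  out <- x
  out$values <- x$values[i, j, drop = FALSE]
  out$flags <- x$flags[i, , drop = FALSE]
  out$meta <- x$meta[match(colnames(out$values), x$meta$sample), , drop = FALSE]
  rownames(out$meta) <- NULL
  if (!is.null(x$ibaq)) out$ibaq <- x$ibaq[i, j, drop = FALSE]
  if (!is.null(x$imputed)) out$imputed <- x$imputed[i, j, drop = FALSE]
  out
}

# ---- MaxQuant-style proteinGroups I/O -------------------------------------

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated dialect written by common search-engine software:
#' one row per protein group, columns `Protein IDs`, `LFQ intensity <sample>`,
#' optionally `iBAQ <sample>`, and the flag columns `Reverse`,
#' `Only identified by site` and `Potential contaminant` (a `+` marks a
#' flagged row). Raw intensities of zero are the software's missing-value
#' sentinel and become `NA`; all intensities are log2-transformed.
#'
#' @param path Path to the TSV file.
#' @return A [protein_matrix()] on log2 scale.
#' @export
read_protein_groups <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Protein IDs" %in% names(tab))
    stopf("required column missing: 'Protein IDs'")
  lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  if (length(lfq_cols) == 0)
    stopf("required column missing: 'LFQ intensity <sample>'")
  samples <- sub("^LFQ intensity ", "", lfq_cols)
  vals <- as.matrix(tab[, lfq_cols, drop = FALSE])
  vals[vals == 0] <- NA_real_
  vals <- log2(vals)
  dimnames(vals) <- list(tab[["Protein IDs"]], samples)

  ibaq_cols <- paste0("iBAQ ", samples)
  ibaq <- NULL
  if (all(ibaq_cols %in% names(tab))) {
    ibaq <- as.matrix(tab[, ibaq_cols, drop = FALSE])
    ibaq[ibaq == 0] <- NA_real_
    dimnames(ibaq) <- list(tab[["Protein IDs"]], samples)
  }
  plus <- function(col) {
    if (col %in% names(tab)) trimws(as.character(tab[[col]])) == "+" else
      logical(nrow(tab))
  }
  flags <- data.frame(reverse = plus("Reverse"),
                      only_by_site = plus("Only identified by site"),
                      contaminant = plus("Potential contaminant"))
  protein_matrix(vals, flags = flags, ibaq = ibaq)
}

#' Write a protein matrix as a MaxQuant-style proteinGroups table
#'
#' Inverse of [read_protein_groups()]: intensities are de-logged and missing
#' values written as 0, flags as `+`/empty.
#'
#' @param x A [protein_matrix()].
#' @param path Output TSV path.
#' @export
write_protein_groups <- function(x, path) {
  raw <- x$log_base^x$values
  raw[is.na(raw)] <- 0
  out <- data.frame(`Protein IDs` = rownames(x$values), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in colnames(x$values)) out[[paste0("LFQ intensity ", s)]] <- raw[, s]
  ibaq <- x$ibaq
  if (is.null(ibaq)) ibaq <- raw
  ibaq[is.na(ibaq)] <- 0
  for (s in colnames(x$values)) out[[paste0("iBAQ ", s)]] <- ibaq[, s]
  out[["Reverse"]] <- ifelse(x$flags$reverse, "+", "")
  out[["Only identified by site"]] <- ifelse(x$flags$only_by_site, "+", "")
  out[["Potential contaminant"]] <- ifelse(x$flags$contaminant, "+", "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GMT annotation I/O ----------------------------------------------------

#' Read / write annotation sets in GMT format
#'
#' GMT is the standard gene-set format: one category per line,
#' tab-separated as `name <tab> description <tab> id1 <tab> id2 ...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors
#'   (category -> protein ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @param sets Named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
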