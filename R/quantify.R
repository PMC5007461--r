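#' Peptide-level intensity table
#'
#' Raw (linear-scale) peptide intensities per sample, with each peptide
#' assigned to exactly one protein group. Zero intensities are treated as
#' missing, matching the convention of MaxQuant-style output.
#'
#' @param peptide Character vector of peptide ids.
#' @param protein Character vector of protein ids, same length.
#' @param intensities Numeric matrix (peptides x samples) of raw
#'   intensities; `NA` or 0 marks a missing observation.
#' @return A `peptide_table` object.
#' @export
peptide_table <- function(peptide, protein, intensities) {
  stopifnot(length(peptide) == length(protein),
            is.matrix(intensities), nrow(intensities) == length(peptide))
  if (any(intensities < 0, na.rm = TRUE))
    stopf("peptide intensities must be nonnegative")
  intensities[!is.na(intensities) & intensities == 0] <- NA_real_
  rownames(intensities) <- peptide
  structure(list(peptide = peptide, protein = protein,
                 intensities = intensities),
            class = "peptide_table")
}

#' @export
print.peptide_table <- function(x, ...) {
  cat(sprintf("peptide_table: %d peptides / %d proteins x %d samples\n",
              length(x$peptide), length(unique(x$protein)),
              ncol(x$intensities)))
  invisible(x)
}

#' Read / write a peptide table in TSV format
#'
#' Columns: `Sequence`, `Protein IDs`, then `Intensity <sample>` per sample;
#' zeros encode missing observations.
#'
#' @param path File path.
#' @export
read_peptide_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("Sequence", "Protein IDs"))
    if (!col %in% names(tab)) stopf("required column missing: '%s'", col)
  int_cols <- grep("^Intensity ", names(tab), value = TRUE)
  if (length(int_cols) == 0)
    stopf("required column missing: 'Intensity <sample>'")
  ints <- as.matrix(tab[, int_cols, drop = FALSE])
  colnames(ints) <- sub("^Intensity ", "", int_cols)
  peptide_table(tab[["Sequence"]], tab[["Protein IDs"]], ints)
}

#' @param x A `peptide_table`.
#' @rdname read_peptide_table
#' @export
write_peptide_table <- function(x, path) {
  ints <- x$intensities
  ints[is.na(ints)] <- 0
  out <- data.frame(Sequence = x$peptide, `Protein IDs` = x$protein,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(ints)) out[[paste0("Intensity ", s)]] <- ints[, s]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the pairwise protein-ratio graph from peptide intensities
#'
#' For every protein and every pair of samples, the protein-level log2 ratio
#' is the median of all pairwise peptide log2 ratios, using only peptides
#' observed in both samples of the pair. Pairs with fewer than
#' `min_ratio_count` shared peptides contribute no edge.
#'
#' @param peptides A [peptide_table()].
#' @param min_ratio_count Minimum number of shared peptides per sample pair
#'   (default 1).
#' @return A `ratio_graph`: a named list (per protein) of edge data frames
#'   with columns `a`, `b`, `log2_ratio` (median log2 of a over b) and `n`
#'   (shared-peptide count), plus per-sample observed protein intensity
#'   totals used downstream for normalization.
#' @export
build_ratio_graph <- function(peptides, min_ratio_count = 1) {
  stopifnot(inherits(peptides, "peptide_table"))
  if (length(peptides$peptide) == 0) stopf("peptide table is empty")
  samples <- colnames(peptides$intensities)
  logint <- log2(peptides$intensities)
  prot_ids <- unique(peptides$protein)

  graphs <- lapply(prot_ids, function(p) {
    rows <- logint[peptides$protein == p, , drop = FALSE]
    pairs <- utils::combn(length(samples), 2)
    edges <- vector("list", ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      shared <- !is.na(rows[, i]) & !is.na(rows[, j])
      if (sum(shared) >= min_ratio_count) {
        edges[[k]] <- data.frame(
          a = samples[i], b = samples[j],
          log2_ratio = stats::median(rows[shared, i] - rows[shared, j]),
          n = sum(shared), stringsAsFactors = FALSE)
      }
    }
    edges <- edges[!vapply(edges, is.null, logical(1))]
    if (length(edges)) do.call(rbind, edges) else
      data.frame(a = character(0), b = character(0),
                 log2_ratio = numeric(0), n = integer(0))
  })
  names(graphs) <- prot_ids

  totals <- t(vapply(prot_ids, function(p) {
    colSums(peptides$intensities[peptides$protein == p, , drop = FALSE],
            na.rm = TRUE)
  }, numeric(length(samples))))
  dimnames(totals) <- list(prot_ids, samples)

  structure(list(edges = graphs, samples = samples, totals = totals),
            class = "ratio_graph")
}

#' Reconstruct relative protein abundance profiles by least squares
#'
#' Per protein, finds the log2 abundance profile `x` minimizing the squared
#' deviation from all pairwise median ratios, `sum((x_a - x_b - r_ab)^2)`,
#' independently on each connected component of the protein's sample graph.
#' The component solution is then shifted so that the summed linear
#' abundance equals the summed observed peptide intensity over that
#' component, preserving the protein's total intensity. Samples outside all
#' components (no observations) stay missing; a single-sample component
#' keeps its observed intensity.
#'
#' @param graph A [build_ratio_graph()] result.
#' @param observed_totals Optional proteins x samples matrix of observed
#'   per-sample protein intensity sums; defaults to the totals recorded in
#'   the graph.
#' @return A [protein_matrix()] of log2 abundance profiles.
#' @export
reconstruct_profiles <- function(graph, observed_totals = NULL) {
  stopifnot(inherits(graph, "ratio_graph"))
  totals <- if (is.null(observed_totals)) graph$totals else observed_totals
  samples <- graph$samples
  prof <- matrix(NA_real_, length(graph$edges), length(samples),
                 dimnames = list(names(graph$edges), samples))

  for (p in names(graph$edges)) {
    ed <- graph$edges[[p]]
    tot <- totals[p, ]
    observed <- samples[tot > 0]
    if (length(observed) == 0) next
    comp <- graph_components(observed, ed$a, ed$b)
    for (ci in unique(comp)) {
      nodes <- observed[comp == ci]
      sub <- ed[ed$a %in% nodes & ed$b %in% nodes, , drop = FALSE]
      if (length(nodes) == 1L || nrow(sub) == 0L) {
        # degenerate: no ratio information; each node keeps its own total
        for (nd in nodes) prof[p, nd] <- log2(tot[nd])
        next
      }
      x <- solve_profile_ls(nodes, sub)
      shift <- log2(sum(tot[nodes])) - log2(sum(2^x))
      prof[p, nodes] <- x + shift
    }
  }
  protein_matrix(prof)
}

# Least-squares log2 profile on one connected component: normal equations
# L x = b with the graph Laplacian L; gauge fixed by anchoring node 1 at 0.
solve_profile_ls <- function(nodes, edges) {
  m <- length(nodes)
  L <- matrix(0, m, m)
  bvec <- numeric(m)
  ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
  for (k in seq_len(nrow(edges))) {
    i <- ia[k]; j <- ib[k]; r <- edges$log2_ratio[k]
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
    bvec[i] <- bvec[i] + r
    bvec[j] <- bvec[j] - r
  }
  x <- numeric(m)
  x[-1] <- solve(L[-1, -1, drop = FALSE], bvec[-1])
  stats::setNames(x, nodes)
}

#' Label-free protein quantification from a peptide table
#'
#' Convenience wrapper chaining [build_ratio_graph()] and
#' [reconstruct_profiles()]: median-of-pairwise-peptide-ratio protein
#' ratios, least-squares profile reconstruction, and total-intensity
#' preservation.
#'
#' @inheritParams build_ratio_graph
#' @return A [protein_matrix()] of log2 protein abundances.
#' @export
quantify_maxlfq <- function(peptides, min_ratio_count = 1) {
  reconstruct_profiles(build_ratio_graph(peptides, min_ratio_count))
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' Total protein intensity divided by the number of theoretically
#' observable peptides, yielding an abundance measure comparable across
#' proteins of different length.
#'
#' @param protein_total_intensity Raw summed intensity (vectorized).
#' @param n_theoretical_peptides Theoretically observable peptide count
#'   (>= 1, vectorized).
#' @return iBAQ values.
#' @export
compute_ibaq <- function(protein_total_intensity, n_theoretical_peptides) {
  if (any(is.na(n_theoretical_peptides)) ||
      any(n_theoretical_peptides < 1) ||
      any(n_theoretical_peptides != floor(n_theoretical_peptides)))
    stopf("`n_theoretical_peptides` must be integers >= 1")
  if (any(protein_total_intensity < 0, na.rm = TRUE))
    stopf("`protein_total_intensity` must be nonnegative")
  protein_total_intensity / n_theoretical_peptides
}
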