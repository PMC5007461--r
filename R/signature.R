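#' Parameters for discriminating-signature derivation
#'
#' @param n_repeats Random-resampling repeats of the train/test split
#'   (default 250).
#' @param train_fraction Fraction of samples used for training in each
#'   repeat (default 0.85, i.e. an 85/15 split).
#' @param s0 Damping constant of the ranking statistic (default 4).
#' @param candidate_ks Ascending list sizes at which the held-out error is
#'   evaluated.
#' @param svm_kernel,svm_cost SVM kernel and cost (defaults: linear, 1 —
#'   the convention for high-dimensional, low-n expression data).
#' @param seed Integer seed.
#' @return A validated `signature_params` list.
#' @export
signature_params <- function(n_repeats = 250, train_fraction = 0.85, s0 = 4,
                             candidate_ks = c(5, 10, 25, 50),
                             svm_kernel = "linear", svm_cost = 1,
                             seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("`train_fraction` must be in (0, 1)")
  if (length(candidate_ks) == 0 || is.unsorted(candidate_ks, strictly = TRUE))
    stopf("`candidate_ks` must be nonempty and strictly ascending")
  if (!is_count(n_repeats)) stopf("`n_repeats` must be a count >= 1")
  if (s0 < 0) stopf("`s0` must be >= 0")
  structure(list(n_repeats = n_repeats, train_fraction = train_fraction,
                 s0 = s0, candidate_ks = as.integer(candidate_ks),
                 svm_kernel = svm_kernel, svm_cost = svm_cost,
                 seed = as.integer(seed)),
            class = "signature_params")
}

#' One-versus-all moderated-t protein ranking
#'
#' Ranks proteins by the p-value of the s0-moderated t statistic comparing
#' the target group against all remaining samples pooled. Ties are broken
#' by descending absolute statistic, then by protein id, so the ordering is
#' deterministic.
#'
#' @param x Numeric matrix (proteins x samples) or [protein_matrix()].
#' @param group_labels Group label per column.
#' @param target_group The group ranked against the rest.
#' @param s0 Damping constant (default 4).
#' @return `data.frame(protein, difference, statistic, p, rank)` in rank
#'   order.
#' @export
rank_proteins_ova <- function(x, group_labels, target_group, s0 = 4) {
  if (inherits(x, "protein_matrix")) x <- x$values
  sel <- group_labels == target_group
  if (sum(sel) < 2 || sum(!sel) < 2)
    stopf("need >= 2 samples in '%s' and in the rest", target_group)
  res <- suppressMessages(
    moderated_t(x[, sel, drop = FALSE], x[, !sel, drop = FALSE], s0 = s0))
  ord <- order(res$p, -abs(res$statistic), res$protein)
  out <- res[ord, c("protein", "difference", "statistic", "p")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' SVM feature selection embedded in cross-validation resampling
#'
#' For each of `n_repeats` stratified random splits (train_fraction of the
#' samples for training, the rest held out), proteins are ranked one-vs-all
#' on the training split only, and for each candidate list size k a linear
#' one-vs-all SVM is trained on the top-k features and scored on the
#' held-out samples. Rankings never see held-out samples, so the error
#' curves are unbiased estimates of generalization error.
#'
#' @param x Complete numeric matrix (proteins x samples) or
#'   [protein_matrix()]; z-scored input is recommended.
#' @param group_labels Group label per column (each group >= 2 samples).
#' @param params A [signature_params()].
#' @return An object of class `cv_signature`: list with
#'   \describe{
#'     \item{error_curves}{groups x ks matrix of mean held-out error.}
#'     \item{error_se}{matching standard errors over repeats.}
#'     \item{ranked_lists}{per group, protein ids ordered by aggregate
#'       (median) rank across repeats.}
#'     \item{aggregate_ranks}{per group, the median rank per protein.}
#'     \item{chosen_ks}{per group, the smallest k whose mean error is
#'       within one standard error of the minimum (1-SE rule).}
#'     \item{error_trace}{per-repeat held-out errors (group x k x repeat).}
#'   }
#' @export
cv_feature_selection <- function(x, group_labels, params = signature_params()) {
  if (inherits(x, "protein_matrix")) x <- x$values
  stopifnot(inherits(params, "signature_params"))
  if (anyNA(x)) stopf("matrix has missing values; impute before selection")
  group_labels <- as.character(group_labels)
  groups <- sort(unique(group_labels))
  if (any(table(group_labels) < 2)) stopf("every group needs >= 2 samples")
  ks <- pmin(params$candidate_ks, nrow(x))
  proteins <- rownames(x)
  R <- params$n_repeats

  rank_mats <- lapply(groups, function(g)
    matrix(NA_real_, nrow(x), R, dimnames = list(proteins, NULL)))
  names(rank_mats) <- groups
  err <- array(NA_real_, c(length(groups), length(ks), R),
               dimnames = list(groups, paste0("k", ks), NULL))
  test_splits <- vector("list", R)

  with_seed(params$seed, {
    for (r in seq_len(R)) {
      train <- unlist(lapply(groups, function(g) {
        idx <- which(group_labels == g)
        n_tr <- round(params$train_fraction * length(idx))
        n_tr <- max(2L, min(length(idx) - 1L, n_tr))
        sample(idx, n_tr)
      }))
      test <- setdiff(seq_len(ncol(x)), train)
      test_splits[[r]] <- test
      xtr <- x[, train, drop = FALSE]; ltr <- group_labels[train]
      xte <- x[, test, drop = FALSE];  lte <- group_labels[test]
      for (g in groups) {
        rk <- rank_proteins_ova(xtr, ltr, g, s0 = params$s0)
        rank_mats[[g]][rk$protein, r] <- rk$rank
        ytr <- factor(ifelse(ltr == g, g, "rest"), levels = c(g, "rest"))
        yte <- factor(ifelse(lte == g, g, "rest"), levels = c(g, "rest"))
        for (ki in seq_along(ks)) {
          feats <- rk$protein[seq_len(ks[ki])]
          fit <- e1071::svm(x = t(xtr[feats, , drop = FALSE]), y = ytr,
                            kernel = params$svm_kernel,
                            cost = params$svm_cost, scale = FALSE)
          pred <- stats::predict(fit, t(xte[feats, , drop = FALSE]))
          err[g, ki, r] <- mean(pred != yte)
        }
      }
    }
  })

  error_curves <- apply(err, c(1, 2), mean)
  error_se <- apply(err, c(1, 2), stats::sd) / sqrt(R)
  error_se[is.na(error_se)] <- 0  # single repeat: no spread estimate
  aggregate_ranks <- lapply(rank_mats, function(m)
    apply(m, 1, stats::median, na.rm = TRUE))
  ranked_lists <- lapply(aggregate_ranks, function(ar)
    proteins[order(ar, names(ar))])
  chosen_ks <- vapply(groups, function(g) {
    mu <- error_curves[g, ]; se <- error_se[g, ]
    best <- which.min(mu)
    ks[min(which(mu <= mu[best] + se[best]))]
  }, integer(1))
  structure(list(error_curves = error_curves, error_se = error_se,
                 ranked_lists = ranked_lists,
                 aggregate_ranks = aggregate_ranks,
                 chosen_ks = chosen_ks, candidate_ks = ks,
                 error_trace = err, test_splits = test_splits,
                 groups = groups, params = params),
            class = "cv_signature")
}

#' @export
print.cv_signature <- function(x, ...) {
  cat(sprintf("cv_signature: %d groups, %d repeats\n",
              length(x$groups), dim(x$error_trace)[3]))
  cat("chosen k per group:",
      paste(sprintf("%s=%d", x$groups, x$chosen_ks), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the final discriminating signature
#'
#' The union of the top-k proteins of each group's ranked list. Reports the
#' per-group contributions and how many proteins are shared between lists
#' (so, e.g., lists of 53, 10 and 10 proteins with six proteins overlapping
#' in total combine into a 67-protein signature).
#'
#' @param ranked_lists Named list of ranked protein id vectors (or a
#'   `cv_signature`, whose aggregate lists are used).
#' @param chosen_ks Per-group list sizes; defaults to the `cv_signature`'s
#'   chosen ks.
#' @return List of class `signature_result` with `signature` (the union,
#'   in first-appearance order), `per_group` (top-k lists), `chosen_ks`
#'   and `n_overlap`.
#' @export
assemble_signature <- function(ranked_lists, chosen_ks = NULL) {
  if (inherits(ranked_lists, "cv_signature")) {
    if (is.null(chosen_ks)) chosen_ks <- ranked_lists$chosen_ks
    ranked_lists <- ranked_lists$ranked_lists
  }
  if (is.null(chosen_ks)) stopf("`chosen_ks` required")
  chosen_ks <- rep_len(chosen_ks, length(ranked_lists))
  if (any(chosen_ks > lengths(ranked_lists)))
    stopf("chosen k exceeds a ranked list length")
  per_group <- Map(function(lst, k) lst[seq_len(k)], ranked_lists, chosen_ks)
  union_sig <- unique(unlist(per_group, use.names = FALSE))
  structure(list(signature = union_sig, per_group = per_group,
                 chosen_ks = stats::setNames(chosen_ks, names(ranked_lists)),
                 n_overlap = sum(chosen_ks) - length(union_sig)),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d proteins (%s; %d overlapping)\n",
              length(x$signature),
              paste(sprintf("%s: %d", names(x$per_group), x$chosen_ks),
                    collapse = ", "),
              x$n_overlap))
  invisible(x)
}

#' Apply a protein signature to stratify a sample cohort
#'
#' Restricts the matrix to the signature proteins, clusters the samples by
#' Spearman correlation distance with average-linkage hierarchical
#' clustering, and cuts the dendrogram into `k_clusters` clusters (default
#' two, an epithelial-like vs mesenchymal-like split). Cluster labels are
#' arbitrary integers; naming them is a downstream marker-direction
#' convention. At least half of the signature proteins must be present in
#' the matrix.
#'
#' @param x Complete numeric matrix (proteins x samples) or
#'   [protein_matrix()]; z-score first ([zscore_matrix()]), group-wise per
#'   cohort when mixing quantification technologies.
#' @param signature Character vector of protein ids.
#' @param k_clusters Number of clusters to cut (default 2).
#' @param linkage Linkage method (default average).
#' @return Named integer vector sample -> cluster, with the dendrogram in
#'   attribute `dendrogram` and the covered signature in attribute
#'   `signature_used`.
#' @export
apply_signature <- function(x, signature, k_clusters = 2,
                            linkage = "average") {
  if (inherits(x, "protein_matrix")) x <- x$values
  present <- intersect(signature, rownames(x))
  if (length(present) < length(signature) / 2)
    stopf("only %d of %d signature proteins present in the matrix",
          length(present), length(signature))
  sub <- x[present, , drop = FALSE]
  dend <- hierarchical_cluster(spearman_distance(sub), linkage = linkage)
  labels <- cut_clusters(dend, k_clusters)
  attr(labels, "dendrogram") <- dend
  attr(labels, "signature_used") <- present
  labels
}
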