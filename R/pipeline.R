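#' Configuration for the end-to-end stratification pipeline
#'
#' Bundles the per-stage parameters of [run_pipeline()]. Every stage keeps
#' its module-level default, so `pipeline_config()` reproduces the standard
#' analysis: flag removal, replicate filter (2 of 3), replicate averaging,
#' variability profiling (SD > 0.5), minimum-valid filter, down-shifted
#' imputation (width 0.15, shift 1.8), z-scoring, Spearman hierarchical
#' clustering and PCA, SVM signature derivation (85/15 x 250, s0 = 4),
#' two-cluster signature application, enrichment (Fisher and 1D, BH 0.02,
#' min size 4), a pairwise volcano comparison (s0 = 2, permutation FDR 5%)
#' and a log-rank survival comparison of the applied clusters.
#'
#' @param panel A [panel_config()] used when no data bundle is supplied.
#' @param min_replicates_quantified Replicate-filter threshold (default 2).
#' @param min_valid_values Minimum valid values per protein for clustering
#'   (default 10).
#' @param variability_cutoff SD cutoff for the high-variability set.
#' @param remove_plasma Drop the packaged plasma-protein list before
#'   multivariate analysis (default `FALSE`; enable for tissue-containing
#'   cohorts).
#' @param impute_width,impute_down_shift Imputation parameters.
#' @param n_groups Number of groups to cut from the whole-proteome
#'   dendrogram; these clusters become the class labels for signature
#'   derivation (default 3).
#' @param signature A [signature_params()].
#' @param k_apply Clusters cut when applying the signature (default 2).
#' @param volcano_s0,volcano_fdr,volcano_permutations Pairwise-comparison
#'   parameters (defaults 2, 0.05, 250).
#' @param enrich_min_size,enrich_fdr Enrichment parameters (defaults 4,
#'   0.02).
#' @param marker_ratio Optional length-2 protein id vector; reports the
#'   per-group log2 ratio of the first over the second (e.g. a
#'   CRABP2/FABP5-style functional read-out).
#' @param seed Pipeline seed; stage seeds derive from it.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(panel = panel_config(),
                            min_replicates_quantified = 2,
                            min_valid_values = 10,
                            variability_cutoff = 0.5,
                            remove_plasma = FALSE,
                            impute_width = 0.15, impute_down_shift = 1.8,
                            n_groups = 3,
                            signature = signature_params(),
                            k_apply = 2,
                            volcano_s0 = 2, volcano_fdr = 0.05,
                            volcano_permutations = 250,
                            enrich_min_size = 4, enrich_fdr = 0.02,
                            marker_ratio = NULL,
                            seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full stratification pipeline
#'
#' Chains the analysis stages in their canonical order on a data bundle
#' (as produced by [generate_panel()], or assembled from files read with
#' [read_protein_groups()], [read_gmt()] and `read.csv`): flag removal ->
#' replicate filter -> replicate averaging -> variability profiling ->
#' minimum-valid filter -> imputation -> z-scoring -> Spearman
#' hierarchical clustering and PCA -> signature derivation on the cluster
#' labels -> two-cluster signature application -> annotation enrichment
#' (Fisher on the signature set, 1D on the pairwise fold changes) ->
#' pairwise volcano comparison with permutation FDR -> survival
#' comparison of the applied clusters. A machine-readable manifest records
#' inputs, parameters, seeds and the row/column counts after every stage.
#'
#' @param config A [pipeline_config()].
#' @param panel Optional data bundle: list with `matrix`
#'   ([protein_matrix()]), and optionally `annotations` and `survival`.
#'   When `NULL`, a synthetic panel is generated from `config$panel`.
#' @return List of class `pipeline_result` with the per-stage outputs and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), panel = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(panel)) panel <- generate_panel(config$panel)
  manifest <- list(seed = config$seed, parameters = config[
    setdiff(names(config), c("panel", "out_dir"))], stages = list())
  log_stage <- function(name, pm) {
    manifest$stages[[name]] <<- c(n_proteins = nrow(pm$values),
                                  n_samples = ncol(pm$values))
    message(sprintf("[%s] %d proteins x %d samples", name,
                    nrow(pm$values), ncol(pm$values)))
  }

  pm <- panel$matrix
  log_stage("input", pm)
  pm <- remove_flagged(pm)
  log_stage("remove_flagged", pm)
  pm <- filter_replicates(pm, config$min_replicates_quantified)
  log_stage("filter_replicates", pm)
  pm <- average_replicates(pm)
  log_stage("average_replicates", pm)

  variability <- protein_variability(pm, min_valid = config$min_valid_values)
  high_var <- high_variability_set(variability, config$variability_cutoff)

  pm <- filter_min_valid(pm, config$min_valid_values)
  log_stage("filter_min_valid", pm)
  if (isTRUE(config$remove_plasma)) {
    pm <- remove_plasma_proteins(pm)
    log_stage("remove_plasma", pm)
  }
  pm <- impute_downshifted(pm, width = config$impute_width,
                           down_shift = config$impute_down_shift,
                           seed = config$seed)
  pmz <- suppressWarnings(zscore_matrix(pm))

  dend <- hierarchical_cluster(spearman_distance(pmz$values))
  groups <- cut_clusters(dend, config$n_groups)
  pca <- pca_samples(pmz$values)

  cv <- cv_feature_selection(pmz$values, groups, config$signature)
  sig <- assemble_signature(cv)
  applied <- apply_signature(pmz$values, sig$signature,
                             k_clusters = config$k_apply)

  # pairwise comparison between the two applied clusters (on imputed,
  # un-standardized log2 values so differences are log2 fold changes)
  volcano <- NULL; enrich_fisher <- NULL; enrich_1d <- NULL
  if (config$k_apply == 2 && length(unique(applied)) == 2) {
    volcano <- permutation_fdr(pm$values, labels = applied,
                               s0 = config$volcano_s0,
                               n_permutations = config$volcano_permutations,
                               fdr_threshold = config$volcano_fdr,
                               seed = config$seed)
    if (!is.null(panel$annotations)) {
      enrich_fisher <- fisher_enrichment(
        foreground = intersect(sig$signature, rownames(pm$values)),
        background = rownames(pm$values),
        annotations = panel$annotations,
        min_category_size = config$enrich_min_size,
        fdr_threshold = config$enrich_fdr)
      diffs <- stats::setNames(volcano$results$difference,
                               volcano$results$protein)
      enrich_1d <- enrichment_1d(diffs[!is.na(diffs)], panel$annotations,
                                 min_category_size = config$enrich_min_size,
                                 fdr_threshold = config$enrich_fdr)
    }
  }

  survival_res <- NULL
  if (!is.null(panel$survival)) {
    tab <- panel$survival
    if (!all(tab$cluster %in% unique(applied)) &&
        "group" %in% names(pm$meta)) {
      # map planted groups to the applied two-cluster split by majority vote
      map <- tapply(applied, pm$meta$group[match(names(applied),
                                                 pm$meta$sample)],
                    function(v) as.integer(names(which.max(table(v)))))
      tab$cluster <- unname(map[as.character(tab$cluster)])
    }
    if (length(unique(tab$cluster)) == 2 &&
        all(tapply(tab$event, tab$cluster, sum) >= 1)) {
      survival_res <- list(
        logrank = logrank_test(tab),
        km = lapply(split(tab, tab$cluster),
                    function(s) km_estimate(s)))
    }
  }

  marker_ratio <- NULL
  if (!is.null(config$marker_ratio)) {
    marker_ratio <- marker_ratio_report(pm, config$marker_ratio[1],
                                        config$marker_ratio[2],
                                        groups = groups)
  }

  out <- structure(list(matrix = pm, zscored = pmz,
                        variability = variability,
                        high_variability = high_var,
                        dendrogram = dend, groups = groups, pca = pca,
                        cv = cv, signature = sig, applied = applied,
                        volcano = volcano, enrichment_fisher = enrich_fisher,
                        enrichment_1d = enrich_1d, survival = survival_res,
                        marker_ratio = marker_ratio, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Per-group log2 ratio of two proteins
#'
#' A configurable functional read-out: the mean log2 ratio of one protein
#' over another within each sample group (for instance the ratio of a
#' retinoic-acid transporter to its competing lipid-binding protein, which
#' separates retinoid-responsive from non-responsive lines).
#'
#' @param x A [protein_matrix()] of log2 values.
#' @param numerator,denominator Protein ids.
#' @param groups Named group label per sample (default: `meta$group`).
#' @return `data.frame(group, mean_log2_ratio, n)`.
#' @export
marker_ratio_report <- function(x, numerator, denominator, groups = NULL) {
  stopifnot(inherits(x, "protein_matrix"))
  for (p in c(numerator, denominator))
    if (!p %in% rownames(x$values)) stopf("protein '%s' not in matrix", p)
  if (is.null(groups)) groups <- stats::setNames(x$meta$group, x$meta$sample)
  lr <- x$values[numerator, ] - x$values[denominator, ]
  g <- groups[colnames(x$values)]
  agg <- tapply(lr, g, function(v) mean(v, na.rm = TRUE))
  data.frame(group = names(agg), mean_log2_ratio = as.numeric(agg),
             n = as.integer(table(g)[names(agg)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (nm in names(x$manifest$stages))
    cat(sprintf("  %-18s %5d proteins x %3d samples\n", nm,
                x$manifest$stages[[nm]][["n_proteins"]],
                x$manifest$stages[[nm]][["n_samples"]]))
  cat(sprintf("  signature: %d proteins; applied clusters: %s\n",
              length(x$signature$signature),
              paste(table(x$applied), collapse = "/")))
  invisible(x)
}

# Write the result bundle as CSV/TSV plus a JSON manifest (if jsonlite is
# available; otherwise the manifest is dput()-serialized).
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$variability, file.path(dir, "variability.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample = names(res$applied),
                              cluster = as.integer(res$applied)),
                   file.path(dir, "applied_clusters.csv"), row.names = FALSE)
  sig_tab <- data.frame(
    protein = res$signature$signature,
    groups = vapply(res$signature$signature, function(p)
      paste(names(res$signature$per_group)[
        vapply(res$signature$per_group, function(l) p %in% l, logical(1))],
        collapse = ";"), character(1)))
  utils::write.table(sig_tab, file.path(dir, "signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(res$cv$error_curves),
                   file.path(dir, "error_curves.csv"))
  if (!is.null(res$volcano))
    utils::write.csv(res$volcano$results, file.path(dir, "volcano.csv"),
                     row.names = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(res$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  } else {
    dput(res$manifest, file.path(dir, "manifest.R"))
  }
  invisible(dir)
}
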