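#' Configuration for the synthetic cell-line panel generator
#'
#' Describes a panel of cell lines measured in replicate: a fixed number of
#' groups (subtypes), each with several lines profiled in consecutive-passage
#' replicates; group-specific marker proteins shifted by a planted log2
#' effect; intensity-dependent (left-censored) missingness; annotation
#' categories concentrated on the markers; and group-dependent survival
#' times for a matched patient cohort.
#'
#' Intensities are generated on log2 scale with Gaussian noise and
#' exponentiated wherever raw intensities are needed, matching the log-scale
#' analysis used throughout the pipeline.
#'
#' @param n_groups Number of planted groups (default 3, as in a panel split
#'   into epithelial / clear-cell / mesenchymal subtypes).
#' @param lines_per_group Cell lines per group (default 10, i.e. a 30-line
#'   panel at three groups).
#' @param replicates_per_line Replicates per line (default 3).
#' @param n_proteins Number of proteins (default 1000).
#' @param markers_per_group Marker proteins planted per group (default 50).
#' @param effect_size Log2 shift of a marker in its own group versus all
#'   others (default 4, i.e. 16-fold; subtype markers in deep proteomes
#'   separate by one to 1.5 orders of magnitude).
#' @param base_mean,base_sd Location and spread of per-protein baseline
#'   log2 intensities (defaults 25 and 2, typical of LFQ intensities).
#' @param noise_sd Within-line replicate noise, log2 units (default 0.3,
#'   consistent with replicate correlations around 0.95).
#' @param missing_censor_quantile Target overall fraction of left-censored
#'   missing values in `[0, 1)` (default 0.2). Missingness probability
#'   decreases smoothly (probit-style) with log intensity around each
#'   sample's censoring quantile, so low-abundance values are lost
#'   preferentially while the overall missing fraction stays near the target.
#' @param n_categories Number of annotation categories (default 20).
#' @param marker_category_fraction Fraction of each group's marker set
#'   collected into that group's dedicated annotation category (default 0.8).
#' @param survival_median_by_group Planted median survival per group, in
#'   months (default `c(58, 50, 43.5)`, spanning the survival gap between
#'   epithelial-like and mesenchymal-like tumour clusters).
#' @param patients_per_group Patients per group in the survival table
#'   (default 28, i.e. 84 patients at three groups).
#' @param censor_rate Expected fraction of censored survival records in
#'   `[0, 1)` (default 0.2).
#' @param seed Integer seed; a fixed seed makes all outputs bit-identical.
#'
#' @return A validated `panel_config` list.
#' @export
panel_config <- function(n_groups = 3, lines_per_group = 10,
                         replicates_per_line = 3, n_proteins = 1000,
                         markers_per_group = 50, effect_size = 4,
                         base_mean = 25, base_sd = 2, noise_sd = 0.3,
                         missing_censor_quantile = 0.2, n_categories = 20,
                         marker_category_fraction = 0.8,
                         survival_median_by_group = c(58, 50, 43.5),
                         patients_per_group = 28, censor_rate = 0.2,
                         seed = 1L) {
  cfg <- list(n_groups = n_groups, lines_per_group = lines_per_group,
              replicates_per_line = replicates_per_line,
              n_proteins = n_proteins, markers_per_group = markers_per_group,
              effect_size = effect_size, base_mean = base_mean,
              base_sd = base_sd, noise_sd = noise_sd,
              missing_censor_quantile = missing_censor_quantile,
              n_categories = n_categories,
              marker_category_fraction = marker_category_fraction,
              survival_median_by_group = rep_len(survival_median_by_group,
                                                 n_groups),
              patients_per_group = patients_per_group,
              censor_rate = censor_rate, seed = as.integer(seed))
  for (f in c("n_groups", "lines_per_group", "replicates_per_line",
              "n_proteins", "patients_per_group"))
    if (!is_count(cfg[[f]])) stopf("invalid config: `%s` must be a count >= 1", f)
  if (!is_count(cfg$markers_per_group, min = 0L))
    stopf("invalid config: `markers_per_group` must be a count >= 0")
  if (cfg$effect_size < 0) stopf("invalid config: `effect_size` must be >= 0")
  for (f in c("missing_censor_quantile", "marker_category_fraction",
              "censor_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1)
      stopf("invalid config: `%s` must be in [0, 1)", f)
  if (cfg$n_groups * cfg$markers_per_group > cfg$n_proteins)
    stopf("invalid config: more markers than proteins")
  if (any(cfg$survival_median_by_group <= 0))
    stopf("invalid config: survival medians must be positive")
  class(cfg) <- "panel_config"
  cfg
}

#' Generate a synthetic cell-line panel with planted structure
#'
#' Draws a full data bundle for pipeline validation: a protein intensity
#' matrix with group-specific markers and left-censored missingness, the
#' sample metadata, an annotation set whose first categories concentrate on
#' the planted markers, a survival table with group-dependent event times,
#' and the ground truth needed for recovery tests.
#'
#' @param config A [panel_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{matrix}{[protein_matrix()] of log2 intensities with iBAQ values.}
#'     \item{meta}{Per-sample metadata (also embedded in the matrix).}
#'     \item{annotations}{Named list of category -> protein ids.}
#'     \item{survival}{`data.frame(time, event, cluster)`, one row per patient.}
#'     \item{truth}{List with `group_of_sample`, `group_of_line`,
#'       `markers_of_group`, `planted_effect`, `planted_survival_medians`.}
#'   }
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  cfg <- config
  with_seed(cfg$seed, {
    groups <- paste0("G", seq_len(cfg$n_groups))
    lines <- unlist(lapply(groups, function(g)
      sprintf("%s_L%02d", g, seq_len(cfg$lines_per_group))))
    group_of_line <- stats::setNames(rep(groups, each = cfg$lines_per_group),
                                     lines)
    samples <- unlist(lapply(lines, function(l)
      sprintf("%s_R%d", l, seq_len(cfg$replicates_per_line))))
    group_of_sample <- stats::setNames(
      rep(group_of_line, each = cfg$replicates_per_line), samples)
    line_of_sample <- rep(lines, each = cfg$replicates_per_line)

    proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
    markers_of_group <- list()
    if (cfg$markers_per_group > 0) {
      for (i in seq_along(groups)) {
        idx <- ((i - 1) * cfg$markers_per_group + 1):(i * cfg$markers_per_group)
        markers_of_group[[groups[i]]] <- proteins[idx]
      }
    } else markers_of_group <- stats::setNames(
      rep(list(character(0)), cfg$n_groups), groups)

    baseline <- stats::rnorm(cfg$n_proteins, cfg$base_mean, cfg$base_sd)
    shift <- matrix(0, cfg$n_proteins, length(samples),
                    dimnames = list(proteins, samples))
    for (g in groups) {
      cols <- group_of_sample == g
      shift[markers_of_group[[g]], cols] <- cfg$effect_size
    }
    vals <- baseline + shift +
      matrix(stats::rnorm(cfg$n_proteins * length(samples), 0, cfg$noise_sd),
             cfg$n_proteins, length(samples))
    dimnames(vals) <- list(proteins, samples)

    # iBAQ: raw intensity divided by a per-protein theoretical peptide count
    n_theor <- sample(5:50, cfg$n_proteins, replace = TRUE)
    ibaq <- 2^vals / n_theor

    # probit-style left censoring around each sample's target quantile
    if (cfg$missing_censor_quantile > 0) {
      tau <- 0.5 * cfg$base_sd
      for (j in seq_len(ncol(vals))) {
        # calibrate the censoring threshold so the expected missing
        # fraction of this column equals the configured target
        thr <- stats::uniroot(function(t)
          mean(stats::pnorm((t - vals[, j]) / tau)) -
            cfg$missing_censor_quantile,
          range(vals[, j]) + c(-10, 10) * tau)$root
        p_miss <- stats::pnorm((thr - vals[, j]) / tau)
        miss <- stats::runif(nrow(vals)) < p_miss
        vals[miss, j] <- NA_real_
        ibaq[miss, j] <- NA_real_
      }
    }

    meta <- data.frame(sample = samples, entity = "cell line",
                       line = line_of_sample,
                       replicate = rep(seq_len(cfg$replicates_per_line),
                                       times = length(lines)),
                       group = unname(group_of_sample), cohort = "LFQ",
                       stringsAsFactors = FALSE)

    annotations <- list()
    for (g in groups) {
      mk <- markers_of_group[[g]]
      n_in <- round(cfg$marker_category_fraction * length(mk))
      annotations[[paste0("MARKER_SET_", g)]] <-
        if (n_in > 0) sample(mk, n_in) else character(0)
    }
    n_rand <- max(0L, cfg$n_categories - length(annotations))
    nonmarkers <- setdiff(proteins, unlist(markers_of_group))
    for (i in seq_len(n_rand)) {
      sz <- min(sample(10:50, 1), length(nonmarkers))
      annotations[[sprintf("RANDOM_SET_%02d", i)]] <-
        if (sz > 0) sample(nonmarkers, sz) else character(0)
    }

    surv_list <- lapply(seq_along(groups), function(i) {
      med <- cfg$survival_median_by_group[i]
      rate <- log(2) / med
      t_event <- stats::rexp(cfg$patients_per_group, rate)
      if (cfg$censor_rate > 0) {
        rate_c <- rate * cfg$censor_rate / (1 - cfg$censor_rate)
        t_cens <- stats::rexp(cfg$patients_per_group, rate_c)
      } else t_cens <- rep(Inf, cfg$patients_per_group)
      data.frame(time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 cluster = groups[i], stringsAsFactors = FALSE)
    })
    survival_tab <- do.call(rbind, surv_list)

    pm <- protein_matrix(vals, meta = meta, ibaq = ibaq)
    list(matrix = pm, meta = meta, annotations = annotations,
         survival = survival_tab,
         truth = list(group_of_sample = group_of_sample,
                      group_of_line = group_of_line,
                      markers_of_group = markers_of_group,
                      planted_effect = cfg$effect_size,
                      planted_survival_medians = stats::setNames(
                        cfg$survival_median_by_group, groups)))
  })
}

#' Generate a synthetic peptide-level intensity table
#'
#' Test fixture for the quantification module: each peptide's raw intensity
#' is its peptide-specific base abundance times its protein's per-sample
#' profile times multiplicative log-normal noise.
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Peptides per protein (>= 1).
#' @param n_samples Number of samples.
#' @param profile True per-sample log2 offsets: either a matrix
#'   (`n_proteins` x `n_samples`), a vector of length `n_samples` shared by
#'   all proteins, or `NULL` to draw standard-normal offsets per protein and
#'   sample.
#' @param noise_sd Multiplicative noise on log2 scale (>= 0).
#' @param missing_rate Fraction of peptide intensities removed completely at
#'   random.
#' @param seed Integer seed.
#'
#' @return A list with `peptides` (a `peptide_table`) and `profiles`
#'   (the true log2 profile matrix, proteins x samples).
#' @export
generate_peptide_table <- function(n_proteins, peptides_per_protein,
                                   n_samples, profile = NULL, noise_sd = 0.1,
                                   missing_rate = 0, seed = 1L) {
  if (!is_count(peptides_per_protein))
    stopf("invalid config: `peptides_per_protein` must be >= 1")
  if (noise_sd < 0) stopf("invalid config: `noise_sd` must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("invalid config: `missing_rate` must be in [0, 1)")
  with_seed(seed, {
    proteins <- sprintf("P%04d", seq_len(n_proteins))
    samples <- sprintf("S%02d", seq_len(n_samples))
    if (is.null(profile)) {
      prof <- matrix(stats::rnorm(n_proteins * n_samples), n_proteins,
                     n_samples)
    } else if (is.matrix(profile)) {
      stopifnot(nrow(profile) == n_proteins, ncol(profile) == n_samples)
      prof <- profile
    } else {
      stopifnot(length(profile) == n_samples)
      prof <- matrix(rep(profile, each = n_proteins), n_proteins, n_samples)
    }
    dimnames(prof) <- list(proteins, samples)

    n_pep <- n_proteins * peptides_per_protein
    pep_protein <- rep(proteins, each = peptides_per_protein)
    pep_id <- sprintf("%s_pep%02d", pep_protein,
                      rep(seq_len(peptides_per_protein), times = n_proteins))
    pep_base <- stats::rnorm(n_pep, mean = 20, sd = 1.5)
    log_int <- pep_base + prof[pep_protein, , drop = FALSE] +
      matrix(stats::rnorm(n_pep * n_samples, 0, noise_sd), n_pep, n_samples)
    intensities <- 2^log_int
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_pep * n_samples) < missing_rate,
                     n_pep, n_samples)
      intensities[miss] <- NA_real_
    }
    dimnames(intensities) <- list(pep_id, samples)
    list(peptides = peptide_table(pep_id, pep_protein, intensities),
         profiles = prof)
  })
}

#' Write a generated panel to disk in standard formats
#'
#' Writes the protein matrix as a MaxQuant-style TSV, the annotations as
#' GMT, and the metadata and survival tables as CSV.
#'
#' @param panel Output of [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteinGroups.txt"),
             annotations = file.path(dir, "annotations.gmt"),
             meta = file.path(dir, "samples.csv"),
             survival = file.path(dir, "survival.csv"))
  write_protein_groups(panel$matrix, paths[["proteins"]])
  write_gmt(panel$annotations, paths[["annotations"]])
  utils::write.csv(panel$meta, paths[["meta"]], row.names = FALSE)
  utils::write.csv(panel$survival, paths[["survival"]], row.names = FALSE)
  invisible(paths)
}
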