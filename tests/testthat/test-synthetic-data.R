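test_that("generation is deterministic under a fixed seed", {
  cfg <- panel_config(n_proteins = 120, markers_per_group = 10,
                      lines_per_group = 3, seed = 99)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$survival, b$survival)
  # and sensitive to the seed
  c <- generate_panel(panel_config(n_proteins = 120, markers_per_group = 10,
                                   lines_per_group = 3, seed = 100))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("panel dimensions and truth bookkeeping are consistent", {
  cfg <- panel_config(n_groups = 3, lines_per_group = 4,
                      replicates_per_line = 3, n_proteins = 200,
                      markers_per_group = 10, seed = 2)
  p <- generate_panel(cfg)
  expect_equal(dim(p$matrix$values), c(200, 36))
  expect_equal(length(p$truth$group_of_sample), 36)
  expect_equal(lengths(p$truth$markers_of_group),
               c(G1 = 10, G2 = 10, G3 = 10))
  # marker sets are disjoint
  expect_equal(anyDuplicated(unlist(p$truth$markers_of_group)), 0)
  # every sample has exactly one group
  expect_true(all(table(names(p$truth$group_of_sample)) == 1))
})

test_that("markers are shifted by the planted effect in their own group", {
  cfg <- panel_config(n_proteins = 300, markers_per_group = 20,
                      effect_size = 3, missing_censor_quantile = 0,
                      seed = 4)
  p <- generate_panel(cfg)
  mk <- p$truth$markers_of_group$G1
  own <- p$truth$group_of_sample == "G1"
  gap <- rowMeans(p$matrix$values[mk, own]) -
    rowMeans(p$matrix$values[mk, !own])
  expect_equal(mean(gap), 3, tolerance = 0.1)
})

test_that("zero censoring quantile gives a complete matrix; zero effect a null panel", {
  p0 <- generate_panel(panel_config(n_proteins = 100, markers_per_group = 10,
                                    missing_censor_quantile = 0, seed = 5))
  expect_false(anyNA(p0$matrix$values))
  pn <- generate_panel(panel_config(n_proteins = 100, markers_per_group = 10,
                                    effect_size = 0,
                                    missing_censor_quantile = 0, seed = 5))
  mk <- pn$truth$markers_of_group$G1
  own <- pn$truth$group_of_sample == "G1"
  gap <- rowMeans(pn$matrix$values[mk, own]) -
    rowMeans(pn$matrix$values[mk, !own])
  expect_lt(abs(mean(gap)), 0.1)
})

test_that("missingness is left-censored and calibrated to the target", {
  cfg <- panel_config(n_proteins = 500, missing_censor_quantile = 0.25,
                      seed = 8)
  cfg0 <- panel_config(n_proteins = 500, missing_censor_quantile = 0,
                       seed = 8)
  p <- generate_panel(cfg)
  truthful <- generate_panel(cfg0)$matrix$values  # same draws, no censoring
  miss <- is.na(p$matrix$values)
  expect_lt(mean(truthful[miss]), mean(truthful[!miss]))
  expect_equal(mean(miss), 0.25, tolerance = 0.02)
})

test_that("planted markers dominate their group's one-vs-all ranking", {
  cfg <- panel_config(n_groups = 3, markers_per_group = 50, effect_size = 4,
                      seed = 1)
  p <- generate_panel(cfg)
  for (g in c("G1", "G2", "G3")) {
    rk <- rank_proteins_ova(p$matrix$values, p$truth$group_of_sample, g,
                            s0 = 4)
    top60 <- rk$protein[1:60]
    recovery <- mean(p$truth$markers_of_group[[g]] %in% top60)
    expect_gte(recovery, 0.9)
  }
})

test_that("Kaplan-Meier medians recover the planted survival ordering", {
  cfg <- panel_config(n_proteins = 10, markers_per_group = 0,
                      survival_median_by_group = c(100, 50, 25),
                      patients_per_group = 400, censor_rate = 0.1, seed = 3)
  p <- generate_panel(cfg)
  meds <- vapply(c("G1", "G2", "G3"),
                 function(g) km_estimate(p$survival, g)$median, numeric(1))
  expect_equal(order(meds, decreasing = TRUE), 1:3)
  # medians near the planted values at this sample size
  expect_equal(unname(meds), c(100, 50, 25), tolerance = 0.2)
  # censoring fraction near its target
  expect_lt(abs((1 - mean(p$survival$event)) - 0.1), 0.03)
})

test_that("annotation categories concentrate on the marker sets as configured", {
  cfg <- panel_config(n_proteins = 300, markers_per_group = 20,
                      marker_category_fraction = 0.8, n_categories = 10,
                      seed = 6)
  p <- generate_panel(cfg)
  expect_equal(length(p$annotations), 10)
  for (g in c("G1", "G2", "G3")) {
    cat_g <- p$annotations[[paste0("MARKER_SET_", g)]]
    expect_equal(length(cat_g), 16)  # 0.8 * 20
    expect_true(all(cat_g %in% p$truth$markers_of_group[[g]]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(panel_config(n_proteins = 0), "invalid config")
  expect_error(panel_config(n_groups = 0), "invalid config")
  expect_error(panel_config(effect_size = -1), "invalid config")
  expect_error(panel_config(missing_censor_quantile = 1), "invalid config")
  expect_error(panel_config(n_proteins = 10, markers_per_group = 5),
               "more markers than proteins")
  expect_error(generate_peptide_table(2, 2, 2, noise_sd = -0.1),
               "invalid config")
  expect_error(generate_peptide_table(2, 0, 2), "invalid config")
})

test_that("panel files round-trip through the standard formats", {
  dir <- withr::local_tempdir()
  p <- generate_panel(panel_config(n_proteins = 50, markers_per_group = 5,
                                   lines_per_group = 2, seed = 12))
  paths <- write_panel(p, dir)
  back <- read_protein_groups(paths[["proteins"]])
  expect_equal(back$values, p$matrix$values, tolerance = 1e-12)
  expect_equal(read_gmt(paths[["annotations"]]), p$annotations)
  surv <- read.csv(paths[["survival"]])
  expect_equal(surv$time, p$survival$time, tolerance = 1e-12)
})
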