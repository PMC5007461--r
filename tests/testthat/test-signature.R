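test_that("one-vs-all ranking puts strong planted markers first", {
  set.seed(61)
  x <- matrix(rnorm(100 * 12, 25, 0.5), 100, 12,
              dimnames = list(sprintf("P%03d", 1:100), paste0("s", 1:12)))
  groups <- rep(c("G1", "G2", "G3"), each = 4)
  x["P001", groups == "G1"] <- x["P001", groups == "G1"] + 3  # 8-fold
  rk <- rank_proteins_ova(x, groups, "G1", s0 = 4)
  expect_equal(rk$protein[1], "P001")
  expect_equal(rk$rank, seq_len(100))
  expect_error(rank_proteins_ova(x[, 1:5], groups[1:5], "G2"), ">= 2 samples")
})

test_that("as s0 grows the ranking converges to ordering by |difference|", {
  set.seed(62)
  x <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("P%02d", 1:50), paste0("s", 1:10)))
  groups <- rep(c("A", "B"), each = 5)
  rk <- rank_proteins_ova(x, groups, "A", s0 = 1e6)
  by_diff <- rk$protein[order(-abs(rk$difference))]
  expect_equal(rk$protein, by_diff)
})

test_that("permuting labels destroys the marker ranking", {
  set.seed(63)
  x <- matrix(rnorm(200 * 12, 25, 0.5), 200, 12,
              dimnames = list(sprintf("P%03d", 1:200), paste0("s", 1:12)))
  groups <- rep(c("G1", "G2"), each = 6)
  x[1:10, groups == "G1"] <- x[1:10, groups == "G1"] + 3
  markers <- sprintf("P%03d", 1:10)
  rk_true <- rank_proteins_ova(x, groups, "G1", s0 = 4)
  true_med <- median(rk_true$rank[match(markers, rk_true$protein)])
  expect_lte(true_med, 10)
  # under permuted labels the studentized (s0 = 0) ranking of markers is
  # indistinguishable from the bulk: median rank near n/2 across draws
  perm_meds <- replicate(40, {
    perm <- sample(groups)
    rk <- rank_proteins_ova(x, perm, "G1", s0 = 0)
    median(rk$rank[match(markers, rk$protein)])
  })
  expect_gt(median(perm_meds), 200 * 0.25)
  expect_lt(median(perm_meds), 200 * 0.75)
})

test_that("cross-validated selection is reproducible and leak-free", {
  p <- generate_panel(panel_config(n_proteins = 150, markers_per_group = 10,
                                   effect_size = 3, lines_per_group = 5,
                                   missing_censor_quantile = 0, seed = 64))
  pm <- average_replicates(p$matrix)
  x <- suppressWarnings(zscore_matrix(pm))$values
  groups <- p$truth$group_of_line[colnames(x)]
  par <- signature_params(n_repeats = 3, candidate_ks = c(5, 10), seed = 7)
  cv1 <- cv_feature_selection(x, groups, par)
  cv2 <- cv_feature_selection(x, groups, par)
  expect_identical(cv1$error_trace, cv2$error_trace)
  expect_identical(cv1$ranked_lists, cv2$ranked_lists)

  # leakage guard: a signal living only in the held-out samples of a split
  # must not move that protein's training-derived rank
  par1 <- signature_params(n_repeats = 1, candidate_ks = c(5, 10), seed = 7)
  cv_a <- cv_feature_selection(x, groups, par1)
  held_out <- cv_a$test_splits[[1]]
  x2 <- x
  x2["P0149", held_out] <- x2["P0149", held_out] + 50
  cv_b <- cv_feature_selection(x2, groups, par1)
  expect_identical(cv_a$aggregate_ranks$G1[["P0149"]],
                   cv_b$aggregate_ranks$G1[["P0149"]])
})

test_that("held-out error sits at chance on null panels and drops with signal", {
  p0 <- generate_panel(panel_config(n_proteins = 100, effect_size = 0,
                                    markers_per_group = 10,
                                    lines_per_group = 5,
                                    missing_censor_quantile = 0, seed = 65))
  pm0 <- average_replicates(p0$matrix)
  x0 <- suppressWarnings(zscore_matrix(pm0))$values
  g0 <- p0$truth$group_of_line[colnames(x0)]
  cv0 <- cv_feature_selection(x0, g0, signature_params(
    n_repeats = 30, candidate_ks = c(5, 10), seed = 1))
  # one-vs-all baseline: always predicting "rest" errs at the group rate
  # (1/3 of held-out samples); errors should hover there, not at zero
  expect_gt(mean(cv0$error_curves), 0.1)

  p1 <- generate_panel(panel_config(n_proteins = 100, markers_per_group = 20,
                                    effect_size = 4, lines_per_group = 5,
                                    missing_censor_quantile = 0, seed = 66))
  pm1 <- average_replicates(p1$matrix)
  x1 <- suppressWarnings(zscore_matrix(pm1))$values
  g1 <- p1$truth$group_of_line[colnames(x1)]
  cv1 <- cv_feature_selection(x1, g1, signature_params(
    n_repeats = 30, candidate_ks = c(5, 10, 20), seed = 1))
  expect_lt(mean(cv1$error_curves), 0.02)
})

test_that("signature assembly counts unions and overlaps correctly", {
  # lists sized 53/10/10 with six overlapping -> union of 67
  pool <- sprintf("Q%03d", 1:200)
  l1 <- pool[1:53]
  l2 <- c(pool[1:3], pool[54:60])          # 3 shared with list 1
  l3 <- c(pool[4:6], pool[61:67])          # 3 more shared with list 1
  sig <- assemble_signature(list(G1 = l1, G2 = l2, G3 = l3),
                            chosen_ks = c(53, 10, 10))
  expect_equal(length(sig$signature), 67)
  expect_equal(sig$n_overlap, 6)
  # disjoint lists of 5 -> union 15; identical lists -> union k
  dis <- assemble_signature(list(a = pool[1:5], b = pool[6:10],
                                 c = pool[11:15]), chosen_ks = 5)
  expect_equal(length(dis$signature), 15)
  same <- assemble_signature(list(a = pool[1:9], b = pool[1:9]),
                             chosen_ks = 4)
  expect_equal(length(same$signature), 4)
  expect_error(assemble_signature(list(a = pool[1:3]), chosen_ks = 5),
               "exceeds")
})

test_that("applying a derived signature separates one group from the rest", {
  p <- generate_panel(panel_config(n_proteins = 300, markers_per_group = 25,
                                   effect_size = 2, lines_per_group = 5,
                                   seed = 67))
  pm <- average_replicates(suppressMessages(filter_replicates(p$matrix)))
  pm <- impute_downshifted(filter_min_valid(pm, 10), seed = 67)
  x <- suppressWarnings(zscore_matrix(pm))$values
  groups <- p$truth$group_of_line[colnames(x)]
  cv <- cv_feature_selection(x, groups, signature_params(
    n_repeats = 25, candidate_ks = c(5, 10, 25), seed = 2))
  sig <- assemble_signature(cv)
  labels <- apply_signature(x, sig$signature, k_clusters = 2)
  aris <- vapply(unique(groups), function(g)
    mclust::adjustedRandIndex(labels, groups == g), numeric(1))
  expect_equal(max(aris), 1)
})

test_that("apply_signature enforces coverage and co-clusters duplicates", {
  set.seed(68)
  x <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("P%02d", 1:50), paste0("s", 1:8)))
  expect_error(apply_signature(x, paste0("Z", 1:10)), "0 of 10")
  dup <- cbind(x, x)
  colnames(dup) <- c(paste0("s", 1:8), paste0("t", 1:8))
  labels <- apply_signature(dup, rownames(x)[1:30], k_clusters = 2)
  expect_equal(unname(labels[1:8]), unname(labels[9:16]))
})

test_that("signatures are stable across generator seeds on strong panels", {
  sigs <- lapply(c(71, 72), function(s) {
    p <- generate_panel(panel_config(n_proteins = 200, markers_per_group = 5,
                                     effect_size = 4, lines_per_group = 5,
                                     missing_censor_quantile = 0, seed = s))
    pm <- average_replicates(p$matrix)
    x <- suppressWarnings(zscore_matrix(pm))$values
    groups <- p$truth$group_of_line[colnames(x)]
    cv <- cv_feature_selection(x, groups, signature_params(
      n_repeats = 25, candidate_ks = c(5, 10), seed = 3))
    assemble_signature(cv)$signature
  })
  jaccard <- length(intersect(sigs[[1]], sigs[[2]])) /
    length(union(sigs[[1]], sigs[[2]]))
  expect_gte(jaccard, 0.8)
})
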