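test_that("proteinGroups TSV round-trips values, mask and flags", {
  flags <- data.frame(reverse = c(TRUE, rep(FALSE, 7)),
                      only_by_site = c(FALSE, TRUE, rep(FALSE, 6)),
                      contaminant = c(FALSE, FALSE, TRUE, rep(FALSE, 5)))
  pm <- make_pm(8, 5, flags = flags)
  pm$values[cbind(c(1, 3, 5), c(2, 4, 1))] <- NA
  pm$ibaq <- 2^pm$values / 7
  path <- withr::local_tempfile(fileext = ".txt")
  write_protein_groups(pm, path)
  back <- read_protein_groups(path)
  expect_equal(back$values, pm$values, tolerance = 1e-12)
  expect_equal(is.na(back$values), is.na(pm$values))
  expect_equal(back$flags, pm$flags, ignore_attr = TRUE)
  expect_equal(back$ibaq, pm$ibaq, tolerance = 1e-12)
})

test_that("zero LFQ intensities read as missing and '+' rows as flagged", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Protein IDs\tLFQ intensity A\tLFQ intensity B\tReverse\tOnly identified by site\tPotential contaminant",
               "P1\t0\t1024\t\t\t",
               "REV_P2\t512\t256\t+\t\t"), path)
  pm <- read_protein_groups(path)
  expect_true(is.na(pm$values["P1", "A"]))
  expect_equal(pm$values["P1", "B"], 10)
  expect_equal(pm$flags$reverse, c(FALSE, TRUE))
  expect_error(read_protein_groups(
    withr::local_tempfile(lines = "Sequence\tfoo", fileext = ".txt")),
    "Protein IDs")
})

test_that("flag removal drops reverse/site rows and (optionally) contaminants", {
  flags <- data.frame(reverse = c(TRUE, rep(FALSE, 9)),
                      only_by_site = c(FALSE, TRUE, rep(FALSE, 8)),
                      contaminant = c(FALSE, FALSE, TRUE, rep(FALSE, 7)))
  pm <- make_pm(10, 4, flags = flags)
  expect_equal(nrow(remove_flagged(pm)$values), 7)
  expect_equal(nrow(remove_flagged(pm, contaminants = FALSE)$values), 8)
  # no flags set -> identity
  pm2 <- make_pm(5, 4)
  expect_equal(remove_flagged(pm2)$values, pm2$values)
})

test_that("replicate filter enforces the per-line 2-of-3 rule", {
  meta <- make_line_meta(3)
  pm <- make_pm(6, 9, meta = meta)
  # protein 1: observed in exactly 1 of 3 replicates of every line -> dropped
  pm$values[1, c(2, 3, 5, 6, 8, 9)] <- NA
  # protein 2: line 1 has 1/3 (masked), line 2 has 2/3 (kept), line 3 full
  pm$values[2, c(1, 2, 4)] <- NA
  out <- suppressMessages(filter_replicates(pm, 2))
  expect_false("P001" %in% rownames(out$values))
  expect_true(all(is.na(out$values["P002", 1:3])))
  expect_equal(sum(!is.na(out$values["P002", 4:6])), 2)
  expect_equal(sum(!is.na(out$values["P002", 7:9])), 3)
  # fully observed rows unchanged
  expect_equal(out$values["P004", ], pm$values[4, ])

  # brute-force oracle on a random missingness pattern
  set.seed(9)
  pm2 <- make_pm(40, 9, meta = meta)
  pm2$values[sample(length(pm2$values), 150)] <- NA
  out2 <- suppressMessages(filter_replicates(pm2, 2))
  expected <- pm2$values
  for (p in seq_len(40)) for (l in 0:2) {
    cols <- l * 3 + 1:3
    if (sum(!is.na(pm2$values[p, cols])) < 2) expected[p, cols] <- NA
  }
  expected <- expected[rowSums(!is.na(expected)) > 0, ]
  expect_equal(out2$values, expected)
})

test_that("replicate averaging is the mean over valid replicates", {
  meta <- make_line_meta(2)
  pm <- make_pm(3, 6, meta = meta)
  pm$values[1, 1:3] <- c(10, 12, NA)
  pm$values[2, 1:3] <- c(NA, NA, NA)
  avg <- average_replicates(pm)
  expect_equal(ncol(avg$values), 2)
  expect_equal(avg$values[1, "L01"], 11)
  expect_true(is.na(avg$values[2, "L01"]))
  expect_equal(unname(avg$values[3, "L02"]), mean(pm$values[3, 4:6]))
})

test_that("minimum-valid filter keeps rows with >= n quantifications", {
  pm <- make_pm(5, 12)
  pm$values[1, 1:3] <- NA   # 9 valid
  pm$values[2, 1:2] <- NA   # 10 valid
  out <- filter_min_valid(pm, 10)
  expect_false("P001" %in% rownames(out$values))
  expect_true("P002" %in% rownames(out$values))
  expect_equal(filter_min_valid(pm, 0)$values, pm$values)
  expect_error(filter_min_valid(pm, 13), "invalid config")
})

test_that("plasma-protein removal drops exactly the listed ids", {
  pm <- make_pm(6, 4)
  rownames(pm$values) <- c("ALB", "APOA1", "X1", "X2", "X3", "X4")
  rownames(pm$flags) <- rownames(pm$values)
  out <- remove_plasma_proteins(pm)
  expect_equal(rownames(out$values), c("X1", "X2", "X3", "X4"))
  expect_equal(remove_plasma_proteins(pm, character(0))$values, pm$values)
  expect_equal(length(plasma_proteins()), 200)
})

test_that("z-scoring standardizes rows with the n-1 denominator", {
  pm <- make_pm(3, 3)
  pm$values[1, ] <- c(1, 2, 3)
  z <- zscore_matrix(pm)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(apply(z$values, 1, sd)), rep(1, 3))
  # constant row -> zeros with a warning
  pm$values[2, ] <- 5
  expect_warning(z2 <- zscore_matrix(pm), "zero-variance")
  expect_equal(unname(z2$values[2, ]), c(0, 0, 0))
})

test_that("group-wise z-scoring standardizes within each cohort", {
  pm <- make_pm(4, 6)
  pm$meta$cohort <- rep(c("LFQ", "ITRAQ"), each = 3)
  z <- zscore_matrix(pm, groupwise = TRUE)
  for (ch in c("LFQ", "ITRAQ")) {
    sub <- z$values[, pm$meta$cohort == ch]
    expect_equal(unname(rowMeans(sub)), rep(0, 4))
    expect_equal(unname(apply(sub, 1, sd)), rep(1, 4))
  }
})

test_that("reporter-channel normalization subtracts control and centres medians", {
  pm <- make_pm(10, 4)
  colnames(pm$values) <- c("S1", "S2", "S3", "C117")
  pm$meta$sample <- colnames(pm$values)
  # column equal to control -> all zeros after control subtraction + median shift
  pm$values[, "S1"] <- pm$values[, "C117"]
  out <- normalize_itraq(pm, "C117")
  expect_equal(unname(out$values[, "S1"]), rep(0, 10))
  expect_equal(unname(apply(out$values, 2, median)), rep(0, 3))
  expect_false("C117" %in% colnames(out$values))
  # brute-force check
  manual <- pm$values[, "S2"] - pm$values[, "C117"]
  manual <- manual - median(manual)
  expect_equal(out$values[, "S2"], manual)
  expect_error(normalize_itraq(pm, "C999"), "control channel")
})

test_that("down-shifted imputation matches its stated distribution", {
  # column with 100 observed values; 10^4 missing entries to impute
  set.seed(1)
  obs <- rnorm(100, mean = 20, sd = 1)
  vals <- matrix(c(obs, rep(NA_real_, 1e4)), ncol = 1,
                 dimnames = list(NULL, "S1"))
  rownames(vals) <- sprintf("P%05d", seq_len(nrow(vals)))
  pm <- protein_matrix(vals)
  out <- impute_downshifted(pm, seed = 7)
  imp <- out$values[is.na(vals[, 1]), 1]
  mu <- mean(obs); sdv <- sd(obs)
  se <- 0.15 * sdv / sqrt(1e4)
  expect_lt(abs(mean(imp) - (mu - 1.8 * sdv)), 3 * se)
  expect_lt(abs(sd(imp) - 0.15 * sdv) / (0.15 * sdv), 0.05)
  # observed entries untouched, provenance mask recorded
  expect_equal(out$values[1:100, 1], vals[1:100, 1])
  expect_equal(unname(out$imputed[, 1]), unname(is.na(vals[, 1])))
})

test_that("imputation degenerate limits behave", {
  pm <- make_pm(6, 3)
  expect_equal(impute_downshifted(pm, seed = 1)$values, pm$values)
  pm$values[1, 2] <- NA
  out <- impute_downshifted(pm, width = 1e-9, down_shift = 0, seed = 1)
  expect_equal(out$values[1, 2], mean(pm$values[-1, 2]), tolerance = 1e-6)
  expect_error(impute_downshifted(pm, width = 0), "invalid config")
})

test_that("imputation is deterministic under a seed and filters are idempotent", {
  pm <- make_pm(20, 6)
  pm$values[sample(length(pm$values), 30)] <- NA
  a <- impute_downshifted(pm, seed = 5)
  b <- impute_downshifted(pm, seed = 5)
  expect_identical(a$values, b$values)
  f1 <- filter_min_valid(pm, 4)
  expect_equal(filter_min_valid(f1, 4)$values, f1$values)
})
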