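test_that("beta classification respects the class boundaries", {
  expect_identical(as.character(classify_beta(c(0.10, 0.15, 0.80, 0.81, 0))),
                   c("hypo", "semi", "semi", "hyper", "hypo"))
  expect_error(classify_beta(1.2), "\\[0, 1\\]")
  expect_error(classify_beta(c(0.5, NA)), "missing")
  thr <- partition_thresholds(0.2, 0.7)
  expect_identical(as.character(classify_beta(c(0.19, 0.2, 0.7, 0.71), thr)),
                   c("hypo", "semi", "semi", "hyper"))
  expect_error(partition_thresholds(0.8, 0.15))
})

test_that("classification agrees with a brute-force three-way comparison", {
  set.seed(1)
  beta <- runif(10000)
  got <- as.character(classify_beta(beta))
  want <- vapply(beta, function(b) {
    if (b < 0.15) "hypo" else if (b > 0.8) "hyper" else "semi"
  }, character(1L))
  expect_identical(got, want)
})

test_that("per-sample partition counts, percentages and mean are right", {
  x <- toy_beta_set(cbind(a = c(0.1, 0.5, 0.9), b = c(0, 0, 0)))
  ps <- sample_partition(x)
  expect_equal(unlist(ps[1, c("pct_hypo", "pct_semi", "pct_hyper")]),
               c(pct_hypo = 100 / 3, pct_semi = 100 / 3, pct_hyper = 100 / 3))
  expect_equal(unlist(ps[2, c("pct_hypo", "pct_semi", "pct_hyper")]),
               c(pct_hypo = 100, pct_semi = 0, pct_hyper = 0))
  expect_equal(ps$mean_beta, c(0.5, 0))
})

test_that("partition percentages sum to 100 with missing data excluded", {
  set.seed(2)
  v <- matrix(runif(600), 100, 6)
  v[sample(length(v), 90)] <- NA
  ps <- sample_partition(toy_beta_set(v))
  expect_equal(ps$pct_hypo + ps$pct_semi + ps$pct_hyper, rep(100, 6))
  expect_equal(ps$n_hypo + ps$n_semi + ps$n_hyper, ps$n_evaluable)
  expect_equal(ps$n_evaluable, colSums(!is.na(v)), ignore_attr = TRUE)
})

test_that("a sample with zero evaluable CpGs is excluded with a warning", {
  v <- cbind(a = c(0.1, 0.9), b = c(NA, NA))
  expect_warning(ps <- sample_partition(toy_beta_set(v)), "zero evaluable")
  expect_identical(ps$sample_id, "a")
})

test_that("per-CpG classes come from the cohort mean and IQR behaves", {
  v <- rbind(c(0.0, 0.1), c(0.7, 0.95), c(0.4, 0.4))
  cp <- cpg_partition(toy_beta_set(v))
  expect_identical(as.character(cp$class), c("hypo", "hyper", "semi"))
  expect_equal(cp$mean_beta, c(0.05, 0.825, 0.4))
  expect_equal(cp$iqr[3], 0)  # constant across samples
  v2 <- rbind(c(NA, NA), c(0.2, 0.3))
  expect_warning(cp2 <- cpg_partition(toy_beta_set(v2)), "all-missing")
  expect_identical(nrow(cp2), 1L)
  expect_error(cpg_partition(toy_beta_set(matrix(0.5, 3, 1))), "two samples")
})

cgi_fixture <- function(values, island_ids, refgene = NULL) {
  n <- nrow(values)
  ann <- do.call(rbind, lapply(seq_len(n), function(i)
    ann_row(sprintf("cg%03d", i), pos = i * 1000,
            relation_to_island = if (is.na(island_ids[i])) "OpenSea"
                                 else "Island",
            island_id = island_ids[i],
            refgene_group = if (is.null(refgene)) "Body" else refgene[i],
            gene = sprintf("GENE%d", i))))
  toy_beta_set(values, annotation = ann)
}

test_that("island hypermethylation status follows the island mean rule", {
  v <- rbind(c(0.90), c(0.85), c(0.10))
  x <- cgi_fixture(v, c("isl1", "isl1", "isl2"))
  cm <- cgi_metrics(x)
  expect_identical(cm$n_islands, 2L)
  expect_identical(unname(cm$status["isl1", 1]), TRUE)   # mean 0.875 > 0.8
  expect_identical(unname(cm$status["isl2", 1]), FALSE)
  expect_equal(cm$per_sample$pct_hyper_cgi, 50)
  # all-zero islands give zero percent and zero mean
  x0 <- cgi_fixture(matrix(0, 3, 1), c("isl1", "isl1", "isl2"))
  cm0 <- cgi_metrics(x0)
  expect_equal(cm0$per_sample$cgi_mean_beta, 0)
  expect_equal(cm0$per_sample$pct_hyper_cgi, 0)
})

test_that("percent hypermethylated CGIs is plain counting over islands", {
  # 10 one-CpG islands, exactly 3 above 0.8
  v <- matrix(c(rep(0.9, 3), rep(0.1, 7)), ncol = 1)
  x <- cgi_fixture(v, sprintf("isl%02d", 1:10))
  expect_equal(cgi_metrics(x)$per_sample$pct_hyper_cgi, 30)
})

test_that("mean rule and any-CpG rule disagree exactly when they should", {
  v <- rbind(c(0.95), c(0.5))  # island mean 0.725 but one CpG above 0.8
  x <- cgi_fixture(v, c("isl1", "isl1"))
  expect_false(cgi_metrics(x, island_rule = "mean")$status["isl1", 1])
  expect_true(cgi_metrics(x, island_rule = "any")$status["isl1", 1])
})

test_that("promoter-restricted islands are a subset of the global set", {
  v <- matrix(runif(8), ncol = 1)
  x <- cgi_fixture(v, c("i1", "i1", "i2", "i2", "i3", NA, NA, NA),
                   refgene = c("TSS200", "TSS200", "Body", "Body",
                               "TSS1500;Body", "Body", "5'UTR", "Body"))
  glob <- cgi_metrics(x)
  prom <- cgi_metrics(x, promoter_only = TRUE)
  expect_lte(prom$n_islands, glob$n_islands)
  expect_true(all(rownames(prom$status) %in% rownames(glob$status)))
  expect_identical(sort(rownames(prom$status)), c("i1", "i3"))
  expect_error(cgi_metrics(x[6:8, ]), "island-annotated")
})

test_that("contiguous-run island grouping is used when island_id is absent", {
  ann <- rbind(
    ann_row("cg1", pos = 100, relation_to_island = "Island"),
    ann_row("cg2", pos = 200, relation_to_island = "Island"),
    ann_row("cg3", pos = 300, relation_to_island = "OpenSea"),
    ann_row("cg4", pos = 400, relation_to_island = "Island"),
    ann_row("cg5", chrom = "chr2", pos = 100, relation_to_island = "Island"))
  ann$island_id <- NULL
  x <- toy_beta_set(matrix(0.5, 5, 1), annotation = ann)
  cm <- cgi_metrics(x)
  expect_identical(cm$n_islands, 3L)  # chr1 run, chr1 singleton, chr2
})

test_that("quartile and median grouping use reference-cohort cutpoints", {
  vals <- setNames(as.numeric(1:8), paste0("s", 1:8))
  qg <- quantile_groups(vals)
  expect_equal(unname(qg$cutpoints), c(2.75, 6.25))
  expect_identical(as.character(qg$labels),
                   c("<Q1", "<Q1", "Q1-Q3", "Q1-Q3", "Q1-Q3", "Q1-Q3",
                     ">Q3", ">Q3"))
  mg <- quantile_groups(vals, "median")
  expect_identical(as.character(mg$labels),
                   rep(c("<median", ">=median"), each = 4))
  # degenerate: all equal
  eq <- quantile_groups(rep(3, 5))
  expect_true(all(eq$labels == "Q1-Q3"))
  expect_true(all(quantile_groups(rep(3, 5), "median")$labels == ">=median"))
  # labeling a subset against the full cohort keeps full-cohort cutpoints
  sub <- quantile_groups(vals[c(1, 7)], reference = vals)
  expect_identical(sub$cutpoints, qg$cutpoints)
  expect_identical(as.character(sub$labels), c("<Q1", ">Q3"))
  expect_error(quantile_groups(1:3, reference = numeric(0)), "empty")
})
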