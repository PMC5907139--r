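series_df <- function(values_by_gene, times = c(0, 2, 4, 12, 24)) {
  do.call(rbind, lapply(names(values_by_gene), function(g)
    data.frame(gene = g, time_h = times,
               fold_change = values_by_gene[[g]])))
}

# Textbook Pearson r, written out from the sum formula.
pearson_manual <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
}

test_that("correlations are Pearson on log10 values with negatives clipped", {
  vals <- list(a = c(1, 2, 4, 8, 16),
               b = c(1, 3, 5, 20, 40),
               c = c(2, 1.5, 1.2, 0.9, 0.1))
  cm <- correlation_matrix(series_df(vals))
  r <- cm$r_clipped
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  rab <- pearson_manual(log10(vals$a), log10(vals$b))
  expect_equal(unname(r["a", "b"]), rab)
  # raw a-c correlation is negative, so the clipped entry is zero
  expect_lt(pearson_manual(log10(vals$a), log10(vals$c)), 0)
  expect_equal(unname(r["a", "c"]), 0)
  # a reciprocal trend is perfectly anticorrelated on the log scale
  vals2 <- list(x = c(1, 2, 4, 8, 16), y = 1 / c(1, 2, 4, 8, 16))
  r2 <- correlation_matrix(series_df(vals2))$r_clipped
  expect_equal(pearson_manual(log10(vals2$x), log10(vals2$y)), -1)
  expect_equal(unname(r2["x", "y"]), 0)
})

test_that("a series against itself correlates exactly 1", {
  vals <- list(a = c(1, 0.5, 2, 0.5, 1), b = c(1, 0.5, 2, 0.5, 1))
  r <- correlation_matrix(series_df(vals))$r_clipped
  expect_equal(unname(r["a", "b"]), 1)
})

test_that("constant series get correlation 0 with a warning", {
  vals <- list(a = c(1, 2, 4, 8, 16), flat = rep(1, 5))
  expect_warning(cm <- correlation_matrix(series_df(vals)), "flat")
  expect_equal(unname(cm$r_clipped["a", "flat"]), 0)
  expect_equal(unname(cm$r_clipped["flat", "flat"]), 1)
})

test_that("correlation on logs ignores per-gene multiplicative rescaling", {
  vals <- list(a = c(1, 2, 4, 8, 16), b = c(1, 3, 5, 20, 40))
  scaled <- list(a = 7.3 * vals$a, b = 0.2 * vals$b)
  r1 <- correlation_matrix(series_df(vals))$r_clipped
  r2 <- correlation_matrix(series_df(scaled))$r_clipped
  expect_equal(r1["a", "b"], r2["a", "b"])
  expect_error(correlation_matrix(series_df(list(a = c(-1, 1, 1, 1, 1)))),
               "positive")
})

test_that("block structure yields exactly two clusters at an intermediate cut", {
  up <- c(1, 2, 4, 8, 16)
  down <- c(1, 2, 4, 8, 16)^c(1, -0.5, 0.5, -1, 0.2)  # unrelated shape
  vals <- list(a1 = up, a2 = up * 2, b1 = down, b2 = down * 3)
  cl <- cluster_genes(correlation_matrix(series_df(vals)), 0.5)
  a <- cl$assignment
  expect_equal(length(setdiff(unique(a), "UNCLUSTERED")), 2L)
  expect_equal(a[["a1"]], a[["a2"]])
  expect_equal(a[["b1"]], a[["b2"]])
  expect_false(a[["a1"]] == a[["b1"]])
})

test_that("a duplicated gene forms a single cluster; one gene is an error", {
  vals <- list(g1 = c(1, 2, 3, 4, 5), g2 = c(1, 2, 3, 4, 5))
  cl <- cluster_genes(correlation_matrix(series_df(vals)), 0.5)
  expect_equal(unname(cl$assignment), c("1", "1"))
  expect_error(cluster_genes(correlation_matrix(
    series_df(list(g = c(1, 2, 3, 4, 5)))), 0.5), "at least two")
})

test_that("a planted 3-cluster fixture is recovered up to label permutation", {
  shapes <- list(c(0, -1, 1, 2, -1), c(0, 0, 0, 2, 1.5), c(0, 1, -1, 1, -1))
  vals <- list()
  set.seed(2)
  for (i in 1:3) for (j in 1:2) {
    vals[[paste0("g", i, j)]] <- 2^(shapes[[i]] + rnorm(5, 0, 0.05) *
                                      c(0, 1, 1, 1, 1))
  }
  cl <- cluster_genes(correlation_matrix(series_df(vals)), 0.5)
  truth <- rep(c("A", "B", "C"), each = 2)
  names(truth) <- names(vals)
  # brute-force check over all label permutations
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  ids <- setdiff(unique(cl$assignment), "UNCLUSTERED")
  expect_equal(length(ids), 3L)
  match_any <- any(vapply(perms, function(p) {
    relab <- setNames(c("A", "B", "C")[p], ids)
    all(relab[cl$assignment[names(truth)]] == truth)
  }, logical(1)))
  expect_true(match_any)
})

test_that("pattern symbols read sign sequences with a dead band", {
  expect_equal(pattern_symbols(c(16, 8, 4, 2, 1)), "----")
  expect_equal(pattern_symbols(c(1, 0.5, 2, 0.5, 1)), "-+-+")
  expect_equal(pattern_symbols(rep(3, 5)), "0000")
  # changes below the log10 dead band read as 0
  expect_equal(pattern_symbols(c(1, 1.05, 1, 1.05, 1), epsilon = 0.05),
               "0000")
  expect_error(pattern_symbols(c(1, -1, 1, 1, 1)), "positive")
})

test_that("cluster descriptors average member genes; singletons get their own", {
  tmpl <- default_cluster_templates()
  vals <- list(x1 = 2^tmpl[["1"]], x2 = 2^tmpl[["1"]],
               lone = 2^tmpl[["DUSP18"]])
  cl <- list(assignment = c(x1 = "1", x2 = "1", lone = "UNCLUSTERED"))
  class(cl) <- "cluster_assignment"
  pats <- assign_patterns(series_df(vals), cl)
  expect_equal(pats[["1"]], "-++-")     # cluster-1 template shape
  expect_equal(pats[["lone"]], "++++")  # gradual rise
})

test_that("planted cluster structure is recovered at the default noise", {
  scores <- vapply(1:8, function(seed) {
    synth <- generate_ct_table(synth_config(seed = seed))
    series <- qpcr_series(synth$records)
    cl <- cluster_genes(correlation_matrix(series),
                        default_run_config()$cut_height)
    cluster_agreement(synth$truth$assignment, cl$assignment)
  }, numeric(1))
  expect_gte(mean(scores), 0.9)
})
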