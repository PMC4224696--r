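toy_expr <- function(values, normals = character()) {
  # values: named list sample -> expression for one gene "G1"
  e <- tibble::tibble(gene = "G1", sample_id = names(values),
                      value = unlist(values, use.names = FALSE))
  attr(e, "normal_samples") <- normals
  e
}

test_that("samples split into mutant and non-mutant by shared-DHS mutation status", {
  muts <- oc_mutations(rep("chr1", 3), c(1000, 1050, 5000),
                       c("A", "C", "G"), c("G", "T", "A"), c("S1", "S2", "S3"))
  expr <- toy_expr(setNames(as.list(1:5), paste0("S", 1:5)), normals = "S5")
  grp <- classify_samples("chr1", 900L, 1100L, muts, expr)
  # two distinct mutations inside the same DHS: both samples are mutant
  expect_equal(grp$mutant, c("S1", "S2"))
  # everyone else, flagged normals included, is non-mutant
  expect_equal(grp$non_mutant, c("S3", "S4", "S5"))
  # a mutant sample missing from the matrix is dropped with a warning
  muts2 <- oc_mutations("chr1", 1000, "A", "G", "S99")
  expect_warning(g2 <- classify_samples("chr1", 900L, 1100L, muts2, expr), "S99")
  expect_length(g2$mutant, 0)
})

test_that("fold change compares the mutant to the non-mutant median", {
  expect_equal(fold_change(10, c(1, 2, 3, 4, 5)), 10 / 3)
  expect_equal(fold_change(3, c(1, 2, 3, 4, 5)), 1)
  expect_equal(fold_change(6, c(2, 4)), 2)  # even-count median 3
  expect_warning(v <- fold_change(5, c(0, 0)), "median")
  expect_true(is.na(v))
  expect_true(is.na(fold_change(5, numeric())))
})

test_that("the per-mutant t-test matches the closed form and stats::t.test", {
  p <- de_test(10, c(1, 2, 3, 4, 5))
  expect_equal(p, 0.0005844106, tolerance = 1e-6)  # frozen: t = -9.8995, df 4
  expect_equal(p, stats::t.test(c(1, 2, 3, 4, 5), mu = 10)$p.value, tolerance = 1e-12)
  # mutant at the non-mutant mean: t = 0, p = 1
  expect_equal(de_test(3, c(1, 2, 3, 4, 5)), 1)
  # two-sidedness: reflecting the mutant about the mean preserves p
  withr::local_seed(31)
  x <- rnorm(10)
  expect_equal(de_test(mean(x) + 2, x), de_test(mean(x) - 2, x), tolerance = 1e-12)
})

test_that("degenerate variance and small-n rules apply", {
  expect_equal(de_test(4, c(4, 4, 4, 4)), 1)
  expect_equal(de_test(5, c(4, 4, 4, 4)), 0)
  expect_true(is.na(de_test(5, c(1, 2))))   # fewer than 3 non-mutants
  expect_true(is.na(de_test(5, c(1, 2, NA))))
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  expect_equal(stats::p.adjust(0.01, "bonferroni", n = 5), 0.05)
  expect_equal(stats::p.adjust(0.5, "bonferroni", n = 10), 1)
  expect_equal(stats::p.adjust(0.3, "bonferroni", n = 1), 0.3)
})

test_that("expression stats attach only to DHS-resident gene-assigned records", {
  cx <- read_cohort(cohort_dir())
  rec <- annotate_cohort(cx)
  evaluated <- !is.na(rec$p_value)
  expect_true(all(rec$in_dhs[evaluated]))
  expect_true(all(!is.na(rec$gene[evaluated])))
  # family size = number of DHS-associated records; adjusted p = min(1, p * n)
  n_tests <- sum(rec$in_dhs & !is.na(rec$gene))
  expect_equal(rec$adj_p_value[evaluated],
               pmin(1, rec$p_value[evaluated] * n_tests))
  expect_true(all(rec$adj_p_value >= rec$p_value, na.rm = TRUE))
  # planted shift is recovered with a large fold change and tiny p
  planted <- rec[rec$pos == 10000 & rec$sample_id == "S01", ]
  expect_gt(planted$fold_change, 1.2)
  expect_lt(planted$adj_p_value, 1e-6)
})
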