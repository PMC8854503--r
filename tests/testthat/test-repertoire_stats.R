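summary_fixture <- function() {
  withr::with_seed(12, {
    rep <- generate_repertoire(generator_config(n_cells = 2000))
    assemble_cells(rep$contigs)
  })
}

test_that("usage fractions use the documented denominators", {
  cells <- summary_fixture()
  s <- summarize_repertoire(cells, sample_id = "fx")
  one_heavy <- sum(cells$n_heavy_productive == 1)
  expect_equal(sum(s$vh_usage$n), one_heavy)
  expect_equal(sum(s$vh_usage$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(s$lc_class_fractions$fraction), 1, tolerance = 1e-9)
  expect_equal(nrow(s$jk_usage), 5L)
  expect_equal(sum(s$jk_usage$fraction), 1, tolerance = 1e-9)
  # a hand-recomputed VH fraction
  v434 <- sum(flag_vh434(cells$heavy_v_gene[cells$n_heavy_productive == 1]))
  expect_equal(s$vh_usage$fraction[s$vh_usage$v_gene == "IGHV4-34"],
               v434 / one_heavy)
})

test_that("Jkappa usage counts kappa chain calls in the chosen subset", {
  cells <- summary_fixture()
  igmd <- summarize_repertoire(cells, jk_subset = "IgMD")
  all_cells <- summarize_repertoire(cells, jk_subset = "all")
  ana <- cells[cells$analyzable, ]
  igmd_ana <- ana[ana$isotype_class == "IgMD", ]
  n_k_calls <- sum(igmd_ana$lc1_locus == "IGK", na.rm = TRUE) +
    sum(igmd_ana$lc2_locus == "IGK", na.rm = TRUE)
  expect_equal(sum(igmd$jk_usage$n), n_k_calls)
  expect_gt(sum(all_cells$jk_usage$n), sum(igmd$jk_usage$n))
})

test_that("CDR3 length statistics come from the delivered string lengths", {
  cells <- assemble_cells(example_contigs())
  # directly check on a two-cell toy: "CARGDYW" (7) and "CARDPAGW" (8)
  s <- summarize_repertoire(cells)
  expect_equal(s$cdr3_len_mean, mean(c(7, 8)))
  expect_equal(s$cdr3_len_sd, sd(c(7, 8)))
})

test_that("summaries are invariant to cell row order", {
  cells <- summary_fixture()
  s1 <- summarize_repertoire(cells)
  s2 <- withr::with_seed(3, summarize_repertoire(cells[sample.int(nrow(cells)), ]))
  expect_equal(glance(s1), glance(s2))
  expect_equal(s1$jk_usage, s2$jk_usage)
})

test_that("zero analyzable cells give an empty but valid summary", {
  s <- summarize_repertoire(assemble_cells(example_contigs()[0, ]), "empty")
  expect_equal(s$n_analyzable, 0L)
  expect_true(is.na(s$cdr3_len_mean))
  expect_equal(sum(s$lc_class_fractions$n), 0L)
})

test_that("the H threshold is control mean + 3 sample SD", {
  # symmetric triple with mean 0.73 and sample SD 0.47
  controls <- c(0.26, 0.73, 1.20)
  expect_equal(mean(controls), 0.73, tolerance = 1e-12)
  expect_equal(sd(controls), 0.47, tolerance = 1e-12)
  expect_equal(high_kl_threshold(controls), 0.73 + 3 * 0.47)
  expect_equal(high_kl_threshold(c(1, 1, 1)), 1)
  expect_equal(high_kl_threshold(c(0, 2)), 1 + 3 * sqrt(2))
  expect_error(high_kl_threshold(1), "2")
})

test_that("patient calls use strict inequality at the threshold", {
  thr <- 2.14
  expect_equal(classify_patient(c(0.5, 4.0, 2.14), thr), c("L", "H", "L"))
})

test_that("adding a control above the mean never lowers the mean term", {
  withr::local_seed(8)
  for (i in 1:20) {
    x <- runif(sample(3:10, 1), 0, 3)
    extra <- mean(x) + runif(1, 0, 2)
    expect_gte(mean(c(x, extra)), mean(x))
  }
})

test_that("Mann-Whitney exact p comes from full rank enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 assignments at least as extreme
  expect_true(r$exact)
  # identical tied samples carry no evidence
  expect_equal(mann_whitney_u(rep(5, 4), rep(5, 4))$p_value, 1)
})

test_that("Mann-Whitney agrees with the reference implementation", {
  withr::local_seed(100)
  # exact branch, no ties
  for (i in 1:50) {
    x <- rnorm(sample(2:8, 1))
    y <- rnorm(sample(2:8, 1))
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # normal-approximation branch at n = 20 per group
  for (i in 1:1000) {
    x <- rnorm(20)
    y <- rnorm(20, mean = runif(1, -1, 1))
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  }
  # ties engage the tie-corrected variance
  x <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9)
  y <- c(2, 3, 3, 4, 5, 7, 7, 8, 10, 11)
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Mann-Whitney is symmetric under sample exchange", {
  withr::local_seed(41)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(9)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$statistic, length(x) * length(y) - b$statistic)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("linear regression recovers slope, r-squared and errors", {
  perfect <- suppressWarnings(linear_regression(0:2, 0:2))
  expect_equal(perfect$effect, 1)
  expect_equal(perfect$r_squared, 1)
  flat <- linear_regression(1:10, rep(3, 10))
  expect_equal(flat$effect, 0)
  expect_equal(flat$r_squared, 0)
  withr::local_seed(5)
  x <- runif(50, 0, 10)
  noisy <- linear_regression(x, 2 * x + rnorm(50, sd = 0.1))
  expect_true(noisy$effect > 1.9 && noisy$effect < 2.1)
  expect_lt(noisy$p_value, 1e-10)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
  expect_error(linear_regression(1:2, 1:2), "3")
})

test_that("tidy and glance return one-row test summaries", {
  td <- tidy(mann_whitney_u(1:4, c(2.5, 3.5, 9, 10)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$method, "mann_whitney_u")
  gl <- glance(linear_regression(1:5, c(1, 2.2, 2.9, 4, 5.1)))
  expect_equal(gl$method, "linear_regression")
})
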