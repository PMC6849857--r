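make_table <- function(cores, necrosis = 0) {
  data.frame(patient_id = 1L, core_index = cores, marker = "Iba1",
             region = "T", percent_positive = 10 * cores,
             necrosis_fraction = necrosis,
             survival_months = 12, event = 1L)
}

test_that("first-core selection keeps core 1, or the lowest with a flag", {
  t1 <- first_core_select(make_table(c(1L, 2L, 3L)))
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$core_index, 1L)
  expect_identical(t1$flag, "")

  t2 <- first_core_select(make_table(2L))
  expect_identical(t2$core_index, 2L)
  expect_identical(t2$flag, "first_core_missing")

  t3 <- first_core_select(make_table(c(2L, 3L)))
  expect_identical(t3$core_index, 2L)
  expect_identical(t3$flag, "first_core_missing")

  expect_error(first_core_select(make_table(1L)[0, ]), "empty")
})

test_that("necrosis exclusion is strictly greater than the limit", {
  tab <- rbind(make_table(1L, necrosis = 0.31),
               make_table(1L, necrosis = 0.30),
               make_table(1L, necrosis = 0.05))
  out <- suppressMessages(exclude_necrotic(tab))
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "n_excluded"), 1L)
  expect_true(all(out$necrosis_fraction <= 0.30))
  expect_warning(exclude_necrotic(make_table(1L, necrosis = 0.9)),
                 "all cores excluded")
})

test_that("rank-sum test: symmetry, the 3-vs-3 enumeration, and U/W", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 4.5)  # n_x n_y / 2
  expect_equal(r$p_value, 1)

  r2 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$p_value, 0.1)   # 2 of C(6,3) = 20 orderings as extreme
  expect_equal(r2$statistic, 0)
  expect_equal(r2$W, 6)           # rank sum of x
  expect_identical(r2$method, "wilcoxon_exact")

  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  expect_error(wilcoxon_rank_sum(c(1, 1, 2), c(2, 3), mode = "exact"),
               "untied")
})

test_that("exact rank-sum p matches full enumeration on random cases", {
  set.seed(20)
  for (i in 1:25) {
    nx <- sample(2:7, 1)
    ny <- sample(2:7, 1)
    v <- sample(1000, nx + ny)  # no ties
    x <- v[seq_len(nx)]
    y <- v[-seq_len(nx)]
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # between unadjusted and plain Bonferroni, element-wise
  set.seed(4)
  p <- runif(10)
  h <- holm_adjust(p)
  expect_true(all(h >= p))
  expect_true(all(h <= pmin(1, length(p) * p)))
})

test_that("Spearman rho: monotone invariance, reversal, ties, errors", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, x^2)$statistic, 1)
  expect_equal(spearman_rho(x, rev(x))$statistic, -1)
  # tied data against the explicit mid-rank Pearson formula
  set.seed(5)
  a <- sample(1:4, 20, replace = TRUE)
  b <- a + sample(0:2, 20, replace = TRUE)
  ra <- rank(a); rb <- rank(b)
  n <- length(a)
  rho_formula <- (n * sum(ra * rb) - sum(ra) * sum(rb)) /
    sqrt((n * sum(ra^2) - sum(ra)^2) * (n * sum(rb^2) - sum(rb)^2))
  expect_equal(spearman_rho(a, b)$statistic, rho_formula, tolerance = 1e-12)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})
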