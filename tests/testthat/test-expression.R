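noiseless_set <- function(n_genes = 50, fc = c(4, -4, 2), n_case = 3) {
  generate_expression(expression_spec(
    n_genes = n_genes, n_case_samples = n_case, n_ref_samples = 2,
    planted_deg_ids = paste0("gene", seq_along(fc)),
    planted_log2fc = fc, noise_sd = 0, seed = 1))
}

test_that("expression generation is deterministic and plants exact shifts", {
  a <- generate_expression(expression_spec(seed = 9))
  b <- generate_expression(expression_spec(seed = 9))
  expect_identical(a$exprs, b$exprs)
  es <- noiseless_set(fc = c(3, -3))
  dt <- deg_filter(es, threshold = 0)
  expect_equal(dt$log2fc[1:2], c(3, -3))
  expect_true(all(abs(dt$log2fc[-(1:2)]) < 1e-12))
})

test_that("the DEG screen has an inclusive boundary and is label-symmetric", {
  # exact arithmetic at the boundary: case mean 8, reference mean 6
  m <- rbind(gene1 = c(8, 8, 6, 6), gene2 = c(7, 7, 7, 7))
  cond <- factor(c("case", "case", "reference", "reference"),
                 levels = c("case", "reference"))
  es_b <- structure(list(exprs = m, condition = cond),
                    class = "expression_set")
  db <- deg_filter(es_b, threshold = 2)
  expect_identical(db$pass, c(TRUE, FALSE))  # log2FC exactly 2 passes

  es <- noiseless_set(fc = c(4, -4))
  dt <- deg_filter(es, threshold = 2)
  expect_identical(dt$gene[dt$pass], paste0("gene", 1:2))
  # swapping condition labels negates log2FC, preserves the pass set
  es2 <- es
  es2$condition <- factor(ifelse(es$condition == "case", "reference", "case"),
                          levels = c("case", "reference"))
  dt2 <- deg_filter(es2, threshold = 2)
  expect_equal(dt2$log2fc, -dt$log2fc)
  expect_identical(dt2$pass, dt$pass)
  expect_error(deg_filter(structure(list(exprs = es$exprs,
                                         condition = factor(rep("case", 5))),
                                    class = "expression_set")),
               "both conditions")
})

test_that("Ward clustering matches the brute-force minimum-variance merges", {
  set.seed(6)
  for (i in 1:5) {
    m <- matrix(rnorm(7 * 4), 7)
    hc <- ward_cluster(m)
    expect_equal(hc$height, ward_heights_oracle(m), tolerance = 1e-9)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
  # identical rows merge first at height 0
  m2 <- rbind(c(1, 1), c(4, 0), c(1, 1), c(9, 3), c(0, 5))
  hc2 <- ward_cluster(m2)
  expect_equal(hc2$height[1], 0)
  expect_setequal(hc2$merge[1, ], c(-1, -3))
  expect_error(ward_cluster(m2[1, , drop = FALSE]), "at least 2")
})

test_that("Ward heights are permutation-invariant as a multiset", {
  set.seed(7)
  m <- matrix(rnorm(40), 10)
  perm <- sample(10)
  expect_equal(sort(ward_cluster(m)$height),
               sort(ward_cluster(m[perm, ])$height), tolerance = 1e-9)
})

test_that("Pearson coexpression equals the covariance formula", {
  set.seed(8)
  m <- matrix(rnorm(60), 10, 6)
  rownames(m) <- paste0("g", 1:10)
  cc <- pearson_coexpression(m)
  expect_equal(diag(cc), setNames(rep(1, 10), rownames(m)))
  expect_equal(cc, t(cc))
  i <- 3; j <- 7
  oracle <- sum((m[i, ] - mean(m[i, ])) * (m[j, ] - mean(m[j, ]))) /
    sqrt(sum((m[i, ] - mean(m[i, ]))^2) * sum((m[j, ] - mean(m[j, ]))^2))
  expect_equal(cc[i, j], oracle, tolerance = 1e-12)
  # negated gene correlates at -1; constant gene yields NA
  m2 <- rbind(m, -m[1, ], 5)
  expect_warning(cc2 <- pearson_coexpression(m2), "constant")
  expect_equal(unname(cc2[1, 11]), -1)
  expect_true(all(is.na(cc2[12, ])))
})

test_that("rank products are extreme for a consistently top-ranked gene", {
  es <- noiseless_set(n_genes = 30, fc = c(6), n_case = 3)
  rp <- rank_product_pfp(es, n_permutations = 50, seed = 2)
  expect_equal(rp$rp_up[1], 1)  # rank 1 in every case sample
  expect_equal(which.min(rp$pfp_up), 1L)
  expect_error(rank_product_pfp(es, n_permutations = 5), "at least 10")
})

test_that("pfp is deterministic per seed and tracks the exact null", {
  es <- generate_expression(expression_spec(
    n_genes = 15, n_case_samples = 3, n_ref_samples = 1,
    planted_deg_ids = paste0("gene", 1:2), planted_log2fc = c(3, -2),
    noise_sd = 0.5, seed = 3))
  a <- rank_product_pfp(es, n_permutations = 200, seed = 5)
  b <- rank_product_pfp(es, n_permutations = 200, seed = 5)
  expect_identical(a, b)
  big <- rank_product_pfp(es, n_permutations = 5000, seed = 6)
  exact_up <- pfp_exact_oracle(big$rp_up, n = 15, k = 3)
  expect_lt(max(abs(big$pfp_up - exact_up)), 0.15)
  # monotone: more extreme rank product implies smaller or equal pfp
  ord <- order(big$rp_up)
  expect_true(all(diff(big$pfp_up[ord]) >= -1e-12))
})
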