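test_that("Kaplan-Meier matches hand product-limit computations", {
  # all events at 1, 2, 3
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # 2 censored: S(1) = 2/3, then 0 at t = 3 via 2/3 * (1 - 1/1)
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # all censored: flat at 1
  km3 <- kaplan_meier(c(5, 8, 10), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  # with no censoring S equals the empirical survival fraction
  set.seed(2)
  t <- rexp(40)
  km4 <- kaplan_meier(t, rep(1, 40))
  expect_equal(km4$surv, vapply(km4$time, function(u) mean(t > u), 0))
  # S non-increasing, starts below or at 1
  expect_true(all(diff(km4$surv) <= 0))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "no subjects")
  expect_error(kaplan_meier(c(1, -1), c(1, 1)), "positive")
  expect_error(kaplan_meier(c(1, 2), c(1, 2)), "0 or 1")
})

test_that("log-rank and Gehan match the 4-subject hand computation", {
  # arm A: events at 1 and 3; arm B: events at 2 and 4
  lr <- logrank_test(c(1, 3), c(1, 1), c(2, 4), c(1, 1))
  # hand O-E table: (O-E) = 2 - 4/3 - ... = 2/3; V = 13/18
  expect_equal(lr$statistic, (2 / 3)^2 / (13 / 18), tolerance = 1e-12)
  gw <- gehan_wilcoxon_test(c(1, 3), c(1, 1), c(2, 4), c(1, 1))
  # weights 4, 3, 2, 1: num = 2, den = 7
  expect_equal(gw$statistic, 4 / 7, tolerance = 1e-12)
})

test_that("identical arms give statistic 0 and p 1", {
  t <- c(2, 5, 7, 9)
  e <- c(1, 0, 1, 1)
  lr <- logrank_test(t, e, t, e)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("both tests match an independent oracle on random cohorts", {
  set.seed(30)
  for (i in 1:40) {
    na <- sample(3:25, 1)
    nb <- sample(3:25, 1)
    ta <- round(rexp(na, 0.1), 1) + 0.1  # rounding forces ties
    tb <- round(rexp(nb, 0.15), 1) + 0.1
    ea <- rbinom(na, 1, 0.8)
    eb <- rbinom(nb, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    lr <- logrank_test(ta, ea, tb, eb)
    or <- survtest_oracle(ta, ea, tb, eb, gehan = FALSE)
    expect_equal(lr$statistic, or$chi2, tolerance = 1e-10)
    gw <- gehan_wilcoxon_test(ta, ea, tb, eb)
    og <- survtest_oracle(ta, ea, tb, eb, gehan = TRUE)
    expect_equal(gw$statistic, og$chi2, tolerance = 1e-10)
    # cross-check log-rank against survival::survdiff
    sd0 <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(na, nb)))
    expect_equal(lr$statistic, unname(sd0$chisq), tolerance = 1e-8)
  }
})

test_that("the tests are invariant to common time rescaling", {
  set.seed(31)
  ta <- rexp(20); ea <- rbinom(20, 1, 0.7)
  tb <- rexp(20, 1.5); eb <- rbinom(20, 1, 0.7)
  lr1 <- logrank_test(ta, ea, tb, eb)
  lr2 <- logrank_test(7 * ta, ea, 7 * tb, eb)
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-12)
  gw1 <- gehan_wilcoxon_test(ta, ea, tb, eb)
  gw2 <- gehan_wilcoxon_test(7 * ta, ea, 7 * tb, eb)
  expect_equal(gw1$statistic, gw2$statistic, tolerance = 1e-12)
})

split_table <- function(values) {
  n <- length(values)
  data.frame(patient_id = seq_len(n), core_index = 1L, marker = "Iba1",
             region = "T", percent_positive = values,
             necrosis_fraction = 0,
             survival_months = seq_len(n) + 0.5,
             event = rep(1L, n))
}

test_that("median split: cutpoint, tie rule, and degenerate input", {
  sp <- median_split(split_table(c(10, 20, 30, 40)))
  expect_equal(sp$cutpoint, 25)
  expect_identical(sort(sp$data$value[sp$data$arm == "high"]), c(30, 40))
  # a value exactly at the cutpoint goes to the low arm
  sp2 <- median_split(split_table(c(10, 12, 12, 40)))
  expect_equal(sp2$cutpoint, 12)
  expect_identical(sp2$n_high, 1L)
  expect_identical(sp2$n_low, 3L)
  expect_error(median_split(split_table(rep(7, 5))), "degenerate")
})

test_that("best split equals exhaustive recomputation and beats the median", {
  set.seed(33)
  coh <- generate_cohort(cohort_spec(
    n_patients = 60, cores_per_patient = 1,
    log_hazard_ratio_high_vs_low = -0.8, seed = 12))
  bs <- best_split(coh, prefilter = FALSE)
  df <- bs$data
  # exhaustive recomputation over all admissible cutpoints
  for (k in seq_len(nrow(bs$scan))) {
    high <- df$value > bs$scan$cutpoint[k]
    expect_equal(bs$scan$chi2[k],
                 logrank_test(df$time[high], df$event[high],
                              df$time[!high], df$event[!high])$statistic,
                 tolerance = 1e-12)
  }
  expect_equal(max(bs$scan$chi2), bs$logrank$statistic, tolerance = 1e-12)
  ms <- median_split(coh, prefilter = FALSE)
  expect_gte(bs$logrank$statistic, ms$logrank$statistic)
  # arm-fraction admissibility: n = 3 with half-half minimum -> no cutpoint
  expect_error(best_split(split_table(c(1, 2, 3)), min_arm_fraction = 0.5),
               "degenerate")
})

test_that("Dunn pairwise z matches the hand formula on a 3 x 5 table", {
  vals <- c(1, 3, 5, 7, 9,   2, 4, 6, 8, 10,   11, 12, 13, 14, 15)
  grp <- rep(c("a", "b", "c"), each = 5)
  dn <- dunn_test(vals, grp)
  N <- 15
  r <- rank(vals)
  rb <- tapply(r, grp, mean)
  sigma <- sqrt((N * (N + 1) / 12) * (1 / 5 + 1 / 5))  # no ties
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "b"],
               unname((rb["a"] - rb["b"]) / sigma), tolerance = 1e-12)
  expect_equal(dn$z[dn$group1 == "b" & dn$group2 == "c"],
               unname((rb["b"] - rb["c"]) / sigma), tolerance = 1e-12)
  expect_equal(dn$p_holm, holm_adjust(dn$p))
})

test_that("region-stratified analysis splits per region", {
  coh <- generate_cohort(cohort_spec(
    n_patients = 60, regions = c("T", "IZ", "NAB"), seed = 21))
  res <- region_stratified_analysis(coh)
  expect_named(res$splits, c("T", "IZ", "NAB"))
  expect_s3_class(res$splits$T, "survival_split")
  expect_s3_class(res$kruskal, "htest")
  expect_identical(nrow(res$dunn), 3L)
  # permuting region labels leaves the pooled Kruskal-Wallis invariant
  coh2 <- coh
  coh2$region <- c(T = "IZ", IZ = "NAB", NAB = "T")[coh2$region]
  res2 <- region_stratified_analysis(coh2)
  expect_equal(res2$kruskal$statistic, res$kruskal$statistic)
})

test_that("Kruskal-Wallis across regions is calibrated under the null", {
  rej <- vapply(1:1000, function(i) {
    coh <- generate_cohort(cohort_spec(
      n_patients = 30, cores_per_patient = 1,
      regions = c("T", "IZ", "NAB"), independent_regions = TRUE,
      seed = 40000 + i))
    stats::kruskal.test(coh$percent_positive,
                        factor(coh$region))$p.value < 0.05
  }, NA)
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})
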