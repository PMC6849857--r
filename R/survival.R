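# Survival analysis: Kaplan-Meier estimation, weighted two-sample tests
# (log-rank and Gehan-Breslow-Wilcoxon), and marker dichotomization by
# median split or best split.
#
# Both two-sample tests are weighted sums over distinct event times of
# observed-minus-expected events in one arm with the hypergeometric
# variance; the log-rank uses weight 1 and Gehan-Breslow-Wilcoxon uses
# the number at risk, so early deaths weigh more.  The chi-square
# statistic is (sum w (O - E))^2 / sum w^2 V on 1 df.

#' Kaplan-Meier product-limit curve
#'
#' Wraps `survival::survfit`; censored subjects remain at risk at their
#' censoring time (events are processed first at tied times), and the
#' standard error is Greenwood's.
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `std_err` (Greenwood SE of S(t)).
#' @examples
#' kaplan_meier(c(1, 2, 3), c(1, 1, 1))
#' @export
kaplan_meier <- function(times, events) {
  check_survival_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, std_err = fit$std.err * fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

check_survival_input <- function(times, events) {
  if (length(times) == 0L) stop("no subjects", call. = FALSE)
  if (length(times) != length(events)) {
    stop("times and events lengths differ", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("survival times must be positive and finite", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("event flags must be 0 or 1", call. = FALSE)
  }
  invisible(NULL)
}

# Weighted two-sample survival test engine.
weighted_survival_test <- function(time_a, event_a, time_b, event_b,
                                   weight = c("logrank", "gehan")) {
  weight <- match.arg(weight)
  check_survival_input(time_a, event_a)
  check_survival_input(time_b, event_b)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1, 0), c(length(time_a), length(time_b)))
  if (sum(event) == 0) {
    stop("test undefined: no events in either arm", call. = FALSE)
  }
  agg <- rowsum(cbind(n = 1, n1 = grp, d = event, d1 = event * grp), time)
  # rowsum orders by sorted unique time
  n_at <- rev(cumsum(rev(agg[, "n"])))
  n1_at <- rev(cumsum(rev(agg[, "n1"])))
  keep <- agg[, "d"] > 0
  n <- n_at[keep]; n1 <- n1_at[keep]
  d <- agg[keep, "d"]; d1 <- agg[keep, "d1"]
  w <- if (weight == "logrank") rep(1, length(n)) else n
  oe <- d1 - d * n1 / n
  v <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  num <- sum(w * oe)
  den <- sum(w^2 * v)
  chi2 <- if (den > 0) num^2 / den else 0
  structure(list(statistic = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 observed = sum(d1), expected = sum(d * n1 / n),
                 n = c(n_a = length(time_a), n_b = length(time_b)),
                 method = if (weight == "logrank") "logrank"
                          else "gehan_breslow_wilcoxon"),
            class = "gamihc_test")
}

#' Log-rank test for two survival arms
#'
#' @param time_a,event_a,time_b,event_b survival times and event flags
#'   of the two arms.
#' @return `gamihc_test` with the 1-df chi-square statistic and p-value.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  weighted_survival_test(time_a, event_a, time_b, event_b, "logrank")
}

#' Gehan-Breslow-Wilcoxon test for two survival arms
#'
#' The weighted variant of the log-rank test with number-at-risk
#' weights, emphasizing early survival differences.
#'
#' @inheritParams logrank_test
#' @return `gamihc_test` with the 1-df chi-square statistic and p-value.
#' @export
gehan_wilcoxon_test <- function(time_a, event_a, time_b, event_b) {
  weighted_survival_test(time_a, event_a, time_b, event_b, "gehan")
}

# Reduce a cohort table to one survival/marker record per patient.
patient_level <- function(table, value_col = "percent_positive",
                          prefilter = TRUE, max_necrosis = 0.30) {
  if (prefilter) {
    if (!is.null(table$necrosis_fraction)) {
      table <- suppressMessages(exclude_necrotic(table, max_necrosis))
    }
    if (!is.null(table$core_index)) table <- first_core_select(table)
  }
  df <- data.frame(patient_id = table$patient_id,
                   value = table[[value_col]],
                   time = table$survival_months,
                   event = table$event)
  if (anyDuplicated(df$patient_id)) {
    stop("multiple rows per patient after filtering; ",
         "supply one marker/region at a time", call. = FALSE)
  }
  df
}

make_split <- function(df, cutpoint, scan = NULL) {
  high <- df$value > cutpoint
  if (!any(high) || all(high)) {
    stop("degenerate split: one arm is empty", call. = FALSE)
  }
  structure(list(
    cutpoint = cutpoint,
    n_high = sum(high), n_low = sum(!high),
    km = list(high = kaplan_meier(df$time[high], df$event[high]),
              low = kaplan_meier(df$time[!high], df$event[!high])),
    logrank = logrank_test(df$time[high], df$event[high],
                           df$time[!high], df$event[!high]),
    gehan = gehan_wilcoxon_test(df$time[high], df$event[high],
                                df$time[!high], df$event[!high]),
    data = transform(df, arm = ifelse(high, "high", "low")),
    scan = scan),
    class = "survival_split")
}

#' @export
print.survival_split <- function(x, ...) {
  cat(sprintf(
    "Survival split at cutpoint %.4g: high n = %d (> cutpoint), low n = %d\n",
    x$cutpoint, x$n_high, x$n_low))
  cat(sprintf("  log-rank chi2 = %.4f, p = %.4g\n",
              x$logrank$statistic, x$logrank$p_value))
  cat(sprintf("  Gehan-Wilcoxon chi2 = %.4f, p = %.4g\n",
              x$gehan$statistic, x$gehan$p_value))
  if (!is.null(x$scan)) {
    cat("  (best split; p-values are not adjusted for the cutpoint scan)\n")
  }
  invisible(x)
}

#' Median-split survival comparison
#'
#' Dichotomizes the marker at the sample median of first-core,
#' non-excluded values: the high arm is strictly above the cutpoint and
#' values at the cutpoint go to the low arm.  Kaplan-Meier curves and
#' both the log-rank and Gehan-Breslow-Wilcoxon tests are computed.
#'
#' @param table cohort table (rows per core; see [generate_cohort()]).
#' @param value_col column holding the marker measurement.
#' @param prefilter apply [exclude_necrotic()] and [first_core_select()]
#'   first (default `TRUE`).
#' @param max_necrosis necrosis exclusion limit.
#' @return object of class `survival_split`.
#' @export
median_split <- function(table, value_col = "percent_positive",
                         prefilter = TRUE, max_necrosis = 0.30) {
  df <- patient_level(table, value_col, prefilter, max_necrosis)
  if (length(unique(df$value)) < 2L) {
    stop("degenerate split: fewer than 2 distinct marker values",
         call. = FALSE)
  }
  make_split(df, stats::median(df$value))
}

#' Best-split survival comparison
#'
#' Scans every distinct observed marker value as a candidate cutpoint
#' (high arm strictly above), keeps those leaving at least
#' `min_arm_fraction` of patients in each arm, and returns the cutpoint
#' maximizing the log-rank chi-square.  The returned p-values are
#' maximally selected and therefore *not* adjusted for the scan; they
#' are flagged as such when printed.
#'
#' @inheritParams median_split
#' @param min_arm_fraction minimum fraction of patients per arm for a
#'   cutpoint to be admissible.
#' @return `survival_split` whose `scan` element is a data.frame with
#'   one row per admissible cutpoint (`cutpoint`, `n_high`, `n_low`,
#'   `chi2`, `p`).
#' @export
best_split <- function(table, value_col = "percent_positive",
                       min_arm_fraction = 0.10, prefilter = TRUE,
                       max_necrosis = 0.30) {
  stopifnot_scalar(min_arm_fraction, "min_arm_fraction", 0, 0.5)
  df <- patient_level(table, value_col, prefilter, max_necrosis)
  n <- nrow(df)
  cands <- sort(unique(df$value))
  n_high <- vapply(cands, function(c) sum(df$value > c), 0)
  n_low <- n - n_high
  ok <- n_high >= min_arm_fraction * n & n_low >= min_arm_fraction * n
  if (!any(ok)) {
    stop("degenerate split: no admissible cutpoint at min_arm_fraction = ",
         min_arm_fraction, call. = FALSE)
  }
  cands <- cands[ok]
  scan <- do.call(rbind, lapply(cands, function(c) {
    high <- df$value > c
    lr <- logrank_test(df$time[high], df$event[high],
                       df$time[!high], df$event[!high])
    data.frame(cutpoint = c, n_high = sum(high), n_low = sum(!high),
               chi2 = lr$statistic, p = lr$p_value)
  }))
  best <- which.max(scan$chi2)   # ties: smallest cutpoint wins
  make_split(df, scan$cutpoint[best], scan = scan)
}

#' Dunn's pairwise rank comparisons
#'
#' Pairwise z-tests on mean mid-ranks after a Kruskal-Wallis analysis,
#' with the tie-corrected pooled variance and Holm adjustment.
#'
#' @param values numeric measurements.
#' @param groups group labels (coerced to factor).
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_holm`.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tabulate(groups)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(seq_along(lv), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    (rbar[i] - rbar[j]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ng[i] + 1 / ng[j]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
             z = as.numeric(z), p = p, p_holm = holm_adjust(p))
}

#' Region-stratified survival and marker comparisons
#'
#' Runs [median_split()] separately within each region (tumour core T,
#' infiltration zone IZ, normal-appearing brain NAB), and compares
#' first-core marker levels across regions by Kruskal-Wallis followed
#' by Dunn's pairwise z-tests with Holm adjustment.
#'
#' @inheritParams median_split
#' @return list with `splits` (named list of `survival_split`, `NULL`
#'   for regions skipped with a warning), `kruskal` (the `htest`), and
#'   `dunn` (pairwise table, `NULL` when fewer than 3 regions).
#' @export
region_stratified_analysis <- function(table,
                                       value_col = "percent_positive",
                                       max_necrosis = 0.30) {
  if (is.null(table$region)) stop("`region` column missing", call. = FALSE)
  if (!is.null(table$necrosis_fraction)) {
    table <- suppressMessages(exclude_necrotic(table, max_necrosis))
  }
  if (!is.null(table$core_index)) table <- first_core_select(table)
  regions <- intersect(c("T", "IZ", "NAB"), unique(table$region))
  splits <- lapply(stats::setNames(regions, regions), function(rg) {
    sub <- table[table$region == rg, , drop = FALSE]
    if (length(unique(sub$patient_id)) < 2L) {
      warning("region ", rg, " has fewer than 2 patients; skipped")
      return(NULL)
    }
    tryCatch(median_split(sub, value_col, prefilter = FALSE),
             error = function(e) {
               warning("region ", rg, " skipped: ", conditionMessage(e))
               NULL
             })
  })
  kw <- stats::kruskal.test(table[[value_col]], factor(table$region))
  dn <- if (length(regions) >= 2L) {
    dunn_test(table[[value_col]], table$region)
  }
  list(splits = splits, kruskal = kw, dunn = dn)
}
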