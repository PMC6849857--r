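# Nonparametric group comparisons, multiplicity adjustment and rank
# agreement used throughout the cohort analyses.

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of two independent samples.  With `mode = "auto"` the
#' exact null distribution is used when both samples have at most 10
#' observations and there are no ties; otherwise the tie-corrected
#' normal approximation with continuity correction applies.  Both the
#' Mann-Whitney U and the rank-sum W of the first sample are reported.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return list of class `gamihc_test`: `statistic` (U), `W`, `p_value`,
#'   `n` (per-group sizes), `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  auto = length(x) <= 10L && length(y) <= 10L && !ties,
                  exact = {
                    if (ties) stop("exact mode requires untied data",
                                   call. = FALSE)
                    TRUE
                  },
                  approx = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  u <- unname(wt$statistic)
  structure(list(statistic = u,
                 W = u + length(x) * (length(x) + 1) / 2,
                 p_value = wt$p.value,
                 n = c(n_x = length(x), n_y = length(y)),
                 method = if (exact) "wilcoxon_exact"
                          else "wilcoxon_normal_approx"),
            class = "gamihc_test")
}

#' @export
print.gamihc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = " vs ")))
  invisible(x)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down Holm procedure: sorted ascending p-values are multiplied by
#' `m - i + 1`, enforced monotone non-decreasing, capped at 1, and
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (so ties are handled), with a
#' two-sided p-value from the t approximation.  Used for repeat-core,
#' intra-rater, inter-rater and manual-vs-automated agreement.
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @return list of class `gamihc_test`: `statistic` (rho), `p_value`,
#'   `n`, `method`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(statistic = rho, p_value = p, n = n,
                 method = "spearman_rho"),
            class = "gamihc_test")
}
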