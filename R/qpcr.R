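# Relative qPCR quantification (delta-delta-Ct) and standard-curve
# amplification efficiency.

#' Delta-delta-Ct relative quantification
#'
#' Triplicate CT values are averaged first (wells more than
#' `outlier_cycles` from the triplicate median are flagged).  Then per
#' sample and target gene:
#' dCT = mean CT(target) - mean CT(reference gene);
#' ddCT = dCT(sample) - mean dCT(control group);
#' R = 2^(-ddCT) * 100 (% of the control group).
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct`,
#'   `replicate`, `role` (`"target"` or `"reference"`), `group`
#'   (`"control"` or `"case"`).
#' @param outlier_cycles flag limit for replicate deviation from the
#'   triplicate median (cycles).
#' @return data.frame of class `ddct_table`: `sample`, `gene`, `dct`,
#'   `ddct`, `r_value` (percent of control group), `ct_sd`,
#'   `flagged_wells`.
#' @export
ddct_quantify <- function(ct, outlier_cycles = 0.5) {
  need <- c("sample", "gene", "ct", "role", "group")
  if (!all(need %in% names(ct))) {
    stop("CT table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(ct$ct <= 0)) stop("CT values must be positive", call. = FALSE)
  if (!any(ct$role == "reference")) {
    stop("reference-gene wells missing", call. = FALSE)
  }
  if (!any(ct$group == "control")) {
    stop("control-group samples missing", call. = FALSE)
  }
  agg <- do.call(rbind, lapply(
    split(ct, list(ct$sample, ct$gene), drop = TRUE), function(d) {
      dev <- abs(d$ct - stats::median(d$ct))
      data.frame(sample = d$sample[1], gene = d$gene[1],
                 role = d$role[1], group = d$group[1],
                 ct_mean = mean(d$ct),
                 ct_sd = if (nrow(d) > 1) stats::sd(d$ct) else NA_real_,
                 flagged_wells = sum(dev > outlier_cycles))
    }))
  ref <- agg[agg$role == "reference", ]
  ref_mean <- tapply(ref$ct_mean, ref$sample, mean)
  tgt <- agg[agg$role == "target", ]
  if (any(!tgt$sample %in% names(ref_mean))) {
    stop("reference-gene wells missing for some samples", call. = FALSE)
  }
  tgt$dct <- tgt$ct_mean - as.numeric(ref_mean[tgt$sample])
  ctrl_dct <- tapply(tgt$dct[tgt$group == "control"],
                     tgt$gene[tgt$group == "control"], mean)
  if (any(!tgt$gene %in% names(ctrl_dct))) {
    stop("control-group wells missing for some genes", call. = FALSE)
  }
  tgt$ddct <- tgt$dct - as.numeric(ctrl_dct[tgt$gene])
  tgt$r_value <- 2^(-tgt$ddct) * 100
  out <- tgt[, c("sample", "gene", "dct", "ddct", "r_value", "ct_sd",
                 "flagged_wells")]
  rownames(out) <- NULL
  class(out) <- c("ddct_table", class(out))
  out
}

#' qPCR standard curve from a serial dilution
#'
#' Least-squares fit of CT against log10(concentration); the
#' amplification efficiency is `10^(-1/slope) - 1` (1 = perfect
#' doubling per cycle; reported as a fraction, multiply by 100 for %).
#'
#' @param concentration relative template amounts (> 0), spanning at
#'   least 2 log10 units.
#' @param ct observed CT per dilution point.
#' @return list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`.
#' @examples
#' conc <- 10^(0:-4)
#' standard_curve(conc, 20 - log2(10) * log10(conc) * 0)  # see tests
#' @export
standard_curve <- function(concentration, ct) {
  if (length(concentration) != length(ct)) {
    stop("concentration and ct lengths differ", call. = FALSE)
  }
  if (length(ct) < 3L) stop("need at least 3 dilution points", call. = FALSE)
  if (any(concentration <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  lc <- log10(concentration)
  if (diff(range(lc)) < 2) {
    stop("dilution series must span at least 2 log10 units", call. = FALSE)
  }
  fit <- stats::lm(ct ~ lc)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-8) {
    stop("efficiency undefined: slope is zero (constant CT)", call. = FALSE)
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: slope %.4f, R^2 %.4f, efficiency %.1f%%\n",
    x$slope, x$r_squared, 100 * x$efficiency))
  invisible(x)
}
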