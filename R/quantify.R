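# Per-spot DAB quantification.
#
# The estimator is threshold-based assessment of stained area: after
# colour deconvolution, a tissue mask is obtained by a single entropy
# threshold on the combined hematoxylin + DAB channel, and the DAB
# threshold is estimated in two steps -- first from all tissue pixels of
# the spot, then re-estimated from only the pixels found by the first
# threshold.  The two-step refinement makes the final threshold robust
# to varying background staining that would otherwise drag a single
# whole-spot threshold into the background.  The per-spot readout is
# the ratio of DAB-positive area to total tissue area.  All thresholds
# are estimated per spot and never shared across spots.

#' Tissue mask from stain concentrations
#'
#' Tissue is defined as pixels whose combined stain OD
#' (hematoxylin + DAB concentration) exceeds a single entropy threshold,
#' separating stained tissue from glass; pixels of the optional
#' exclusion mask (e.g. annotated necrosis) are removed.
#'
#' @param hematoxylin,dab numeric matrices of per-stain concentrations
#'   (OD units), same shape.
#' @param exclusion_mask optional logical matrix, `TRUE` = excluded.
#' @param bins,method histogram bins and entropy criterion
#'   (see [entropy_threshold()]).
#' @return list with `mask` (logical), `threshold`, `total_area_px`.
#' @export
tissue_mask <- function(hematoxylin, dab, exclusion_mask = NULL,
                        bins = 256L, method = "li") {
  if (!identical(dim(hematoxylin), dim(dab))) {
    stop("channel shapes differ", call. = FALSE)
  }
  combined <- hematoxylin + dab
  keep <- !is.na(combined)
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(combined))) {
      stop("exclusion mask shape differs from channels", call. = FALSE)
    }
    keep <- keep & !exclusion_mask
  }
  if (!any(keep)) empty_tissue_error("all pixels excluded")
  thr <- tryCatch(
    entropy_threshold(od_histogram(combined[keep], bins = bins),
                      method = method),
    gamihc_degenerate_histogram = function(e) {
      empty_tissue_error("combined stain histogram is degenerate")
    })
  mask <- keep & combined >= as.numeric(thr)
  if (!any(mask)) empty_tissue_error("no pixels above tissue threshold")
  list(mask = mask, threshold = as.numeric(thr),
       total_area_px = sum(mask))
}

empty_tissue_error <- function(msg) {
  stop(structure(class = c("gamihc_empty_tissue", "error", "condition"),
                 list(message = paste0("empty tissue: ", msg),
                      call = NULL)))
}

#' Two-step DAB threshold
#'
#' First a threshold `t1` is estimated from all tissue pixels of the
#' spot; the final threshold `t2` is then re-estimated from only the
#' pixels at or above `t1`.  A degenerate histogram at step one yields
#' an empty DAB mask with `t1 = t2 = Inf` (a zero-DAB spot); a
#' degenerate second step falls back to `t2 = t1`.  If the re-estimate
#' falls below `t1` it is raised to `t1` (flagged), so the final mask is
#' always a subset of the step-one mask.
#'
#' @param dab numeric matrix of DAB concentrations (OD units).
#' @param tissue logical tissue mask (non-empty).
#' @param bins,method see [entropy_threshold()].
#' @return object of class `threshold_result`: list with `t1`, `t2`,
#'   `mask` (final DAB mask), `histogram` (step-one histogram), `flags`
#'   (character vector).
#' @export
two_step_dab_threshold <- function(dab, tissue, bins = 256L, method = "li") {
  if (!any(tissue)) stop("tissue mask is empty", call. = FALSE)
  vals <- dab[tissue]
  flags <- character()
  h1 <- od_histogram(vals, bins = bins)
  t1 <- tryCatch(as.numeric(entropy_threshold(h1, method = method)),
                 gamihc_degenerate_histogram = function(e) NA_real_)
  if (is.na(t1)) {
    # no DAB contrast: all tissue sits at a single level.  A level in
    # the bottom bin is an unstained (zero-DAB) spot; any higher single
    # level is uniformly stained tissue, i.e. a fully positive spot.
    j <- which(h1$counts > 0)[1L]
    if (j == 1L) {
      return(structure(list(t1 = Inf, t2 = Inf,
                            mask = tissue & FALSE, histogram = h1,
                            flags = "degenerate_step1_zero"),
                       class = "threshold_result"))
    }
    t0 <- h1$edges[j]
    return(structure(list(t1 = t0, t2 = t0,
                          mask = tissue & dab >= t0, histogram = h1,
                          flags = "degenerate_step1_saturated"),
                     class = "threshold_result"))
  }
  vals2 <- vals[vals >= t1]
  t2 <- tryCatch(
    as.numeric(entropy_threshold(
      od_histogram(vals2, bins = bins, upper = h1$edges[length(h1$edges)]),
      method = method)),
    gamihc_degenerate_histogram = function(e) {
      flags <<- c(flags, "degenerate_step2")
      t1
    })
  if (t2 < t1) {
    flags <- c(flags, "t2_below_t1")
    t2 <- t1
  }
  structure(list(t1 = t1, t2 = t2, mask = tissue & dab >= t2,
                 histogram = h1, flags = flags),
            class = "threshold_result")
}

#' Quantify the DAB-positive area fraction of one TMA spot
#'
#' Composes [rgb_to_od()], [deconvolve_stains()], [tissue_mask()] and
#' [two_step_dab_threshold()], and returns the ratio of DAB area to
#' total tissue area together with all estimated thresholds.  The
#' hematoxylin channel threshold is estimated and reported but does not
#' enter the ratio.
#'
#' @param image 8-bit RGB array (or a `gt_spot`, whose rendered image is
#'   used).
#' @param stains stain matrix, default [stain_matrix_hdab()].
#' @param exclusion_mask optional logical matrix of excluded pixels
#'   (e.g. necrosis), `TRUE` = excluded.
#' @param bins,method see [entropy_threshold()].
#' @param two_step if `FALSE`, the first-pass threshold `t1` is used
#'   directly (single-threshold estimator, for comparison).
#' @param i0 blank reference intensity.
#' @return object of class `spot_quant`: list with `ratio`,
#'   `dab_area_px`, `total_area_px`, `t1`, `t2`, `tissue_threshold`,
#'   `hematoxylin_threshold`, `method`, `flags`.
#' @examples
#' spot <- generate_spot(spot_spec(width = 128, height = 128, seed = 3))
#' q <- quantify_spot(spot)
#' c(truth = spot$true_fraction, estimate = q$ratio)
#' @export
quantify_spot <- function(image, stains = stain_matrix_hdab(),
                          exclusion_mask = NULL, bins = 256L,
                          method = "li", two_step = TRUE, i0 = 255) {
  od <- rgb_to_od(image, i0 = i0)
  conc <- deconvolve_stains(od, stains = stains)
  hema <- conc[, , "hematoxylin"]
  dab <- conc[, , "dab"]
  tm <- tissue_mask(hema, dab, exclusion_mask = exclusion_mask,
                    bins = bins, method = method)
  tr <- two_step_dab_threshold(dab, tm$mask, bins = bins, method = method)
  flags <- tr$flags
  if (two_step) {
    dab_mask <- tr$mask
    t_final <- tr$t2
  } else {
    t_final <- tr$t1
    dab_mask <- if (is.finite(t_final)) tm$mask & dab >= t_final
                else tm$mask & FALSE
  }
  hthr <- tryCatch(
    as.numeric(entropy_threshold(od_histogram(hema[tm$mask], bins = bins),
                                 method = method)),
    gamihc_degenerate_histogram = function(e) NA_real_)
  structure(list(ratio = sum(dab_mask) / tm$total_area_px,
                 dab_area_px = sum(dab_mask),
                 total_area_px = tm$total_area_px,
                 t1 = tr$t1, t2 = t_final,
                 tissue_threshold = tm$threshold,
                 hematoxylin_threshold = hthr,
                 method = method, two_step = two_step,
                 flags = flags),
            class = "spot_quant")
}

#' @export
print.spot_quant <- function(x, ...) {
  cat(sprintf(
    paste0("DAB quantification (%s%s): ratio %.4f ",
           "(%d / %d px); t1 = %.4f, t2 = %.4f, tissue thr = %.4f\n"),
    x$method, if (x$two_step) ", two-step" else ", one-step",
    x$ratio, x$dab_area_px, x$total_area_px, x$t1, x$t2,
    x$tissue_threshold))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Quantify a batch of spots
#'
#' Applies [quantify_spot()] to each element; a failing spot (e.g. empty
#' tissue) is flagged in the output and the batch continues.
#'
#' @param spots list of images or `gt_spot` objects.
#' @param ... passed to [quantify_spot()].
#' @return data.frame with one row per spot: `spot_id`, `t1`, `t2`,
#'   `tissue_threshold`, `dab_area_px`, `total_area_px`, `ratio`,
#'   `flags` (comma-separated; `"error: <message>"` for failed spots).
#' @export
quantify_spots <- function(spots, ...) {
  ids <- names(spots) %||% as.character(seq_along(spots))
  ids[ids == ""] <- as.character(which(ids == ""))
  rows <- lapply(seq_along(spots), function(i) {
    q <- tryCatch(quantify_spot(spots[[i]], ...), error = function(e) e)
    if (inherits(q, "error")) {
      data.frame(spot_id = ids[i], t1 = NA_real_, t2 = NA_real_,
                 tissue_threshold = NA_real_, dab_area_px = NA_integer_,
                 total_area_px = NA_integer_, ratio = NA_real_,
                 flags = paste0("error: ", conditionMessage(q)))
    } else {
      data.frame(spot_id = ids[i], t1 = q$t1, t2 = q$t2,
                 tissue_threshold = q$tissue_threshold,
                 dab_area_px = q$dab_area_px,
                 total_area_px = q$total_area_px, ratio = q$ratio,
                 flags = paste(q$flags, collapse = ","))
    }
  })
  do.call(rbind, rows)
}
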