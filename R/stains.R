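# Beer-Lambert optical-density transform and colour deconvolution.
#
# Brightfield stains attenuate light multiplicatively, so absorbances add:
# OD_c = -log10(I_c / I0) for each RGB channel c.  A pixel stained by
# several chromogens has OD equal to a non-negative combination of the
# stains' unit OD vectors; inverting that linear system ("colour
# deconvolution", Ruifrok & Johnston) yields per-stain concentrations in
# OD units.

#' Default H-DAB stain matrix
#'
#' Rows are unit-norm optical-density vectors for hematoxylin, DAB, and a
#' residual channel (the normalized cross product of the first two).
#' These are the widely used published H-DAB reference vectors; batches
#' with calibrated vectors can supply their own matrix.
#'
#' @param hematoxylin,dab numeric length-3 OD vectors; normalized internally.
#' @return A 3 x 3 matrix of class `stain_matrix`, rows named
#'   `hematoxylin`, `dab`, `residual`.
#' @examples
#' stain_matrix_hdab()
#' @export
stain_matrix_hdab <- function(hematoxylin = c(0.650, 0.704, 0.286),
                              dab = c(0.269, 0.568, 0.778)) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("red", "green", "blue")
  class(m) <- c("stain_matrix", class(m))
  validate_stain_matrix(m)
  m
}

validate_stain_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || !is.numeric(m)) {
    stop("stain matrix must be a numeric 3 x 3 matrix", call. = FALSE)
  }
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("stain matrix rows must have unit Euclidean norm", call. = FALSE)
  }
  if (kappa(m, exact = TRUE) >= 1e6) {
    stop("stain matrix is singular or ill-conditioned", call. = FALSE)
  }
  invisible(m)
}

#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer-Lambert transform `od = log10(i0 / I)` channel-wise,
#' after clamping intensities to `[1, i0]` so saturated (black) pixels map
#' to a finite OD.
#'
#' @param image numeric array `height x width x 3` with intensities in
#'   `[0, 255]` (or a `gt_spot` object, whose `$image` is used).
#' @param i0 reference (blank) intensity, default 255.
#' @return numeric array of the same shape with per-channel OD values.
#' @examples
#' px <- array(c(128, 128, 128), dim = c(1, 1, 3))
#' rgb_to_od(px)[1, 1, ]  # log10(255/128) in each channel
#' @export
rgb_to_od <- function(image, i0 = 255) {
  if (inherits(image, "gt_spot")) image <- image$image
  stopifnot_scalar(i0, "i0", lo = 1e-12)
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L ||
      prod(dim(image)) == 0L) {
    stop("`image` must be a non-empty height x width x 3 array", call. = FALSE)
  }
  od <- log10(i0 / pmin(pmax(image, 1), i0))
  dim(od) <- dim(image)
  od
}

#' Unmix an OD image into per-stain concentrations
#'
#' Solves `od = t(M) %*% c` per pixel, where `M` has the stain OD vectors
#' as rows; negative concentrations (out-of-span noise) are clipped to 0.
#'
#' @param od OD array `height x width x 3` (see [rgb_to_od()]).
#' @param stains a `stain_matrix`, default [stain_matrix_hdab()].
#' @param clip clip negative concentrations to zero (default `TRUE`).
#' @return array `height x width x 3`; third dimension named
#'   `hematoxylin`, `dab`, `residual`.
#' @export
deconvolve_stains <- function(od, stains = stain_matrix_hdab(), clip = TRUE) {
  validate_stain_matrix(stains)
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L) {
    stop("`od` must be a height x width x 3 array", call. = FALSE)
  }
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)            # pixels x channels
  conc <- flat %*% solve(stains)           # solves od = conc %*% M row-wise
  if (clip) conc[conc < 0] <- 0
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(stains))
  out
}

# Forward render: concentrations -> 8-bit RGB (used by the spot generator).
od_to_rgb <- function(hema, dab, stains = stain_matrix_hdab(), i0 = 255) {
  d <- dim(hema)
  od <- outer(as.vector(hema), stains["hematoxylin", ]) +
    outer(as.vector(dab), stains["dab", ])
  img <- round(i0 * 10^(-od))
  img[img < 0] <- 0
  img[img > i0] <- i0
  array(img, dim = c(d, 3L))
}
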