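# Synthetic H-DAB TMA spot generator.
#
# Spots are rendered through the Beer-Lambert forward model: per-pixel
# hematoxylin and DAB optical densities are composed and converted to
# 8-bit RGB as I = 255 * 10^(-OD . stain_vector).  Tissue is a centred
# disc on glass; DAB-positive cells are filled discs with
# Gaussian-blurred edges (sigma = 1 px); background DAB haze (constant
# or a linear gradient) stains the non-positive tissue, blending with
# the cell deposit at blurred boundaries.  The painted (pre-blur) disc
# set is the ground-truth positive mask, giving a known positive-area
# fraction used as the oracle for the DAB ratio.

#' Specification of a synthetic TMA spot
#'
#' @param width,height image size in pixels.
#' @param cell_count number of hematoxylin-stained nuclei rendered as
#'   counterstain texture (it does not control the DAB-positive area;
#'   that is driven by `positive_fraction`).
#' @param positive_fraction target fraction of tissue area that is
#'   DAB-positive, in `[0, 1]`.
#' @param dab_od_mean optical density of positive-cell DAB deposit; must
#'   exceed the maximum background haze OD.
#' @param haze_profile background DAB haze descriptor: either
#'   `list(type = "flat", od = <level>)` or
#'   `list(type = "linear", od_start = , od_end = , axis = "x"|"y")`.
#' @param hematoxylin_od_mean OD of the nuclear counterstain.
#' @param noise_sd per-pixel OD noise standard deviation.
#' @param tissue_fraction fraction of the image covered by the tissue
#'   disc (the rest is glass).
#' @param cell_radius_range range (pixels) of positive-cell disc radii;
#'   the defaults correspond to stained microglial somata of roughly
#'   6-10 um radius at a 0.25 um/px scan.
#' @param seed RNG seed; identical specs with identical seeds produce
#'   byte-identical spots.
#' @return a validated list of class `spot_spec`.
#' @export
spot_spec <- function(width = 384L, height = 384L, cell_count = 350L,
                      positive_fraction = 0.2, dab_od_mean = 0.8,
                      haze_profile = list(type = "flat", od = 0.05),
                      hematoxylin_od_mean = 0.45, noise_sd = 0.03,
                      tissue_fraction = 0.72,
                      cell_radius_range = c(26, 40), seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               cell_count = as.integer(cell_count),
               positive_fraction = positive_fraction,
               dab_od_mean = dab_od_mean, haze_profile = haze_profile,
               hematoxylin_od_mean = hematoxylin_od_mean,
               noise_sd = noise_sd, tissue_fraction = tissue_fraction,
               cell_radius_range = cell_radius_range, seed = as.integer(seed))
  class(spec) <- "spot_spec"
  validate_spot_spec(spec)
  spec
}

haze_range <- function(haze) {
  switch(haze$type,
         flat = c(haze$od, haze$od),
         linear = range(haze$od_start, haze$od_end),
         stop("haze_profile$type must be 'flat' or 'linear'", call. = FALSE))
}

haze_field <- function(haze, height, width) {
  if (haze$type == "flat") {
    matrix(haze$od, height, width)
  } else {
    axis <- haze$axis %||% "x"
    if (axis == "x") {
      ramp <- seq(haze$od_start, haze$od_end, length.out = width)
      matrix(ramp, height, width, byrow = TRUE)
    } else {
      ramp <- seq(haze$od_start, haze$od_end, length.out = height)
      matrix(ramp, height, width)
    }
  }
}

validate_spot_spec <- function(spec) {
  stopifnot_scalar(spec$width, "width", lo = 16)
  stopifnot_scalar(spec$height, "height", lo = 16)
  stopifnot_scalar(spec$cell_count, "cell_count", lo = 0)
  stopifnot_scalar(spec$positive_fraction, "positive_fraction", 0, 1)
  stopifnot_scalar(spec$dab_od_mean, "dab_od_mean", lo = 0)
  stopifnot_scalar(spec$hematoxylin_od_mean, "hematoxylin_od_mean", lo = 0)
  stopifnot_scalar(spec$noise_sd, "noise_sd", lo = 0)
  stopifnot_scalar(spec$tissue_fraction, "tissue_fraction", 0.05, 1)
  hz <- haze_range(spec$haze_profile)
  if (any(hz < 0)) stop("haze OD must be non-negative", call. = FALSE)
  if (spec$dab_od_mean <= max(hz)) {
    stop("dab_od_mean must exceed the maximum haze OD", call. = FALSE)
  }
  if (length(spec$cell_radius_range) != 2L ||
      any(spec$cell_radius_range < 1) ||
      diff(spec$cell_radius_range) < 0) {
    stop("cell_radius_range must be an increasing pair >= 1", call. = FALSE)
  }
  invisible(spec)
}

disc_offsets <- function(r) {
  d <- -ceiling(r):ceiling(r)
  g <- expand.grid(di = d, dj = d)
  g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
}

# Separable Gaussian blur, zero-padded edges.
blur_gaussian <- function(m, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  pass <- function(x, along_rows) {
    out <- x * 0
    for (o in -r:r) {
      wt <- k[o + r + 1L]
      if (along_rows) {
        src <- max(1L, 1L - o):min(h, h - o)
        dst <- src + o
        out[dst, ] <- out[dst, ] + wt * x[src, ]
      } else {
        src <- max(1L, 1L - o):min(w, w - o)
        dst <- src + o
        out[, dst] <- out[, dst] + wt * x[, src]
      }
    }
    out
  }
  pass(pass(m, TRUE), FALSE)
}

#' Generate a ground-truthed synthetic TMA spot
#'
#' Renders the spot described by `spec` and returns the image together
#' with the generator's truth: the positive mask, the tissue mask, the
#' realized positive-area fraction, and the per-pixel stain OD maps used
#' for rendering (the oracle for deconvolution round-trips).
#'
#' @param spec a [spot_spec()].
#' @return object of class `gt_spot`: a list with `image`
#'   (height x width x 3, 8-bit), `positive_mask`, `tissue_mask`,
#'   `true_fraction`, `hematoxylin_od`, `dab_od`, and `spec`.
#' @examples
#' spot <- generate_spot(spot_spec(width = 96, height = 96, seed = 7))
#' spot$true_fraction
#' @export
generate_spot <- function(spec) {
  validate_spot_spec(spec)
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    # tissue disc
    radius <- min(sqrt(spec$tissue_fraction * h * w / pi),
                  min(h, w) / 2 - 1)
    ci <- (h + 1) / 2; cj <- (w + 1) / 2
    ii <- matrix(seq_len(h), h, w)
    jj <- matrix(seq_len(w), h, w, byrow = TRUE)
    tissue <- (ii - ci)^2 + (jj - cj)^2 <= radius^2
    tissue_idx <- which(tissue)
    tissue_area <- length(tissue_idx)

    # paint DAB-positive discs until the target pixel count is met exactly
    positive <- matrix(FALSE, h, w)
    target <- round(spec$positive_fraction * tissue_area)
    covered <- 0L
    stalled <- 0L
    while (covered < target) {
      r <- stats::runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
      centre <- tissue_idx[sample.int(tissue_area, 1L)]
      c_i <- (centre - 1L) %% h + 1L
      c_j <- (centre - 1L) %/% h + 1L
      off <- disc_offsets(r)
      di <- c_i + off$di; dj <- c_j + off$dj
      ok <- di >= 1L & di <= h & dj >= 1L & dj <= w
      lin <- di[ok] + (dj[ok] - 1L) * h
      lin <- lin[tissue[lin] & !positive[lin]]
      if (length(lin) == 0L) {
        stalled <- stalled + 1L
        if (stalled > 200L) {  # dense spot: fill remaining pixels directly
          rest <- tissue_idx[!positive[tissue_idx]]
          positive[rest[seq_len(target - covered)]] <- TRUE
          covered <- target
        }
        next
      }
      stalled <- 0L
      if (covered + length(lin) > target) {
        lin <- lin[seq_len(target - covered)]
      }
      positive[lin] <- TRUE
      covered <- covered + length(lin)
    }
    true_fraction <- covered / tissue_area

    # nuclei counterstain texture
    nuclei <- matrix(FALSE, h, w)
    if (spec$cell_count > 0L) {
      centres <- tissue_idx[sample.int(tissue_area, spec$cell_count,
                                       replace = TRUE)]
      off <- disc_offsets(6)
      for (centre in centres) {
        c_i <- (centre - 1L) %% h + 1L
        c_j <- (centre - 1L) %/% h + 1L
        di <- c_i + off$di; dj <- c_j + off$dj
        ok <- di >= 1L & di <= h & dj >= 1L & dj <= w
        nuclei[di[ok] + (dj[ok] - 1L) * h] <- TRUE
      }
    }

    # OD maps: blurred cell deposit blends over the background haze
    b <- blur_gaussian(positive * 1, sigma = 1)
    b[b > 1] <- 1
    haze <- haze_field(spec$haze_profile, h, w)
    dab <- spec$dab_od_mean * b + haze * (1 - b)
    hema <- spec$hematoxylin_od_mean *
      (0.75 + 0.5 * blur_gaussian(nuclei * 1, sigma = 1))
    dab[!tissue] <- 0
    hema[!tissue] <- 0
    if (spec$noise_sd > 0) {
      dab <- dab + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      hema <- hema + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      dab[dab < 0] <- 0
      hema[hema < 0] <- 0
    }

    structure(list(image = od_to_rgb(hema, dab),
                   positive_mask = positive,
                   tissue_mask = tissue,
                   true_fraction = true_fraction,
                   hematoxylin_od = hema,
                   dab_od = dab,
                   spec = spec),
              class = "gt_spot")
  })
}

#' @export
print.gt_spot <- function(x, ...) {
  cat(sprintf(
    "Synthetic H-DAB spot: %d x %d px, tissue %d px, positive fraction %.4f\n",
    x$spec$height, x$spec$width, sum(x$tissue_mask), x$true_fraction))
  invisible(x)
}
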