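# File interchange: spot images and masks as 8-bit PNG, tables as CSV,
# with a sidecar JSON per generated artifact recording spec and seed.

#' Write a generated spot to disk
#'
#' Writes the RGB image and the two truth masks as 8-bit PNGs plus a
#' sidecar JSON with the generating spec (including the seed).
#'
#' @param spot a `gt_spot`.
#' @param dir output directory (created if needed).
#' @param name file stem, default `"spot"`.
#' @return invisibly, the paths written.
#' @export
write_spot <- function(spot, dir, name = "spot") {
  if (!inherits(spot, "gt_spot")) stop("need a gt_spot", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(name, c(".png", "_positive_mask.png",
                                         "_tissue_mask.png", ".json")))
  png::writePNG(spot$image / 255, paths[1])
  png::writePNG(spot$positive_mask * 1, paths[2])
  png::writePNG(spot$tissue_mask * 1, paths[3])
  spec <- spot$spec
  class(spec) <- NULL
  jsonlite::write_json(list(spec = spec,
                            true_fraction = spot$true_fraction),
                       paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a spot image (PNG or TIFF) as an 8-bit RGB array
#'
#' @param path image path; `.png` requires the png package (imported),
#'   `.tif`/`.tiff` the tiff package (suggested).
#' @return numeric array height x width x 3 with values in `[0, 255]`.
#' @export
read_spot_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE)) {
                    stop("the tiff package is required for TIFF input",
                         call. = FALSE)
                  }
                  tiff::readTIFF(path)
                },
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Read an exclusion mask PNG (nonzero = excluded)
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_exclusion_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0
}

#' Write a cohort or result table as CSV with a sidecar JSON
#'
#' @param table data.frame.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @param meta list stored in the sidecar (e.g. spec and seed).
#' @return invisibly, `path`.
#' @export
write_table_csv <- function(table, path, meta = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(path)
}

#' Serialize a survival comparison to JSON
#'
#' Curves are emitted as arrays of (time, survival, at-risk) triples,
#' together with the cutpoint and both test results.
#'
#' @param split a `survival_split`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_split_json <- function(split, path) {
  curves <- lapply(split$km, function(km) {
    data.frame(time = km$time, surv = km$surv, n_risk = km$n_risk)
  })
  jsonlite::write_json(
    list(cutpoint = split$cutpoint,
         n_high = split$n_high, n_low = split$n_low,
         logrank = split$logrank[c("statistic", "p_value")],
         gehan = split$gehan[c("statistic", "p_value")],
         curves = curves,
         scan = split$scan),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
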