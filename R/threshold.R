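# Entropy-based histogram thresholding.
#
# Two criteria are provided.  The default, Li's minimum cross-entropy,
# picks the bin edge minimizing the cross entropy between the image and
# its two-level (below/above) representation; in the reduced form used
# here the criterion for a split is
#   eta(t) = -(m1(t) * log mu1(t) + m2(t) * log mu2(t))
# where m1, m2 are the grey-level-weighted masses and mu1, mu2 the mean
# grey levels below/above t.  Kapur's maximum-entropy criterion
# (selectable) maximizes the summed Shannon entropies of the two classes.
# Both are evaluated by exhaustive scan over all admissible bin edges, so
# the returned threshold is the global optimum by construction.

#' Build an OD histogram with a stabilized upper edge
#'
#' 256 uniform bins over `[0, max(2.5, max(values))]`; the fixed lower
#' edge and the 2.5 OD floor on the upper edge keep bin geometry (and so
#' thresholds) comparable across spots of an 8-bit batch.
#'
#' @param values non-negative numeric vector (OD or concentration values).
#' @param bins number of bins (default 256, matching 8-bit provenance).
#' @param upper optional fixed upper edge; default `max(2.5, max(values))`.
#' @return list with `edges` (length `bins + 1`), `counts` (length `bins`),
#'   and `centers`.
#' @export
od_histogram <- function(values, bins = 256L, upper = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to bin", call. = FALSE)
  if (any(values < 0)) stop("OD values must be non-negative", call. = FALSE)
  stopifnot_scalar(bins, "bins", lo = 2)
  upper <- upper %||% max(2.5, max(values))
  edges <- seq(0, upper, length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > bins] <- bins
  counts <- tabulate(idx, nbins = bins)
  list(edges = edges, counts = counts,
       centers = (edges[-1L] + edges[-length(edges)]) / 2)
}

#' Entropy threshold of a histogram
#'
#' Exhaustive search for the bin edge optimizing the chosen entropy
#' criterion.  Pixels with value greater than or equal to the returned
#' edge are "above" the threshold.
#'
#' @param hist histogram as returned by [od_histogram()] (a list with
#'   `edges` and `counts`).
#' @param method `"li"` (minimum cross-entropy, default) or `"kapur"`
#'   (maximum entropy).
#' @return the optimal threshold (a bin edge, in the units of the
#'   histogram), with attributes `index` (edge index), `candidates` and
#'   `criterion` (criterion value per candidate edge; minimized for Li,
#'   maximized for Kapur).
#' @seealso [two_step_dab_threshold()] which applies this twice.
#' @export
entropy_threshold <- function(hist, method = c("li", "kapur")) {
  method <- match.arg(method)
  counts <- hist$counts
  edges <- hist$edges
  if (length(edges) != length(counts) + 1L) {
    stop("histogram edges/counts length mismatch", call. = FALSE)
  }
  nonempty <- which(counts > 0)
  if (length(nonempty) < 2L) {
    stop(structure(
      class = c("gamihc_degenerate_histogram", "error", "condition"),
      list(message = "degenerate histogram: fewer than 2 non-empty bins",
           call = sys.call(-1))))
  }
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  # candidate split edges: both sides must contain at least one count
  lo <- nonempty[1L] + 1L
  hi <- nonempty[length(nonempty)]
  ks <- lo:hi
  crit <- if (method == "li") {
    gh <- centers * counts
    m1 <- cumsum(gh)[ks - 1L]
    n1 <- cumsum(counts)[ks - 1L]
    m2 <- sum(gh) - m1
    n2 <- sum(counts) - n1
    -(m1 * log(m1 / n1) + m2 * log(m2 / n2))
  } else {
    p <- counts / sum(counts)
    plogp <- ifelse(p > 0, p * log(p), 0)
    P1 <- cumsum(p)[ks - 1L]
    H1 <- -cumsum(plogp)[ks - 1L]
    Htot <- -sum(plogp)
    log(P1 * (1 - P1)) + H1 / P1 + (Htot - H1) / (1 - P1)
  }
  best <- if (method == "li") which.min(crit) else which.max(crit)
  k <- ks[best]
  structure(edges[k], index = k, candidates = edges[ks], criterion = crit)
}
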