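# Expression-side computations: fold-change DEG screen, Ward
# clustering, Pearson coexpression and rank-product false-prediction
# estimates.

get_exprs <- function(x) {
  if (inherits(x, "expression_set")) {
    list(exprs = x$exprs, condition = x$condition)
  } else if (is.matrix(x)) {
    stop("supply an `expression_set` (matrix plus condition labels)",
         call. = FALSE)
  } else {
    stop("unsupported expression input", call. = FALSE)
  }
}

#' Log2 fold-change DEG screen
#'
#' Per gene, log2FC = mean(case) - mean(reference); a gene passes if
#' |log2FC| is at or above the threshold (inclusive boundary, so a gene
#' at exactly the threshold passes).
#'
#' @param x an `expression_set` (log2-scale matrix with condition
#'   labels; see [generate_expression()]).
#' @param threshold absolute log2FC cut, default 2.
#' @return data.frame of class `deg_table`: `gene`, `log2fc`, `pass`.
#' @export
deg_filter <- function(x, threshold = 2) {
  stopifnot_scalar(threshold, "threshold", lo = 0)
  e <- get_exprs(x)
  if (!all(c("case", "reference") %in% e$condition)) {
    stop("both conditions must be present", call. = FALSE)
  }
  case_mean <- rowMeans(e$exprs[, e$condition == "case", drop = FALSE])
  ref_mean <- rowMeans(e$exprs[, e$condition == "reference", drop = FALSE])
  lfc <- case_mean - ref_mean
  out <- data.frame(gene = rownames(e$exprs), log2fc = unname(lfc),
                    pass = unname(abs(lfc) >= threshold))
  class(out) <- c("deg_table", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering of genes or samples with Ward's
#' minimum-variance criterion on Euclidean distances
#' (`hclust(method = "ward.D2")`, which implements Ward's criterion for
#' Euclidean input).  Merge heights are non-decreasing; the leaf order
#' is available for heatmap display.
#'
#' @param x an `expression_set` or numeric matrix.
#' @param axis `"genes"` (rows, default) or `"samples"` (columns).
#' @return an `hclust` object.
#' @export
ward_cluster <- function(x, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- if (inherits(x, "expression_set")) x$exprs else x
  if (!is.matrix(m)) stop("need a matrix input", call. = FALSE)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}

#' Pearson coexpression matrix
#'
#' Gene-by-gene Pearson correlations across samples; constant genes
#' yield `NA` rows/columns (undefined correlation) and a warning.
#'
#' @param x an `expression_set` or numeric genes x samples matrix.
#' @return symmetric correlation matrix with unit diagonal (NA for
#'   constant genes).
#' @export
pearson_coexpression <- function(x) {
  m <- if (inherits(x, "expression_set")) x$exprs else x
  if (ncol(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  const <- apply(m, 1, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(t(m), method = "pearson"))
  if (any(const)) {
    warning(sum(const), " constant gene(s): correlations undefined (NA)")
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  diag(cc)[!const] <- 1
  cc
}

# Geometric-mean rank products of per-sample fold-change ranks,
# up- and down-regulation separately.  Internal engine shared by the
# estimator and its permutation null.
rank_products <- function(case_fc) {
  k <- ncol(case_fc)
  up <- apply(-case_fc, 2, rank, ties.method = "average")
  dn <- apply(case_fc, 2, rank, ties.method = "average")
  list(up = exp(rowMeans(log(up))), down = exp(rowMeans(log(dn))))
}

#' Rank-product significance with permutation pfp
#'
#' Per gene, fold changes against the reference mean are ranked within
#' each case sample (up- and down-regulation separately) and combined
#' as the geometric-mean rank product.  Significance is reported as the
#' pfp (proportion of false prediction, an FDR-type measure): expected
#' number of null genes at least as extreme -- estimated by permuting
#' the expression values within each sample -- divided by the observed
#' rank of the gene.
#'
#' @param x an `expression_set` with >= 2 case samples.
#' @param n_permutations number of within-sample permutations (>= 10).
#' @param seed RNG seed for the permutations.
#' @return data.frame of class `rank_product_table`: `gene`, `rp_up`,
#'   `rp_down`, `pfp_up`, `pfp_down`.
#' @export
rank_product_pfp <- function(x, n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 10L) {
    stop("n_permutations must be at least 10", call. = FALSE)
  }
  e <- get_exprs(x)
  case <- e$exprs[, e$condition == "case", drop = FALSE]
  if (ncol(case) < 2L) stop("need >= 2 case samples", call. = FALSE)
  ref_mean <- rowMeans(e$exprs[, e$condition == "reference", drop = FALSE])
  fc <- case - ref_mean
  ng <- nrow(fc)
  obs <- rank_products(fc)

  pfp_dir <- function(rp_obs, perm_counts) {
    # perm_counts: total permuted rank products <= each observed value.
    # Step-up smoothing keeps pfp non-increasing in extremity, as for
    # other FDR-type measures.
    e_false <- perm_counts / n_permutations
    r <- rank(rp_obs, ties.method = "max")
    raw <- e_false / r
    ord <- order(rp_obs)
    out <- numeric(length(raw))
    out[ord] <- rev(cummin(rev(raw[ord])))
    out
  }
  with_seed(seed, {
    cnt_up <- numeric(ng)
    cnt_dn <- numeric(ng)
    ord_up <- order(obs$up)
    ord_dn <- order(obs$down)
    for (b in seq_len(n_permutations)) {
      perm <- apply(fc, 2, sample)
      null <- rank_products(perm)
      # counts of null rank products <= observed, via sorted merge
      cnt_up <- cnt_up + findInterval(obs$up, sort(null$up))
      cnt_dn <- cnt_dn + findInterval(obs$down, sort(null$down))
    }
    out <- data.frame(gene = rownames(e$exprs),
                      rp_up = obs$up, rp_down = obs$down,
                      pfp_up = pfp_dir(obs$up, cnt_up),
                      pfp_down = pfp_dir(obs$down, cnt_dn))
    rownames(out) <- NULL
    class(out) <- c("rank_product_table", class(out))
    out
  })
}
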