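# Synthetic expression matrix generator: a two-condition log2-scale
# matrix (case samples vs a small reference group, mirroring GAM
# profiles vs pooled normal white-matter microglia) with planted
# fold changes of known size.

#' Specification of a synthetic expression data set
#'
#' @param n_genes number of genes.
#' @param n_case_samples,n_ref_samples samples per condition; defaults
#'   mirror a 6-case vs single-pooled-reference design.
#' @param planted_deg_ids character vector of gene ids carrying a
#'   planted shift; must be a subset of `gene<1..n_genes>`.  Default:
#'   the first 40 genes.
#' @param planted_log2fc numeric shift per planted gene (recycled);
#'   default alternating +4 / -4.
#' @param noise_sd residual SD on the log2 scale.
#' @param baseline_mean,baseline_sd per-gene baseline distribution.
#' @param seed RNG seed.
#' @return validated list of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 2000L, n_case_samples = 6L,
                            n_ref_samples = 1L,
                            planted_deg_ids = paste0("gene", 1:40),
                            planted_log2fc = rep(c(4, -4), length.out = 40),
                            noise_sd = 0.25, baseline_mean = 7,
                            baseline_sd = 1, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_case_samples = as.integer(n_case_samples),
               n_ref_samples = as.integer(n_ref_samples),
               planted_deg_ids = as.character(planted_deg_ids),
               planted_log2fc = rep(planted_log2fc,
                                    length.out = length(planted_deg_ids)),
               noise_sd = noise_sd, baseline_mean = baseline_mean,
               baseline_sd = baseline_sd, seed = as.integer(seed))
  class(spec) <- "expression_spec"
  validate_expression_spec(spec)
  spec
}

validate_expression_spec <- function(spec) {
  stopifnot_scalar(spec$n_genes, "n_genes", lo = 1)
  stopifnot_scalar(spec$n_case_samples, "n_case_samples", lo = 1)
  stopifnot_scalar(spec$n_ref_samples, "n_ref_samples", lo = 1)
  stopifnot_scalar(spec$noise_sd, "noise_sd", lo = 0)
  genes <- paste0("gene", seq_len(spec$n_genes))
  if (!all(spec$planted_deg_ids %in% genes)) {
    stop("planted_deg_ids must be a subset of the generated gene ids",
         call. = FALSE)
  }
  invisible(spec)
}

#' Generate a synthetic two-condition expression matrix
#'
#' @param spec an [expression_spec()].
#' @return object of class `expression_set`: list with `exprs`
#'   (genes x samples log2 matrix), `condition` (factor `case` /
#'   `reference` per sample) and `truth` (planted ids and shifts).
#' @examples
#' es <- generate_expression(expression_spec(n_genes = 100, seed = 5))
#' dim(es$exprs)
#' @export
generate_expression <- function(spec) {
  validate_expression_spec(spec)
  with_seed(spec$seed, {
    genes <- paste0("gene", seq_len(spec$n_genes))
    ns <- spec$n_case_samples + spec$n_ref_samples
    cond <- factor(rep(c("case", "reference"),
                       c(spec$n_case_samples, spec$n_ref_samples)),
                   levels = c("case", "reference"))
    base <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    x <- matrix(base, spec$n_genes, ns) +
      matrix(stats::rnorm(spec$n_genes * ns, 0, spec$noise_sd),
             spec$n_genes, ns)
    shift <- stats::setNames(numeric(spec$n_genes), genes)
    shift[spec$planted_deg_ids] <- spec$planted_log2fc
    x[, cond == "case"] <- x[, cond == "case"] + shift
    dimnames(x) <- list(genes,
                        c(paste0("case", seq_len(spec$n_case_samples)),
                          paste0("ref", seq_len(spec$n_ref_samples))))
    structure(list(exprs = x, condition = cond,
                   truth = list(planted_deg_ids = spec$planted_deg_ids,
                                planted_log2fc = spec$planted_log2fc),
                   spec = spec),
              class = "expression_set")
  })
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("Expression set: %d genes x %d samples (%d case, %d reference)\n",
              nrow(x$exprs), ncol(x$exprs), sum(x$condition == "case"),
              sum(x$condition == "reference")))
  invisible(x)
}
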