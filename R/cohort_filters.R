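# Cohort filtering rules applied before statistical analysis.

#' Select the first core of each patient
#'
#' Keeps exactly one row per patient x marker x region: the core with
#' index 1, or the lowest core index present if core 1 is missing (in
#' which case the row is flagged in the `flag` column).
#'
#' @param table a cohort data.frame with columns `patient_id`,
#'   `core_index`, `marker`, `region`.
#' @return the filtered table with an added `flag` column
#'   (`"first_core_missing"` where the fallback applied).
#' @export
first_core_select <- function(table) {
  if (nrow(table) == 0L) stop("cohort table is empty", call. = FALSE)
  key <- interaction(table$patient_id, table$marker, table$region,
                     drop = TRUE)
  idx <- unlist(lapply(split(seq_len(nrow(table)), key), function(i) {
    i[which.min(table$core_index[i])]
  }), use.names = FALSE)
  out <- table[sort(idx), , drop = FALSE]
  out$flag <- ifelse(out$core_index == 1L, "", "first_core_missing")
  rownames(out) <- NULL
  out
}

#' Exclude cores with extensive necrosis
#'
#' Cores with a necrosis fraction strictly above `max_necrosis`
#' (default 30%) are removed; cores at exactly the limit are retained.
#'
#' @param table cohort data.frame with a `necrosis_fraction` column.
#' @param max_necrosis exclusion limit as a fraction (default 0.30).
#' @return the filtered table; the number of removed rows is reported
#'   via `message()` and stored in the `n_excluded` attribute.
#' @export
exclude_necrotic <- function(table, max_necrosis = 0.30) {
  stopifnot_scalar(max_necrosis, "max_necrosis", 0, 1)
  if (is.null(table$necrosis_fraction)) {
    stop("`necrosis_fraction` column missing", call. = FALSE)
  }
  drop <- table$necrosis_fraction > max_necrosis
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  if (sum(drop) > 0L) {
    message(sprintf("excluded %d core(s) with necrosis fraction > %.2f",
                    sum(drop), max_necrosis))
  }
  if (nrow(out) == 0L) warning("all cores excluded by necrosis rule")
  out
}
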