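# Synthetic survival cohort generator.
#
# Emulates a TMA cohort of IDH1R132H-non-mutant GBM patients with up to
# three repeated cores per patient: a right-skewed percent-positive
# marker per patient with core-to-core noise, exponential survival
# whose hazard is multiplied by exp(log HR) for patients whose recorded
# first-core marker lies above the dichotomization point (the cohort
# median by default, or a fixed change-point), and independent
# censoring (competing exponential with a long administrative cap).

#' Specification of a synthetic marker/survival cohort
#'
#' @param n_patients number of patients (>= 2).
#' @param marker_distribution latent percent-positive distribution:
#'   `list(family = "beta", shape1, shape2, scale)`; the default
#'   Beta(2, 5) scaled to `[0, 100]` gives the right-skew typical of
#'   percent-positive IHC scores.
#' @param log_hazard_ratio_high_vs_low log hazard ratio of the high
#'   marker arm relative to the low arm (0 = null).
#' @param baseline_hazard exponential event rate per month for the low
#'   arm; the default `log(2)/15` corresponds to a 15-month median
#'   survival.
#' @param censoring_rate target fraction of censored patients.
#' @param cores_per_patient number of repeat cores (1-3) per patient and
#'   region.
#' @param core_noise_sd SD of the within-patient spread across repeat
#'   cores (percent-positive units).
#' @param hazard_cutpoint optional fixed marker value at which the
#'   hazard changes; `NULL` (default) dichotomizes at the median of the
#'   first-core marker values (the variable the analysis splits on).
#' @param regions character vector of region labels to generate
#'   (subset of `c("T", "IZ", "NAB")`).
#' @param region_shift named numeric shift of the latent marker per
#'   region (default all zero, i.e. identical distributions).
#' @param independent_regions draw a fresh latent marker per
#'   patient x region instead of sharing the patient latent (default
#'   `FALSE`, the repeated-measures structure of a TMA; set `TRUE` for
#'   independent groups, e.g. null calibration of across-region tests).
#' @param marker name of the marker column value (default `"Iba1"`).
#' @param admin_cap administrative censoring time (months).
#' @param seed RNG seed.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 241L,
                        marker_distribution = list(family = "beta",
                                                   shape1 = 2, shape2 = 5,
                                                   scale = 100),
                        log_hazard_ratio_high_vs_low = 0,
                        baseline_hazard = log(2) / 15,
                        censoring_rate = 0.2,
                        cores_per_patient = 3L,
                        core_noise_sd = 5,
                        hazard_cutpoint = NULL,
                        regions = "T",
                        region_shift = NULL,
                        independent_regions = FALSE,
                        marker = "Iba1",
                        admin_cap = 240,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               marker_distribution = marker_distribution,
               log_hazard_ratio_high_vs_low = log_hazard_ratio_high_vs_low,
               baseline_hazard = baseline_hazard,
               censoring_rate = censoring_rate,
               cores_per_patient = as.integer(cores_per_patient),
               core_noise_sd = core_noise_sd,
               hazard_cutpoint = hazard_cutpoint,
               regions = regions,
               region_shift = region_shift,
               independent_regions = isTRUE(independent_regions),
               marker = marker,
               admin_cap = admin_cap,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot_scalar(spec$n_patients, "n_patients", lo = 2)
  stopifnot_scalar(spec$log_hazard_ratio_high_vs_low,
                   "log_hazard_ratio_high_vs_low")
  stopifnot_scalar(spec$baseline_hazard, "baseline_hazard", lo = 1e-12)
  stopifnot_scalar(spec$censoring_rate, "censoring_rate", 0, 0.95)
  stopifnot_scalar(spec$cores_per_patient, "cores_per_patient", 1, 3)
  stopifnot_scalar(spec$core_noise_sd, "core_noise_sd", lo = 0)
  if (!is.null(spec$hazard_cutpoint)) {
    stopifnot_scalar(spec$hazard_cutpoint, "hazard_cutpoint", 0, 100)
  }
  if (!all(spec$regions %in% c("T", "IZ", "NAB"))) {
    stop("regions must be a subset of c('T', 'IZ', 'NAB')", call. = FALSE)
  }
  md <- spec$marker_distribution
  if (!identical(md$family, "beta")) {
    stop("marker_distribution$family must be 'beta'", call. = FALSE)
  }
  invisible(spec)
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `cohort_table`, one row per
#'   patient x region x core: `patient_id`, `core_index`, `region`,
#'   `marker`, `percent_positive`, `necrosis_fraction`,
#'   `survival_months`, `event`, `group`.  The attribute `truth` stores
#'   the latent markers, arm assignment and cutpoint used for the
#'   hazard.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 20, seed = 2))
#' head(coh)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_patients
    md <- spec$marker_distribution
    latent <- stats::rbeta(n, md$shape1, md$shape2) * md$scale

    regions <- spec$regions
    shift <- spec$region_shift %||%
      stats::setNames(numeric(length(regions)), regions)
    k <- spec$cores_per_patient
    grid <- expand.grid(core_index = seq_len(k), region = regions,
                        patient_id = seq_len(n),
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$patient_id, grid$region, grid$core_index), ]
    m <- nrow(grid)
    base <- if (spec$independent_regions && length(regions) > 1L) {
      # fresh latent per patient x region (independent groups, e.g. for
      # null calibration of across-region tests)
      idx <- match(paste(grid$patient_id, grid$region),
                   unique(paste(grid$patient_id, grid$region)))
      lat2 <- stats::rbeta(max(idx), md$shape1, md$shape2) * md$scale
      lat2[idx]
    } else {
      latent[grid$patient_id]
    }
    pp <- unname(base + shift[grid$region] +
                   stats::rnorm(m, 0, spec$core_noise_sd))
    pp <- pmin(pmax(pp, 0), 100)

    # the planted hazard acts on the recorded first-core marker of the
    # first region -- the variable the analysis dichotomizes
    first_row <- match(seq_len(n),
                       ifelse(grid$core_index == 1L &
                                grid$region == regions[1L],
                              grid$patient_id, NA_integer_))
    marker_val <- unname(pp[first_row])
    cut <- spec$hazard_cutpoint %||% stats::median(marker_val)
    high <- marker_val > cut
    rate <- spec$baseline_hazard *
      exp(spec$log_hazard_ratio_high_vs_low * high)
    t_event <- stats::rexp(n, rate)
    if (spec$censoring_rate == 0) {
      t_cens <- rep(Inf, n)
    } else {
      rc <- spec$baseline_hazard *
        spec$censoring_rate / (1 - spec$censoring_rate)
      t_cens <- pmin(stats::rexp(n, rc), spec$admin_cap)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    out <- data.frame(patient_id = grid$patient_id,
                      core_index = grid$core_index,
                      region = grid$region,
                      marker = spec$marker,
                      percent_positive = pp,
                      necrosis_fraction = stats::rbeta(m, 1, 12),
                      survival_months = time[grid$patient_id],
                      event = event[grid$patient_id],
                      group = "GBM_IDHwt",
                      row.names = NULL)
    attr(out, "truth") <- list(latent = latent, marker = marker_val,
                               high = high, cutpoint = cut, spec = spec)
    class(out) <- c("cohort_table", class(out))
    out
  })
}
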