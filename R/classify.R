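#' Risk-class labels in increasing order of severity
#'
#' @return Character vector `c("low", "medium", "high", "very_high")`.
#' @export
risk_levels <- function() c("low", "medium", "high", "very_high")

# Gestational-age switch for the ratio cutoffs: 34+0 weeks in completed days
GA_34W_DAYS <- 238L
GA_37W_DAYS <- 259L

#' sFlt-1/PlGF ratio cutoffs at a given gestational age
#'
#' The four-class stratification uses `low < 38` at every gestational age,
#' while the upper and extreme cutoffs switch at 34+0 weeks (238 completed
#' days): (85, 655) before, (110, 201) at or after.
#'
#' @param ga_days Gestational age in completed days (integer vector).
#' @return A tibble with columns `lower` (38), `upper` (85 or 110) and
#'   `extreme` (655 or 201), one row per element of `ga_days`.
#' @export
ratio_cutoffs <- function(ga_days) {
  late <- ga_days >= GA_34W_DAYS
  tibble::tibble(
    lower = rep(38, length(ga_days)),
    upper = ifelse(late, 110, 85),
    extreme = ifelse(late, 201, 655)
  )
}

#' Classify an sFlt-1/PlGF ratio into the four risk classes
#'
#' Partition of the positive ratio axis at fixed gestational age:
#' `low` if ratio < 38; `medium` if 38 <= ratio <= upper cutoff;
#' `high` if upper < ratio <= extreme cutoff; `very_high` if ratio >
#' extreme. Cutoff values follow [ratio_cutoffs()]: (upper, extreme) =
#' (85, 655) before 34+0 weeks and (110, 201) at or after. The boundary
#' values 38 and the upper cutoff belong to `medium`; the extreme cutoff
#' belongs to `high` (strict inequalities for `high` and `very_high`).
#' Classification always uses the raw, unrounded ratio.
#'
#' @param ratio Positive numeric vector, raw sFlt-1/PlGF ratio.
#' @param ga_days Gestational age at dosage in completed days, recycled
#'   against `ratio`; must be >= 140 (20 weeks).
#' @return An ordered factor with levels [risk_levels()].
#' @examples
#' classify_ratio(726.88, ga_days = 34 * 7 + 4)  # very_high
#' classify_ratio(100, ga_days = c(237, 238))    # high, medium
#' @export
classify_ratio <- function(ratio, ga_days) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("invalid ratio: must be positive and finite", call. = FALSE)
  }
  if (any(ga_days < 140)) {
    stop("ga_days must be >= 140 (dosages from 20 weeks of gestation)",
         call. = FALSE)
  }
  n <- max(length(ratio), length(ga_days))
  ratio <- rep_len(ratio, n)
  cuts <- ratio_cutoffs(rep_len(ga_days, n))
  label <- ifelse(ratio < cuts$lower, "low",
           ifelse(ratio <= cuts$upper, "medium",
           ifelse(ratio <= cuts$extreme, "high", "very_high")))
  factor(label, levels = risk_levels(), ordered = TRUE)
}

#' Append a risk-class column to a cohort table
#'
#' Adds `risk_class` from the raw ratio and gestational age. If the cohort
#' has no `ratio` column yet, Mtp columns are computed first via
#' [compute_mtp()].
#'
#' @inheritParams compute_mtp
#' @return The cohort tibble with a `risk_class` ordered-factor column.
#' @export
classify_cohort <- function(cohort, ref = default_reference()) {
  cohort <- tibble::as_tibble(cohort)
  if (!"ratio" %in% names(cohort)) {
    cohort <- compute_mtp(cohort, ref)
  }
  if (!"ga_days" %in% names(cohort)) {
    stop("cohort is missing column 'ga_days'", call. = FALSE)
  }
  cohort$risk_class <- classify_ratio(cohort$ratio, cohort$ga_days)
  cohort
}
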