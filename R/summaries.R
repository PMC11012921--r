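#' Gestational-age strata used throughout the summary tables
#'
#' All dosages; dosages before 37+0 weeks (< 259 completed days); dosages
#' before 34+0 weeks (< 238 days). The strata are nested.
#'
#' @return Character vector `c("all", "lt37w", "lt34w")`.
#' @export
ga_strata <- function() c("all", "lt37w", "lt34w")

stratum_mask <- function(stratum, ga_days) {
  switch(stratum,
    all = rep(TRUE, length(ga_days)),
    lt37w = ga_days < GA_37W_DAYS,
    lt34w = ga_days < GA_34W_DAYS,
    stop("unknown stratum: ", stratum, call. = FALSE)
  )
}

# Median and IQR of time-to-delivery plus n/% bookkeeping for one group.
# quantile_type follows stats::quantile; the default (7) interpolates
# linearly between order statistics.
summary_row <- function(times, stratum_total, quantile_type) {
  n <- length(times)
  if (n == 0) {
    return(tibble::tibble(n = 0L, pct = 0,
                          median_days = NA_real_,
                          iqr_lower = NA_real_, iqr_upper = NA_real_))
  }
  q <- stats::quantile(times, probs = c(0.25, 0.5, 0.75),
                       type = quantile_type, names = FALSE)
  tibble::tibble(
    n = n,
    pct = round_display(100 * n / stratum_total, 0),
    median_days = q[2],
    iqr_lower = q[1],
    iqr_upper = q[3]
  )
}

require_cohort_columns <- function(cohort, cols) {
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Time-to-delivery summary by sFlt-1/PlGF risk class
#'
#' For each gestational-age stratum (all dosages, before 37 weeks, before
#' 34 weeks) and each of the four risk classes, tabulates the number of
#' dosages, its percentage of the stratum total, and the median and IQR of
#' days from dosage to delivery. The unit of analysis is the dosage, not
#' the patient; risk classes partition each stratum, so class counts sum
#' to the stratum total.
#'
#' @inheritParams compute_mtp
#' @param quantile_type Quantile algorithm passed to [stats::quantile()];
#'   the default 7 interpolates linearly between order statistics.
#' @return A tibble with one row per (stratum, risk class): columns
#'   `stratum`, `group`, `n`, `pct` (integer, half-away-from-zero),
#'   `median_days`, `iqr_lower`, `iqr_upper`. Empty groups have `n = 0`
#'   and `NA` summaries.
#' @export
summarize_by_risk_class <- function(cohort, ref = default_reference(),
                                    quantile_type = 7) {
  cohort <- classify_cohort(cohort, ref)
  require_cohort_columns(cohort, c("ga_days", "time_to_delivery_days"))
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  out <- list()
  for (stratum in ga_strata()) {
    sub <- cohort[stratum_mask(stratum, cohort$ga_days), ]
    total <- nrow(sub)
    for (class in risk_levels()) {
      times <- sub$time_to_delivery_days[sub$risk_class == class]
      row <- summary_row(times, total, quantile_type)
      out[[length(out) + 1]] <- tibble::tibble(
        stratum = stratum, group = class, row
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Time-to-delivery summary by Mtp category
#'
#' As [summarize_by_risk_class()], but grouping by the 19 Mtp categories.
#' One dosage may belong to several categories (or none), so category
#' counts do not sum to the stratum total; percentages are still taken
#' against the stratum total.
#'
#' @inheritParams summarize_by_risk_class
#' @return A tibble with one row per (stratum, category): columns
#'   `stratum`, `group` (canonical category id), `display`, `n`, `pct`,
#'   `median_days`, `iqr_lower`, `iqr_upper`.
#' @export
summarize_by_category <- function(cohort, ref = default_reference(),
                                  quantile_type = 7) {
  cohort <- categorize_cohort(cohort, ref)
  require_cohort_columns(cohort, c("ga_days", "time_to_delivery_days"))
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  registry <- category_registry()
  out <- list()
  for (stratum in ga_strata()) {
    sub <- cohort[stratum_mask(stratum, cohort$ga_days), ]
    total <- nrow(sub)
    for (i in seq_len(nrow(registry))) {
      times <- sub$time_to_delivery_days[sub[[registry$id[i]]]]
      row <- summary_row(times, total, quantile_type)
      out[[length(out) + 1]] <- tibble::tibble(
        stratum = stratum, group = registry$id[i],
        display = registry$display[i], row
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Cross-tabulate Mtp categories against risk classes
#'
#' For each Mtp category, counts how its member dosages distribute over
#' the four sFlt-1/PlGF risk classes, with row percentages (of the
#' category count, rounded to integers half away from zero). Risk classes
#' partition each category's members, so the four counts sum to `n`.
#'
#' @inheritParams compute_mtp
#' @return A tidy tibble with one row per (category, risk class): columns
#'   `group` (category id), `display`, `n` (category total), `risk_class`,
#'   `count`, `pct`.
#' @export
crosstab_categories_by_class <- function(cohort, ref = default_reference()) {
  cohort <- categorize_cohort(classify_cohort(cohort, ref), ref)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  registry <- category_registry()
  out <- list()
  for (i in seq_len(nrow(registry))) {
    members <- cohort[cohort[[registry$id[i]]], ]
    n <- nrow(members)
    counts <- unname(vapply(risk_levels(),
                            function(cl) sum(members$risk_class == cl),
                            integer(1)))
    pct <- if (n > 0) round_display(100 * counts / n, 0) else rep(0, 4)
    out[[length(out) + 1]] <- tibble::tibble(
      group = registry$id[i],
      display = registry$display[i],
      n = n,
      risk_class = risk_levels(),
      count = counts,
      pct = pct
    )
  }
  dplyr::bind_rows(out)
}
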