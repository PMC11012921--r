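# Brute-force order-statistic quantile (linear interpolation between order
# statistics), coded from the definition, independent of stats::quantile.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# Random marker concentrations spanning all category thresholds
random_marker_table <- function(n) {
  tibble::tibble(
    plgf = exp(stats::runif(n, log(5), log(500))),
    sflt1 = exp(stats::runif(n, log(1000), log(40000)))
  )
}

# A one-class toy cohort: fixed low-ratio markers, arbitrary times
low_ratio_cohort <- function(times) {
  tibble::tibble(
    patient_id = sprintf("P%02d", seq_along(times)),
    ga_days = 230L,
    plgf = 200,
    sflt1 = 2000,
    time_to_delivery_days = as.integer(times)
  )
}

worked_example <- function() {
  tibble::tibble(
    patient_id = "EX1",
    ga_days = 34L * 7L + 4L,
    plgf = 24.48,
    sflt1 = 17794,
    time_to_delivery_days = 2L
  )
}
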