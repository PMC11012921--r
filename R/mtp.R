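#' Round half away from zero for display
#'
#' Decimal rounding in which a half is always rounded away from zero
#' (0.45 -> 0.5 at one decimal), the convention matching the printed Mtp
#' values, as opposed to R's `round()` which rounds half to even. Raw
#' (unrounded) values are what every classification and category decision
#' uses; this rounding exists only for display and reporting.
#'
#' @param x Numeric vector.
#' @param places Non-negative integer: decimals to keep. Mtp values are
#'   displayed with 1, the sFlt-1/PlGF ratio with 2, percentages with 0.
#' @return `x` rounded to `places` decimals, halves away from zero.
#' @examples
#' round_display(24.48 / 54.4, 1)   # 0.5, not 0.4
#' round_display(17794 / 24.48, 2)  # 726.88
#' @export
round_display <- function(x, places = 1) {
  stopifnot(length(places) == 1, places >= 0, places == as.integer(places))
  scale <- 10^places
  trunc(abs(x) * scale + 0.5) * sign(x) / scale
}

#' Mtp profile of a single measurement
#'
#' The Mtp ("Multiples of a normal term placenta") score of a marker
#' concentration is that concentration divided by a term-pregnancy
#' reference centile: how many multiples of the normal term value the
#' measurement represents. One measurement yields six Mtp values (PlGF
#' against its 2.5th/5th/10th centiles, sFlt-1 against its
#' 90th/95th/97.5th) plus the sFlt-1/PlGF ratio.
#'
#' @param plgf,sflt1 Serum concentrations in pg/mL, strictly positive
#'   scalars.
#' @param ref Reference table, see [default_reference()].
#' @return An object of class `mtp_profile`: a list with named numeric
#'   vectors `mtp_plgf`, `mtp_sflt1` (raw, unrounded), scalar `ratio`, and
#'   a `display` list holding the rounded twins (Mtp to 1 decimal, ratio
#'   to 2).
#' @examples
#' p <- mtp_profile(plgf = 24.48, sflt1 = 17794)
#' p$display$mtp_sflt1[["90"]]  # 2.3
#' p$display$ratio              # 726.88
#' @export
mtp_profile <- function(plgf, sflt1, ref = default_reference()) {
  ref <- validate_reference(ref)
  if (!is.finite(plgf) || !is.finite(sflt1) || plgf <= 0 || sflt1 <= 0) {
    stop("invalid concentration: plgf and sflt1 must be positive and finite",
         call. = FALSE)
  }
  mtp_plgf <- plgf / ref$plgf
  mtp_sflt1 <- sflt1 / ref$sflt1
  structure(
    list(
      mtp_plgf = mtp_plgf,
      mtp_sflt1 = mtp_sflt1,
      ratio = sflt1 / plgf,
      display = list(
        mtp_plgf = round_display(mtp_plgf, 1),
        mtp_sflt1 = round_display(mtp_sflt1, 1),
        ratio = round_display(sflt1 / plgf, 2)
      )
    ),
    class = "mtp_profile"
  )
}

#' @export
print.mtp_profile <- function(x, ...) {
  d <- x$display
  cat("Mtp profile (displayed to 1 decimal; classification uses raw values)\n")
  cat(sprintf("  Mtp PlGF   %sth c: %s\n", names(d$mtp_plgf),
              format(d$mtp_plgf, nsmall = 1)), sep = "")
  cat(sprintf("  Mtp sFlt-1 %sth c: %s\n", names(d$mtp_sflt1),
              format(d$mtp_sflt1, nsmall = 1)), sep = "")
  cat(sprintf("  sFlt-1/PlGF ratio: %s\n", format(d$ratio, nsmall = 2)))
  invisible(x)
}

#' Columns added by [compute_mtp()]
#' @keywords internal
mtp_column_names <- function() {
  c(paste0("mtp_plgf_", PLGF_CENTILES),
    paste0("mtp_sflt1_", SFLT1_CENTILES),
    "ratio")
}

#' Compute Mtp scores and the sFlt-1/PlGF ratio for a cohort
#'
#' Appends, for each dosage row, the six raw Mtp values and the raw
#' sFlt-1/PlGF ratio, plus display-rounded twins (`*_display`; Mtp to one
#' decimal, ratio to two, half away from zero). All downstream
#' classification and category membership operates on the raw columns.
#'
#' @param cohort Data frame with at least numeric columns `plgf` and
#'   `sflt1` (serum pg/mL), as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param ref Reference table, see [default_reference()].
#' @return The input as a tibble with columns `mtp_plgf_2.5`, `mtp_plgf_5`,
#'   `mtp_plgf_10`, `mtp_sflt1_90`, `mtp_sflt1_95`, `mtp_sflt1_97.5`,
#'   `ratio` and their `*_display` twins appended.
#' @examples
#' compute_mtp(tibble::tibble(plgf = 24.48, sflt1 = 17794))
#' @export
compute_mtp <- function(cohort, ref = default_reference()) {
  ref <- validate_reference(ref)
  cohort <- tibble::as_tibble(cohort)
  for (col in c("plgf", "sflt1")) {
    if (!col %in% names(cohort)) {
      stop("cohort is missing column '", col, "'", call. = FALSE)
    }
    v <- cohort[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("invalid concentration: '", col,
           "' must be positive and finite", call. = FALSE)
    }
  }
  out <- cohort
  for (centile in PLGF_CENTILES) {
    out[[paste0("mtp_plgf_", centile)]] <- cohort$plgf / ref$plgf[[centile]]
  }
  for (centile in SFLT1_CENTILES) {
    out[[paste0("mtp_sflt1_", centile)]] <- cohort$sflt1 / ref$sflt1[[centile]]
  }
  out$ratio <- cohort$sflt1 / cohort$plgf
  for (col in setdiff(mtp_column_names(), "ratio")) {
    out[[paste0(col, "_display")]] <- round_display(out[[col]], 1)
  }
  out$ratio_display <- round_display(out$ratio, 2)
  out
}
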