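COHORT_FILE_COLUMNS <- c("patient_id", "ga_weeks", "ga_days",
                         "plgf_pg_ml", "sflt1_pg_ml",
                         "time_to_delivery_days")

#' Read a per-dosage cohort CSV
#'
#' Expects a header with columns `patient_id`, `ga_weeks`, `ga_days`
#' (the weeks+days split of gestational age at dosage), `plgf_pg_ml`,
#' `sflt1_pg_ml`, and `time_to_delivery_days`. Gestational age is
#' combined into completed days (`ga_weeks * 7 + ga_days`). Rows are
#' validated (positive finite concentrations, gestational age of at least
#' 140 days / 20 weeks, non-negative time to delivery) and errors cite
#' the offending data row.
#'
#' @param path Path to a CSV file, UTF-8, `.` decimal mark by default.
#' @param decimal_comma If `TRUE`, parse with `,` as the decimal mark and
#'   `;` as the field separator (common in European exports). Never
#'   auto-detected.
#' @return A tibble with columns `patient_id` (character), `ga_days`
#'   (integer, completed days), `plgf`, `sflt1` (pg/mL),
#'   `time_to_delivery_days` (integer).
#' @export
read_cohort <- function(path, decimal_comma = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (decimal_comma) readr::read_csv2 else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_guess()),
                progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(COHORT_FILE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(patient_id = character(0), ga_days = integer(0),
                          plgf = numeric(0), sflt1 = numeric(0),
                          time_to_delivery_days = integer(0)))
  }
  numeric_cols <- setdiff(COHORT_FILE_COLUMNS, "patient_id")
  for (col in numeric_cols) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))) |
                     is.na(raw[[col]]))
      stop("row-level validation error (row ",
           paste(utils::head(bad, 5), collapse = ", "),
           "): non-numeric value in '", col, "'", call. = FALSE)
    }
  }
  ga_total <- as.integer(raw$ga_weeks * 7 + raw$ga_days)
  problems <- character(0)
  flag <- function(mask, what) {
    rows <- which(mask)
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(what, " (row ",
                                      paste(utils::head(rows, 5),
                                            collapse = ", "), ")"))
    }
  }
  flag(is.na(raw$plgf_pg_ml) | raw$plgf_pg_ml <= 0,
       "non-positive PlGF concentration")
  flag(is.na(raw$sflt1_pg_ml) | raw$sflt1_pg_ml <= 0,
       "non-positive sFlt-1 concentration")
  flag(is.na(raw$ga_days) | raw$ga_days < 0 | raw$ga_days > 6,
       "ga_days component must be 0-6")
  flag(is.na(ga_total) | ga_total < 140, "gestational age below 140 days")
  flag(is.na(raw$time_to_delivery_days) | raw$time_to_delivery_days < 0,
       "negative time to delivery")
  if (length(problems) > 0) {
    stop("row-level validation error: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  tibble::tibble(
    patient_id = as.character(raw$patient_id),
    ga_days = ga_total,
    plgf = as.numeric(raw$plgf_pg_ml),
    sflt1 = as.numeric(raw$sflt1_pg_ml),
    time_to_delivery_days = as.integer(raw$time_to_delivery_days)
  )
}

#' Write a cohort back to the pipeline CSV schema
#'
#' Inverse of [read_cohort()]: splits `ga_days` into the weeks+days pair
#' and writes the canonical header. Any extra columns (Mtp scores, risk
#' class, category flags) are appended after the canonical ones.
#'
#' @param cohort Tibble with the columns returned by [read_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  require_cohort_columns(cohort, c("patient_id", "ga_days", "plgf", "sflt1",
                                   "time_to_delivery_days"))
  out <- tibble::tibble(
    patient_id = cohort$patient_id,
    ga_weeks = cohort$ga_days %/% 7L,
    ga_days = cohort$ga_days %% 7L,
    plgf_pg_ml = cohort$plgf,
    sflt1_pg_ml = cohort$sflt1,
    time_to_delivery_days = cohort$time_to_delivery_days
  )
  extra <- setdiff(names(cohort),
                   c("patient_id", "ga_days", "plgf", "sflt1",
                     "time_to_delivery_days"))
  for (col in extra) out[[col]] <- cohort[[col]]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
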