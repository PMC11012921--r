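run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full Mtp analysis pipeline
#'
#' Reads a cohort CSV, computes Mtp scores and the sFlt-1/PlGF ratio,
#' classifies the ratio into risk classes, evaluates Mtp category
#' memberships, and writes the stratified summary tables and the
#' category-by-class cross-tabulation, plus a JSON run manifest. With the
#' same input and options the output files are bit-identical across runs.
#'
#' Output files in `output_dir`:
#' \describe{
#'   \item{mtp.csv}{input rows plus raw and display Mtp/ratio columns}
#'   \item{classified.csv}{as above plus `risk_class`}
#'   \item{categorized.csv}{as above plus one logical column per category}
#'   \item{summary_by_class.csv}{[summarize_by_risk_class()] output}
#'   \item{summary_by_category.csv}{[summarize_by_category()] output}
#'   \item{crosstab.csv}{[crosstab_categories_by_class()] output}
#'   \item{manifest.json}{package version, option hash, cohort sizes,
#'     reference values, per-stratum and per-class dosage counts}
#' }
#'
#' @param input Path to a cohort CSV (see [read_cohort()]) or a cohort
#'   data frame.
#' @param output_dir Directory for outputs; created if absent.
#' @param reference `NULL` for [default_reference()], a path to a
#'   YAML/JSON override (see [read_reference()]), or an `mtp_reference`.
#' @param quantile_type Passed to the summary operations.
#' @param decimal_comma Passed to [read_cohort()] when `input` is a path.
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_pipeline <- function(input, output_dir, reference = NULL,
                         quantile_type = 7, decimal_comma = FALSE) {
  ref <- run_stage("reference", {
    if (is.null(reference)) {
      default_reference()
    } else if (is.character(reference)) {
      read_reference(reference)
    } else {
      validate_reference(reference)
    }
  })
  cohort <- run_stage("read", {
    if (is.character(input)) {
      read_cohort(input, decimal_comma = decimal_comma)
    } else {
      tibble::as_tibble(input)
    }
  })
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)

  with_mtp <- run_stage("compute", compute_mtp(cohort, ref))
  classified <- run_stage("classify", classify_cohort(with_mtp, ref))
  categorized <- run_stage("categorize", categorize_cohort(classified, ref))
  by_class <- run_stage("summarize",
                        summarize_by_risk_class(classified, ref,
                                                quantile_type = quantile_type))
  by_category <- run_stage("summarize",
                           summarize_by_category(categorized, ref,
                                                 quantile_type = quantile_type))
  crosstab <- run_stage("crosstab",
                        crosstab_categories_by_class(categorized, ref))

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mtp = file.path(output_dir, "mtp.csv"),
    classified = file.path(output_dir, "classified.csv"),
    categorized = file.path(output_dir, "categorized.csv"),
    summary_by_class = file.path(output_dir, "summary_by_class.csv"),
    summary_by_category = file.path(output_dir, "summary_by_category.csv"),
    crosstab = file.path(output_dir, "crosstab.csv"),
    manifest = file.path(output_dir, "manifest.json")
  )
  run_stage("write", {
    write_cohort(with_mtp, paths[["mtp"]])
    write_cohort(classified, paths[["classified"]])
    write_cohort(categorized, paths[["categorized"]])
    readr::write_csv(by_class, paths[["summary_by_class"]], progress = FALSE)
    readr::write_csv(by_category, paths[["summary_by_category"]],
                     progress = FALSE)
    readr::write_csv(crosstab, paths[["crosstab"]], progress = FALSE)
    manifest <- list(
      package = "mtplacenta",
      version = as.character(utils::packageVersion("mtplacenta")),
      options_hash = rlang::hash(list(ref, quantile_type)),
      n_dosages = nrow(cohort),
      n_patients = length(unique(cohort$patient_id)),
      n_per_stratum = vapply(ga_strata(), function(st) {
        sum(stratum_mask(st, cohort$ga_days))
      }, integer(1)),
      n_per_risk_class = as.list(table(classified$risk_class)),
      reference = list(sflt1 = as.list(ref$sflt1), plgf = as.list(ref$plgf)),
      quantile_type = quantile_type
    )
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })
  invisible(paths)
}
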