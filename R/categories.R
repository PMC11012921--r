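op_fun <- function(op) {
  switch(op,
    le = `<=`, lt = `<`, ge = `>=`, gt = `>`,
    stop("unknown comparator: ", op, call. = FALSE)
  )
}

op_symbol <- function(op) {
  switch(op, le = "\u2264", lt = "<", ge = "\u2265", gt = ">")
}

clause <- function(marker, centile, op, thr) {
  list(marker = marker, centile = centile, op = op, thr = thr)
}

clause_display <- function(cl, with_prefix = TRUE) {
  marker_name <- if (cl$marker == "plgf") "PlGF" else "sFlt-1"
  sprintf("%s%s %sth c %s %s", if (with_prefix) "Mtp " else "",
          marker_name, cl$centile, op_symbol(cl$op), format(cl$thr))
}

clause_id <- function(cl) {
  sprintf("%s_%sc_%s_%s", cl$marker, cl$centile, cl$op, format(cl$thr))
}

make_category <- function(...) {
  clauses <- list(...)
  id <- paste(vapply(clauses, clause_id, character(1)), collapse = "_and_")
  display <- paste(
    vapply(seq_along(clauses),
           function(i) clause_display(clauses[[i]], with_prefix = TRUE),
           character(1)),
    collapse = " and "
  )
  tibble::tibble(id = id, display = display, n_clauses = length(clauses),
                 clauses = list(clauses))
}

#' Registry of the 19 Mtp categories
#'
#' The named thresholds on individual Mtp values whose time-to-delivery
#' profile the analysis reports: four PlGF 10th-centile categories
#' (<= 0.5, < 1, >= 2, >= 3), two each for PlGF 5th and 2.5th (<= 0.5,
#' <= 1), four sFlt-1 90th-centile categories (<= 0.5, > 1, >= 2, >= 3),
#' two each for sFlt-1 95th and 97.5th (>= 1, >= 2), and three combined
#' categories pairing a PlGF clause with an sFlt-1 clause at matched
#' centiles (10th/90th, 5th/95th, 2.5th/97.5th). The comparator set is
#' deliberately asymmetric between the two markers (no "< 1" for sFlt-1,
#' no "> 1" for PlGF) and the categories are not a partition: one
#' measurement may satisfy several, or none.
#'
#' @return A tibble with one row per category: `id` (canonical ASCII
#'   label, e.g. `"plgf_10c_le_0.5"`), `display` (typeset name, e.g.
#'   `"Mtp PlGF 10th c \u2264 0.5"`), `n_clauses` (1 or 2) and `clauses`
#'   (list-column; each clause has `marker`, `centile`, `op` in
#'   le/lt/ge/gt, `thr`).
#' @export
category_registry <- function() {
  dplyr::bind_rows(
    make_category(clause("plgf", "10", "le", 0.5)),
    make_category(clause("plgf", "10", "lt", 1)),
    make_category(clause("plgf", "10", "ge", 2)),
    make_category(clause("plgf", "10", "ge", 3)),
    make_category(clause("plgf", "5", "le", 0.5)),
    make_category(clause("plgf", "5", "le", 1)),
    make_category(clause("plgf", "2.5", "le", 0.5)),
    make_category(clause("plgf", "2.5", "le", 1)),
    make_category(clause("sflt1", "90", "le", 0.5)),
    make_category(clause("sflt1", "90", "gt", 1)),
    make_category(clause("sflt1", "90", "ge", 2)),
    make_category(clause("sflt1", "90", "ge", 3)),
    make_category(clause("sflt1", "95", "ge", 1)),
    make_category(clause("sflt1", "95", "ge", 2)),
    make_category(clause("sflt1", "97.5", "ge", 1)),
    make_category(clause("sflt1", "97.5", "ge", 2)),
    make_category(clause("plgf", "10", "lt", 1), clause("sflt1", "90", "gt", 1)),
    make_category(clause("plgf", "5", "le", 1), clause("sflt1", "95", "ge", 1)),
    make_category(clause("plgf", "2.5", "le", 1), clause("sflt1", "97.5", "ge", 1))
  )
}

eval_clause_on_columns <- function(cl, cohort) {
  col <- paste0("mtp_", cl$marker, "_", cl$centile)
  if (!col %in% names(cohort)) {
    stop("cohort is missing Mtp column '", col,
         "'; run compute_mtp() first", call. = FALSE)
  }
  op_fun(cl$op)(cohort[[col]], cl$thr)
}

#' Append one logical membership column per Mtp category
#'
#' Evaluates every category of [category_registry()] on the raw Mtp
#' columns (exact threshold comparisons, no tolerance) and appends one
#' logical column per category, named by its canonical `id`. Mtp columns
#' are computed first if absent.
#'
#' @inheritParams compute_mtp
#' @return The cohort tibble with 19 logical columns appended.
#' @export
categorize_cohort <- function(cohort, ref = default_reference()) {
  cohort <- tibble::as_tibble(cohort)
  if (!"mtp_plgf_10" %in% names(cohort)) {
    cohort <- compute_mtp(cohort, ref)
  }
  registry <- category_registry()
  for (i in seq_len(nrow(registry))) {
    hits <- Reduce(`&`, lapply(registry$clauses[[i]], eval_clause_on_columns,
                               cohort = cohort))
    cohort[[registry$id[i]]] <- hits
  }
  cohort
}

#' Category memberships of a single Mtp profile
#'
#' @param profile An `mtp_profile` from [mtp_profile()].
#' @param registry Category registry, see [category_registry()].
#' @return Character vector of canonical category ids the profile belongs
#'   to (possibly empty; categories are not mutually exclusive).
#' @examples
#' memberships(mtp_profile(plgf = 24.48, sflt1 = 17794))
#' @export
memberships <- function(profile, registry = category_registry()) {
  stopifnot(inherits(profile, "mtp_profile"))
  value_of <- function(cl) {
    if (cl$marker == "plgf") profile$mtp_plgf[[cl$centile]]
    else profile$mtp_sflt1[[cl$centile]]
  }
  hit <- vapply(registry$clauses, function(clauses) {
    all(vapply(clauses,
               function(cl) op_fun(cl$op)(value_of(cl), cl$thr),
               logical(1)))
  }, logical(1))
  registry$id[hit]
}
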