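#' @keywords internal
PLGF_CENTILES <- c("2.5", "5", "10")

#' @keywords internal
SFLT1_CENTILES <- c("90", "95", "97.5")

new_reference <- function(sflt1, plgf) {
  structure(list(sflt1 = sflt1, plgf = plgf), class = "mtp_reference")
}

#' Term-pregnancy reference centiles for sFlt-1 and PlGF
#'
#' Serum concentrations (pg/mL) observed in uncomplicated pregnancies at
#' term (>= 37 weeks), used as the denominator of every Mtp score. The
#' defaults are the upper centiles of sFlt-1 (90th, 95th, 97.5th) and the
#' lower centiles of PlGF (2.5th, 5th, 10th), the tails that placental
#' dysfunction pushes a measurement towards.
#'
#' @return An object of class `mtp_reference`: a list with named numeric
#'   vectors `sflt1` (names "90", "95", "97.5") and `plgf` (names "2.5",
#'   "5", "10"), concentrations in pg/mL.
#' @examples
#' ref <- default_reference()
#' ref$sflt1[["90"]]   # 7901 pg/mL
#' ref$plgf[["2.5"]]   # 48.9 pg/mL
#' @export
default_reference <- function() {
  new_reference(
    sflt1 = c("90" = 7901, "95" = 9184, "97.5" = 11471),
    plgf  = c("2.5" = 48.9, "5" = 54.4, "10" = 68.6)
  )
}

#' Validate a reference centile table
#'
#' Checks that a reference table carries exactly the six required centile
#' labels, that every concentration is strictly positive, and that values
#' increase strictly with the centile label for each marker. Mtp categories
#' are defined only for these six centiles, so replacement tables (e.g. for
#' a different assay platform) must supply all of them.
#'
#' @param ref An `mtp_reference` or a list with `sflt1` and `plgf` named
#'   numeric vectors.
#' @return The validated `mtp_reference`, unchanged.
#' @examples
#' validate_reference(default_reference())
#' @export
validate_reference <- function(ref) {
  if (!is.list(ref) || !all(c("sflt1", "plgf") %in% names(ref))) {
    stop("reference must contain 'sflt1' and 'plgf' centile vectors",
         call. = FALSE)
  }
  sflt1 <- ref$sflt1
  plgf <- ref$plgf
  if (!setequal(names(sflt1), SFLT1_CENTILES) ||
      !setequal(names(plgf), PLGF_CENTILES)) {
    stop("reference centile labels must be exactly {90, 95, 97.5} for ",
         "sFlt-1 and {2.5, 5, 10} for PlGF", call. = FALSE)
  }
  sflt1 <- sflt1[SFLT1_CENTILES]
  plgf <- plgf[PLGF_CENTILES]
  if (any(!is.finite(sflt1)) || any(!is.finite(plgf)) ||
      any(sflt1 <= 0) || any(plgf <= 0)) {
    stop("invalid concentration: reference values must be positive and finite",
         call. = FALSE)
  }
  if (any(diff(sflt1) <= 0) || any(diff(plgf) <= 0)) {
    stop("non-monotone centiles: reference values must increase strictly ",
         "with the centile label", call. = FALSE)
  }
  new_reference(sflt1 = sflt1, plgf = plgf)
}

#' Read a reference table override from a YAML or JSON file
#'
#' The file may override any subset of the six reference concentrations;
#' unspecified values fall back to [default_reference()]. Schema:
#'
#' ```yaml
#' sflt1:
#'   "90": 7901
#'   "95": 9184
#'   "97.5": 11471
#' plgf:
#'   "2.5": 48.9
#'   "5": 54.4
#'   "10": 68.6
#' ```
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @param base Reference table supplying unspecified values.
#' @return A validated `mtp_reference`.
#' @export
read_reference <- function(path, base = default_reference()) {
  raw <- yaml::read_yaml(path)
  ref <- validate_reference(base)
  for (marker in c("sflt1", "plgf")) {
    if (is.null(raw[[marker]])) next
    vals <- raw[[marker]]
    bad <- setdiff(names(vals), names(ref[[marker]]))
    if (length(bad) > 0) {
      stop("unknown ", marker, " centile label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (centile in names(vals)) {
      ref[[marker]][[centile]] <- as.numeric(vals[[centile]])
    }
  }
  validate_reference(ref)
}

#' @export
print.mtp_reference <- function(x, ...) {
  cat("Term-pregnancy reference centiles (pg/mL)\n")
  cat("  sFlt-1:", paste(sprintf("%sth=%g", names(x$sflt1), x$sflt1),
                         collapse = "  "), "\n")
  cat("  PlGF:  ", paste(sprintf("%sth=%g", names(x$plgf), x$plgf),
                         collapse = "  "), "\n")
  invisible(x)
}
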