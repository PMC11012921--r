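#' Configuration for the synthetic cohort generator
#'
#' Bundles every constant of the generative model in one place. The
#' defaults emulate a hospital cohort of singleton pregnancies with a
#' diagnosis or suspicion of a hypertensive disorder: about 182 women
#' contributing about 240 biomarker dosages, roughly 64% drawn before
#' 37+0 weeks and 34% before 34+0 weeks, with negatively correlated
#' log-scale PlGF and sFlt-1 whose imbalance worsens with a latent
#' severity, and a time to delivery that decreases stochastically with
#' the sFlt-1/PlGF ratio.
#'
#' The model, per patient \eqn{i} and dosage \eqn{j}:
#' \itemize{
#'   \item severity \eqn{s_i ~ Uniform(0, 1)}, shared by the patient's
#'     dosages;
#'   \item dosage count \eqn{1 + Geometric(p)} with
#'     \eqn{p = 1 / mean\_dosages};
#'   \item gestational age drawn from a three-component uniform mixture
#'     over [154, 237], [238, 258], [259, 294] completed days with
#'     weights `ga_weights`;
#'   \item \eqn{log PlGF = log\_plgf0 + plgf\_severity \cdot s +
#'     plgf\_ga\_slope (ga - 238) + \epsilon_1} and analogously for
#'     sFlt-1, with \eqn{(\epsilon_1, \epsilon_2)} bivariate normal,
#'     sds `plgf_sd`/`sflt1_sd`, correlation `noise_cor` (negative);
#'   \item time to delivery
#'     \eqn{T = round(min(exp(a - b \log ratio + \epsilon), 294 - ga))},
#'     \eqn{\epsilon ~ N(0, \sigma^2)}, so no synthetic delivery occurs
#'     after 42+0 weeks.
#' }
#'
#' @param n_patients Number of women (default 182).
#' @param mean_dosages Expected dosages per patient (default 240/182).
#' @param ga_weights Mixture weights for gestational age at dosage:
#'   before 34 weeks, 34-36+6 weeks, at/after 37 weeks; normalised to 1.
#' @param log_plgf0,log_sflt10 Baseline log concentrations (pg/mL) at
#'   severity 0 and 34+0 weeks.
#' @param plgf_severity,sflt1_severity Log-scale severity slopes; PlGF
#'   falls and sFlt-1 rises as severity increases.
#' @param plgf_ga_slope,sflt1_ga_slope Log-scale change per day of
#'   gestational age, centred at 238 days.
#' @param plgf_sd,sflt1_sd Log-scale residual standard deviations (>= 0).
#' @param noise_cor Correlation of the two log-scale residuals, in
#'   (-1, 1); negative by default.
#' @param ttd_a Intercept of log time-to-delivery at ratio 1.
#' @param ttd_b Decay exponent of time-to-delivery in the ratio (>= 0;
#'   0 gives a ratio-independent time).
#' @param ttd_sigma Log-scale noise sd of time-to-delivery (>= 0).
#' @param seed Integer seed; a fixed seed yields a bit-identical cohort.
#' @return A list of class `mtp_generator_config`.
#' @export
generator_config <- function(n_patients = 182,
                             mean_dosages = 240 / 182,
                             ga_weights = c(0.34, 0.30, 0.36),
                             log_plgf0 = log(250),
                             plgf_severity = -2.53,
                             plgf_ga_slope = -0.004,
                             plgf_sd = 0.35,
                             log_sflt10 = log(3000),
                             sflt1_severity = 1.67,
                             sflt1_ga_slope = 0.004,
                             sflt1_sd = 0.30,
                             noise_cor = -0.4,
                             ttd_a = 3.25,
                             ttd_b = 0.35,
                             ttd_sigma = 0.6,
                             seed = 1L) {
  config <- list(
    n_patients = n_patients, mean_dosages = mean_dosages,
    ga_weights = ga_weights / sum(ga_weights),
    log_plgf0 = log_plgf0, plgf_severity = plgf_severity,
    plgf_ga_slope = plgf_ga_slope, plgf_sd = plgf_sd,
    log_sflt10 = log_sflt10, sflt1_severity = sflt1_severity,
    sflt1_ga_slope = sflt1_ga_slope, sflt1_sd = sflt1_sd,
    noise_cor = noise_cor,
    ttd_a = ttd_a, ttd_b = ttd_b, ttd_sigma = ttd_sigma,
    seed = as.integer(seed)
  )
  bad <- config$n_patients < 1 || config$mean_dosages < 1 ||
    length(config$ga_weights) != 3 || any(config$ga_weights < 0) ||
    config$plgf_sd < 0 || config$sflt1_sd < 0 ||
    abs(config$noise_cor) >= 1 ||
    config$ttd_b < 0 || config$ttd_sigma < 0
  if (bad) stop("invalid generator parameter", call. = FALSE)
  structure(config, class = "mtp_generator_config")
}

# Uniform mixture over the three GA windows, in completed days
GA_WINDOWS <- cbind(lo = c(154L, 238L, 259L), hi = c(237L, 258L, 294L))

#' Generate a seeded synthetic cohort
#'
#' Draws a cohort of biomarker dosages from the generative model of
#' [generator_config()]. With the same config (including seed) the
#' cohort is bit-identical across calls; the caller's RNG state is left
#' untouched.
#'
#' @param config A [generator_config()].
#' @param keep_latent If `TRUE`, also return `severity` and `ttd_latent`,
#'   the pre-truncation continuous time to delivery; with `ttd_sigma = 0`
#'   the decay exponent is exactly recoverable by a log-log regression on
#'   `ttd_latent` (integer rounding and the 42-week cap make the recorded
#'   day counts only approximately log-linear).
#' @return A tibble with one row per dosage: `patient_id`, `ga_days`
#'   (completed days), `plgf`, `sflt1` (pg/mL), `time_to_delivery_days`.
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 7))
#' nrow(cohort)  # about 240
#' @export
generate_cohort <- function(config = generator_config(),
                            keep_latent = FALSE) {
  stopifnot(inherits(config, "mtp_generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n_pat <- as.integer(config$n_patients)
  dosages <- 1L + stats::rgeom(n_pat, prob = 1 / config$mean_dosages)
  severity <- stats::runif(n_pat)
  idx <- rep.int(seq_len(n_pat), dosages)
  n <- length(idx)
  s <- severity[idx]

  comp <- sample.int(3L, n, replace = TRUE, prob = config$ga_weights)
  lo <- GA_WINDOWS[comp, "lo"]
  hi <- GA_WINDOWS[comp, "hi"]
  ga <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))

  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  e_plgf <- z1
  e_sflt1 <- config$noise_cor * z1 + sqrt(1 - config$noise_cor^2) * z2
  plgf <- exp(config$log_plgf0 + config$plgf_severity * s +
                config$plgf_ga_slope * (ga - GA_34W_DAYS) +
                config$plgf_sd * e_plgf)
  sflt1 <- exp(config$log_sflt10 + config$sflt1_severity * s +
                 config$sflt1_ga_slope * (ga - GA_34W_DAYS) +
                 config$sflt1_sd * e_sflt1)
  ratio <- sflt1 / plgf

  eps <- stats::rnorm(n, sd = config$ttd_sigma)
  latent <- exp(config$ttd_a - config$ttd_b * log(ratio) + eps)
  cap <- 294L - ga
  ttd <- as.integer(round_display(pmin(latent, cap), 0))

  out <- tibble::tibble(
    patient_id = sprintf("P%03d", idx),
    ga_days = ga,
    plgf = plgf,
    sflt1 = sflt1,
    time_to_delivery_days = ttd
  )
  if (keep_latent) {
    out$severity <- s
    out$ttd_latent <- latent
  }
  out
}

#' Class-wise median time to delivery
#'
#' Classifies each dosage's ratio and returns the median time to delivery
#' per risk class, in increasing class order. Under the generative model
#' (and in the motivating clinical data) the medians decrease from low to
#' very high.
#'
#' @inheritParams compute_mtp
#' @param min_n Minimum dosages required in every class.
#' @return Named numeric vector of medians (days), names [risk_levels()].
#' @export
recover_trend <- function(cohort, ref = default_reference(), min_n = 30) {
  cohort <- classify_cohort(cohort, ref)
  counts <- table(cohort$risk_class)
  if (any(counts < min_n)) {
    stop("insufficient class occupancy: every class needs at least ",
         min_n, " dosages", call. = FALSE)
  }
  vapply(risk_levels(), function(cl) {
    stats::median(cohort$time_to_delivery_days[cohort$risk_class == cl])
  }, numeric(1))
}

#' Recover the time-to-delivery decay exponent
#'
#' Ordinary least squares of `log(ttd_latent)` on `log(ratio)`; the
#' negated slope estimates the generator's `ttd_b`. With `ttd_sigma = 0`
#' the recovery is exact to machine precision, because the latent time is
#' exactly log-linear in the ratio.
#'
#' @param cohort A cohort generated with `keep_latent = TRUE`, with an
#'   appended `ratio` column (see [compute_mtp()]) or raw `plgf`/`sflt1`.
#' @return The estimated decay exponent (positive scalar for `ttd_b > 0`).
#' @export
recover_exponent <- function(cohort) {
  if (!"ttd_latent" %in% names(cohort)) {
    stop("cohort must be generated with keep_latent = TRUE", call. = FALSE)
  }
  if (!"ratio" %in% names(cohort)) {
    cohort$ratio <- cohort$sflt1 / cohort$plgf
  }
  keep <- cohort$ttd_latent > 0
  fit <- stats::lm(log(ttd_latent) ~ log(ratio), data = cohort[keep, ])
  -unname(stats::coef(fit)[2])
}
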