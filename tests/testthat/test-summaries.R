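test_that("median and IQR follow the declared quantile convention", {
  # three low-class dosages: odd-length median
  s <- summarize_by_risk_class(low_ratio_cohort(c(4, 10, 23)))
  low_all <- s[s$stratum == "all" & s$group == "low", ]
  expect_identical(low_all$n, 3L)
  expect_identical(low_all$median_days, 10)
  # single dosage: degenerate IQR collapses onto the value
  s1 <- summarize_by_risk_class(low_ratio_cohort(5))
  row <- s1[s1$stratum == "all" & s1$group == "low", ]
  expect_identical(row$median_days, 5)
  expect_identical(row$iqr_lower, 5)
  expect_identical(row$iqr_upper, 5)
  # even-length sample, checked against the hand-derived order statistics
  s2 <- summarize_by_risk_class(low_ratio_cohort(c(0, 1, 2, 3)))
  row2 <- s2[s2$stratum == "all" & s2$group == "low", ]
  expect_identical(row2$median_days, 1.5)
  expect_identical(c(row2$iqr_lower, row2$iqr_upper),
                   oracle_quantile(c(0, 1, 2, 3), c(0.25, 0.75)))
})

test_that("summary quantiles match the order-statistic oracle on random samples", {
  set.seed(41)
  for (rep in 1:200) {
    times <- sample(0:60, size = sample(1:20, 1), replace = TRUE)
    s <- summarize_by_risk_class(low_ratio_cohort(times))
    row <- s[s$stratum == "all" & s$group == "low", ]
    q <- oracle_quantile(times, c(0.25, 0.5, 0.75))
    expect_identical(c(row$iqr_lower, row$median_days, row$iqr_upper), q)
  }
})

test_that("risk-class rows partition each stratum and percentages add up", {
  cohort <- generate_cohort(generator_config(seed = 5))
  s <- summarize_by_risk_class(cohort)
  expect_identical(nrow(s), 12L)  # 3 strata x 4 classes
  for (st in ga_strata()) {
    rows <- s[s$stratum == st, ]
    total <- switch(st, all = nrow(cohort),
                    lt37w = sum(cohort$ga_days < 259),
                    lt34w = sum(cohort$ga_days < 238))
    expect_identical(sum(rows$n), total)
    expect_lte(abs(sum(rows$pct) - 100), 2)
  }
})

test_that("strata are nested so group counts never increase", {
  cohort <- generate_cohort(generator_config(seed = 6))
  for (s in list(summarize_by_risk_class(cohort),
                 summarize_by_category(cohort))) {
    wide <- tidyr::pivot_wider(s[, c("stratum", "group", "n")],
                               names_from = "stratum", values_from = "n")
    expect_true(all(wide$lt37w <= wide$all))
    expect_true(all(wide$lt34w <= wide$lt37w))
  }
})

test_that("category summaries respect membership nesting", {
  cohort <- generate_cohort(generator_config(seed = 7))
  s <- summarize_by_category(cohort)
  n_of <- function(id, st) s$n[s$group == id & s$stratum == st]
  for (st in ga_strata()) {
    expect_lte(n_of("plgf_10c_ge_3", st), n_of("plgf_10c_ge_2", st))
    expect_lte(n_of("sflt1_90c_ge_3", st), n_of("sflt1_90c_ge_2", st))
    expect_lte(n_of("plgf_10c_lt_1_and_sflt1_90c_gt_1", st),
               n_of("plgf_10c_lt_1", st))
  }
})

test_that("an all-ones cohort occupies only the boundary-inclusive categories", {
  ref <- default_reference()
  cohort <- tibble::tibble(
    patient_id = c("A", "B"),
    ga_days = c(230L, 260L),
    plgf = ref$plgf[["2.5"]], sflt1 = ref$sflt1[["90"]],
    time_to_delivery_days = c(3L, 4L)
  )
  # score each marker against its own centile: set the other centile
  # columns by hand so all six Mtp values are exactly 1
  scored <- compute_mtp(cohort)
  for (col in c("mtp_plgf_2.5", "mtp_plgf_5", "mtp_plgf_10",
                "mtp_sflt1_90", "mtp_sflt1_95", "mtp_sflt1_97.5")) {
    scored[[col]] <- 1
  }
  s <- summarize_by_category(scored)
  occupied <- unique(s$group[s$stratum == "all" & s$n > 0])
  expect_setequal(occupied, c("plgf_5c_le_1", "plgf_2.5c_le_1",
                              "sflt1_95c_ge_1", "sflt1_97.5c_ge_1",
                              "plgf_5c_le_1_and_sflt1_95c_ge_1",
                              "plgf_2.5c_le_1_and_sflt1_97.5c_ge_1"))
})

test_that("two dosages of the worked-example profile summarize correctly", {
  cohort <- dplyr::bind_rows(worked_example(), worked_example())
  s <- summarize_by_category(cohort)
  row <- s[s$stratum == "all" & s$group == "sflt1_90c_ge_2", ]
  expect_identical(row$n, 2L)
  expect_identical(row$median_days, 2)
})

test_that("cross-tab rows sum to the category total with sane percentages", {
  cohort <- generate_cohort(generator_config(seed = 8))
  ct <- crosstab_categories_by_class(cohort)
  expect_identical(nrow(ct), 19L * 4L)
  per_group <- dplyr::summarise(dplyr::group_by(ct, group),
                                adds_up = sum(count) == n[1])
  expect_true(all(per_group$adds_up))
  # a homogeneous toy cohort: one category, all very high
  toy <- tibble::tibble(patient_id = letters[1:4], ga_days = 240L,
                        plgf = 10, sflt1 = 30000,
                        time_to_delivery_days = 1L)
  ct2 <- crosstab_categories_by_class(toy)
  row <- ct2[ct2$group == "sflt1_90c_ge_3" & ct2$risk_class == "very_high", ]
  expect_identical(row$count, 4L)
  expect_identical(row$pct, 100)
  others <- ct2[ct2$group == "sflt1_90c_ge_3" &
                  ct2$risk_class != "very_high", ]
  expect_true(all(others$count == 0))
})

test_that("empty cohorts are refused", {
  empty <- low_ratio_cohort(integer(0))
  expect_error(summarize_by_risk_class(empty), "empty|invalid")
  expect_error(crosstab_categories_by_class(empty), "empty|invalid")
})
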