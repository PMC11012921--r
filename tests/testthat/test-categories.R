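test_that("registry holds the 19 category definitions", {
  reg <- category_registry()
  expect_identical(nrow(reg), 19L)
  expect_identical(anyDuplicated(reg$id), 0L)
  expect_true("sflt1_90c_ge_3" %in% reg$id)
  expect_true("Mtp sFlt-1 90th c \u2265 3" %in% reg$display)
  expect_true("plgf_10c_lt_1_and_sflt1_90c_gt_1" %in% reg$id)
  expect_true("Mtp PlGF 10th c < 1 and Mtp sFlt-1 90th c > 1" %in% reg$display)
  # combined categories pair matched centiles, one clause per marker
  combined <- reg[reg$n_clauses == 2, ]
  expect_identical(nrow(combined), 3L)
  for (clauses in combined$clauses) {
    markers <- vapply(clauses, `[[`, character(1), "marker")
    expect_setequal(markers, c("plgf", "sflt1"))
  }
  # the comparator asymmetry between the markers is preserved
  expect_false("sflt1_90c_lt_1" %in% reg$id)
  expect_false("plgf_10c_gt_1" %in% reg$id)
})

test_that("worked-example profile lands in exactly the expected categories", {
  got <- memberships(mtp_profile(plgf = 24.48, sflt1 = 17794))
  expect_contains(got, c("plgf_10c_le_0.5", "plgf_10c_lt_1",
                         "sflt1_90c_gt_1", "sflt1_90c_ge_2",
                         "sflt1_97.5c_ge_1",
                         "plgf_10c_lt_1_and_sflt1_90c_gt_1"))
  expect_false("sflt1_90c_ge_3" %in% got)
  expect_false("sflt1_97.5c_ge_2" %in% got)
})

test_that("all-ones profile keeps only the boundary-inclusive categories", {
  ref <- default_reference()
  prof <- mtp_profile(plgf = ref$plgf[["2.5"]], sflt1 = ref$sflt1[["90"]])
  # force every Mtp to exactly 1 by scoring each marker against itself
  prof$mtp_plgf[] <- 1
  prof$mtp_sflt1[] <- 1
  # the strict < and > clauses fail at exactly 1, so the 10th/90th simple
  # and combined categories drop out; the two fully non-strict combined
  # categories are retained along with their parents
  expect_setequal(memberships(prof),
                  c("plgf_5c_le_1", "plgf_2.5c_le_1",
                    "sflt1_95c_ge_1", "sflt1_97.5c_ge_1",
                    "plgf_5c_le_1_and_sflt1_95c_ge_1",
                    "plgf_2.5c_le_1_and_sflt1_97.5c_ge_1"))
})

test_that("a clearly elevated PlGF profile joins only the >= categories", {
  prof <- mtp_profile(plgf = 68.6 * 2.5, sflt1 = 5000)
  got <- memberships(prof)
  expect_true("plgf_10c_ge_2" %in% got)
  expect_false("plgf_10c_ge_3" %in% got)
  expect_false(any(grepl("^plgf.*(le|lt)", got)))
})

test_that("category nesting holds on random profiles", {
  set.seed(31)
  out <- categorize_cohort(random_marker_table(2000))
  implies <- function(a, b) expect_true(all(out[[b]][out[[a]]]))
  implies("plgf_10c_le_0.5", "plgf_10c_lt_1")
  implies("plgf_10c_ge_3", "plgf_10c_ge_2")
  implies("sflt1_90c_ge_3", "sflt1_90c_ge_2")
  implies("sflt1_90c_ge_2", "sflt1_90c_gt_1")
  implies("plgf_10c_lt_1_and_sflt1_90c_gt_1", "plgf_10c_lt_1")
  implies("plgf_10c_lt_1_and_sflt1_90c_gt_1", "sflt1_90c_gt_1")
  implies("plgf_5c_le_1_and_sflt1_95c_ge_1", "plgf_5c_le_1")
  implies("plgf_2.5c_le_1_and_sflt1_97.5c_ge_1", "sflt1_97.5c_ge_1")
})

test_that("vectorized membership agrees with the per-profile evaluator", {
  set.seed(32)
  tab <- random_marker_table(100)
  out <- categorize_cohort(tab)
  reg <- category_registry()
  for (i in seq_len(nrow(tab))) {
    single <- memberships(mtp_profile(tab$plgf[i], tab$sflt1[i]))
    expect_setequal(single, reg$id[unlist(out[i, reg$id])])
  }
})

test_that("very elevated PlGF with modest sFlt-1 implies a low ratio", {
  # Mtp_plgf10 >= 3 forces plgf >= 205.8; whenever sflt1 < 38 * 205.8 the
  # ratio is below 38 — the conditional counterpart of the observed
  # all-low column for that category.
  set.seed(33)
  tab <- random_marker_table(5000)
  out <- classify_cohort(compute_mtp(tab) |>
                           dplyr::mutate(ga_days = 230L))
  sel <- out$mtp_plgf_10 >= 3 & out$sflt1 < 38 * 3 * 68.6
  expect_true(all(out$risk_class[sel] == "low"))
})
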