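fix <- reconstruct_fixture()
scored <- score_records(fix)

count_by_cat <- function(field) {
  vapply(c("MILD", "MODERATE", "SEVERE"), function(cc)
    sum(fix[[field]][scored$category == cc], na.rm = TRUE), numeric(1),
    USE.NAMES = FALSE)
}

test_that("fixture satisfies every published category-level count", {
  expect_equal(nrow(fix), 83)
  expect_equal(unname(table(scored$category)[c("MILD", "MODERATE", "SEVERE")]),
               c(5, 65, 13), ignore_attr = TRUE)
  expect_equal(count_by_cat("death_ecls"), c(0, 12, 10))
  expect_equal(count_by_cat("ecls"), c(0, 8, 8))
  expect_equal(count_by_cat("died"), c(0, 7, 7))
  expect_equal(count_by_cat("ino"), c(1, 50, 13))
  expect_equal(count_by_cat("vasoactive"), c(0, 42, 13))
  expect_equal(count_by_cat("imv"), c(1, 49, 13))
  expect_equal(count_by_cat("hfov"), c(0, 41, 13))
  expect_equal(count_by_cat("male"), c(1, 43, 9))
  expect_equal(count_by_cat("meconium"), c(1, 25, 4))
  expect_equal(count_by_cat("lung_malformation"), c(0, 2, 3))
})

test_that("inclusion-exclusion on died and ECLS gives 8 overlapping patients", {
  expect_equal(sum(fix$died), 14)
  expect_equal(sum(fix$died & fix$ecls), 8)
  # per category: moderate 3, severe 5, by the same identity
  expect_equal(sum(fix$died & fix$ecls & scored$category == "MODERATE"), 3)
  expect_equal(sum(fix$died & fix$ecls & scored$category == "SEVERE"), 5)
  expect_equal(sum(fix$death_ecls), sum(fix$died) + sum(fix$ecls) -
                 sum(fix$died & fix$ecls))
})

test_that("an impossible composite count raises a consistency error", {
  expect_error(
    fixture_spec(outcomes = modifyList(fixture_spec()$outcomes,
                                       list(death_ecls = c(0L, 6L, 10L)))),
    class = "hrfph_consistency_error")  # composite < max(died, ecls)
  expect_error(
    fixture_spec(outcomes = modifyList(fixture_spec()$outcomes,
                                       list(death_ecls = c(0L, 20L, 10L)))),
    class = "hrfph_consistency_error")  # negative implied overlap
})

test_that("fixture raw measurements reproduce the assigned scores end to end", {
  expect_equal(scored$total, fix$assigned_total)
  expect_true(all(scored$total == scored$hrf + scored$ph))
  expect_equal(range(scored$total), c(2, 12))       # observed score range
  expect_equal(mean(scored$total), 8.5, tolerance = 0.01)  # observed mean
})

test_that("summaries of the fixture reproduce the published percentages within 1 point", {
  by_cat <- function(field, cc) {
    v <- fix[[field]][scored$category == cc]
    summarize_outcome(v[!is.na(v)], "dichotomous")$percent
  }
  expect_equal(by_cat("death_ecls", "SEVERE"), 77, tolerance = 1)
  expect_equal(by_cat("death_ecls", "MODERATE"), 18, tolerance = 1)
  expect_equal(by_cat("ecls", "SEVERE"), 62, tolerance = 1)
  expect_equal(by_cat("ecls", "MODERATE"), 12, tolerance = 1)
  expect_equal(by_cat("died", "SEVERE"), 54, tolerance = 1)
  expect_equal(by_cat("died", "MODERATE"), 11, tolerance = 1)
  expect_equal(by_cat("ino", "MODERATE"), 77, tolerance = 1)
  expect_equal(by_cat("ino", "MILD"), 20, tolerance = 1)
  expect_equal(by_cat("vasoactive", "MODERATE"), 65, tolerance = 1)
  expect_equal(by_cat("imv", "MODERATE"), 75, tolerance = 1)
  expect_equal(by_cat("ventilated_week", "MODERATE"), 50, tolerance = 1)
  expect_equal(by_cat("ventilated_2week", "MODERATE"), 17, tolerance = 1)
  expect_equal(by_cat("los_over_week", "MILD"), 80, tolerance = 1)
  expect_equal(by_cat("los_over_week", "MODERATE"), 91, tolerance = 1)
  expect_equal(100 * mean(fix$died), 17, tolerance = 1)
  expect_equal(100 * mean(scored$category == "MILD"), 6, tolerance = 1)
  expect_equal(100 * mean(fix$male), 64, tolerance = 1)
  expect_equal(100 * mean(fix$meconium), 36, tolerance = 1)
  expect_equal(100 * sum(fix$died & fix$ecls) / sum(fix$died), 57,
               tolerance = 1)
  # HFOV against the ventilated denominator (84% in the moderate category)
  hv <- attr(fix, "hfov_ventilated")
  expect_equal(100 * hv$numerator[2] / hv$denominator[2], 84, tolerance = 1)
})

test_that("survivor-only fields are missing exactly for the patients who died", {
  expect_true(all(is.na(fix$los_days[fix$died == 1])))
  expect_true(all(!is.na(fix$los_days[fix$died == 0])))
  expect_true(all(is.na(fix$los_over_week[fix$died == 1])))
  # the single mild iNO survivor carries the printed singleton duration
  mild_ino <- fix$ino_hours[scored$category == "MILD" & fix$ino == 1]
  expect_equal(mild_ino, 8)
  s <- summarize_outcome(mild_ino)
  expect_equal(c(s$median, s$q1, s$q3), c(8, 8, 8))
})

test_that("continuous reconstructions sit near their median/IQR anchors", {
  v <- fix$ino_hours[scored$category == "MODERATE" & !is.na(fix$ino_hours)]
  expect_equal(length(v), 43)  # 50 on iNO minus 7 deaths
  expect_equal(unname(median(v)), 86, tolerance = 0.05)
  q <- unname(quantile(v, c(0.25, 0.75)))
  expect_equal(q[1], 57, tolerance = 0.1)
  expect_equal(q[2], 158, tolerance = 0.1)
})

test_that("the fixture is deterministic", {
  expect_identical(reconstruct_fixture(), fix)
})
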