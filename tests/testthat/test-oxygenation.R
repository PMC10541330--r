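test_that("OI and OSI follow their printed formulas", {
  expect_equal(compute_oi(1.0, 20, 40), 50.0)
  expect_equal(compute_oi(0.5, 10, 50), 10.0)
  expect_equal(compute_oi(0.21, 0, 60), 0.0)
  expect_equal(compute_osi(1.0, 20, 80), 25.0)
  expect_equal(compute_osi(0.4, 10, 100), 4.0)
  expect_error(compute_oi(1.0, 20, 0), class = "hrfph_domain_error")
  expect_error(compute_oi(40, 20, 50), class = "hrfph_validation_error")
  expect_error(compute_osi(1.0, 20, 0), class = "hrfph_domain_error")
})

test_that("OSI equals OI when SpO2 numerically equals PaO2", {
  set.seed(11)
  for (i in 1:50) {
    fio2 <- runif(1, 0.21, 1)
    map <- runif(1, 0, 25)
    x <- runif(1, 20, 100)
    expect_identical(compute_osi(fio2, map, x), compute_oi(fio2, map, x))
  }
})

test_that("SpO2 selection follows site preference, then nearness, then recency", {
  r <- rbind(spo2_reading(97, "LOWER_LIMB"),
             spo2_reading(92, "RIGHT_UPPER_LIMB"))
  expect_equal(select_spo2(r)$value, 92)
  expect_equal(select_spo2(spo2_reading(95, "LEFT_UPPER_LIMB"))$value, 95)
  r2 <- rbind(spo2_reading(90, "LEFT_UPPER_LIMB"),
              spo2_reading(88, "LOWER_LIMB"))
  expect_equal(select_spo2(r2)$value, 90)
  # same site: nearest to the echo wins; equidistant -> the later reading
  r3 <- rbind(spo2_reading(85, "RIGHT_UPPER_LIMB", offset_hours = -2),
              spo2_reading(88, "RIGHT_UPPER_LIMB", offset_hours = 0.5))
  expect_equal(select_spo2(r3)$value, 88)
  r4 <- rbind(spo2_reading(85, "RIGHT_UPPER_LIMB", offset_hours = -1),
              spo2_reading(88, "RIGHT_UPPER_LIMB", offset_hours = 1))
  expect_equal(select_spo2(r4)$value, 88)
  expect_error(select_spo2(NULL), class = "hrfph_missing_data_error")
})

test_that("the gas window decides between OI and OSI", {
  spo2 <- spo2_reading(80, "RIGHT_UPPER_LIMB")
  oi <- select_severity_index(ox_imv(1.0, 20, pao2 = 40, gas = 2))
  expect_equal(oi$kind, "OI"); expect_equal(oi$value, 50.0)
  osi <- select_severity_index(ox_imv(1.0, 20, pao2 = 40, gas = 6,
                                      spo2 = spo2))
  expect_equal(osi$kind, "OSI"); expect_equal(osi$value, 25.0)
  osi2 <- select_severity_index(ox_imv(0.4, 10,
                                       spo2 = spo2_reading(100, "RIGHT_UPPER_LIMB")))
  expect_equal(osi2$kind, "OSI"); expect_equal(osi2$value, 4.0)
  expect_error(select_severity_index(ox_imv(1.0, 20, pao2 = 40, gas = 6)),
               class = "hrfph_missing_data_error")
  # the window is configurable
  wide <- score_config(gas_window_hours = 8)
  expect_equal(select_severity_index(ox_imv(1.0, 20, pao2 = 40, gas = 6,
                                            spo2 = spo2), wide)$kind, "OI")
})

test_that("low-support branch scores 0/1 on the flow and FiO2 thresholds", {
  expect_equal(oxygenation_score(ox_nc(flow = 1, fio2 = 0.21))$score, 0L)
  expect_equal(oxygenation_score(ox_nc(flow = 2, fio2 = 0.21,
                                       mode = "HFNC"))$score, 1L)
  expect_equal(oxygenation_score(ox_nc(flow = 0.5, fio2 = 0.30))$score, 1L)
  expect_equal(oxygenation_score(
    oxygenation_observation("NONE", fio2 = 0.21))$score, 0L)
})

test_that("positive-pressure branch scores 2-5 by band lookup of the index", {
  cfg <- score_config()
  # OI exactly 10 sits in the lower-inclusive [10, 15) band -> 3
  obs <- ox_imv(0.5, 10, pao2 = 50, gas = 1)
  res <- oxygenation_score(obs, cfg)
  expect_equal(res$index$value, 10.0)
  expect_equal(res$score, 3L)
  # every band agrees with an explicit interval-walk oracle
  set.seed(22)
  for (i in 1:200) {
    oi <- runif(1, 0, 40)
    map <- max(oi * 50 / 100, 1e-9)
    obs <- ox_imv(1.0, map, pao2 = 50, gas = 0)
    expect_equal(oxygenation_score(obs, cfg)$score,
                 interval_oracle(compute_oi(1.0, map, 50), cfg$oi_breaks, 2L))
  }
  # HFOV scores through the same invasive branch as IMV
  a <- oxygenation_score(ox_imv(0.8, 15, pao2 = 45, gas = 1, mode = "HFOV"))
  b <- oxygenation_score(ox_imv(0.8, 15, pao2 = 45, gas = 1, mode = "IMV"))
  expect_identical(a$score, b$score)
  expect_error(oxygenation_observation("IMV", fio2 = 0.5),
               class = "hrfph_validation_error")
})

test_that("oxygenation score is bounded per branch and monotone in the index", {
  cfg <- score_config()
  set.seed(33)
  prev <- NULL
  for (oi in sort(runif(100, 0, 50))) {
    map <- max(oi * 50 / 100, 1e-9)
    s <- oxygenation_score(ox_imv(1.0, map, pao2 = 50, gas = 0), cfg)$score
    expect_true(s %in% 2:5)
    if (!is.null(prev)) expect_gte(s, prev)
    prev <- s
  }
  for (flow in seq(0, 8, by = 0.5))
    expect_lte(oxygenation_score(ox_nc(flow = flow, fio2 = 0.29))$score, 1L)
})

test_that("percent-scale FiO2 is rejected loudly", {
  expect_error(oxygenation_observation("IMV", fio2 = 40, map_cmh2o = 10),
               class = "hrfph_unit_error")
})
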