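cfg <- default_config()

test_that("S/F ratio and OSI honour the 97% interpretability ceiling", {
  expect_equal(sf_ratio(88, 0.40, cfg), 220)
  expect_true(is.na(sf_ratio(98, 0.40, cfg)))
  expect_equal(sf_ratio(97, 1.0, cfg), 97)  # boundary included
  expect_error(sf_ratio(90, 1.2, cfg), "fio2")
  expect_equal(osi(0.60, 10, 90, cfg), 6.67, tolerance = 0.01 / 6.67)
  expect_true(is.na(osi(0.60, 10, 98, cfg)))
  expect_equal(osi(0.21, 5, 97, cfg), 1.08, tolerance = 0.01 / 1.08)
  expect_true(is.na(osi(0.60, NA, 90, cfg)))
})

test_that("support stratum is the maximum over days under the fixed order", {
  p <- make_patient(d1_support = "SIMPLE_O2", d2_support = "IMV")
  p$d3_support <- "HFNC"
  expect_equal(support_stratum(p), "IMV")
  q <- make_patient(d1_support = "NONE")
  expect_equal(support_stratum(q), "NONE")
  r <- make_patient(d1_support = "CPAP", d2_support = "HFNC")
  expect_equal(support_stratum(r), "NIV")
  s <- blank_patients(1)
  expect_warning(st <- support_stratum(s), "no support")
  expect_equal(st, "NONE")
})

test_that("full PARDS path: IMV with opacity and high OSI", {
  p <- make_patient(d1_support = "IMV", d1_spo2 = 92, d1_fio2 = 0.8,
                    d1_map = 10, d1_iface = "INVASIVE",
                    cxr_obtained = TRUE, cxr_opacity = TRUE)
  a <- assess_one(p)
  expect_true(a$eligible_full)
  expect_equal(a$category, "PARDS")
  expect_equal(a$osi, 0.8 * 10 * 100 / 92)
  # opacity attributed to cardiac failure negates the clause
  p2 <- make_patient(d1_support = "IMV", d1_spo2 = 92, d1_fio2 = 0.8,
                     d1_map = 10, cxr_obtained = TRUE, cxr_opacity = TRUE,
                     attributed = TRUE)
  expect_equal(assess_one(p2)$category, "EVALUATED_NEGATIVE")
  # below the OSI threshold: evaluable but negative
  p3 <- make_patient(d1_support = "IMV", d1_spo2 = 92, d1_fio2 = 0.3,
                     d1_map = 10, cxr_obtained = TRUE, cxr_opacity = FALSE)
  a3 <- assess_one(p3)
  expect_true(a3$eligible_full)
  expect_equal(a3$category, "EVALUATED_NEGATIVE")
})

test_that("possible PARDS path: nasal support without a chest X-ray", {
  p <- make_patient(d1_support = "HFNC", d1_spo2 = 90, d1_fio2 = 0.5,
                    d1_flow = 30, weight = 10)
  a <- assess_one(p)
  expect_true(a$eligible_possible)
  expect_equal(a$category, "POSSIBLE_PARDS")
  # same oxygenation but S/F above threshold
  p2 <- make_patient(d1_support = "HFNC", d1_spo2 = 95, d1_fio2 = 0.3,
                     d1_flow = 30, weight = 10)
  expect_equal(assess_one(p2)$category, "EVALUATED_NEGATIVE")
  # CPAP with nasal interface qualifies; full-face does not
  p3 <- make_patient(d1_support = "CPAP", d1_spo2 = 90, d1_fio2 = 0.5,
                     d1_iface = "NASAL")
  expect_equal(assess_one(p3)$category, "POSSIBLE_PARDS")
  p4 <- make_patient(d1_support = "CPAP", d1_spo2 = 90, d1_fio2 = 0.5,
                     d1_iface = "FULL_FACE")
  a4 <- assess_one(p4)
  expect_true(a4$eligible_possible)
  expect_equal(a4$category, "EVALUATED_NEGATIVE")
  # an obtained X-ray with a missing result blocks the category
  p5 <- make_patient(d1_support = "HFNC", d1_spo2 = 90, d1_fio2 = 0.5,
                     d1_flow = 30, cxr_obtained = TRUE, cxr_opacity = NA)
  a5 <- assess_one(p5)
  expect_false(a5$eligible_possible)
  expect_match(a5$missing_fields, "possible:cxr_result")
})

test_that("at-risk path: opacity plus qualifying low-flow oxygen", {
  p <- make_patient(d1_support = "SIMPLE_O2", d1_spo2 = 90, d1_flow = 4,
                    weight = 8, cxr_obtained = TRUE, cxr_opacity = TRUE)
  a <- assess_one(p)
  expect_true(a$eligible_at_risk)
  expect_equal(a$category, "AT_RISK")
  # flow below the weight-banded minimum does not qualify
  p2 <- make_patient(d1_support = "SIMPLE_O2", d1_spo2 = 90, d1_flow = 1,
                     weight = 30, cxr_obtained = TRUE, cxr_opacity = TRUE)
  expect_equal(assess_one(p2)$category, "EVALUATED_NEGATIVE")
  # missing flow makes the category unevaluable
  p3 <- make_patient(d1_support = "SIMPLE_O2", d1_spo2 = 90,
                     cxr_obtained = TRUE, cxr_opacity = TRUE)
  a3 <- assess_one(p3)
  expect_false(a3$eligible_at_risk)
  expect_match(a3$missing_fields, "at_risk:flow")
})

test_that("non-trigger patients are never classified", {
  p <- make_patient(d1_support = "IMV", d1_spo2 = 92, d1_fio2 = 0.8,
                    d1_map = 10, cxr_obtained = TRUE, cxr_opacity = TRUE,
                    dx = "asthma")
  a <- assess_one(p)
  expect_equal(a$category, "NOT_CLASSIFIABLE")
  expect_equal(a$missing_fields, "no_trigger")
  expect_false(a$eligible_full)
})

test_that("cascade assigns exactly one category and is deterministic", {
  set.seed(99)
  for (i in 1:150) {
    p <- random_trigger_patient()
    a <- assess_one(p)
    expect_true(a$category %in% c("PARDS", "POSSIBLE_PARDS", "AT_RISK",
                                  "EVALUATED_NEGATIVE", "NOT_CLASSIFIABLE"))
    if (a$category == "PARDS") expect_true(a$eligible_full)
    if (a$category == "NOT_CLASSIFIABLE") {
      expect_false(a$eligible_full || a$eligible_possible || a$eligible_at_risk)
      expect_gt(nchar(a$missing_fields), 0)
    }
    expect_identical(assess_one(p), a)  # pure function of the record
  }
})

test_that("perturbing SpO2 from 97 to 98 never creates a PARDS category", {
  set.seed(7)
  for (i in 1:80) {
    p <- random_trigger_patient()
    p$d1_spo2_min <- 97
    a97 <- assess_one(p)
    p$d1_spo2_min <- 98
    a98 <- assess_one(p)
    expect_false(a98$category %in% c("PARDS", "POSSIBLE_PARDS"))
    if (a97$category == "NOT_CLASSIFIABLE") {
      expect_true(a98$category %in% c("NOT_CLASSIFIABLE", "AT_RISK",
                                      "EVALUATED_NEGATIVE"))
    }
  }
})

test_that("raising FiO2 never demotes a PARDS classification", {
  p <- make_patient(d1_support = "IMV", d1_spo2 = 92, d1_fio2 = 0.5,
                    d1_map = 12, cxr_obtained = TRUE, cxr_opacity = TRUE)
  expect_equal(assess_one(p)$category, "PARDS")
  for (f in c(0.6, 0.8, 1.0)) {
    p$d1_fio2 <- f
    expect_equal(assess_one(p)$category, "PARDS")
  }
})

test_that("missingness report locates absent fields by stratum", {
  complete <- make_patient(d1_support = "IMV", d1_spo2 = 92, d1_fio2 = 0.8,
                           d1_map = 10, cxr_obtained = TRUE,
                           cxr_opacity = TRUE)
  a <- assess_one(complete)
  rep0 <- missingness_report(a)
  expect_equal(sum(rep0$by_stratum), 0)
  nomap <- make_patient(d1_support = "IMV", d1_spo2 = 92, d1_fio2 = 0.8,
                        cxr_obtained = TRUE, cxr_opacity = TRUE)
  r1 <- missingness_report(assess_one(nomap))
  expect_equal(unname(r1$by_stratum["map", "IMV"]), 1)
})
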