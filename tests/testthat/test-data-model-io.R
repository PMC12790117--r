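test_that("patient reader round-trips generated records losslessly", {
  g <- generate_cohort(default_generator_params(n_patients = 300L, seed = 11L))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_table(g$patients, tmp)
  back <- read_patients(tmp)
  expect_equal(nrow(attr(back, "problems")), 0)
  expect_equal(nrow(back), nrow(g$patients))
  for (col in names(g$patients)) {
    expect_equal(back[[col]], g$patients[[col]], info = col,
                 tolerance = 1e-12)
  }
})

test_that("site and survey readers round-trip and validate vocabulary", {
  g <- generate_cohort(default_generator_params(n_patients = 50L, seed = 3L))
  st <- withr::local_tempfile(fileext = ".csv")
  sv <- withr::local_tempfile(fileext = ".csv")
  write_table(g$sites, st)
  write_table(g$surveys[, c("site_id", "item", "response")], sv)
  sites <- read_sites(st)
  expect_equal(sites$sdi_quintile, g$sites$sdi_quintile)
  surveys <- read_site_surveys(sv)
  expect_equal(surveys$level, g$surveys$level)
  # unknown item is a schema error
  bad <- rbind(g$surveys[1, c("site_id", "item", "response")],
               data.frame(site_id = "S01", item = "warp_drive",
                          response = "always"))
  write_table(bad, sv)
  expect_error(read_site_surveys(sv), "unknown resource item")
})

test_that("likert blanks are stored missing, labels map to levels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,item,response",
               "S1,oxygen_source,always",
               "S1,suction,",
               "S1,nebulizer,often"), f)
  sv <- read_site_surveys(f)
  expect_equal(sv$level[sv$item == "oxygen_source"], 5L)
  expect_true(is.na(sv$level[sv$item == "suction"]))
  expect_equal(sv$level[sv$item == "nebulizer"], 4L)
})

test_that("row validation rejects bad values with located diagnostics", {
  p <- make_patient()
  p2 <- make_patient(); p2$patient_id <- "P2"; p2$d1_fio2 <- 1.5
  p3 <- make_patient(); p3$patient_id <- "P3"; p3$d1_support <- "ROCKET"
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_table(rbind(p, p2, p3), tmp)
  expect_warning(got <- read_patients(tmp), "problem")
  expect_equal(got$patient_id, "P1")
  pr <- attr(got, "problems")
  expect_true(any(pr$column == "d1_fio2" & grepl("bounds", pr$message)))
  expect_true(any(pr$column == "d1_support"))
})

test_that("empty file with valid header yields an empty table", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_table(blank_patients(0), tmp)
  got <- read_patients(tmp)
  expect_equal(nrow(got), 0)
})

test_that("missing mandatory column is a schema error naming the column", {
  p <- make_patient()
  p$died <- NULL
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_table(p, tmp)
  expect_error(read_patients(tmp), "died")
})

test_that("percent-entered FiO2 is shimmed to a fraction with a note", {
  p <- make_patient(d1_fio2 = 0.4)
  p$d1_fio2 <- 40  # percentage convention
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_table(p, tmp)
  expect_message(got <- read_patients(tmp), "percentages")
  expect_equal(got$d1_fio2, 0.4)
})

test_that("cross-field invariants are enforced", {
  p <- make_patient()
  p$died_in_ed <- TRUE  # without died
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_table(p, tmp)
  expect_warning(got <- read_patients(tmp), "problem")
  expect_equal(nrow(got), 0)
  q <- make_patient(died = TRUE)
  q$los_days <- 4  # LOS recorded for a non-survivor
  write_table(q, tmp)
  expect_warning(got2 <- read_patients(tmp), "problem")
  expect_equal(nrow(got2), 0)
})

test_that("unknown columns pass through untouched", {
  p <- make_patient()
  p$site_notes <- "transferred"
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_table(p, tmp)
  got <- read_patients(tmp)
  expect_true("site_notes" %in% attr(got, "passthrough"))
  expect_equal(got$site_notes, "transferred")
})
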