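cfg <- default_config()

test_that("hypoxemia clauses fire in the documented order", {
  # SpO2 87 on day 3, no oxygen
  p <- make_patient(d1_support = "NONE", d1_spo2 = 95)
  p$d3_spo2_min <- 87
  hx <- is_hypoxemic(p, cfg)
  expect_true(hx$hypoxemic)
  expect_equal(hx$reason, "SPO2_LT_CUTOFF")
  # saturations fine but simple oxygen on day 1
  q <- make_patient(d1_support = "SIMPLE_O2", d1_spo2 = 96)
  expect_equal(is_hypoxemic(q, cfg)$reason, "ON_OXYGEN")
  # SpO2 of exactly 88 is not hypoxemia (strict less-than)
  r <- make_patient(d1_support = "NONE", d1_spo2 = 88)
  expect_false(is_hypoxemic(r, cfg)$hypoxemic)
  expect_equal(is_hypoxemic(r, cfg)$reason, "NOT_HYPOXEMIC")
  # ED death clause requires died_in_ed
  s <- make_patient(d1_support = "NONE", d1_spo2 = NA, died = TRUE)
  s$ed_death_spo2_pct <- 80
  expect_false(is_hypoxemic(s, cfg)$hypoxemic)
  s$died_in_ed <- TRUE
  expect_equal(is_hypoxemic(s, cfg)$reason, "ED_DEATH_CLAUSE")
  # all-missing observations are not hypoxemic
  t <- blank_patients(1); t$died_in_ed <- FALSE
  expect_false(is_hypoxemic(t, cfg)$hypoxemic)
})

test_that("screening excludes cyanotic heart disease before evaluation", {
  p <- make_patient(d1_spo2 = 80)  # would qualify by SpO2
  p$cyanotic_chd <- TRUE
  q <- make_patient(d1_support = "NONE", d1_spo2 = 95)
  q$patient_id <- "P2"
  scr <- screen_cohort(rbind(p, q), cfg)
  expect_equal(scr$flow[["n_excluded_cyanotic_chd"]], 1)
  expect_equal(scr$flow[["n_hypoxemic_included"]], 0)
  # all-cyanotic input: everything lands in the exclusion arm
  pp <- rbind(p, p, p); pp$patient_id <- paste0("P", 1:3)
  scr2 <- screen_cohort(pp, cfg)
  expect_equal(scr2$flow[["n_excluded_cyanotic_chd"]], 3)
  expect_equal(scr2$flow[["n_hypoxemic_included"]], 0)
})

test_that("screening arms partition any random cohort", {
  for (seed in c(5L, 17L)) {
    g <- generate_cohort(default_generator_params(n_patients = 400L,
                                                  seed = seed))
    fl <- screen_cohort(g$patients, cfg)$flow
    expect_equal(fl[["n_excluded_cyanotic_chd"]] +
                   fl[["n_hypoxemic_included"]] +
                   fl[["n_admitted_no_hypoxemia"]] +
                   fl[["n_not_admitted_no_hypoxemia"]],
                 fl[["n_enrolled"]])
  }
})

test_that("LODS sums its three components and stays in 0..3", {
  p <- blank_patients(4)
  p$lods_prostration_or_feed <- c(FALSE, TRUE, TRUE, NA)
  p$lods_coma <- c(FALSE, TRUE, FALSE, NA)
  p$lods_deep_breathing <- c(FALSE, TRUE, FALSE, NA)
  expect_message(sc <- lods(p), "missing")
  expect_equal(sc, c(0L, 3L, 1L, 0L))
  # age 3 months with inability to feed scores the prostration point
  infant <- make_patient(age = 0.25)
  infant$lods_prostration_or_feed <- TRUE
  infant$lods_coma <- FALSE; infant$lods_deep_breathing <- FALSE
  expect_equal(lods(infant), 1L)
  # monotone in each component
  base <- blank_patients(1)
  base$lods_prostration_or_feed <- FALSE
  base$lods_coma <- FALSE; base$lods_deep_breathing <- FALSE
  for (comp in c("lods_prostration_or_feed", "lods_coma",
                 "lods_deep_breathing")) {
    up <- base; up[[comp]] <- TRUE
    expect_gte(lods(up), lods(base))
  }
})

test_that("malnutrition applies strict cutoffs and the reported-OR clause", {
  p <- blank_patients(4)
  p$muac_cm <- c(12.4, 12.5, NA, NA)
  p$waz <- c(NA, -2.0, NA, NA)
  p$reported_malnutrition <- c(FALSE, FALSE, TRUE, NA)
  expect_equal(malnutrition(p), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("trigger grouping matches exhaustive enumeration of diagnosis sets", {
  dxs <- c("pneumonia", "bronchiolitis", "covid19", "sepsis", "trauma",
           "aspiration", "drowning", "other_shock", "asthma", "malaria")
  sets <- lapply(0:(2^8 - 1), function(m) {
    dxs[c(which(bitwAnd(m, 2^(0:7)) > 0), if (m %% 3 == 0) 9L else 10L)]
  })
  p <- blank_patients(length(sets))
  p$final_diagnoses <- vapply(sets, paste, character(1), collapse = ";")
  got <- assign_trigger(p, cfg)
  want_group <- vapply(sets, oracle_trigger_group, character(1))
  expect_equal(got$trigger_group, want_group)
  expect_equal(got$has_trigger, want_group != "NONE")
  # raw set retained for multi-trigger patients
  pq <- blank_patients(1); pq$final_diagnoses <- "sepsis;pneumonia"
  one <- assign_trigger(pq, cfg)
  expect_equal(one$trigger_group, "LRTI")
  expect_setequal(strsplit(one$raw_triggers, ";")[[1]],
                  c("sepsis", "pneumonia"))
  # unknown code warns and is ignored
  pu <- blank_patients(1); pu$final_diagnoses <- "dragon_pox"
  expect_warning(tr <- assign_trigger(pu, cfg), "unknown diagnosis")
  expect_false(tr$has_trigger)
})
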