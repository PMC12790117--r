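# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.cache$fixture)) .cache$fixture <- build_paper_fixture()
  .cache$fixture
}

get_run <- function() {
  if (is.null(.cache$run)) {
    .cache$run <- suppressMessages(suppressWarnings(run_all(get_fixture())))
  }
  .cache$run
}

# minimal all-missing patient frame for constructing hand-built records
blank_patients <- function(n) respaudit:::empty_patient_frame(n)

# one hand-built patient with day-1 (and optionally day-2) observations
make_patient <- function(d1_support = "SIMPLE_O2", d1_spo2 = 92,
                         d1_fio2 = NA, d1_map = NA, d1_flow = NA,
                         d1_iface = NA, d2_support = NA, d2_spo2 = NA,
                         d2_fio2 = NA, d2_map = NA,
                         weight = 10, cxr_obtained = FALSE, cxr_opacity = NA,
                         attributed = NA, dx = "pneumonia", died = FALSE,
                         age = 2) {
  p <- blank_patients(1)
  p$patient_id <- "P1"; p$site_id <- "S1"
  p$age_years <- age; p$sex <- "F"; p$weight_kg <- weight
  p$cyanotic_chd <- FALSE; p$died <- died; p$died_in_ed <- FALSE
  p$admitted <- TRUE
  p$final_diagnoses <- dx
  p$cxr_obtained <- cxr_obtained; p$cxr_opacity <- cxr_opacity
  p$cxr_opacity_attributed_nonparenchymal <- attributed
  p$d1_support <- d1_support; p$d1_spo2_min <- d1_spo2
  p$d1_fio2 <- d1_fio2; p$d1_map_cmh2o <- d1_map
  p$d1_flow_lpm <- d1_flow; p$d1_interface <- d1_iface
  p$d2_support <- d2_support; p$d2_spo2_min <- d2_spo2
  p$d2_fio2 <- d2_fio2; p$d2_map_cmh2o <- d2_map
  p
}

assess_one <- function(p, config = default_config()) {
  trg <- assign_trigger(p, config)
  suppressWarnings(evaluate_pards(p, trg, config))
}

# a randomized trigger patient covering the classifier's input space,
# including missing fields; draws from the current RNG
random_trigger_patient <- function() {
  supp <- sample(c("IMV", "CPAP", "BIPAP", "HFNC", "SIMPLE_O2", "NONE"), 1)
  make_patient(
    d1_support = supp,
    d1_spo2 = sample(c(NA, 85:99), 1),
    d1_fio2 = sample(c(NA, 0.21, 0.3, 0.5, 0.8, 1.0), 1),
    d1_map = sample(c(NA, 6, 10, 18), 1),
    d1_flow = sample(c(NA, 0.5, 2, 6, 30), 1),
    d1_iface = sample(c(NA, "NASAL", "FULL_FACE", "INVASIVE"), 1),
    weight = sample(c(NA, 4, 8, 15, 30), 1),
    cxr_obtained = sample(c(TRUE, FALSE), 1),
    cxr_opacity = sample(c(NA, TRUE, FALSE), 1),
    attributed = sample(c(NA, TRUE, FALSE), 1)
  )
}
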