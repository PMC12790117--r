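# Hypoxemia cohort construction (screening flow), bedside clinical scores
# (LODS, malnutrition), and PARDS-trigger grouping.

day_matrix <- function(patients, field) {
  cols <- sprintf("d%d_%s", 1:7, field)
  m <- as.matrix(patients[, cols, drop = FALSE])
  dimnames(m) <- list(NULL, cols)
  m
}

#' Hypoxemia inclusion test
#'
#' A patient is hypoxemic when, on any of hospital days 1-7, the minimum
#' oxygen saturation is below the cutoff (default strict < 88%), or any form
#' of supplemental oxygen / respiratory support is received, or the patient
#' dies in the emergency department with SpO2 below the cutoff or while on
#' oxygen. The reason reports the first satisfied clause in that order.
#'
#' @param patients validated patient table.
#' @param config run configuration.
#' @return data frame with logical \code{hypoxemic} and \code{reason}
#'   (\code{SPO2_LT_CUTOFF}, \code{ON_OXYGEN}, \code{ED_DEATH_CLAUSE},
#'   \code{NOT_HYPOXEMIC}), one row per patient.
#' @export
is_hypoxemic <- function(patients, config = default_config()) {
  spo2 <- day_matrix(patients, "spo2_min")
  supp <- day_matrix(patients, "support")
  low_spo2 <- rowSums(spo2 < config$spo2_hypoxemia_cutoff, na.rm = TRUE) > 0
  on_oxygen <- rowSums(!is.na(supp) & supp != "NONE") > 0
  ed_clause <- patients$died_in_ed %in% TRUE &
    ((!is.na(patients$ed_death_spo2_pct) &
        patients$ed_death_spo2_pct < config$spo2_hypoxemia_cutoff) |
       patients$ed_death_on_oxygen %in% TRUE)
  reason <- rep("NOT_HYPOXEMIC", nrow(patients))
  reason[ed_clause] <- "ED_DEATH_CLAUSE"
  reason[on_oxygen] <- "ON_OXYGEN"
  reason[low_spo2] <- "SPO2_LT_CUTOFF"
  data.frame(hypoxemic = low_spo2 | on_oxygen | ed_clause, reason = reason,
             stringsAsFactors = FALSE)
}

#' Screen an enrolled population into the hypoxemia cohort
#'
#' Patients with cyanotic congenital heart disease are excluded before
#' hypoxemia is evaluated (baseline saturations are uninterpretable); the
#' remainder are split into hypoxemic included patients, patients admitted
#' without hypoxemia, and non-admitted non-hypoxemic patients. The four arms
#' partition the enrolled population.
#'
#' @param patients validated patient table (the full enrolled population).
#' @param config run configuration.
#' @return list with \code{flow} (named counts: \code{n_enrolled},
#'   \code{n_excluded_cyanotic_chd}, \code{n_hypoxemic_included},
#'   \code{n_admitted_no_hypoxemia}, \code{n_not_admitted_no_hypoxemia}, and
#'   per-arm death counts) and \code{included} (the hypoxemic patient rows,
#'   with the inclusion \code{reason} column appended).
#' @export
screen_cohort <- function(patients, config = default_config()) {
  cyanotic <- patients$cyanotic_chd %in% TRUE
  rest <- patients[!cyanotic, , drop = FALSE]
  hx <- is_hypoxemic(rest, config)
  included <- rest[hx$hypoxemic, , drop = FALSE]
  included$inclusion_reason <- hx$reason[hx$hypoxemic]
  nonhyp <- rest[!hx$hypoxemic, , drop = FALSE]
  adm <- nonhyp$admitted %in% TRUE
  flow <- c(
    n_enrolled = nrow(patients),
    n_excluded_cyanotic_chd = sum(cyanotic),
    n_hypoxemic_included = nrow(included),
    n_admitted_no_hypoxemia = sum(adm),
    n_not_admitted_no_hypoxemia = sum(!adm),
    deaths_hypoxemic = sum(included$died %in% TRUE),
    deaths_admitted_no_hypoxemia = sum(nonhyp$died[adm] %in% TRUE),
    deaths_excluded_cyanotic_chd = sum(patients$died[cyanotic] %in% TRUE)
  )
  rownames(included) <- NULL
  list(flow = flow, included = included)
}

#' Lambarene Organ Dysfunction Score
#'
#' Three-point severity score: one point each for prostration (or inability
#' to feed if under 5 months; the age substitution is resolved upstream at
#' ingestion into \code{lods_prostration_or_feed}), coma (Blantyre < 3,
#' Glasgow <= 8, or reported unconscious), and deep breathing. Missing
#' components count as absent; the number of patients with any missing
#' component is reported as a message for audit.
#'
#' @param patients validated patient table.
#' @return integer vector in 0..3.
#' @export
lods <- function(patients) {
  comp <- cbind(patients$lods_prostration_or_feed,
                patients$lods_coma,
                patients$lods_deep_breathing)
  n_missing <- sum(rowSums(is.na(comp)) > 0)
  if (n_missing > 0) {
    message(n_missing, " patient(s) with missing LODS component(s) scored as absent")
  }
  as.integer(rowSums(comp, na.rm = TRUE))
}

#' Malnutrition indicator
#'
#' Present when mid-upper arm circumference is under 12.5 cm (strict), the
#' weight-for-age Z-score is under -2 (strict), or comorbid malnutrition was
#' reported on intake. Missing fields contribute false.
#'
#' @param patients validated patient table.
#' @return logical vector.
#' @export
malnutrition <- function(patients) {
  (!is.na(patients$muac_cm) & patients$muac_cm < 12.5) |
    (!is.na(patients$waz) & patients$waz < -2) |
    (patients$reported_malnutrition %in% TRUE)
}

#' PARDS trigger assignment
#'
#' Scans the coded final diagnoses for PARDS triggers (pneumonia,
#' bronchiolitis, COVID-19, sepsis, trauma, aspiration, drowning, other
#' shock). Pneumonia/bronchiolitis/COVID-19 collapse to LRTI;
#' aspiration/drowning/other shock collapse to OTHER. Multi-trigger patients
#' take a single primary group by the configured precedence
#' (default LRTI > SEPSIS > TRAUMA > OTHER); the raw trigger set is retained.
#' Unknown diagnosis codes raise a warning and are treated as non-triggers.
#'
#' @param patients validated patient table; \code{final_diagnoses} holds
#'   semicolon-separated codes.
#' @param config run configuration.
#' @return data frame with \code{has_trigger}, \code{trigger_group}
#'   (\code{LRTI/SEPSIS/TRAUMA/OTHER/NONE}) and \code{raw_triggers}
#'   (semicolon-joined), one row per patient.
#' @export
assign_trigger <- function(patients, config = default_config()) {
  dx_list <- strsplit(ifelse(is.na(patients$final_diagnoses), "",
                             patients$final_diagnoses), ";", fixed = TRUE)
  dx_list <- lapply(dx_list, function(d) trimws(d[d != ""]))
  unknown <- setdiff(unique(unlist(dx_list)), known_diagnoses())
  if (length(unknown)) {
    warning("unknown diagnosis code(s) treated as non-triggers: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  group_of <- c(pneumonia = "LRTI", bronchiolitis = "LRTI", covid19 = "LRTI",
                sepsis = "SEPSIS", trauma = "TRAUMA",
                aspiration = "OTHER", drowning = "OTHER", other_shock = "OTHER")
  res <- lapply(dx_list, function(d) {
    raw <- intersect(d, names(group_of))
    groups <- unique(unname(group_of[raw]))
    primary <- config$trigger_precedence[config$trigger_precedence %in% groups][1]
    list(has = length(raw) > 0L,
         group = if (length(raw)) primary else "NONE",
         raw = paste(raw, collapse = ";"))
  })
  data.frame(
    has_trigger = vapply(res, `[[`, logical(1), "has"),
    trigger_group = vapply(res, `[[`, character(1), "group"),
    raw_triggers = vapply(res, `[[`, character(1), "raw"),
    stringsAsFactors = FALSE
  )
}
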