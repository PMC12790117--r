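# Operationalized PALICC-2 assessment: saturation-based oxygenation metrics,
# a data-sufficiency (eligibility) screen per category, and the cascade
# PARDS -> Possible PARDS -> At-risk. Blood-gas pathways (PaO2/FiO2, OI) are
# deliberately absent: the case-report data carry no blood gases, so
# oxygenation impairment rests on pulse-oximetry metrics alone.

#' SpO2/FiO2 (S/F) ratio
#'
#' Defined only while the pulse-oximetry signal is informative: above an SpO2
#' of 97% the oxyhemoglobin dissociation curve flattens and the ratio is
#' returned as \code{NA}.
#'
#' @param spo2_pct oxygen saturation, percent (0, 100].
#' @param fio2_fraction inspired oxygen fraction in [0.21, 1.0]; out-of-range
#'   values are an error.
#' @param config run configuration (ceiling default 97, inclusive).
#' @return numeric vector; \code{NA} where undefined.
#' @export
#' @examples
#' sf_ratio(88, 0.40)  # 220
sf_ratio <- function(spo2_pct, fio2_fraction, config = default_config()) {
  bad <- !is.na(fio2_fraction) & (fio2_fraction < 0.21 | fio2_fraction > 1)
  if (any(bad)) stop("fio2 outside [0.21, 1.0]: ",
                     paste(fio2_fraction[bad], collapse = ", "))
  out <- spo2_pct / fio2_fraction
  out[is.na(spo2_pct) | spo2_pct > config$spo2_sf_ceiling] <- NA_real_
  out
}

#' Oxygenation saturation index (OSI)
#'
#' \code{FiO2 x MAP x 100 / SpO2}, with mean airway pressure (MAP) taken from
#' the capture 6 h after starting mechanical ventilation. Undefined when MAP
#' is missing or SpO2 exceeds the interpretability ceiling.
#'
#' @param fio2_fraction inspired oxygen fraction in [0.21, 1.0].
#' @param map_cmh2o mean airway pressure, cm H2O (> 0).
#' @param spo2_pct oxygen saturation, percent.
#' @param config run configuration.
#' @return numeric vector; \code{NA} where undefined.
#' @export
#' @examples
#' osi(0.60, 10, 90)  # ~6.67
osi <- function(fio2_fraction, map_cmh2o, spo2_pct, config = default_config()) {
  bad <- !is.na(fio2_fraction) & (fio2_fraction < 0.21 | fio2_fraction > 1)
  if (any(bad)) stop("fio2 outside [0.21, 1.0]: ",
                     paste(fio2_fraction[bad], collapse = ", "))
  out <- fio2_fraction * map_cmh2o * 100 / spo2_pct
  out[is.na(map_cmh2o) | is.na(spo2_pct) |
        spo2_pct > config$spo2_sf_ceiling] <- NA_real_
  out
}

#' Highest respiratory support over days 1-7
#'
#' Fixed severity order IMV > non-invasive positive pressure (CPAP/BiPAP,
#' reported as NIV) > HFNC > simple/low-flow oxygen > none. Patients with all
#' support observations missing are returned as NONE with a warning.
#'
#' @param patients validated patient table.
#' @return character vector in \code{{IMV, NIV, HFNC, SIMPLE_O2, NONE}}.
#' @export
support_stratum <- function(patients) {
  supp <- day_matrix(patients, "support")
  rk <- apply(supp, 1, function(s) {
    r <- support_rank(s)
    if (all(is.na(r))) -1 else max(r, na.rm = TRUE)
  })
  if (any(rk < 0)) {
    warning(sum(rk < 0), " patient(s) with no support observations; stratum NONE",
            call. = FALSE)
    rk[rk < 0] <- 0
  }
  c("NONE", "SIMPLE_O2", "HFNC", "NIV", "IMV")[rk + 1L]
}

# index (1..7) of the first day attaining the maximum support rank; NA when
# no support was ever recorded
peak_support_day <- function(patients) {
  supp <- day_matrix(patients, "support")
  apply(supp, 1, function(s) {
    r <- support_rank(s)
    if (all(is.na(r))) NA_integer_ else which.max(ifelse(is.na(r), -1, r))
  })
}

day_value <- function(patients, field, day) {
  m <- day_matrix(patients, field)
  out <- m[cbind(seq_len(nrow(m)), ifelse(is.na(day), 1L, day))]
  out[is.na(day)] <- NA
  out
}

# does the HFNC flow qualify as nasal high-flow support: >= per-kg minimum or
# the absolute minimum
hfnc_flow_qualifies <- function(flow, weight, config) {
  !is.na(flow) & ((!is.na(weight) & flow >= config$hfnc_flow_per_kg * weight) |
                    flow >= config$hfnc_flow_abs)
}

#' PALICC-2 assessment of trigger patients
#'
#' For each patient with a PARDS trigger, runs the data-sufficiency screen
#' for the three categories and then the exclusive cascade
#' PARDS -> Possible PARDS -> At-risk:
#' \itemize{
#' \item \strong{PARDS}: unattributed chest X-ray opacity, invasive
#'   mechanical ventilation, and OSI at or above the configured threshold.
#'   Airway pressures are not captured for non-invasive ventilation, so NIV
#'   patients cannot satisfy the positive-pressure arm and are at best
#'   eligible for the lower categories.
#' \item \strong{Possible PARDS}: nasal respiratory support (NIV via nasal
#'   interface, or HFNC at qualifying flow), S/F ratio at or below the
#'   configured threshold, and no chest X-ray obtained.
#' \item \strong{At-risk}: unattributed opacity plus flow-delivered oxygen
#'   meeting the weight-banded minimum flow, when no higher category is met.
#' }
#' A category is evaluable only when every field its rule reads is present
#' (and SpO2 is at or below the interpretability ceiling); the missing or
#' disqualifying fields are recorded per category as \code{category:field}
#' tokens. Patients with no evaluable category are NOT_CLASSIFIABLE. An
#' opacity attributed to atelectasis, cardiac failure, or fluid overload
#' negates the opacity clause; an unattributed opacity counts as acute
#' parenchymal disease.
#'
#' @param patients validated patient table (typically the hypoxemic cohort).
#' @param triggers trigger assignment from [assign_trigger()] (row-aligned);
#'   non-trigger patients are returned NOT_CLASSIFIABLE with reason
#'   \code{no_trigger}.
#' @param config run configuration.
#' @return data frame, one row per patient: \code{patient_id},
#'   \code{site_id}, \code{support_stratum}, \code{sf_ratio}, \code{osi},
#'   \code{eligible_full}, \code{eligible_possible}, \code{eligible_at_risk},
#'   \code{missing_fields} (semicolon-joined \code{category:field} tokens),
#'   \code{category}.
#' @export
evaluate_pards <- function(patients, triggers, config = default_config()) {
  stopifnot(nrow(patients) == nrow(triggers))
  n <- nrow(patients)
  stratum <- support_stratum(patients)
  day <- peak_support_day(patients)
  spo2 <- day_value(patients, "spo2_min", day)
  fio2 <- as.numeric(day_value(patients, "fio2", day))
  map <- as.numeric(day_value(patients, "map_cmh2o", day))
  iface <- day_value(patients, "interface", day)
  flow <- as.numeric(day_value(patients, "flow_lpm", day))
  spo2 <- as.numeric(spo2)

  sf <- sf_ratio(spo2, fio2, config)
  os <- osi(fio2, map, spo2, config)

  supp_all <- day_matrix(patients, "support")
  flow_all <- day_matrix(patients, "flow_lpm")
  flow_iface <- supp_all %in% c("SIMPLE_O2", "HFNC")
  dim(flow_iface) <- dim(supp_all)

  cxr_done <- patients$cxr_obtained %in% TRUE
  cxr_result <- cxr_done & !is.na(patients$cxr_opacity)
  opacity_ok <- cxr_result & patients$cxr_opacity %in% TRUE &
    !(patients$cxr_opacity_attributed_nonparenchymal %in% TRUE)
  min_flow <- min_flow_for_weight(patients$weight_kg, config)

  elig_full <- logical(n); elig_poss <- logical(n); elig_risk <- logical(n)
  met_pards <- logical(n); met_poss <- logical(n); met_risk <- logical(n)
  missing_fields <- character(n)

  for (i in seq_len(n)) {
    miss <- character(0)
    add <- function(tok) miss <<- c(miss, tok)
    spo2_usable <- !is.na(spo2[i]) && spo2[i] <= config$spo2_sf_ceiling

    # -- PARDS (full criteria): IMV only ------------------------------------
    if (!identical(stratum[i], "IMV")) {
      add("full:stratum_not_imv")
    } else {
      if (is.na(spo2[i])) add("full:spo2")
      else if (!spo2_usable) add("full:spo2_gt_ceiling")
      if (is.na(fio2[i])) add("full:fio2")
      if (is.na(map[i])) add("full:map")
      if (!cxr_done[i]) add("full:cxr")
      else if (!cxr_result[i]) add("full:cxr_result")
    }
    elig_full[i] <- identical(stratum[i], "IMV") && spo2_usable &&
      !is.na(fio2[i]) && !is.na(map[i]) && cxr_result[i]
    met_pards[i] <- elig_full[i] && opacity_ok[i] &&
      !is.na(os[i]) && os[i] >= config$osi_pards_threshold

    # -- Possible PARDS: nasal support, no CXR obtained ---------------------
    nasal_capable <- stratum[i] %in% c("NIV", "HFNC")
    nasal_qualifies <- FALSE
    if (!nasal_capable) {
      add("possible:stratum_not_nasal")
    } else {
      if (stratum[i] == "NIV") {
        if (is.na(iface[i])) add("possible:interface")
        else nasal_qualifies <- identical(iface[i], "NASAL")
      } else { # HFNC
        if (is.na(flow[i])) add("possible:flow")
        else if (is.na(patients$weight_kg[i]) &&
                   flow[i] < config$hfnc_flow_abs) add("possible:weight")
        else nasal_qualifies <- hfnc_flow_qualifies(flow[i],
                                                    patients$weight_kg[i],
                                                    config)
      }
      if (is.na(spo2[i])) add("possible:spo2")
      else if (!spo2_usable) add("possible:spo2_gt_ceiling")
      if (is.na(fio2[i])) add("possible:fio2")
      if (cxr_done[i] && !cxr_result[i]) add("possible:cxr_result")
    }
    elig_poss[i] <- nasal_capable && spo2_usable && !is.na(fio2[i]) &&
      !(cxr_done[i] && !cxr_result[i]) &&
      !any(miss %in% c("possible:interface", "possible:flow", "possible:weight"))
    met_poss[i] <- elig_poss[i] && nasal_qualifies && !cxr_done[i] &&
      !is.na(sf[i]) && sf[i] <= config$sf_possible_threshold

    # -- At-risk: opacity + flow-delivered oxygen at minimum flow -----------
    fi <- flow_iface[i, ] & !is.na(supp_all[i, ])
    has_flow_o2_day <- any(fi)
    flow_known <- fi & !is.na(flow_all[i, ])
    if (!cxr_done[i]) add("at_risk:cxr")
    else if (!cxr_result[i]) add("at_risk:cxr_result")
    if (!has_flow_o2_day) add("at_risk:no_flow_oxygen")
    else if (!any(flow_known)) add("at_risk:flow")
    else if (is.na(min_flow[i])) add("at_risk:weight")
    elig_risk[i] <- cxr_result[i] && any(flow_known) && !is.na(min_flow[i])
    met_risk[i] <- elig_risk[i] && opacity_ok[i] &&
      any(flow_all[i, flow_known] >= min_flow[i])

    missing_fields[i] <- paste(miss, collapse = ";")
  }

  category <- ifelse(met_pards, "PARDS",
              ifelse(met_poss, "POSSIBLE_PARDS",
              ifelse(met_risk, "AT_RISK",
              ifelse(elig_full | elig_poss | elig_risk,
                     "EVALUATED_NEGATIVE", "NOT_CLASSIFIABLE"))))

  # assessment is only defined for trigger patients
  no_trig <- !(triggers$has_trigger %in% TRUE)
  elig_full[no_trig] <- elig_poss[no_trig] <- elig_risk[no_trig] <- FALSE
  category[no_trig] <- "NOT_CLASSIFIABLE"
  missing_fields[no_trig] <- "no_trigger"

  data.frame(
    patient_id = patients$patient_id,
    site_id = patients$site_id,
    support_stratum = stratum,
    sf_ratio = sf,
    osi = os,
    eligible_full = elig_full,
    eligible_possible = elig_poss,
    eligible_at_risk = elig_risk,
    missing_fields = missing_fields,
    category = category,
    stringsAsFactors = FALSE
  )
}

#' Tabulate missing PARDS fields by support stratum (and SDI)
#'
#' Counts, for each field named in the assessments' \code{missing_fields}
#' tokens, how many patients lack it, split by support stratum; with a site
#' table, also split by SDI quintile.
#'
#' @param assessments output of [evaluate_pards()].
#' @param sites optional validated site table for the SDI breakdown.
#' @return list with \code{by_stratum} (field x stratum counts) and, when
#'   sites are supplied, \code{by_sdi} (field x SDI counts).
#' @export
missingness_report <- function(assessments, sites = NULL) {
  structural <- c("stratum_not_imv", "stratum_not_nasal", "no_flow_oxygen")
  toks <- strsplit(assessments$missing_fields, ";", fixed = TRUE)
  keep <- lapply(toks, function(t) {
    t <- t[t != "" & t != "no_trigger"]
    setdiff(unique(sub("^[a-z_]+:", "", t)), structural)
  })
  n_per <- lengths(keep)
  field <- unlist(keep)
  strat <- rep(assessments$support_stratum, n_per)
  fields_all <- sort(unique(field))
  strata_all <- c("IMV", "NIV", "HFNC", "SIMPLE_O2", "NONE")
  by_stratum <- table(factor(field, levels = fields_all),
                      factor(strat, levels = strata_all))
  names(dimnames(by_stratum)) <- c("field", "stratum")
  out <- list(by_stratum = by_stratum)
  if (!is.null(sites)) {
    m <- match(rep(assessments$site_id, n_per), sites$site_id)
    by_sdi <- table(factor(field, levels = fields_all),
                    factor(sites$sdi_quintile[m], levels = sdi_levels()))
    names(dimnames(by_sdi)) <- c("field", "sdi")
    out$by_sdi <- by_sdi
  }
  out
}
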