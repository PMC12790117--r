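# Synthetic clinical data in two modes:
#   * generate_cohort(): stochastic cohorts with configurable prevalences,
#     effect sizes and missingness, for property and parameter-recovery
#     tests;
#   * build_paper_fixture(): a deterministic dataset that reproduces, through
#     the pipeline's own classification logic (never pre-labelled
#     categories), the published marginal counts of the multicentre
#     hypoxemia study this package re-analyses.

# largest-remainder allocation of `total` into parts proportional to weights;
# ties broken by position
lr_alloc <- function(total, weights) {
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# k indices spread evenly over 1..n (distinct, increasing)
spread_idx <- function(n, k) {
  if (k == 0L) return(integer(0))
  floor((seq_len(k) - 1) * n / k) + 1L
}

# deterministic quantiles of a log-normal with given median and log-sd,
# clamped to a range: used for ages, weights, lengths of stay
lnorm_quantiles <- function(n, median, sdlog, lo = -Inf, hi = Inf) {
  if (n == 0L) return(numeric(0))
  q <- stats::qlnorm(stats::ppoints(n), meanlog = log(median), sdlog = sdlog)
  pmin(pmax(round(q, 2), lo), hi)
}

smallest_passing <- function(n_total, threshold) {
  thr_pct <- round(threshold * 100)
  ceiling(thr_pct * n_total / 100)
}

# realize atomic survey responses for one item so that its availability is
# `avail`; `pick` supplies level choices (random or deterministic)
realize_item <- function(item, avail, bundle_def, pick_avail, pick_unavail) {
  if (item %in% names(bundle_def$composites)) {
    cdef <- bundle_def$composites[[item]]
    k <- length(cdef$of)
    if (avail) {
      if (cdef$rule == "all") {
        lv <- pick_avail(k)
      } else {
        lv <- pick_unavail(k)
        lv[1L] <- pick_avail(1L)
      }
    } else {
      lv <- pick_unavail(k)
      if (cdef$rule == "all" && k > 1L) lv[1L] <- pick_avail(1L)  # AND broken by the rest
    }
    data.frame(item = cdef$of, level = lv, stringsAsFactors = FALSE)
  } else {
    data.frame(item = item,
               level = if (avail) pick_avail(1L) else pick_unavail(1L),
               stringsAsFactors = FALSE)
  }
}

build_survey <- function(site_id, n_avail_by_tier, bundle_def, config,
                         pick_avail, pick_unavail) {
  rows <- list()
  for (tier in names(bundle_def$tiers)) {
    items <- bundle_def$tiers[[tier]]
    k <- n_avail_by_tier[[tier]]
    avail_set <- seq_len(k)  # first k items of the tier available
    for (j in seq_along(items)) {
      rows[[length(rows) + 1L]] <- realize_item(
        items[j], j %in% avail_set, bundle_def, pick_avail, pick_unavail)
    }
  }
  out <- do.call(rbind, rows)
  lv_names <- names(likert_levels())
  data.frame(site_id = site_id, item = out$item,
             response = ifelse(is.na(out$level), NA_character_,
                               lv_names[out$level]),
             level = out$level, stringsAsFactors = FALSE)
}

#' Generate a site survey that classifies to a target tier
#'
#' Draws Likert responses (using the current RNG state) such that every tier
#' at or below the target passes the availability threshold, the next tier
#' up fails it, and higher tiers are arbitrary: [classify_sites()] recovers
#' the target tier by construction.
#'
#' @param target_tier one of NONE, BASIC, INTERMEDIATE, ADVANCED, EXPERT.
#' @param bundle_def a \code{bundle_definition}.
#' @param config run configuration.
#' @param site_id identifier for the generated survey.
#' @return survey data frame as from [read_site_surveys()].
#' @export
generate_site_survey <- function(target_tier,
                                 bundle_def = default_bundle_definition(),
                                 config = default_config(),
                                 site_id = "S1") {
  tiers <- names(bundle_def$tiers)
  target_tier <- match.arg(target_tier, bundle_tiers())
  target_i <- match(target_tier, bundle_tiers()) - 1L  # 0 = NONE
  avail_levels <- available_level_set(config)
  low_levels <- setdiff(seq_along(likert_levels()), avail_levels)
  pick_avail <- function(k) sample(avail_levels, k, replace = TRUE)
  pick_unavail <- function(k) {
    lv <- sample(c(low_levels, NA_integer_), k, replace = TRUE)
    as.integer(lv)
  }
  pick1 <- function(v) v[sample.int(length(v), 1L)]  # safe for length-1 v
  n_avail <- list()
  for (i in seq_along(tiers)) {
    n_tot <- length(bundle_def$tiers[[i]])
    need <- smallest_passing(n_tot, config$bundle_threshold)
    n_avail[[tiers[i]]] <-
      if (i <= target_i) pick1(need:n_tot)
      else if (i == target_i + 1L) pick1(0:(need - 1L))
      else pick1(0:n_tot)
  }
  build_survey(site_id, n_avail, bundle_def, config, pick_avail, pick_unavail)
}

#' Parameters for the stochastic cohort generator
#'
#' Defaults mirror the observed study conditions: 46 sites with tier mix
#' (3, 11, 13, 16, 3)/46, hypoxemia prevalence 10.1%, trigger prevalence
#' 56.3% among hypoxemic children, and a mortality logit whose exposure
#' coefficient for low-resource care is log(18) with baseline mortality
#' matching the advanced/expert stratum. Field-level missingness increases
#' with decreasing SDI.
#'
#' @param n_sites,n_patients dataset dimensions.
#' @param tier_distribution probabilities over the five tiers (sums to 1).
#' @param hypoxemia_prevalence probability a patient is hypoxemic.
#' @param trigger_prevalence_given_hypoxemia probability of a PARDS trigger
#'   among hypoxemic patients.
#' @param mortality_logit named coefficients: \code{intercept},
#'   \code{low_resource}, \code{trigger}, \code{age_le5},
#'   \code{malnutrition}, \code{lods_gt0}.
#' @param missingness named list of per-field missingness probabilities by
#'   SDI quintile (low, low_middle, middle, high_middle).
#' @param admitted_prob_no_hypoxemia admission probability for non-hypoxemic
#'   patients.
#' @param seed integer RNG seed.
#' @return list of class \code{"generator_params"}.
#' @export
default_generator_params <- function(
    n_sites = 46L,
    n_patients = 7538L,
    tier_distribution = c(NONE = 3, BASIC = 11, INTERMEDIATE = 13,
                          ADVANCED = 16, EXPERT = 3) / 46,
    hypoxemia_prevalence = 0.101,
    trigger_prevalence_given_hypoxemia = 430 / 763,
    mortality_logit = c(intercept = -4.75, low_resource = log(18),
                        trigger = log(0.56), age_le5 = -0.3,
                        malnutrition = log(2), lods_gt0 = log(2)),
    missingness = list(
      fio2 = c(0.95, 0.90, 0.80, 0.70),
      map = c(0.90, 0.85, 0.75, 0.65),
      interface = c(0.80, 0.70, 0.60, 0.50),
      flow = c(0.85, 0.80, 0.70, 0.60),
      weight = c(0.15, 0.12, 0.08, 0.05)
    ),
    admitted_prob_no_hypoxemia = 0.28,
    seed = 20260101L) {
  stopifnot(abs(sum(tier_distribution) - 1) < 1e-8,
            hypoxemia_prevalence >= 0, hypoxemia_prevalence <= 1,
            trigger_prevalence_given_hypoxemia >= 0,
            trigger_prevalence_given_hypoxemia <= 1,
            all(vapply(missingness, function(p) all(p >= 0 & p <= 1),
                       logical(1))))
  if (hypoxemia_prevalence == 0 &&
      any(mortality_logit[c("trigger")] != 0) &&
      trigger_prevalence_given_hypoxemia > 0) {
    # triggers only arise within the hypoxemic stratum
  }
  structure(as.list(environment()), class = "generator_params")
}

empty_patient_frame <- function(n) {
  dict <- patient_dictionary()
  out <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(dict))) {
    out[[dict$column[i]]] <- switch(dict$type[i],
      numeric = rep(NA_real_, n),
      logical = rep(NA, n),
      rep(NA_character_, n))
  }
  out
}

#' Generate a stochastic synthetic cohort
#'
#' Draws sites (tier mix then SDI correlated with tier), per-site surveys
#' that classify back to the drawn tier, and patients whose hypoxemia,
#' trigger, severity scores and death follow the configured Bernoulli/logit
#' structure. Field-level missingness is applied by SDI. Every record
#' validates under the packaged data dictionary, and output is fully
#' reproducible from the seed.
#'
#' @param params a \code{generator_params} list.
#' @param config run configuration.
#' @return list with \code{sites}, \code{surveys}, \code{patients} data
#'   frames and a \code{manifest} (seed and key parameters).
#' @export
generate_cohort <- function(params = default_generator_params(),
                            config = default_config()) {
  set.seed(params$seed)
  tiers <- bundle_tiers()
  n_sites <- params$n_sites

  site_tier <- sample(tiers, n_sites, replace = TRUE,
                      prob = params$tier_distribution)
  high_tier <- site_tier %in% c("ADVANCED", "EXPERT")
  sdi <- character(n_sites)
  sdi[high_tier] <- sample(sdi_levels(), sum(high_tier), replace = TRUE,
                           prob = c(0.05, 0.06, 0.49, 0.40))
  sdi[!high_tier] <- sample(sdi_levels(), sum(!high_tier), replace = TRUE,
                            prob = c(0.45, 0.35, 0.15, 0.05))
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    country = sprintf("C%02d", sample(19, n_sites, replace = TRUE)),
    sdi_quintile = sdi,
    gbd_region = sample(gbd_regions(), n_sites, replace = TRUE,
                        prob = c(0.39, 0.17, 0.30, 0.06, 0.05, 0.03)),
    urban = stats::runif(n_sites) < 0.89,
    academic = stats::runif(n_sites) < 0.72,
    census_gt50 = stats::runif(n_sites) < 0.39,
    picu = stats::runif(n_sites) < 0.65,
    intensivist_weekday = stats::runif(n_sites) < 0.54,
    stringsAsFactors = FALSE
  )
  surveys <- do.call(rbind, lapply(seq_len(n_sites), function(i)
    generate_site_survey(site_tier[i], default_bundle_definition(), config,
                         site_id = sites$site_id[i])))
  low_resource_site <- !high_tier

  n <- params$n_patients
  pat <- empty_patient_frame(n)
  s_idx <- sample(n_sites, n, replace = TRUE)
  pat$patient_id <- sprintf("P%05d", seq_len(n))
  pat$site_id <- sites$site_id[s_idx]
  sdi_idx <- match(sites$sdi_quintile[s_idx], sdi_levels())

  hyp <- stats::runif(n) < params$hypoxemia_prevalence
  trig <- hyp & (stats::runif(n) < params$trigger_prevalence_given_hypoxemia)

  pat$age_years <- pmin(pmax(round(stats::rlnorm(n, log(1.9), 1.1), 2),
                             29 / 365), 14)
  pat$sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.44, 0.56))
  weight <- round(stats::rlnorm(n, log(10), 0.5), 1)
  pat$weight_kg <- pmin(pmax(weight, 1), 80)
  pat$admission_spo2_pct <- round(pmin(pmax(
    stats::rnorm(n, ifelse(hyp, 93, 97), 3), 60), 100))
  maln <- stats::runif(n) < 0.26
  pat$muac_cm <- round(ifelse(maln, stats::runif(n, 9, 12.4),
                              stats::runif(n, 12.6, 17)), 1)
  pat$waz <- round(ifelse(maln, stats::runif(n, -4, -2.1),
                          stats::runif(n, -1.9, 2)), 2)
  pat$reported_malnutrition <- maln & stats::runif(n) < 0.3
  pat$cyanotic_chd <- FALSE
  pat$prior_pulmonary_disease <- stats::runif(n) < 0.03
  lods_p <- stats::runif(n) < ifelse(trig, 0.35, 0.2)
  lods_c <- stats::runif(n) < 0.1
  lods_d <- stats::runif(n) < ifelse(hyp, 0.3, 0.1)
  pat$lods_prostration_or_feed <- lods_p
  pat$lods_coma <- lods_c
  pat$lods_deep_breathing <- lods_d

  trig_dx <- sample(c("pneumonia", "bronchiolitis", "sepsis", "covid19",
                      "trauma", "aspiration", "drowning", "other_shock"),
                    n, replace = TRUE,
                    prob = c(0.55, 0.25, 0.12, 0.02, 0.02, 0.02, 0.01, 0.01))
  other_dx <- sample(c("malaria", "gastroenteritis", "meningitis",
                       "status_epilepticus", "asthma"), n, replace = TRUE)
  pat$final_diagnoses <- ifelse(trig, trig_dx, other_dx)

  # respiratory support for hypoxemic patients; everyone else unexposed
  supp <- rep("NONE", n)
  supp[hyp] <- sample(c("SIMPLE_O2", "HFNC", "CPAP", "BIPAP", "IMV", "NONE"),
                      sum(hyp), replace = TRUE,
                      prob = c(0.72, 0.08, 0.05, 0.03, 0.1, 0.02))
  pat$d1_support <- supp
  pat$d1_spo2_min <- round(ifelse(hyp & supp == "NONE",
                                  stats::runif(n, 75, 87.9),
                                  ifelse(hyp, stats::runif(n, 80, 96),
                                         stats::runif(n, 92, 99))))
  keep_field <- function(field) {
    stats::runif(n) >= vapply(sdi_idx, function(k)
      params$missingness[[field]][k], numeric(1))
  }
  on_o2 <- supp != "NONE"
  kf2 <- on_o2 & keep_field("fio2")
  pat$d1_fio2[kf2] <- round(stats::runif(sum(kf2), 0.25, 1), 2)
  flow_if <- supp %in% c("SIMPLE_O2", "HFNC")
  kf <- flow_if & keep_field("flow")
  pat$d1_flow_lpm[kf] <- round(stats::runif(sum(kf), 0.5, 40), 1)
  niv <- supp %in% c("CPAP", "BIPAP")
  ki <- niv & keep_field("interface")
  pat$d1_interface[ki] <- sample(c("NASAL", "FULL_FACE"), sum(ki),
                                 replace = TRUE)
  pat$d1_interface[supp == "IMV"] <- "INVASIVE"
  km <- supp == "IMV" & keep_field("map")
  pat$d1_map_cmh2o[km] <- round(stats::runif(sum(km), 6, 25), 1)
  kw <- !keep_field("weight")
  pat$weight_kg[kw] <- NA_real_
  pat$cxr_obtained <- hyp & stats::runif(n) < 0.3
  pat$cxr_opacity[pat$cxr_obtained] <- (stats::runif(n) < 0.5)[pat$cxr_obtained]
  pat$cxr_opacity_attributed_nonparenchymal[pat$cxr_opacity %in% TRUE] <-
    (stats::runif(n) < 0.15)[pat$cxr_opacity %in% TRUE]
  pat$sedation_gt4h <- supp == "IMV"
  pat$vasoactives <- hyp & stats::runif(n) < 0.08

  eta <- params$mortality_logit["intercept"] +
    params$mortality_logit["low_resource"] * low_resource_site[s_idx] +
    params$mortality_logit["trigger"] * trig +
    params$mortality_logit["age_le5"] * (pat$age_years <= 5) +
    params$mortality_logit["malnutrition"] * maln +
    params$mortality_logit["lods_gt0"] * (lods_p | lods_c | lods_d)
  died <- hyp & (stats::runif(n) < stats::plogis(eta))
  died[!hyp] <- (stats::runif(n) < 0.008)[!hyp]
  pat$died <- died
  pat$died_in_ed <- FALSE
  pat$admitted <- hyp | died | (stats::runif(n) < params$admitted_prob_no_hypoxemia)
  surv_adm <- pat$admitted & !died
  pat$los_days[surv_adm] <- round(stats::rlnorm(sum(surv_adm), log(3.25), 0.7), 1)

  list(sites = sites, surveys = surveys, patients = pat,
       manifest = list(seed = params$seed,
                       n_sites = n_sites, n_patients = n,
                       mortality_logit = params$mortality_logit))
}
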