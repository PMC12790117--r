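# Pipeline orchestration and the study's result surfaces: screening flow,
# group-comparison table, mortality by bundle tier, the PALICC-2 eligibility
# cascade, missingness tables, and both mortality models.

#' Score a hypoxemia cohort for analysis
#'
#' Joins the included cohort to its site bundle classification and site
#' attributes and appends the derived analysis columns: trigger assignment,
#' LODS, malnutrition, bundle tier and dichotomized group.
#'
#' @param included hypoxemic cohort rows from [screen_cohort()].
#' @param classifications site classifications from [classify_sites()].
#' @param sites validated site table.
#' @param config run configuration.
#' @return the cohort data frame with columns \code{has_trigger},
#'   \code{trigger_group}, \code{raw_triggers}, \code{lods},
#'   \code{malnourished}, \code{bundle_tier}, \code{bundle_group},
#'   \code{sdi_quintile}, \code{gbd_region} appended.
#' @export
score_cohort <- function(included, classifications, sites,
                         config = default_config()) {
  mC <- match(included$site_id, classifications$site_id)
  mS <- match(included$site_id, sites$site_id)
  if (anyNA(mC) || anyNA(mS)) {
    stop("join error: cohort site_id(s) missing from classifications or sites: ",
         paste(unique(included$site_id[is.na(mC) | is.na(mS)]), collapse = ", "))
  }
  trg <- assign_trigger(included, config)
  out <- cbind(included, trg)
  out$lods <- lods(included)
  out$malnourished <- malnutrition(included)
  out$bundle_tier <- classifications$assigned_tier[mC]
  out$bundle_group <- classifications$group[mC]
  out$sdi_quintile <- sites$sdi_quintile[mS]
  out$gbd_region <- sites$gbd_region[mS]
  out
}

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
}

fmt_n_pct <- function(k, n) sprintf("%d (%.3g)", k, 100 * k / n)

#' Cohort characteristics by trigger group
#'
#' Median (IQR) for continuous variables with Wilcoxon rank-sum p-values;
#' n (percent) for categorical variables with Pearson chi-square p-values
#' (omnibus over all levels for multi-level factors).
#'
#' @param cohort scored cohort from [score_cohort()]; both trigger groups
#'   must be non-empty.
#' @param config run configuration.
#' @return data frame with columns \code{variable}, \code{total},
#'   \code{trigger}, \code{no_trigger}, \code{p_value}, \code{test}.
#' @export
table1 <- function(cohort, config = default_config()) {
  g <- cohort$has_trigger %in% TRUE
  if (!any(g) || !any(!g)) stop("both trigger groups must be non-empty")
  rows <- list()
  cont <- function(label, x) {
    w <- wilcoxon_rank_sum(x[g & !is.na(x)], x[!g & !is.na(x)])
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = label, total = fmt_median_iqr(x),
      trigger = fmt_median_iqr(x[g]), no_trigger = fmt_median_iqr(x[!g]),
      p_value = w$p_value, test = "wilcoxon", stringsAsFactors = FALSE)
  }
  cat2 <- function(label, flag) {
    tab <- rbind(c(sum(flag & g), sum(!flag & g)),
                 c(sum(flag & !g), sum(!flag & !g)))
    p <- tryCatch(chi_square(t(tab))$p_value, error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = label, total = fmt_n_pct(sum(flag), length(flag)),
      trigger = fmt_n_pct(sum(flag & g), sum(g)),
      no_trigger = fmt_n_pct(sum(flag & !g), sum(!g)),
      p_value = p, test = "chi-square", stringsAsFactors = FALSE)
  }
  omnibus <- function(label, f) {
    tab <- table(factor(f), factor(ifelse(g, "trigger", "no_trigger")))
    p <- tryCatch(chi_square(as.matrix(tab))$p_value,
                  error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = label, total = "", trigger = "", no_trigger = "",
      p_value = p, test = "chi-square (omnibus)", stringsAsFactors = FALSE)
  }
  cont("age_years", cohort$age_years)
  cat2("female", cohort$sex %in% "F")
  cont("weight_kg", cohort$weight_kg)
  cont("admission_spo2_pct", cohort$admission_spo2_pct)
  cat2("malnutrition", cohort$malnourished %in% TRUE)
  cont("lods", cohort$lods)
  omnibus("gbd_region", cohort$gbd_region)
  omnibus("sdi_quintile", cohort$sdi_quintile)
  out <- do.call(rbind, rows)
  attr(out, "group_n") <- c(trigger = sum(g), no_trigger = sum(!g))
  out
}

#' Mortality by resource bundle tier
#'
#' Per-tier deaths/patients/percent plus the dichotomized 2x2 table
#' (intermediate-or-less vs advanced-or-expert) feeding [odds_ratio()].
#'
#' @param cohort cohort rows with \code{site_id} and \code{died}.
#' @param classifications site classifications; every cohort site must join.
#' @return list with \code{by_tier} (5-row data frame in ascending tier
#'   order) and \code{dichotomized} (2x2 matrix: rows exposed
#'   low-resource / unexposed, columns died / survived).
#' @export
mortality_by_bundle <- function(cohort, classifications) {
  m <- match(cohort$site_id, classifications$site_id)
  if (anyNA(m)) {
    stop("join error: cohort site_id(s) without classification: ",
         paste(unique(cohort$site_id[is.na(m)]), collapse = ", "))
  }
  tier <- factor(classifications$assigned_tier[m], levels = bundle_tiers())
  died <- cohort$died %in% TRUE
  n <- as.vector(table(tier))
  d <- as.vector(table(tier[died]))
  by_tier <- data.frame(tier = bundle_tiers(), patients = n, deaths = d,
                        pct_mortality = ifelse(n > 0, 100 * d / n, NA_real_),
                        stringsAsFactors = FALSE)
  low <- tier %in% c("NONE", "BASIC", "INTERMEDIATE")
  dich <- matrix(c(sum(low & died), sum(low & !died),
                   sum(!low & died), sum(!low & !died)),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("INTERMEDIATE_OR_LESS", "ADVANCED_OR_EXPERT"),
                                 c("died", "survived")))
  list(by_tier = by_tier, dichotomized = dich)
}

#' Length of stay among admitted survivors, by trigger group
#'
#' @param cohort scored cohort (needs \code{los_days}, \code{died},
#'   \code{admitted}, \code{has_trigger}).
#' @return list with per-group \code{median}, \code{iqr}, group sizes, and
#'   the Wilcoxon rank-sum \code{p_value}.
#' @export
los_comparison <- function(cohort) {
  keep <- cohort$admitted %in% TRUE & !(cohort$died %in% TRUE) &
    !is.na(cohort$los_days)
  if (!any(keep)) stop("no admitted survivors with recorded length of stay")
  x <- cohort$los_days[keep & cohort$has_trigger %in% TRUE]
  y <- cohort$los_days[keep & !(cohort$has_trigger %in% TRUE)]
  if (!length(x) || !length(y)) stop("a trigger group has no surviving stays")
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  w <- wilcoxon_rank_sum(x, y)
  list(trigger = list(n = length(x), median = qs(x)[2], iqr = qs(x)[c(1, 3)]),
       no_trigger = list(n = length(y), median = qs(y)[2], iqr = qs(y)[c(1, 3)]),
       p_value = w$p_value)
}

cascade_counts <- function(assessments, triggers) {
  trig <- triggers$has_trigger %in% TRUE
  a <- assessments[trig, , drop = FALSE]
  c(
    n_trigger = nrow(a),
    any_eligible = sum(a$eligible_full | a$eligible_possible | a$eligible_at_risk),
    not_classifiable = sum(a$category == "NOT_CLASSIFIABLE"),
    full_evaluable = sum(a$eligible_full),
    pards = sum(a$category == "PARDS"),
    possible_evaluable = sum(a$eligible_possible),
    possible = sum(a$category == "POSSIBLE_PARDS"),
    at_risk_evaluable = sum(a$eligible_at_risk),
    at_risk = sum(a$category == "AT_RISK")
  )
}

# p-value presentation convention: two significant figures, "<0.001" floor
format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "<0.001", signif(p, 2)))
}

#' Run the full analysis pipeline
#'
#' Executes read/validate -> bundle classification -> cohort screening ->
#' scores -> PALICC-2 assessment -> statistics in order, cross-checks that
#' the assembled counts reconcile, and (optionally) writes every result
#' table. Deterministic for fixed inputs and configuration.
#'
#' @param data either a list with \code{sites}, \code{surveys},
#'   \code{patients} data frames (e.g. from [build_paper_fixture()] or
#'   [generate_cohort()]) or a named list of file paths
#'   (\code{patients}, \code{sites}, \code{surveys}) to read.
#' @param config run configuration.
#' @param outdir optional directory for artifact files (flow.json,
#'   table1.csv, mortality_by_bundle.csv, pards_cascade.csv,
#'   missingness.csv, fit_bundle.json, fit_trigger.json, manifest.json).
#' @param bundle_def bundle definition (default packaged).
#' @return list of class \code{"respaudit_run"}: screening \code{flow},
#'   \code{classifications}, \code{tier_sdi}, scored \code{cohort},
#'   \code{table1}, \code{mortality} (by tier + dichotomized +
#'   \code{or}), \code{cascade}, \code{missingness}, \code{fit_bundle},
#'   \code{fit_trigger}, \code{los}.
#' @export
run_all <- function(data, config = default_config(), outdir = NULL,
                    bundle_def = default_bundle_definition()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(data$patients) && is.character(data$patients)) {
    data <- stage("read", list(
      patients = read_patients(data$patients),
      sites = read_sites(data$sites),
      surveys = read_site_surveys(data$surveys, bundle_def)))
  }
  for (nm in c("patients", "sites", "surveys")) {
    if (is.null(data[[nm]])) stop("stage 'read': missing input '", nm, "'")
  }

  cls <- stage("bundles", classify_sites(data$surveys, bundle_def, config))
  tier_sdi <- stage("bundles", summarize_bundles_by_sdi(cls, data$sites))
  scr <- stage("cohort", screen_cohort(data$patients, config))
  cohort <- stage("scores",
                  score_cohort(scr$included, cls, data$sites, config))
  triggers <- cohort[, c("has_trigger", "trigger_group", "raw_triggers")]
  assess <- stage("pards", evaluate_pards(cohort, triggers, config))
  cascade <- cascade_counts(assess, triggers)
  miss <- missingness_report(assess, data$sites)
  tb1 <- stage("stats", table1(cohort, config))
  mort <- stage("stats", mortality_by_bundle(cohort, cls))
  mort$or <- odds_ratio(as.vector(t(mort$dichotomized)), config)
  fit_b <- stage("stats",
                 fit_bundle_mortality_model(cohort, cls, data$sites, config))
  fit_t <- stage("stats", fit_trigger_mortality_model(cohort, config))
  los <- stage("stats", los_comparison(cohort))

  # assembly reconciliation
  stopifnot(
    sum(mort$by_tier$patients) == nrow(cohort),
    sum(mort$by_tier$deaths) == sum(cohort$died %in% TRUE),
    sum(mort$dichotomized) == nrow(cohort),
    identical(sum(mort$dichotomized[1, ]),
              sum(mort$by_tier$patients[1:3])),
    cascade[["any_eligible"]] + cascade[["not_classifiable"]] ==
      cascade[["n_trigger"]],
    sum(cohort$has_trigger) + sum(!cohort$has_trigger) == nrow(cohort)
  )

  out <- structure(list(
    flow = scr$flow, classifications = cls, tier_sdi = tier_sdi,
    cohort = cohort, table1 = tb1, mortality = mort, cascade = cascade,
    missingness = miss, fit_bundle = fit_b, fit_trigger = fit_t, los = los,
    config = config
  ), class = "respaudit_run")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(as.list(scr$flow), file.path(outdir, "flow.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    tb1_out <- tb1
    tb1_out$p_value <- format_p(tb1_out$p_value)
    write_table(tb1_out, file.path(outdir, "table1.csv"))
    write_table(mort$by_tier, file.path(outdir, "mortality_by_bundle.csv"))
    write_table(data.frame(measure = names(cascade), n = as.vector(cascade)),
                file.path(outdir, "pards_cascade.csv"))
    write_table(as.data.frame.matrix(miss$by_stratum),
                file.path(outdir, "missingness.csv"))
    fit_json <- function(f) list(
      exposure = f$exposure,
      unadjusted = list(or = unname(f$exposure_or["unadjusted", "or"]),
                        ci = unname(f$exposure_or["unadjusted", 2:3]),
                        converged = f$unadjusted$converged,
                        n_iter = f$unadjusted$n_iter),
      adjusted = list(or = unname(f$exposure_or["adjusted", "or"]),
                      ci = unname(f$exposure_or["adjusted", 2:3]),
                      converged = f$adjusted$converged,
                      n_iter = f$adjusted$n_iter,
                      coefficients = as.list(coef(f$adjusted))))
    jsonlite::write_json(fit_json(fit_b), file.path(outdir, "fit_bundle.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(fit_json(fit_t), file.path(outdir, "fit_trigger.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(seed = config$seed, ci_level = config$ci_level,
           bundle_threshold = config$bundle_threshold,
           n_patients = nrow(data$patients), n_sites = nrow(data$sites)),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.respaudit_run <- function(x, ...) {
  f <- x$flow
  cat("Hypoxemia cohort analysis\n")
  cat(sprintf("  enrolled %d; hypoxemic included %d (%.1f%%); deaths %d (%.1f%%)\n",
              f[["n_enrolled"]], f[["n_hypoxemic_included"]],
              100 * f[["n_hypoxemic_included"]] / f[["n_enrolled"]],
              f[["deaths_hypoxemic"]],
              100 * f[["deaths_hypoxemic"]] / f[["n_hypoxemic_included"]]))
  cat("  site tiers:", paste(sprintf("%s=%d", x$mortality$by_tier$tier,
                                     table(factor(x$classifications$assigned_tier,
                                                  levels = bundle_tiers()))),
                             collapse = " "), "\n")
  cat("  mortality by tier:\n")
  print(x$mortality$by_tier, row.names = FALSE)
  or <- x$mortality$or
  cat(sprintf("  low- vs high-resource OR %.2f (%d%% CI %.2f-%.2f)\n",
              or$or, round(100 * x$config$ci_level), or$ci_low, or$ci_high))
  cat("  PALICC-2 cascade:",
      paste(sprintf("%s=%d", names(x$cascade), x$cascade), collapse = " "), "\n")
  invisible(x)
}
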