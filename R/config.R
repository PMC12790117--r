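#' Run configuration for cohort screening, bundle scoring and PARDS assessment
#'
#' Collects every tunable threshold used across the pipeline in one validated
#' list so that analyses are reproducible from a single object.
#'
#' @param likert_available_levels Likert labels counted as "available"
#'   (default \code{c("often", "always")}).
#' @param bundle_threshold Fraction of a tier's items that must be available
#'   for the tier to count as available; inclusive (default 0.80).
#' @param spo2_hypoxemia_cutoff Hypoxemia SpO2 cutoff in percent; the
#'   comparison is a strict less-than (default 88).
#' @param spo2_sf_ceiling Highest SpO2 (percent) at which saturation-based
#'   oxygenation metrics (S/F ratio, OSI) are interpretable; inclusive upper
#'   bound (default 97; the oxyhemoglobin dissociation curve flattens above).
#' @param sf_possible_threshold S/F ratio at or below which the oxygenation
#'   criterion for Possible PARDS is met (default 250).
#' @param osi_pards_threshold Oxygenation saturation index at or above which
#'   an invasively ventilated patient meets PARDS oxygenation criteria
#'   (default 5).
#' @param hfnc_flow_per_kg,hfnc_flow_abs Minimum high-flow nasal cannula flow
#'   for nasal-support criteria: at least \code{hfnc_flow_per_kg} L/min/kg or
#'   \code{hfnc_flow_abs} L/min in absolute terms (defaults 1.5 and 30).
#' @param min_flow_table Weight-banded minimum acceptable oxygen flow (L/min)
#'   for the At-risk oxygen-supplementation criterion: a data frame with
#'   columns \code{weight_max_kg} (ascending, last \code{Inf}) and
#'   \code{flow_lpm}.
#' @param trigger_precedence Priority order used to collapse multiple raw
#'   PARDS triggers to a single analysis group.
#' @param ci_level Confidence level for all intervals (default 0.95).
#' @param seed Integer seed recorded with generated data.
#'
#' @return A list of class \code{"respaudit_config"}.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$bundle_threshold
default_config <- function(likert_available_levels = c("often", "always"),
                           bundle_threshold = 0.80,
                           spo2_hypoxemia_cutoff = 88,
                           spo2_sf_ceiling = 97,
                           sf_possible_threshold = 250,
                           osi_pards_threshold = 5,
                           hfnc_flow_per_kg = 1.5,
                           hfnc_flow_abs = 30,
                           min_flow_table = default_min_flow_table(),
                           trigger_precedence = c("LRTI", "SEPSIS", "TRAUMA", "OTHER"),
                           ci_level = 0.95,
                           seed = 1L) {
  stopifnot(
    all(likert_available_levels %in% names(likert_levels())),
    is.numeric(bundle_threshold), length(bundle_threshold) == 1L,
    bundle_threshold > 0, bundle_threshold <= 1,
    spo2_hypoxemia_cutoff > 0, spo2_hypoxemia_cutoff <= 100,
    spo2_sf_ceiling > 0, spo2_sf_ceiling <= 100,
    sf_possible_threshold > 0,
    osi_pards_threshold > 0,
    ci_level > 0, ci_level < 1
  )
  if (!is.data.frame(min_flow_table) ||
      !all(c("weight_max_kg", "flow_lpm") %in% names(min_flow_table)) ||
      is.unsorted(min_flow_table$weight_max_kg) ||
      !is.infinite(min_flow_table$weight_max_kg[nrow(min_flow_table)])) {
    stop("min_flow_table must have ascending weight_max_kg ending in Inf and a flow_lpm column")
  }
  structure(list(
    likert_available_levels = likert_available_levels,
    bundle_threshold = bundle_threshold,
    spo2_hypoxemia_cutoff = spo2_hypoxemia_cutoff,
    spo2_sf_ceiling = spo2_sf_ceiling,
    sf_possible_threshold = sf_possible_threshold,
    osi_pards_threshold = osi_pards_threshold,
    hfnc_flow_per_kg = hfnc_flow_per_kg,
    hfnc_flow_abs = hfnc_flow_abs,
    min_flow_table = min_flow_table,
    trigger_precedence = trigger_precedence,
    ci_level = ci_level,
    seed = as.integer(seed)
  ), class = "respaudit_config")
}

#' Default weight-banded minimum oxygen flow thresholds
#'
#' Minimum acceptable liter flow for the At-risk oxygen-supplementation
#' criterion, banded by body weight.
#'
#' @return data frame with columns \code{weight_max_kg}, \code{flow_lpm}.
#' @export
default_min_flow_table <- function() {
  data.frame(
    weight_max_kg = c(10, 20, 40, Inf),
    flow_lpm = c(2, 4, 6, 8)
  )
}

#' Look up the minimum qualifying oxygen flow for a body weight
#'
#' @param weight_kg numeric vector of weights (kg); \code{NA} allowed.
#' @param config run configuration (see [default_config()]).
#' @return numeric vector of minimum flows (L/min); \code{NA} where weight is
#'   missing.
#' @export
min_flow_for_weight <- function(weight_kg, config = default_config()) {
  tab <- config$min_flow_table
  idx <- findInterval(weight_kg, tab$weight_max_kg, left.open = TRUE) + 1L
  out <- tab$flow_lpm[idx]
  out[is.na(weight_kg)] <- NA_real_
  out
}

#' Likert response levels
#'
#' The 5-point availability scale used on facility resource surveys.
#'
#' @return named integer vector mapping label to level 1..5.
#' @export
likert_levels <- function() {
  c(never = 1L, rarely = 2L, sometimes = 3L, often = 4L, always = 5L)
}

# Canonical orderings used throughout ----------------------------------------

bundle_tiers <- function() c("NONE", "BASIC", "INTERMEDIATE", "ADVANCED", "EXPERT")

support_levels <- function() c("NONE", "SIMPLE_O2", "HFNC", "BIPAP", "CPAP", "IMV")

# rank for "highest support": IMV > NIV (CPAP/BiPAP) > HFNC > simple O2 > none
support_rank <- function(support) {
  r <- c(NONE = 0, SIMPLE_O2 = 1, HFNC = 2, BIPAP = 3, CPAP = 3, IMV = 4)
  out <- unname(r[support])
  out[is.na(support)] <- NA_real_
  out
}

interface_levels <- function() c("NASAL", "FULL_FACE", "INVASIVE", "NA")

sdi_levels <- function() c("low", "low_middle", "middle", "high_middle")

gbd_regions <- function() c("SSA", "SA", "LA", "SLA", "CE", "NA_ME")

trigger_diagnoses <- function() {
  c("pneumonia", "bronchiolitis", "covid19", "sepsis", "trauma",
    "aspiration", "drowning", "other_shock")
}

known_diagnoses <- function() {
  c(trigger_diagnoses(),
    "gastroenteritis", "malaria", "meningitis", "status_epilepticus", "asthma")
}

pards_categories <- function() {
  c("PARDS", "POSSIBLE_PARDS", "AT_RISK", "EVALUATED_NEGATIVE", "NOT_CLASSIFIABLE")
}

# Bundle definitions ----------------------------------------------------------

#' Read a tiered bundle definition from YAML
#'
#' A bundle definition lists the resource items belonging to each of the four
#' explicit tiers (basic, intermediate, advanced, expert; "none" is the
#' implicit floor) plus composite items resolved by an any/all rule over
#' atomic constituents (e.g. pulse oximetry = portable OR continuous).
#'
#' @param path YAML file with \code{tiers} and optional \code{composites}.
#' @return list of class \code{"bundle_definition"} with elements
#'   \code{tiers} (named list of character vectors, names
#'   BASIC/INTERMEDIATE/ADVANCED/EXPERT) and \code{composites} (named list of
#'   \code{list(rule = "any"|"all", of = character())}).
#' @export
read_bundle_definition <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$tiers)) stop("bundle definition has no 'tiers' block")
  tiers <- raw$tiers
  names(tiers) <- toupper(names(tiers))
  tiers <- lapply(tiers, as.character)
  composites <- lapply(raw$composites, function(cdef) {
    list(rule = match.arg(cdef$rule, c("any", "all")), of = as.character(cdef$of))
  })
  new_bundle_definition(tiers, composites)
}

#' Construct and validate a bundle definition
#'
#' @param tiers named list of item identifier vectors; names must be
#'   BASIC, INTERMEDIATE, ADVANCED, EXPERT in ascending order.
#' @param composites named list of composite rules
#'   (\code{list(rule = "any"|"all", of = <atomic ids>)}).
#' @return object of class \code{"bundle_definition"}.
#' @export
new_bundle_definition <- function(tiers, composites = list()) {
  expected <- bundle_tiers()[-1]
  if (!identical(names(tiers), expected)) {
    stop("tiers must be named ", paste(expected, collapse = ", "), " in order")
  }
  if (any(lengths(tiers) == 0L)) stop("every tier needs a non-empty item list")
  all_items <- unlist(tiers, use.names = FALSE)
  if (anyDuplicated(all_items)) {
    stop("tier item lists must be pairwise disjoint; duplicated: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "))
  }
  for (nm in names(composites)) {
    cdef <- composites[[nm]]
    if (!nm %in% all_items) stop("composite '", nm, "' is not a tier item")
    if (length(cdef$of) == 0L) stop("composite '", nm, "' has no constituents")
    if (any(cdef$of %in% names(composites))) {
      stop("composite '", nm, "' references another composite")
    }
  }
  structure(list(tiers = tiers, composites = composites),
            class = "bundle_definition")
}

#' Default bundle definition shipped with the package
#'
#' @return a \code{bundle_definition}; see [read_bundle_definition()].
#' @export
default_bundle_definition <- function() {
  read_bundle_definition(system.file("extdata", "bundle_definition.yaml",
                                     package = "respaudit", mustWork = TRUE))
}

#' Atomic survey vocabulary of a bundle definition
#'
#' Items a site survey may respond to: every non-composite tier item plus
#' every composite constituent.
#'
#' @param bundle_def a \code{bundle_definition}.
#' @return character vector of atomic item identifiers.
#' @export
survey_vocabulary <- function(bundle_def) {
  atoms <- setdiff(unlist(bundle_def$tiers, use.names = FALSE),
                   names(bundle_def$composites))
  c(atoms, unlist(lapply(bundle_def$composites, `[[`, "of"), use.names = FALSE))
}

#' @export
print.bundle_definition <- function(x, ...) {
  cat("Tiered resource bundle definition\n")
  for (t in names(x$tiers)) {
    cat(sprintf("  %-12s %d items: %s\n", t, length(x$tiers[[t]]),
                paste(x$tiers[[t]], collapse = ", ")))
  }
  if (length(x$composites)) {
    cat("Composites:\n")
    for (nm in names(x$composites)) {
      cat(sprintf("  %s = %s(%s)\n", nm, x$composites[[nm]]$rule,
                  paste(x$composites[[nm]]$of, collapse = ", ")))
    }
  }
  invisible(x)
}
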