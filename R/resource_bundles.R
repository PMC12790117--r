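# Scoring of site surveys into the five tiered respiratory-care resource
# bundles (NONE < BASIC < INTERMEDIATE < ADVANCED < EXPERT) and the
# dichotomy used for modelling (intermediate-or-less vs advanced-or-expert).

available_level_set <- function(config) {
  unname(likert_levels()[config$likert_available_levels])
}

#' Is a single resource item available at a site?
#'
#' An atomic item is available when its Likert response is one of the
#' configured "available" labels (default: often or always). A composite item
#' applies its any/all rule over atomic constituents (pulse oximetry =
#' portable OR continuous; intubation supplies = laryngoscopes AND
#' endotracheal tubes; sedation = any of four agents). A missing response is
#' never evidence of availability and counts as not available.
#'
#' @param survey survey rows for one site (columns \code{item}, \code{level}).
#' @param item item identifier, atomic or composite.
#' @param bundle_def a \code{bundle_definition}.
#' @param config run configuration.
#' @return single logical.
#' @export
item_available <- function(survey, item, bundle_def = default_bundle_definition(),
                           config = default_config()) {
  if (item %in% names(bundle_def$composites)) {
    cdef <- bundle_def$composites[[item]]
    hits <- vapply(cdef$of, function(it)
      item_available(survey, it, bundle_def, config), logical(1))
    return(if (cdef$rule == "any") any(hits) else all(hits))
  }
  if (!item %in% survey_vocabulary(bundle_def)) {
    stop("item '", item, "' is not defined in the bundle definition")
  }
  lev <- survey$level[survey$item == item]
  length(lev) > 0L && !is.na(lev[1L]) && lev[1L] %in% available_level_set(config)
}

#' Fraction of a tier's items available at a site
#'
#' @param survey survey rows for one site.
#' @param tier one of BASIC, INTERMEDIATE, ADVANCED, EXPERT.
#' @param bundle_def a \code{bundle_definition}.
#' @param config run configuration.
#' @return fraction in [0, 1].
#' @export
tier_fraction <- function(survey, tier, bundle_def = default_bundle_definition(),
                          config = default_config()) {
  items <- bundle_def$tiers[[tier]]
  if (is.null(items) || length(items) == 0L) {
    stop("tier '", tier, "' has no item list in the bundle definition")
  }
  mean(vapply(items, function(it)
    item_available(survey, it, bundle_def, config), logical(1)))
}

# inclusive >= threshold on the exact rational fraction: integer arithmetic
# so that e.g. 4/5 vs 0.80 cannot be lost to float rounding
tier_passes <- function(n_avail, n_total, threshold) {
  thr_pct <- round(threshold * 100)
  n_avail * 100L >= thr_pct * n_total
}

classify_one_site <- function(survey, bundle_def, config) {
  tiers <- names(bundle_def$tiers)
  n_avail <- integer(length(tiers))
  n_total <- integer(length(tiers))
  for (i in seq_along(tiers)) {
    items <- bundle_def$tiers[[tiers[i]]]
    n_total[i] <- length(items)
    n_avail[i] <- sum(vapply(items, function(it)
      item_available(survey, it, bundle_def, config), logical(1)))
  }
  passes <- tier_passes(n_avail, n_total, config$bundle_threshold)
  # cumulative rule: the assigned tier is the highest tier such that it and
  # every lower tier pass the threshold
  chain <- cumprod(passes) > 0
  assigned <- if (any(chain)) tiers[max(which(chain))] else "NONE"
  group <- if (assigned %in% c("ADVANCED", "EXPERT"))
    "ADVANCED_OR_EXPERT" else "INTERMEDIATE_OR_LESS"
  out <- data.frame(site_id = survey$site_id[1L], stringsAsFactors = FALSE)
  for (i in seq_along(tiers)) {
    out[[paste0("frac_", tolower(tiers[i]))]] <- n_avail[i] / n_total[i]
  }
  out$assigned_tier <- assigned
  out$group <- group
  out
}

#' Classify site surveys into resource bundle tiers
#'
#' Assigns each site the highest tier whose item-availability fraction, and
#' that of every lower tier, is at least the configured threshold (default
#' 80%, inclusive). A site failing the basic tier is NONE. The dichotomized
#' modelling group is \code{INTERMEDIATE_OR_LESS} (none/basic/intermediate)
#' vs \code{ADVANCED_OR_EXPERT}.
#'
#' @param surveys validated survey table ([read_site_surveys()]), one or many
#'   sites.
#' @param bundle_def a \code{bundle_definition}.
#' @param config run configuration.
#' @return data frame with one row per site: per-tier availability fractions
#'   (\code{frac_basic} ..), \code{assigned_tier}, \code{group}.
#' @export
#' @examples
#' cfg <- default_config()
#' def <- default_bundle_definition()
#' sv <- generate_site_survey("ADVANCED", def, cfg)
#' classify_sites(sv, def, cfg)$assigned_tier
classify_sites <- function(surveys, bundle_def = default_bundle_definition(),
                           config = default_config()) {
  pieces <- lapply(split(surveys, surveys$site_id), classify_one_site,
                   bundle_def = bundle_def, config = config)
  out <- do.call(rbind, pieces)
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname classify_sites
#' @export
classify_site <- classify_sites

#' Cross-tabulate bundle tiers against site SDI quintiles
#'
#' @param classifications output of [classify_sites()].
#' @param sites validated site table ([read_sites()]); every classified site
#'   must join.
#' @return list with \code{table} (tier x SDI contingency counts, tiers in
#'   ascending order) and \code{n_advexp_mid_high} (count of
#'   advanced/expert-tier sites in middle or high-middle SDI countries).
#' @export
summarize_bundles_by_sdi <- function(classifications, sites) {
  m <- match(classifications$site_id, sites$site_id)
  if (anyNA(m)) {
    stop("join error: site_id(s) without a site record: ",
         paste(classifications$site_id[is.na(m)], collapse = ", "))
  }
  tier <- factor(classifications$assigned_tier, levels = bundle_tiers())
  sdi <- factor(sites$sdi_quintile[m], levels = sdi_levels())
  tab <- table(tier = tier, sdi = sdi)
  list(
    table = tab,
    n_advexp_mid_high = sum(tab[c("ADVANCED", "EXPERT"),
                                c("middle", "high_middle")])
  )
}
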