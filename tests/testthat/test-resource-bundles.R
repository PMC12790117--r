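cfg <- default_config()
def <- default_bundle_definition()

survey_of <- function(...) {
  resp <- c(...)
  lv <- likert_levels()
  data.frame(site_id = "S1", item = names(resp), response = unname(resp),
             level = unname(lv[resp]), stringsAsFactors = FALSE)
}

test_that("atomic and composite availability follow the often/always rule", {
  sv <- survey_of(oxygen_source = "often", suction = "sometimes")
  expect_true(item_available(sv, "oxygen_source", def, cfg))
  expect_false(item_available(sv, "suction", def, cfg))
  # OR composite: either oximeter flavour suffices
  sv2 <- survey_of(portable_oximetry = "never", continuous_oximetry = "always")
  expect_true(item_available(sv2, "pulse_oximetry", def, cfg))
  # AND composite with one constituent missing fails
  sv3 <- survey_of(laryngoscopes = "always")
  expect_false(item_available(sv3, "intubation_supplies", def, cfg))
  # missing response is never availability
  expect_false(item_available(survey_of(oxygen_source = "always"),
                              "nebulizer", def, cfg))
  expect_error(item_available(sv, "warp_drive", def, cfg), "not defined")
})

test_that("tier fractions count available items over tier size", {
  all5 <- generate_site_survey("EXPERT", def, cfg)
  expect_equal(tier_fraction(all5, "BASIC", def, cfg), 1.0)
  empty <- data.frame(site_id = character(), item = character(),
                      response = character(), level = integer(),
                      stringsAsFactors = FALSE)
  expect_equal(tier_fraction(empty, "ADVANCED", def, cfg), 0.0)
  expect_error(tier_fraction(all5, "GALACTIC", def, cfg), "no item list")
})

test_that("a tier at exactly the threshold fraction counts as available", {
  # intermediate has 5 items: 4/5 = 0.80 must pass (inclusive threshold)
  sv <- generate_site_survey("EXPERT", def, cfg)
  inter <- def$tiers$INTERMEDIATE
  sv$level[sv$item == inter[5]] <- 1L
  sv$response[sv$item == inter[5]] <- "never"
  cls <- classify_sites(sv, def, cfg)
  expect_equal(cls$frac_intermediate, 0.8)
  expect_equal(cls$assigned_tier, "EXPERT")
})

test_that("cumulative rule: a failing lower tier breaks the chain", {
  sv <- generate_site_survey("EXPERT", def, cfg)
  # knock advanced below threshold while expert stays complete
  adv <- def$tiers$ADVANCED
  for (it in adv[1:2]) {
    atoms <- if (it %in% names(def$composites)) def$composites[[it]]$of else it
    sv$level[sv$item %in% atoms] <- 2L
    sv$response[sv$item %in% atoms] <- "rarely"
  }
  cls <- classify_sites(sv, def, cfg)
  expect_lt(cls$frac_advanced, 0.8)
  expect_equal(cls$frac_expert, 1.0)
  expect_equal(cls$assigned_tier, "INTERMEDIATE")
  expect_equal(cls$group, "INTERMEDIATE_OR_LESS")
})

test_that("raising a single response never lowers the assigned tier", {
  set.seed(42)
  tiers <- c("NONE", "BASIC", "INTERMEDIATE", "ADVANCED", "EXPERT")
  for (rep in 1:40) {
    target <- sample(tiers, 1)
    sv <- generate_site_survey(target, def, cfg)
    before <- match(classify_sites(sv, def, cfg)$assigned_tier, tiers)
    i <- sample(nrow(sv), 1)
    sv$level[i] <- 5L
    sv$response[i] <- "always"
    after <- match(classify_sites(sv, def, cfg)$assigned_tier, tiers)
    expect_gte(after, before)
  }
})

test_that("dichotomy partitions the sites", {
  fx <- get_fixture()
  cls <- classify_sites(fx$surveys, def, cfg)
  expect_equal(nrow(cls), 46)
  expect_equal(sum(cls$group == "INTERMEDIATE_OR_LESS"),
               sum(cls$assigned_tier %in% c("NONE", "BASIC", "INTERMEDIATE")))
  expect_equal(table(cls$group)[["INTERMEDIATE_OR_LESS"]] +
                 table(cls$group)[["ADVANCED_OR_EXPERT"]], 46)
})

test_that("tier-by-SDI summary counts advanced/expert sites in upper quintiles", {
  fx <- get_fixture()
  cls <- classify_sites(fx$surveys, def, cfg)
  sm <- summarize_bundles_by_sdi(cls, fx$sites)
  expect_equal(sm$n_advexp_mid_high, 17)
  expect_equal(sum(sm$table), 46)
  # single site
  one <- classify_sites(fx$surveys[fx$surveys$site_id == "S01", ], def, cfg)
  sm1 <- summarize_bundles_by_sdi(one, fx$sites)
  expect_equal(sum(sm1$table), 1)
  # permuted row order gives an identical table
  perm <- fx$surveys[rev(seq_len(nrow(fx$surveys))), ]
  cls_p <- classify_sites(perm, def, cfg)
  expect_equal(summarize_bundles_by_sdi(cls_p, fx$sites)$table, sm$table)
  # orphan site is a join error
  expect_error(summarize_bundles_by_sdi(cls, fx$sites[-1, ]), "join error")
})
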