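test_that("lens prescreen cutoffs are boundary-correct", {
  expect_equal(lens_prescreen(c(10.5, 17, 12, 7, 16, NA)),
               c("candidate-wild", "estuarine-check", "hatchery",
                 "candidate-wild", "hatchery", "no-lens"))
})

test_that("exogenous reassignment fires only for weakly-assigned hatchery
          fish with wild check scores", {
  got <- reassign_exogenous(
    top_class = c("NIH", "NIH", "AME", "NIH", "NIH"),
    class_prob = c(0.7, 0.85, 0.3, 0.79, 0.7),
    exo_score = c(2.0, 2.0, 1.0, 1.5, 1.6))
  expect_equal(got$final_source, c("AME", "NIH", "AME", "NIH", "AME"))
  expect_equal(got$reassigned, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("juvenile constraints zero violated sources, renormalise, and
          preserve the ranking of untouched sources", {
  probs <- c(AME = 0.30, NIH = 0.45, STA = 0.15, OTH = 0.10)
  # fry-sized juvenile: hatchery zeroed, top remaining wild source wins
  got <- juvenile_constraints(probs, fl = 50, sample_date = NA, site = "x",
                              hatchery_sources = "NIH")
  expect_equal(got$final_source, "AME")
  expect_equal(got$applied_rules, "fry-size-wild")
  expect_equal(unname(got$class_probs[["NIH"]]), 0)
  expect_equal(sum(got$class_probs), 1)
  # untouched sources keep their relative order
  expect_true(got$class_probs[["AME"]] > got$class_probs[["STA"]])
  expect_true(got$class_probs[["STA"]] > got$class_probs[["OTH"]])

  # sampled before the hatchery's first unmarked release
  got <- juvenile_constraints(probs, fl = 60,
                              sample_date = as.Date("2016-02-01"),
                              site = "x", hatchery_sources = "NIH",
                              release_dates = list(NIH = as.Date("2016-04-15")))
  expect_equal(got$final_source, "AME")
  expect_equal(got$applied_rules, "pre-release:NIH")

  # southern-tributary source impossible at the upstream trawl
  got <- juvenile_constraints(c(STA = 0.6, AME = 0.4), fl = 60,
                              sample_date = NA, site = "sherwood",
                              excluded_sources_by_site =
                                list(sherwood = "STA"))
  expect_equal(got$final_source, "AME")

  # everything zeroed: unassignable
  got <- juvenile_constraints(c(NIH = 1), fl = 40, sample_date = NA,
                              site = "x", hatchery_sources = "NIH")
  expect_true(got$unassignable)
  expect_error(juvenile_constraints(c(A = 0.5, B = 0.4), 60, NA, "x"),
               "sum to 1")
})

test_that("adult age assignment uses scales first, then size fallbacks", {
  expect_equal(assign_age(c(NA, NA, NA, 2, 4), c(80, 55, 105, 90, 60)),
               c(3L, 2L, 4L, 2L, 4L))
})

test_that("rule chain is deterministic and ordered: constraints before
          exogenous reassignment", {
  input <- list(top_class = "NIH",
                class_probs = c(AME = 0.35, NIH = 0.65),
                exo_score = 2.0, lens_d34s = NULL, fl = 50,
                sample_date = NA, site = "x", is_juvenile = TRUE)
  got <- provenance_assign(input, hatchery_sources = "NIH")
  # fry rule zeroes NIH first; exo rule then has nothing to reassign
  expect_equal(got$final_source, "AME")
  expect_equal(got$applied_rules, "fry-size-wild")
  got2 <- provenance_assign(input, hatchery_sources = "NIH")
  expect_identical(got, got2)
})

test_that("lens prescreen short-circuits clearly hatchery adults", {
  input <- list(top_class = "AME", class_probs = c(AME = 0.9, NIH = 0.1),
                exo_score = 2, lens_d34s = 14.2, fl = NA,
                sample_date = NA, site = "carcass", is_juvenile = FALSE)
  got <- provenance_assign(input)
  expect_equal(got$origin, "hatchery")
  expect_equal(got$applied_rules, "lens-prescreen-hatchery")
})

test_that("on synthetic adults the rule chain never degrades raw top-class
          assignment accuracy", {
  iso <- isoscape_config()
  for (s in c(2L, 9L, 23L)) {
    cfg <- sim_config(n_fish = 400, seed = s)
    out <- simulate_cohort(cfg, iso)
    ad <- out$records[out$records$point == "adult", ]
    set.seed(s)
    exo <- ifelse(ad$origin_true == "natal-river-wild",
                  sample(c(1, 1.5, 2), nrow(ad), TRUE, c(.1, .3, .6)),
                  sample(c(1, 1.5, 2), nrow(ad), TRUE, c(.6, .3, .1)))
    truth <- ifelse(ad$origin_true == "natal-river-wild", "wild", "hatchery")
    raw <- character(nrow(ad)); ruled <- character(nrow(ad))
    for (i in seq_len(nrow(ad))) {
      pr <- standin_assignment(out$profiles[[ad$record_id[i]]], iso)
      raw[i] <- if (names(pr)[which.max(pr)] == "NIH") "hatchery" else "wild"
      res <- provenance_assign(list(
        top_class = names(pr)[which.max(pr)], class_probs = pr,
        exo_score = exo[i], lens_d34s = ad$lens_d34s[i], fl = NA,
        sample_date = NA, site = "carcass", is_juvenile = FALSE))
      ruled[i] <- res$origin
    }
    expect_gte(mean(ruled == truth), mean(raw == truth))
  }
})
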