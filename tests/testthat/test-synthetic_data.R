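test_that("survey generation is deterministic for a fixed seed", {
  cfg <- survey_sim_config(n_informants = 30, n_species = 10,
                           n_categories = 5, exponent = 0.7, seed = 42)
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  cfg2 <- survey_sim_config(n_informants = 30, n_species = 10,
                            n_categories = 5, exponent = 0.7, seed = 43)
  expect_false(identical(generate_survey(cfg), generate_survey(cfg2)))
})

test_that("a certain-citation single-species config saturates FC", {
  cfg <- survey_sim_config(n_informants = 25, n_species = 1,
                           n_categories = 3, exponent = 1,
                           top_citation_prob = 1, seed = 1)
  s <- generate_survey(cfg)
  expect_identical(unname(fc_counts(s)["species_01"]), 25L)
})

test_that("realized top-rank citation rate tracks the configured law", {
  cfg0 <- survey_sim_config(n_informants = 60, n_species = 12,
                            n_categories = 5, exponent = 0.7, seed = 0)
  max_rates <- vapply(1:50, function(seed) {
    cfg <- survey_sim_config(n_informants = 60, n_species = 12,
                             n_categories = 5, exponent = 0.7, seed = seed)
    s <- generate_survey(cfg)
    max(fc_counts(s)) / length(s$informants)
  }, numeric(1))
  expect_lt(abs(mean(max_rates) - cfg0$top_citation_prob), 0.1)
})

test_that("the default exponent is fitted from the packaged fixture", {
  cfg <- survey_sim_config()
  expect_equal(cfg$exponent,
               fit_citation_exponent(load_citation_fixture()$citations))
  expect_gt(cfg$exponent, 0)
  # the fitted law spans the fixture's citation range in expectation
  expect_equal(cfg$top_citation_prob, 70 / 145)
})

test_that("infeasible survey configs are rejected", {
  expect_error(survey_sim_config(n_categories = 0), "positive")
  expect_error(survey_sim_config(exponent = -1), "positive")
  expect_error(survey_sim_config(top_citation_prob = 0), "\\(0, 1\\]")
})

test_that("generated surveys satisfy every index invariant across seeds", {
  for (seed in 1:100) {
    cfg <- survey_sim_config(n_informants = 30, n_species = 12,
                             n_categories = 6, exponent = 0.7, seed = seed)
    s <- generate_survey(cfg)
    tab <- compute_index_table(s)
    expect_true(all(tab$fc <= length(s$informants)))
    expect_true(all(tab$nu <= length(s$use_categories)))
    expect_equal(tab$uv, tab$cii)
    expect_true(all(tab$rfc <= tab$uv + 1e-12))
    expect_true(all(tab$cvi <= tab$cii + 1e-12))
    expect_true(all(tab$ri > 0 & tab$ri <= 1))
    expect_identical(tab$rank_rfc, rank(-tab$fc, ties.method = "min"))
  }
})

test_that("preference tables are deterministic and respect Bernoulli moments", {
  cfg <- covariate_sim_config(n = 145, seed = 8)
  expect_identical(generate_preference_table(cfg),
                   generate_preference_table(cfg))
  big <- generate_preference_table(covariate_sim_config(n = 6000, seed = 2))
  expect_lt(abs(mean(big$knowledge) - 0.5742), 0.1)  # + ethnicity link boost
  expect_lt(abs(mean(big$loan) - 0.6229), 0.03)
  expect_lt(abs(mean(big$family_beliefs) - 0.7163), 0.03)
  expect_lt(abs(mean(big$agroforestry_income) - 36.6), 1.5)
  expect_true(all(big$prefers_herbal %in% c(0, 1)))
})

test_that("null coefficients with auto-intercept give a balanced outcome", {
  beta <- setNames(rep(0, 3), c("knowledge", "loan", "sex"))
  cfg <- covariate_sim_config(n = 5000, beta = beta, seed = 4)
  expect_equal(cfg$intercept, 0)
  d <- generate_preference_table(cfg)
  expect_lt(abs(mean(d$prefers_herbal) - 0.5), 0.03)
})

test_that("fit_logit recovers a strong knowledge effect at n = 5000", {
  beta <- c(knowledge = 1.33, loan = 0.1, sex = -0.07)
  cfg <- covariate_sim_config(n = 5000, beta = beta, seed = 99)
  d <- generate_preference_table(cfg)
  fit <- fit_logit(d, outcome = "prefers_herbal", covariates = names(beta))
  co <- fit$coefficients
  k <- co[co$term == "knowledge", ]
  expect_lt(abs(k$estimate - 1.33), 3 * k$std_error)
})

test_that("perception statements round-trip their target tallies exactly", {
  target <- data.frame(user_group = "allopathy_user",
                       medicine_evaluated = "allopathy",
                       capability = "affiliation", enabler = 18, barrier = 7,
                       stringsAsFactors = FALSE)
  st <- generate_perception_statements(target, seed = 3)
  expect_identical(nrow(st), 25L)
  tl <- tally_capabilities(st, "allopathy_user", "allopathy")
  expect_identical(tl$enabler[tl$capability == "affiliation"], 18L)
  expect_identical(tl$barrier[tl$capability == "affiliation"], 7L)
})

test_that("random perception targets round-trip across 20 seeds", {
  caps <- default_capabilities()
  for (seed in 1:20) {
    set.seed(seed + 1000)
    targets <- expand.grid(user_group = c("allopathy_user", "herbal_user"),
                           medicine_evaluated = c("allopathy", "herbal"),
                           capability = caps, stringsAsFactors = FALSE)
    targets$enabler <- rpois(nrow(targets), 3)
    targets$barrier <- rpois(nrow(targets), 1)
    st <- generate_perception_statements(targets, seed = seed)
    expect_identical(nrow(st), sum(targets$enabler) + sum(targets$barrier))
    cells <- compare_groups(st, capabilities = caps)
    for (key in names(cells)) {
      parts <- strsplit(key, ":")[[1]]
      want <- targets[targets$user_group == parts[1] &
                        targets$medicine_evaluated == parts[2], ]
      want <- want[match(caps, want$capability), ]
      expect_identical(cells[[key]]$enabler, as.integer(want$enabler))
      expect_identical(cells[[key]]$barrier, as.integer(want$barrier))
    }
  }
})

test_that("all-zero perception targets give an empty statement set", {
  target <- data.frame(user_group = "herbal_user",
                       medicine_evaluated = "herbal",
                       capability = "life", enabler = 0, barrier = 0,
                       stringsAsFactors = FALSE)
  expect_identical(nrow(generate_perception_statements(target)), 0L)
  expect_error(generate_perception_statements(transform(target, enabler = -1)),
               "nonnegative")
})
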