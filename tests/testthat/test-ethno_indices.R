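test_that("use value sums per-informant report counts over N", {
  # N = 3, informants report 2, 1, 0 uses -> UV = 1
  reports <- data.frame(informant_id = c("A", "A", "B"), species_id = "S",
                        use_category = c("c1", "c2", "c1"),
                        stringsAsFactors = FALSE)
  s <- survey(reports, informants = c("A", "B", "C"))
  expect_equal(use_value(s, "S"), 1.0)
  expect_equal(use_value(s, "never_cited"), 0)

  # all N informants report exactly one use -> UV = 1
  one_each <- data.frame(informant_id = paste0("i", 1:6), species_id = "S",
                         use_category = "c1", stringsAsFactors = FALSE)
  expect_equal(use_value(survey(one_each), "S"), 1.0)
})

test_that("rfc is the exact citation fraction with domain checks", {
  expect_equal(rfc(68, 145), 68 / 145)
  expect_equal(truncate_decimal(rfc(68, 145), 3), 0.468)
  expect_equal(rfc(0, 37), 0)
  expect_equal(rfc(37, 37), 1)
  expect_error(rfc(5, 4), "\\[0, n\\]")
  expect_error(rfc(1, 0), ">= 1")
})

test_that("relative importance honours both conventions", {
  # species at both maxima always scores 1 under normalization
  expect_equal(relative_importance(0.5, 4, 0.5, 4, "normalized"), 1.0)
  expect_equal(relative_importance(0.5, 2, 0.5, 4, "raw_rfc"), 0.5)
  expect_equal(relative_importance(0.25, 4, 0.5, 4, "normalized"), 0.75)
  expect_error(relative_importance(0.1, 1, 0, 4), "positive")
  expect_error(relative_importance(0.6, 1, 0.5, 4), "exceed")
})

test_that("cii accumulates category-wise informant counts over N", {
  # N = 2; informant 1 reports the species in 2 categories, informant 2 in 1
  reports <- data.frame(informant_id = c("i1", "i1", "i2"), species_id = "S",
                        use_category = c("c1", "c2", "c1"),
                        stringsAsFactors = FALSE)
  s <- survey(reports)
  expect_equal(cii(s, "S"), 1.5)
  expect_equal(cii(s, "ghost"), 0)

  # every informant in every category -> CII = NC
  grid <- expand.grid(informant_id = paste0("i", 1:3),
                      use_category = paste0("c", 1:4),
                      stringsAsFactors = FALSE)
  grid$species_id <- "S"
  expect_equal(cii(survey(grid), "S"), 4)
})

test_that("cvi follows its closed form and never exceeds cii", {
  expect_equal(cvi(2, 4, 1, 2, 1.5), 0.375)
  expect_equal(cvi(0, 4, 0, 2, 0), 0)
  expect_equal(cvi(3, 3, 5, 5, 1.23), 1.23) # both factors 1 -> CVI = CII
  expect_error(cvi(1, 0, 1, 2, 1), ">= 1")
  expect_error(cvi(5, 4, 1, 2, 1), "required")
})

test_that("decimal truncation cuts toward zero without rounding", {
  expect_equal(truncate_decimal(0.46896, 3), 0.468)
  expect_equal(truncate_decimal(0.4206, 2), 0.42)
  expect_equal(truncate_decimal(0.29, 2), 0.29)   # already at precision
  expect_equal(truncate_decimal(0.999999, 3), 0.999)
  expect_equal(truncate_decimal(-0.46896, 2), -0.46)
  expect_equal(truncate_decimal(c(0.125, 3), 1), c(0.1, 3))
  expect_error(truncate_decimal(0.5, -1), "nonnegative")
})

test_that("index table matches hand-computed two-species survey", {
  # S1: cited by A (2 cats) and B (1 cat); S2: cited by A (1 cat)
  reports <- data.frame(informant_id = c("A", "A", "B", "A"),
                        species_id = c("S1", "S1", "S1", "S2"),
                        use_category = c("c1", "c2", "c1", "c2"),
                        stringsAsFactors = FALSE)
  s <- survey(reports, informants = c("A", "B", "C"),
              use_categories = c("c1", "c2", "c3"))
  tab <- compute_index_table(s)
  s1 <- tab[tab$species_id == "S1", ]
  s2 <- tab[tab$species_id == "S2", ]
  expect_equal(s1$fc, 2L);  expect_equal(s1$nu, 2L)
  expect_equal(s1$uv, 1);   expect_equal(s1$rfc, 2 / 3)
  expect_equal(s1$cii, 1)
  expect_equal(s1$cvi, (2 / 3) * (2 / 3) * 1)
  expect_equal(s1$ri, (2 / 3 + 1) / 2)
  expect_equal(s2$fc, 1L);  expect_equal(s2$nu, 1L)
  expect_equal(s2$uv, 1 / 3)
  expect_equal(s2$cvi, (1 / 3) * (1 / 3) * (1 / 3))
  expect_equal(s1$rank_rfc, 1L)
  expect_equal(s2$rank_rfc, 2L)
})

test_that("index table equals the brute-force oracle on random surveys", {
  for (seed in 1:20) {
    s <- random_survey(seed)
    for (conv in c("raw_rfc", "normalized")) {
      expect_tables_equal(compute_index_table(s, convention = conv),
                          oracle_index_table(s, convention = conv))
    }
  }
})

test_that("index invariants hold on random surveys", {
  for (seed in 21:40) {
    s <- random_survey(seed, n_inf = 7, n_sp = 5, n_cat = 4, n_draws = 25)
    tab <- compute_index_table(s)
    nc <- length(s$use_categories)
    expect_equal(tab$uv, tab$cii)                   # UV == CII identity
    expect_true(all(tab$rfc >= 0 & tab$rfc <= tab$uv + 1e-12))
    expect_true(all(tab$cvi <= tab$cii + 1e-12))
    expect_true(all(tab$cii <= nc + 1e-12))
    expect_true(all(tab$ri > 0 & tab$ri <= 1))
    # RFC ranking is FC ranking (monotone transform)
    expect_identical(tab$rank_rfc, rank(-tab$fc, ties.method = "min"))
  }
})

test_that("single species cited by all informants ranks first", {
  reports <- data.frame(informant_id = paste0("i", 1:4), species_id = "S",
                        use_category = "c1", stringsAsFactors = FALSE)
  tab <- compute_index_table(survey(reports))
  expect_identical(tab$rank_rfc, 1L)
  expect_equal(tab$rfc, 1)
})

test_that("ties share the minimum rank and display order breaks ties by name", {
  reports <- data.frame(informant_id = c("A", "B", "A", "B"),
                        species_id = c("S2", "S2", "S1", "S1"),
                        use_category = "c1", stringsAsFactors = FALSE)
  tab <- compute_index_table(survey(reports))
  expect_identical(tab$rank_rfc, c(1L, 1L))
  expect_identical(tab$species_id, c("S1", "S2"))
})

test_that("empty survey yields an empty table; NC override feeds CVI", {
  s <- survey(toy_reports())
  empty <- survey(toy_reports()[0, ],
                  informants = "A", use_categories = "c")
  expect_identical(nrow(compute_index_table(empty)), 0L)

  tab3 <- compute_index_table(s)             # NC = 3 observed
  tab12 <- compute_index_table(s, nc = 12)
  expect_equal(tab12$cvi, tab3$cvi * 3 / 12)
  expect_equal(tab12$cii, tab3$cii)          # CII does not depend on NC
})

test_that("formatting policy is applied only at reporting time", {
  s <- survey(toy_reports())
  tab <- compute_index_table(s)
  tr <- format_index_table(tab, "truncate", 2)
  rd <- format_index_table(tab, "round", 2)
  expect_equal(tr$rfc, truncate_decimal(tab$rfc, 2))
  expect_equal(rd$rfc, round(tab$rfc, 2))
  expect_identical(tr$rank_rfc, tab$rank_rfc)  # ranks computed pre-format
})
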