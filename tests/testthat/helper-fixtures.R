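# Shared fixtures: tiny hand-checkable surveys, a random-survey generator,
# and a brute-force enumeration oracle for the index table that shares no
# code with compute_index_table().

toy_reports <- function() {
  data.frame(
    informant_id = c("A", "A", "A", "B", "B"),
    species_id = c("S1", "S1", "S2", "S1", "S2"),
    use_category = c("digestive", "skin", "digestive", "digestive", "fever"),
    plant_part = c("leaf", "leaf", "root", "leaf", "root"),
    stringsAsFactors = FALSE)
}

random_survey <- function(seed, n_inf = 5, n_sp = 4, n_cat = 3,
                          n_draws = 15) {
  set.seed(seed)
  reports <- data.frame(
    informant_id = sample(paste0("i", seq_len(n_inf)), n_draws, replace = TRUE),
    species_id = sample(paste0("s", seq_len(n_sp)), n_draws, replace = TRUE),
    use_category = sample(paste0("c", seq_len(n_cat)), n_draws, replace = TRUE),
    stringsAsFactors = FALSE)
  suppressWarnings(survey(reports,
                          informants = paste0("i", seq_len(n_inf)),
                          use_categories = paste0("c", seq_len(n_cat))))
}

# Brute force: enumerate every informant x species x category cell and count.
oracle_index_table <- function(survey, convention = "raw_rfc", nc = NULL) {
  N <- length(survey$informants)
  NC <- if (is.null(nc)) length(survey$use_categories) else nc
  species <- sort(unique(survey$reports$species_id))
  rows <- lapply(species, function(sp) {
    fc <- 0L; total <- 0L
    cats_hit <- character(0)
    for (inf in survey$informants) {
      k <- 0L
      for (cat in survey$use_categories) {
        hit <- any(survey$reports$informant_id == inf &
                     survey$reports$species_id == sp &
                     survey$reports$use_category == cat)
        if (hit) {
          k <- k + 1L
          cats_hit <- union(cats_hit, cat)
        }
      }
      if (k > 0L) fc <- fc + 1L
      total <- total + k
    }
    data.frame(species_id = sp, fc = fc, nu = length(cats_hit),
               total = total, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d$uv <- d$total / N
  d$rfc <- d$fc / N
  d$rnu <- d$nu / max(d$nu)
  cite <- if (convention == "normalized") d$rfc / max(d$rfc) else d$rfc
  d$ri <- (cite + d$rnu) / 2
  d$cii <- d$total / N
  d$cvi <- (d$nu / NC) * (d$fc / N) * d$cii
  d$rank_rfc <- rank(-d$rfc, ties.method = "min")
  d$rank_ri <- rank(-d$ri, ties.method = "min")
  d$rank_cii <- rank(-d$cii, ties.method = "min")
  d$rank_cvi <- rank(-d$cvi, ties.method = "min")
  d[order(-d$ri, d$species_id), setdiff(names(d), "total")]
}

expect_tables_equal <- function(computed, oracle) {
  computed <- computed[order(computed$species_id), ]
  oracle <- oracle[order(oracle$species_id), ]
  expect_equal(computed$species_id, oracle$species_id)
  for (col in c("fc", "nu", "uv", "rfc", "rnu", "ri", "cii", "cvi",
                "rank_rfc", "rank_ri", "rank_cii", "rank_cvi")) {
    expect_equal(unname(computed[[col]]), unname(oracle[[col]]),
                 tolerance = 1e-12, label = col)
  }
}
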