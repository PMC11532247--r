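# Seeded synthetic-data generators.
#
# The raw field data behind the survey (use reports, perception statements,
# respondent covariates) are not deposited, so every pipeline stage is
# exercised on synthetic data whose statistical structure mimics what the
# published summaries show: heavy-tailed species citation counts (FCs
# spanning roughly 5-70 among 145 informants), per-species use-category
# versatility across ~12 categories, covariate moments matching the
# published demographic table, and a preference outcome drawn from a latent
# logistic model.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Fit a Zipf-like exponent to a rank-frequency citation profile
#'
#' Least-squares slope of log(count) on log(rank) for a decreasing citation
#' profile; used to calibrate the synthetic citation law against the
#' packaged 51-species fixture rather than hard-coding an exponent.
#'
#' @param counts positive citation counts (sorted internally).
#' @return Positive exponent gamma such that count(rank) ~ rank^(-gamma).
#' @export
fit_citation_exponent <- function(counts) {
  counts <- sort(as.numeric(counts[counts > 0]), decreasing = TRUE)
  if (length(counts) < 2L) stop("need at least two positive counts", call. = FALSE)
  r <- seq_along(counts)
  -unname(stats::coef(stats::lm(log(counts) ~ log(r)))[2])
}

#' Configuration for the synthetic use-report survey
#'
#' Defaults mirror the published study conditions: 145 informants, 51
#' species, 12 use categories, citation probabilities decaying as a
#' Zipf-like rank law with the exponent fitted to the packaged citation
#' fixture and the top-rank citation probability anchored at the fixture's
#' maximum (70/145).
#'
#' @param n_informants number of informants N (default 145).
#' @param n_species number of species (default 51).
#' @param n_categories number of use categories NC (default 12).
#' @param exponent rank-law exponent; default fitted from the fixture via
#'   [fit_citation_exponent()].
#' @param top_citation_prob per-informant citation probability of the
#'   rank-1 species (default 70/145).
#' @param versatility_mean mean per-species use-category repertoire size
#'   (default 3).
#' @param seed integer RNG seed.
#' @return List of class `survey_sim_config`.
#' @export
survey_sim_config <- function(n_informants = 145L, n_species = 51L,
                              n_categories = 12L, exponent = NULL,
                              top_citation_prob = 70 / 145,
                              versatility_mean = 3, seed = 1L) {
  if (n_informants < 1L || n_species < 1L || n_categories < 1L) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (is.null(exponent)) {
    exponent <- fit_citation_exponent(load_citation_fixture()$citations)
  }
  if (exponent <= 0) stop("`exponent` must be positive", call. = FALSE)
  if (top_citation_prob <= 0 || top_citation_prob > 1) {
    stop("`top_citation_prob` must lie in (0, 1]", call. = FALSE)
  }
  if (versatility_mean < 1) stop("`versatility_mean` must be >= 1", call. = FALSE)
  structure(list(n_informants = as.integer(n_informants),
                 n_species = as.integer(n_species),
                 n_categories = as.integer(n_categories),
                 exponent = exponent, top_citation_prob = top_citation_prob,
                 versatility_mean = versatility_mean, seed = as.integer(seed)),
            class = "survey_sim_config")
}

# plant-part shares used by the generator (synthetic; leaf- and root-heavy
# as medicinal-plant surveys typically report)
default_part_shares <- function() {
  c(leaf = 0.40, root = 0.14, fruit = 0.15, bark = 0.13, seed = 0.11,
    stem = 0.03, flower = 0.02, latex = 0.01, `whole-aerial` = 0.01)
}

#' Generate a synthetic use-report survey
#'
#' Citation counts are drawn by thinning a Zipf-like rank law directly at
#' the informant level: species at rank r is cited by each informant
#' independently with probability `top_citation_prob * r^(-exponent)`, so
#' realized FCs are Binomial(N, p_r) and need no post-hoc deduplication.
#' Each species carries a category repertoire (its versatility); each citing
#' informant reports the species in one to three categories drawn from that
#' repertoire. Deterministic for a fixed seed.
#'
#' @param config a [survey_sim_config()].
#' @return An `ethno_survey`.
#' @export
generate_survey <- function(config = survey_sim_config()) {
  stopifnot(inherits(config, "survey_sim_config"))
  with_seed(config$seed, {
    n <- config$n_informants
    informants <- sprintf("inf%03d", seq_len(n))
    species <- sprintf("species_%02d", seq_len(config$n_species))
    categories <- sprintf("category_%02d", seq_len(config$n_categories))
    p <- pmin(1, config$top_citation_prob * seq_len(config$n_species)^(-config$exponent))
    part_shares <- default_part_shares()
    preparations <- c("decoction", "paste", "juice", "powder", "raw")
    administrations <- c("oral", "topical")

    rows <- vector("list", config$n_species)
    for (s in seq_len(config$n_species)) {
      citers <- informants[stats::runif(n) < p[s]]
      if (length(citers) == 0L) next
      rep_size <- min(config$n_categories,
                      1L + stats::rpois(1L, config$versatility_mean - 1))
      repertoire <- sample(categories, rep_size)
      part <- sample(names(part_shares), 1L, prob = part_shares)
      per_citer <- lapply(citers, function(ci) {
        k <- sample.int(min(3L, rep_size), 1L)
        data.frame(informant_id = ci, species_id = species[s],
                   use_category = sample(repertoire, k),
                   plant_part = part,
                   preparation = sample(preparations, 1L),
                   administration = sample(administrations, 1L),
                   stringsAsFactors = FALSE)
      })
      rows[[s]] <- do.call(rbind, per_citer)
    }
    reports <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(reports)) {
      stop("configuration generated no reports; increase `top_citation_prob`",
           call. = FALSE)
    }
    survey(reports, informants = informants, use_categories = categories)
  })
}

#' Configuration for synthetic respondent covariates and preference outcome
#'
#' Covariate distributions are calibrated to the published demographic
#' summary of the 145 respondents: age-like continuous covariates use the
#' reported means and standard deviations (normal, truncated at zero where
#' negative values are meaningless), binary covariates use the reported
#' shares (e.g. loan 62.29 %, knowledge of medicinal plants 57.42 %, family
#' beliefs 71.63 %, social-forestry beneficiary 13.79 %, male 42.75 %,
#' indigenous ethnicity 72 %). The outcome is Bernoulli with
#' logit(p) = intercept + beta . x; slope defaults are the published
#' regression estimates, and the intercept defaults to the value putting
#' the prevalence at `prevalence_target` for the configured covariate means
#' (the published study reports no preference prevalence).
#'
#' @param n number of respondents (default 145).
#' @param beta named numeric vector of true slopes; defaults to the
#'   published estimates for the twelve covariates.
#' @param intercept true intercept; `NULL` (default) auto-calibrates to
#'   `prevalence_target`.
#' @param prevalence_target target P(prefers herbal) at the covariate means
#'   (default 0.5), used only when `intercept` is `NULL`.
#' @param ethnicity_knowledge_link correlation-inducing probability boost:
#'   indigenous respondents' probability of knowledge of medicinal plants is
#'   raised by this amount (default 0.15; synthetic, qualitative only).
#' @param seed integer RNG seed.
#' @return List of class `covariate_sim_config`.
#' @export
covariate_sim_config <- function(n = 145L, beta = NULL, intercept = NULL,
                                 prevalence_target = 0.5,
                                 ethnicity_knowledge_link = 0.15,
                                 seed = 1L) {
  default_beta <- c(sex = -0.07096, agroforestry_income = 0.151492,
                    education = -0.33496, collection_challenge = -1.51703,
                    ethnicity = 0.113192, social_forestry = 0.315263,
                    knowledge = 1.328981, medical_facility = -1.0092,
                    family_size = 0.00517, loan = 0.065782,
                    other_income = -0.12507, family_beliefs = 0.018258)
  if (is.null(beta)) beta <- default_beta
  if (is.null(names(beta)) || any(!nzchar(names(beta)))) {
    stop("`beta` must be a named vector", call. = FALSE)
  }
  if (prevalence_target <= 0 || prevalence_target >= 1) {
    stop("`prevalence_target` must lie in (0, 1)", call. = FALSE)
  }
  moments <- list(
    sex = list(type = "binary", p = 0.4275),
    agroforestry_income = list(type = "normal", mean = 36.6, sd = 17.45),
    education = list(type = "normal", mean = 4.76, sd = 2.673),
    collection_challenge = list(type = "binary", p = 0.5),
    ethnicity = list(type = "binary", p = 0.72),
    social_forestry = list(type = "binary", p = 0.1379),
    knowledge = list(type = "binary", p = 0.5742),
    medical_facility = list(type = "binary", p = 0.5),
    family_size = list(type = "count", mean = 4.385, sd = 2.162, min = 1),
    loan = list(type = "binary", p = 0.6229),
    other_income = list(type = "normal", mean = 64.59, sd = 24.61),
    family_beliefs = list(type = "binary", p = 0.7163))
  unknown <- setdiff(names(beta), names(moments))
  if (length(unknown) > 0L) {
    stop("no distribution configured for covariate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(intercept)) {
    mu <- vapply(names(beta), function(v) {
      m <- moments[[v]]
      if (m$type == "binary") m$p else m$mean
    }, numeric(1))
    intercept <- stats::qlogis(prevalence_target) - sum(beta * mu)
  }
  structure(list(n = as.integer(n), beta = beta, intercept = intercept,
                 moments = moments[names(beta)],
                 ethnicity_knowledge_link = ethnicity_knowledge_link,
                 seed = as.integer(seed)),
            class = "covariate_sim_config")
}

#' Generate a synthetic respondent table with a preference outcome
#'
#' Draws the covariates from the configured distributions (independently,
#' except for a configurable positive link raising knowledge prevalence
#' among indigenous respondents) and the outcome `prefers_herbal` from the
#' logistic law at the configured true coefficients. Deterministic for a
#' fixed seed.
#'
#' @param config a [covariate_sim_config()].
#' @return data frame with `respondent_id`, `prefers_herbal` (0/1) and one
#'   column per configured covariate; the true coefficients are attached as
#'   attributes `true_beta` and `true_intercept`.
#' @export
generate_preference_table <- function(config = covariate_sim_config()) {
  stopifnot(inherits(config, "covariate_sim_config"))
  with_seed(config$seed, {
    n <- config$n
    draw <- function(m) {
      switch(m$type,
             binary = as.numeric(stats::runif(n) < m$p),
             normal = pmax(0, stats::rnorm(n, m$mean, m$sd)),
             count = pmax(m$min, round(stats::rnorm(n, m$mean, m$sd))))
    }
    x <- lapply(config$moments, draw)
    link <- config$ethnicity_knowledge_link
    if (link > 0 && all(c("ethnicity", "knowledge") %in% names(x))) {
      boost <- x$ethnicity == 1 & stats::runif(n) < link
      x$knowledge <- as.numeric(x$knowledge == 1 | boost)
    }
    X <- as.data.frame(x)
    eta <- config$intercept +
      drop(as.matrix(X[names(config$beta)]) %*% config$beta)
    outcome <- as.numeric(stats::runif(n) < stats::plogis(eta))
    out <- cbind(data.frame(respondent_id = sprintf("resp%04d", seq_len(n)),
                            prefers_herbal = outcome,
                            stringsAsFactors = FALSE),
                 X)
    attr(out, "true_beta") <- config$beta
    attr(out, "true_intercept") <- config$intercept
    out
  })
}

#' Generate perception statements reproducing target tallies exactly
#'
#' The inverse of [tally_capabilities()]: given target enabler/barrier
#' counts per (user group, medicine, capability) cell, emits one statement
#' per count so that re-tallying the output reproduces the targets exactly.
#' Respondent ids cycle within each user group; the output row order is
#' shuffled under the seed (the tallies are order-invariant).
#'
#' @param targets data frame with columns `user_group`,
#'   `medicine_evaluated`, `capability`, `enabler`, `barrier` (counts >= 0).
#' @param respondents_per_group number of distinct respondent ids to cycle
#'   through per user group (default 25).
#' @param seed integer RNG seed for the shuffle.
#' @return Statements data frame as consumed by [tally_capabilities()].
#' @export
generate_perception_statements <- function(targets, respondents_per_group = 25L,
                                           seed = 1L) {
  needed <- c("user_group", "medicine_evaluated", "capability",
              "enabler", "barrier")
  missing_cols <- setdiff(needed, names(targets))
  if (length(missing_cols) > 0L) {
    stop("targets missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(targets$enabler < 0) || any(targets$barrier < 0)) {
    stop("target counts must be nonnegative", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    valence <- c(rep("enabler", t$enabler), rep("barrier", t$barrier))
    if (length(valence) == 0L) return(NULL)
    data.frame(user_group = t$user_group,
               medicine_evaluated = t$medicine_evaluated,
               capability = t$capability, valence = valence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(respondent_id = character(0), user_group = character(0),
                      medicine_evaluated = character(0),
                      capability = character(0), valence = character(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    prefix <- c(allopathy_user = "A", herbal_user = "H")[out$user_group]
    idx <- stats::ave(seq_len(nrow(out)), out$user_group, FUN = seq_along)
    out$respondent_id <- sprintf("%s%02d", prefix,
                                 (idx - 1L) %% respondents_per_group + 1L)
    out <- out[sample.int(nrow(out)), c("respondent_id", "user_group",
                                        "medicine_evaluated", "capability",
                                        "valence")]
    rownames(out) <- NULL
    out
  })
}
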