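# End-to-end pipeline driver: reads the configured inputs, runs every stage
# that has data, and writes CSV outputs plus a JSON manifest. Used by the
# numbered scripts under analysis/; all computation lives in the stage
# functions, this file only sequences and persists.

# FNV-1a 32-bit hash over the serialized config, for manifest provenance
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # modular multiply by the FNV prime in 16-bit halves (doubles stay exact)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline run configuration
#'
#' @param reports_path path to a long-format use-report CSV, or `NULL` for
#'   fixture-only degraded mode (index table limited to RFC from the
#'   packaged citation counts).
#' @param statements_path path to a perception-statement CSV, or `NULL` to
#'   skip the capability stage.
#' @param preferences_path path to a respondent covariate/outcome CSV, or
#'   `NULL` to skip the preference-model stage.
#' @param outcome name of the 0/1 outcome column in the preference table.
#' @param nc optional NC override for the index table.
#' @param ri_convention RI convention (see [relative_importance()]).
#' @param rounding index-table reporting policy, `"truncate"` or `"round"`.
#' @param digits reporting decimal places.
#' @param vif_threshold VIF exclusion threshold (default 5).
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory (created if absent).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(reports_path = NULL, statements_path = NULL,
                            preferences_path = NULL,
                            outcome = "prefers_herbal", nc = NULL,
                            ri_convention = c("raw_rfc", "normalized"),
                            rounding = c("truncate", "round"), digits = 3,
                            vif_threshold = 5, seed = 1L,
                            out_dir = "results") {
  structure(list(reports_path = reports_path,
                 statements_path = statements_path,
                 preferences_path = preferences_path, outcome = outcome,
                 nc = nc, ri_convention = match.arg(ri_convention),
                 rounding = match.arg(rounding), digits = digits,
                 vif_threshold = vif_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full survey-analysis pipeline
#'
#' Executes, for each configured input, the matching stage: index table from
#' use reports (or a degraded RFC-only table from the packaged citation
#' fixture when no reports are given), capability tallies from perception
#' statements, and the VIF-screened logistic preference model. Writes each
#' product as CSV under `out_dir` plus a `manifest.json` (package version,
#' seed, resolved config and its hash) and returns the products invisibly.
#' Outputs are reproducible byte-for-byte for identical config + inputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the computed tables and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$reports_path, config$statements_path,
              config$preferences_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  products <- list()

  if (!is.null(config$reports_path)) {
    surv <- read_use_reports(config$reports_path)
    tab <- compute_index_table(surv, convention = config$ri_convention,
                               nc = config$nc)
    tab_fmt <- format_index_table(tab, policy = config$rounding,
                                  digits = config$digits)
  } else {
    message("no use reports configured: index table limited to RFC from ",
            "the packaged citation fixture; capability of the survey-level ",
            "indices (UV, RI, CII, CVI) requires raw reports")
    fx <- load_citation_fixture()
    tab <- data.frame(species_id = fx$species, fc = fx$citations,
                      rfc = rfc(fx$citations, citation_fixture_n_informants()),
                      stringsAsFactors = FALSE)
    tab_fmt <- tab
    tab_fmt$rfc <- if (config$rounding == "truncate") {
      truncate_decimal(tab$rfc, config$digits)
    } else round(tab$rfc, config$digits)
  }
  path <- file.path(config$out_dir, "index_table.csv")
  utils::write.csv(tab_fmt, path, row.names = FALSE)
  products$index_table <- tab
  products$index_table_path <- path

  if (!is.null(config$statements_path)) {
    statements <- read_perception_statements(config$statements_path)
    cells <- compare_groups(statements)
    long <- do.call(rbind, lapply(names(cells), function(k) {
      cbind(data.frame(user_group = sub(":.*", "", k),
                       medicine_evaluated = sub(".*:", "", k),
                       stringsAsFactors = FALSE),
            as.data.frame(cells[[k]]))
    }))
    path <- file.path(config$out_dir, "capability_tallies.csv")
    utils::write.csv(long, path, row.names = FALSE)
    products$capability_tallies <- cells
    products$capability_tallies_path <- path
  }

  if (!is.null(config$preferences_path)) {
    pref <- utils::read.csv(config$preferences_path, stringsAsFactors = FALSE)
    covars <- setdiff(names(pref)[vapply(pref, is.numeric, logical(1))],
                      config$outcome)
    screen <- vif_screen(pref[covars], threshold = config$vif_threshold)
    fit <- fit_logit(pref, outcome = config$outcome,
                     covariates = screen$kept)
    out_tab <- fit$coefficients
    num <- c("estimate", "std_error", "z", "p", "odds_ratio")
    out_tab[num] <- lapply(out_tab[num], round, digits = config$digits)
    path <- file.path(config$out_dir, "logit_table.csv")
    utils::write.csv(out_tab, path, row.names = FALSE)
    products$vif_screen <- screen
    products$logit_fit <- fit
    products$logit_table_path <- path
  }

  resolved <- config
  class(resolved) <- NULL
  config_json <- jsonlite::toJSON(resolved, auto_unbox = TRUE, null = "null")
  manifest <- list(
    package = "ethnoindices",
    version = as.character(utils::packageVersion("ethnoindices")),
    seed = config$seed,
    config = resolved,
    config_hash = fnv1a_hash(as.character(config_json)))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  products$manifest_path <- manifest_path
  invisible(products)
}
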