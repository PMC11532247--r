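# Data model for informant use-report surveys.
#
# The atomic datum is the use report: one informant citing one species for
# one use category. All ethnobotanical indices are functions of the
# deduplicated set of (informant, species, category) triples.

PLANT_PARTS <- c("leaf", "root", "bark", "stem", "flower", "seed", "fruit",
                 "latex", "whole-aerial", "unknown")

REPORT_COLUMNS <- c("informant_id", "species_id", "use_category",
                    "plant_part", "preparation", "administration")

normalize_species <- function(x) {
  gsub("\\s+", " ", trimws(as.character(x)))
}

#' Construct a validated use-report survey
#'
#' Bundles the informant universe (size N), the use-category universe
#' (size NC) and the deduplicated use reports into a single object, the sole
#' input to index computation. Duplicate (informant, species, category)
#' triples are collapsed to one report with a warning; species names are
#' whitespace-normalized (no taxonomic resolution is attempted).
#'
#' @param reports data frame with at least `informant_id`, `species_id` and
#'   `use_category`; optional `plant_part` (closed vocabulary, see
#'   [plant_part_levels()]), `preparation` and `administration`.
#' @param informants optional character vector fixing the informant universe;
#'   defaults to the distinct informants observed. Every report's informant
#'   must belong to it.
#' @param use_categories optional character vector fixing the category
#'   universe (NC is deliberately configurable rather than hard-coded, since
#'   surveys differ in whether rare categories are kept as distinct strata);
#'   defaults to the distinct categories observed.
#' @return An object of class `ethno_survey` with elements `informants`,
#'   `use_categories` and `reports`.
#' @export
survey <- function(reports, informants = NULL, use_categories = NULL) {
  if (!is.data.frame(reports)) {
    stop("`reports` must be a data frame", call. = FALSE)
  }
  mandatory <- c("informant_id", "species_id", "use_category")
  missing_cols <- setdiff(mandatory, names(reports))
  if (length(missing_cols) > 0L) {
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reports$informant_id <- as.character(reports$informant_id)
  reports$species_id <- normalize_species(reports$species_id)
  reports$use_category <- as.character(reports$use_category)
  if (nrow(reports) > 0L &&
      (any(!nzchar(reports$informant_id)) || any(!nzchar(reports$species_id)) ||
       any(!nzchar(reports$use_category)) || anyNA(reports[mandatory]))) {
    stop("informant_id, species_id and use_category must be non-empty",
         call. = FALSE)
  }
  if (is.null(reports$plant_part)) {
    reports$plant_part <- rep("unknown", nrow(reports))
  } else {
    part <- tolower(trimws(as.character(reports$plant_part)))
    part[is.na(part) | !nzchar(part)] <- "unknown"
    bad <- !(part %in% PLANT_PARTS)
    if (any(bad)) {
      warning("plant_part value(s) outside the vocabulary set to 'unknown': ",
              paste(unique(part[bad]), collapse = ", "), call. = FALSE)
      part[bad] <- "unknown"
    }
    reports$plant_part <- part
  }
  for (free_col in c("preparation", "administration")) {
    v <- if (is.null(reports[[free_col]])) rep("", nrow(reports)) else
      as.character(reports[[free_col]])
    v[is.na(v)] <- ""
    reports[[free_col]] <- v
  }
  reports <- reports[REPORT_COLUMNS]

  key <- paste(reports$informant_id, reports$species_id,
               reports$use_category, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate (informant, species, category) report(s) collapsed",
            call. = FALSE)
    reports <- reports[!dup, , drop = FALSE]
  }
  rownames(reports) <- NULL

  informants <- if (is.null(informants)) {
    sort(unique(reports$informant_id))
  } else {
    unique(as.character(informants))
  }
  use_categories <- if (is.null(use_categories)) {
    sort(unique(reports$use_category))
  } else {
    unique(as.character(use_categories))
  }
  if (length(informants) < 1L) stop("survey needs at least one informant", call. = FALSE)
  if (length(use_categories) < 1L) stop("survey needs at least one use category", call. = FALSE)
  stray_inf <- setdiff(reports$informant_id, informants)
  if (length(stray_inf) > 0L) {
    stop("report informant(s) outside the informant universe: ",
         paste(utils::head(stray_inf, 5L), collapse = ", "), call. = FALSE)
  }
  stray_cat <- setdiff(reports$use_category, use_categories)
  if (length(stray_cat) > 0L) {
    stop("report use category(ies) outside the category universe: ",
         paste(utils::head(stray_cat, 5L), collapse = ", "), call. = FALSE)
  }

  structure(list(informants = informants, use_categories = use_categories,
                 reports = reports),
            class = "ethno_survey")
}

#' @export
print.ethno_survey <- function(x, ...) {
  cat("Use-report survey: N =", length(x$informants),
      "informants, NC =", length(x$use_categories), "use categories,",
      nrow(x$reports), "reports on",
      length(unique(x$reports$species_id)), "species\n")
  invisible(x)
}

#' Closed vocabulary of plant parts
#' @return Character vector of recognized plant-part labels.
#' @export
plant_part_levels <- function() PLANT_PARTS

#' Read a long-format use-report file
#'
#' Reads delimiter-separated text (header row, UTF-8) where one row is one
#' informant x species x use-category report, and returns a validated
#' [survey()]. Column names can be remapped through `columns` so files from
#' other survey tools can be ingested without editing.
#'
#' @param path path to the file.
#' @param columns named character vector mapping the canonical names
#'   (`informant_id`, `species_id`, `use_category`, `plant_part`,
#'   `preparation`, `administration`) to the names used in the file.
#' @param delim field delimiter (default comma).
#' @param informants,use_categories optional universe overrides, passed to
#'   [survey()].
#' @return An `ethno_survey`.
#' @export
read_use_reports <- function(path, columns = NULL, delim = ",",
                             informants = NULL, use_categories = NULL) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, quote = "\"",
                           fileEncoding = "UTF-8", comment.char = "")
  if (nrow(raw) == 0L) {
    stop("format error: no data rows in ", path, call. = FALSE)
  }
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      src <- columns[[canon]]
      if (!src %in% names(raw)) {
        stop("format error: column '", src, "' (mapped to ", canon,
             ") not found in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- c("informant_id", "species_id", "use_category")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0L) {
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  survey(raw, informants = informants, use_categories = use_categories)
}

#' Write a survey back to long-format delimited text
#'
#' Inverse of [read_use_reports()]: `read_use_reports(write_use_reports(s))`
#' reproduces `s` whenever the universes equal the observed sets.
#'
#' @param survey an `ethno_survey`.
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_use_reports <- function(survey, path, delim = ",") {
  stopifnot(inherits(survey, "ethno_survey"))
  utils::write.table(survey$reports, path, sep = delim, row.names = FALSE,
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' Frequency of citation per species
#'
#' FCs: the number of DISTINCT informants with at least one report for the
#' species. An informant citing a species in several use categories counts
#' once. Uncited species are absent from the result.
#'
#' @param survey an `ethno_survey`.
#' @return Named integer vector, species id -> citation count, sorted
#'   decreasing.
#' @export
fc_counts <- function(survey) {
  stopifnot(inherits(survey, "ethno_survey"))
  r <- survey$reports
  if (nrow(r) == 0L) return(stats::setNames(integer(0), character(0)))
  pair <- unique(r[c("species_id", "informant_id")])
  out <- vapply(split(pair$informant_id, pair$species_id), length, integer(1))
  sort(out, decreasing = TRUE)
}

#' Number of distinct cited use categories per species
#'
#' NUs: how many different use categories the species was cited in, by any
#' informant. Bounded by NC.
#'
#' @param survey an `ethno_survey`.
#' @return Named integer vector, species id -> category count, sorted
#'   decreasing.
#' @export
nu_counts <- function(survey) {
  stopifnot(inherits(survey, "ethno_survey"))
  r <- survey$reports
  if (nrow(r) == 0L) return(stats::setNames(integer(0), character(0)))
  pair <- unique(r[c("species_id", "use_category")])
  out <- vapply(split(pair$use_category, pair$species_id), length, integer(1))
  sort(out, decreasing = TRUE)
}

#' Share of reports per plant part
#'
#' Fractions over all reports (not species), summing to 1. If every report's
#' part is unknown a warning is raised and `c(unknown = 1)` returned; an
#' empty survey returns an empty vector.
#'
#' @param survey an `ethno_survey`.
#' @return Named numeric vector of fractions, sorted decreasing.
#' @export
part_usage_shares <- function(survey) {
  stopifnot(inherits(survey, "ethno_survey"))
  part <- survey$reports$plant_part
  if (length(part) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (all(part == "unknown")) {
    warning("all plant parts are unknown", call. = FALSE)
    return(c(unknown = 1.0))
  }
  tab <- table(part)
  sort(stats::setNames(as.vector(tab) / sum(tab), names(tab)), decreasing = TRUE)
}
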