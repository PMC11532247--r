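# The five ethnobotanical indices.
#
# With deduplicated use reports, let for species s:
#   FCs = number of distinct citing informants
#   NUs = number of distinct cited use categories
#   UR  = an (informant, category) use report
# and N = number of informants, NC = number of use categories. Then
#   UV  = (total reports for s) / N
#   RFC = FCs / N
#   RI  = (RFCs' + RNUs) / 2      with RNUs = NUs / max NU; RFCs' is RFC
#                                 either raw or divided by max RFC (see below)
#   CII = sum over categories of per-category report counts / N
#   CVI = (NUs / NC) * (FCs / N) * CII
# Under this data model UV and CII coincide (both equal total reports / N);
# both are still emitted for fidelity to the index literature.

#' Use value (UV) of a species
#'
#' Sum over informants of the number of use reports each contributed for the
#' species, divided by the number of informants N. A species nobody cites
#' has UV 0.
#'
#' @param survey an `ethno_survey`.
#' @param species_id species identifier (whitespace-normalized before lookup).
#' @return Nonnegative fraction.
#' @export
use_value <- function(survey, species_id) {
  stopifnot(inherits(survey, "ethno_survey"))
  sp <- normalize_species(species_id)
  sum(survey$reports$species_id == sp) / length(survey$informants)
}

#' Relative frequency of citation (RFC)
#'
#' @param fc number of distinct citing informants (FCs).
#' @param n total number of informants (N >= 1).
#' @return `fc / n`, kept unformatted; apply [truncate_decimal()] (or
#'   rounding) only at reporting time.
#' @export
rfc <- function(fc, n) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  if (any(fc < 0) || any(fc > n)) {
    stop("`fc` must lie in [0, n]", call. = FALSE)
  }
  fc / n
}

#' Relative importance index (RI)
#'
#' Mean of a citation term and the relative number of use categories
#' RNUs = `nu_s / nu_max`. The citation term is ambiguous in the index
#' literature between the raw RFC and RFC normalized by its maximum; both
#' conventions are implemented and the choice is always carried in output:
#' \describe{
#'   \item{`raw_rfc`}{`(rfc_s + nu_s/nu_max) / 2` (default)}
#'   \item{`normalized`}{`(rfc_s/rfc_max + nu_s/nu_max) / 2`}
#' }
#'
#' @param rfc_s species RFC.
#' @param nu_s species NU count.
#' @param rfc_max maximum RFC over species (> 0).
#' @param nu_max maximum NU over species (>= 1).
#' @param convention `"raw_rfc"` or `"normalized"`.
#' @return Fraction in (0, 1\] for cited species.
#' @export
relative_importance <- function(rfc_s, nu_s, rfc_max, nu_max,
                                convention = c("raw_rfc", "normalized")) {
  convention <- match.arg(convention)
  if (any(rfc_max <= 0) || any(nu_max < 1)) {
    stop("`rfc_max` and `nu_max` must be positive", call. = FALSE)
  }
  if (any(rfc_s > rfc_max) || any(nu_s > nu_max)) {
    stop("per-species values cannot exceed their maxima", call. = FALSE)
  }
  cite_term <- if (convention == "normalized") rfc_s / rfc_max else rfc_s
  (cite_term + nu_s / nu_max) / 2
}

#' Cultural importance index (CII)
#'
#' Sum over use categories of the number of informants reporting the species
#' in that category, divided by N. Ranges over \[0, NC\]; with deduplicated
#' reports it equals [use_value()].
#'
#' @inheritParams use_value
#' @return Value in \[0, NC\].
#' @export
cii <- function(survey, species_id) {
  stopifnot(inherits(survey, "ethno_survey"))
  sp <- normalize_species(species_id)
  r <- survey$reports[survey$reports$species_id == sp, , drop = FALSE]
  if (nrow(r) == 0L) return(0)
  per_cat <- vapply(split(r$informant_id, r$use_category),
                    function(x) length(unique(x)), integer(1))
  sum(per_cat) / length(survey$informants)
}

#' Cultural value index (CVI)
#'
#' `(nu_s / nc) * (fc / n) * cii_s`; both leading factors lie in \[0, 1\] so
#' CVI never exceeds CII.
#'
#' @param nu_s distinct cited use categories for the species.
#' @param nc total number of use categories (>= 1).
#' @param fc distinct citing informants.
#' @param n total informants (>= 1).
#' @param cii_s the species CII.
#' @return Nonnegative value, at most `cii_s`.
#' @export
cvi <- function(nu_s, nc, fc, n, cii_s) {
  if (any(nc < 1) || any(n < 1)) stop("`nc` and `n` must be >= 1", call. = FALSE)
  if (any(nu_s > nc) || any(fc > n)) {
    stop("`nu_s` <= `nc` and `fc` <= `n` required", call. = FALSE)
  }
  (nu_s / nc) * (fc / n) * cii_s
}

#' Truncate a value at a decimal place (no rounding)
#'
#' Truncation toward zero, the formatting used by the reported index tables
#' (e.g. 68/145 = 0.46896 prints as 0.468, not 0.469). A small fuzz absorbs
#' binary floating-point noise so values already at the requested precision
#' pass through unchanged (0.29 at 2 places stays 0.29).
#'
#' @param x numeric vector.
#' @param places nonnegative integer number of decimal places.
#' @return Truncated values.
#' @export
truncate_decimal <- function(x, places) {
  if (length(places) != 1L || places < 0 || places != floor(places)) {
    stop("`places` must be a single nonnegative integer", call. = FALSE)
  }
  f <- 10^places
  trunc(x * f + sign(x) * 1e-8) / f
}

#' Compute the full species index table
#'
#' The survey-table engine: one row per cited species with FC, NU, UV, RFC,
#' RNU, RI, CII and CVI, plus rank columns for RFC, RI, CII and CVI. Ranks
#' are computed on the unformatted values, descending, with competition
#' ranking (ties share the minimum rank); display order is RI-descending
#' with ties broken by species name.
#'
#' @param survey an `ethno_survey`.
#' @param convention RI convention, see [relative_importance()].
#' @param nc optional override for the number of use categories NC (defaults
#'   to the survey's category universe size).
#' @return data frame of class `species_index_table` with attribute
#'   `ri_convention`; empty survey gives an empty table.
#' @seealso [format_index_table()] for report formatting.
#' @export
compute_index_table <- function(survey,
                                convention = c("raw_rfc", "normalized"),
                                nc = NULL) {
  stopifnot(inherits(survey, "ethno_survey"))
  convention <- match.arg(convention)
  n <- length(survey$informants)
  nc <- if (is.null(nc)) length(survey$use_categories) else as.integer(nc)
  if (nc < 1L) stop("`nc` must be >= 1", call. = FALSE)

  species <- sort(unique(survey$reports$species_id))
  if (length(species) == 0L) {
    out <- data.frame(species_id = character(0), fc = integer(0),
                      nu = integer(0), uv = numeric(0), rfc = numeric(0),
                      rnu = numeric(0), ri = numeric(0), cii = numeric(0),
                      cvi = numeric(0), rank_rfc = integer(0),
                      rank_ri = integer(0), rank_cii = integer(0),
                      rank_cvi = integer(0))
    class(out) <- c("species_index_table", "data.frame")
    attr(out, "ri_convention") <- convention
    return(out)
  }

  fc <- fc_counts(survey)[species]
  nu <- nu_counts(survey)[species]
  uv <- vapply(species, function(s) use_value(survey, s), numeric(1))
  rfc_v <- rfc(as.numeric(fc), n)
  rnu <- as.numeric(nu) / max(nu)
  ri <- relative_importance(rfc_v, as.numeric(nu), max(rfc_v), max(nu),
                            convention = convention)
  cii_v <- vapply(species, function(s) cii(survey, s), numeric(1))
  cvi_v <- cvi(as.numeric(nu), nc, as.numeric(fc), n, cii_v)

  comp_rank <- function(v) rank(-v, ties.method = "min")
  out <- data.frame(species_id = species, fc = as.integer(fc),
                    nu = as.integer(nu), uv = uv, rfc = rfc_v, rnu = rnu,
                    ri = ri, cii = cii_v, cvi = cvi_v,
                    rank_rfc = comp_rank(rfc_v), rank_ri = comp_rank(ri),
                    rank_cii = comp_rank(cii_v), rank_cvi = comp_rank(cvi_v),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ri, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("species_index_table", "data.frame")
  attr(out, "ri_convention") <- convention
  out
}

#' Format an index table for reporting
#'
#' Applies the reporting policy to the index columns: `"truncate"` (the
#' convention of the reported species table; see [truncate_decimal()]) or
#' `"round"` (the convention of regression tables). Rank columns and counts
#' are untouched.
#'
#' @param table a `species_index_table` from [compute_index_table()].
#' @param policy `"truncate"` or `"round"`.
#' @param digits decimal places (default 3).
#' @return The table with formatted index columns.
#' @export
format_index_table <- function(table, policy = c("truncate", "round"),
                               digits = 3) {
  policy <- match.arg(policy)
  cols <- intersect(c("uv", "rfc", "rnu", "ri", "cii", "cvi"), names(table))
  for (cl in cols) {
    table[[cl]] <- if (policy == "truncate") {
      truncate_decimal(table[[cl]], digits)
    } else {
      round(table[[cl]], digits)
    }
  }
  table
}
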