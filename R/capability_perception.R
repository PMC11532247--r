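# Capability-approach perception tallies.
#
# Respondents (frequent allopathy users vs frequent herbal users) evaluate a
# medicine system (allopathy or herbal) through statements coded against a
# set of Nussbaum central capabilities, each statement carrying a valence:
# the medicine is an enabler or a barrier for that capability. The unit of
# tallying is the statement ("instance"), not the respondent — one
# respondent may contribute several statements.

USER_GROUPS <- c("allopathy_user", "herbal_user")
MEDICINES <- c("allopathy", "herbal")
VALENCES <- c("enabler", "barrier")

#' Default capability label set
#'
#' An editorial reconstruction of a seven-capability subset of Nussbaum's
#' ten central capabilities, assembled from the capabilities that perception
#' studies of medicine choice discuss most (affiliation, bodily health,
#' control over one's environment, practical reasons) padded with life,
#' bodily integrity and emotions. Study-specific subsets differ, so every
#' tallying function accepts its own `capabilities` vector; this default is
#' a convenience, not a canonical set.
#'
#' @return Character vector of seven capability labels.
#' @export
default_capabilities <- function() {
  c("life", "bodily health", "bodily integrity", "emotions",
    "practical reasons", "affiliation", "control over one's environment")
}

validate_statements <- function(statements, capabilities) {
  if (!is.data.frame(statements)) {
    stop("`statements` must be a data frame", call. = FALSE)
  }
  needed <- c("respondent_id", "user_group", "medicine_evaluated",
              "capability", "valence")
  missing_cols <- setdiff(needed, names(statements))
  if (length(missing_cols) > 0L) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in needed) statements[[col]] <- as.character(statements[[col]])
  bad_group <- setdiff(unique(statements$user_group), USER_GROUPS)
  if (length(bad_group) > 0L) {
    stop("unknown user_group: ", paste(bad_group, collapse = ", "),
         "; allowed: ", paste(USER_GROUPS, collapse = ", "), call. = FALSE)
  }
  bad_med <- setdiff(unique(statements$medicine_evaluated), MEDICINES)
  if (length(bad_med) > 0L) {
    stop("unknown medicine_evaluated: ", paste(bad_med, collapse = ", "),
         "; allowed: ", paste(MEDICINES, collapse = ", "), call. = FALSE)
  }
  bad_cap <- setdiff(unique(statements$capability), capabilities)
  if (length(bad_cap) > 0L) {
    stop("unknown capability label(s): ", paste(bad_cap, collapse = ", "),
         "; allowed: ", paste(capabilities, collapse = ", "), call. = FALSE)
  }
  bad_val <- setdiff(unique(statements$valence), VALENCES)
  if (length(bad_val) > 0L) {
    stop("unknown valence: ", paste(bad_val, collapse = ", "),
         "; allowed: ", paste(VALENCES, collapse = ", "), call. = FALSE)
  }
  statements
}

#' Tally perception statements for one (group, medicine) cell
#'
#' Counts enabler and barrier statements per capability among statements
#' made by the given user group about the given medicine. Capabilities with
#' no statements appear with zero counts, so tallies from different cells
#' always align row-for-row.
#'
#' @param statements data frame with columns `respondent_id`, `user_group`,
#'   `medicine_evaluated`, `capability`, `valence`.
#' @param user_group `"allopathy_user"` or `"herbal_user"`.
#' @param medicine_evaluated `"allopathy"` or `"herbal"`.
#' @param capabilities allowed capability labels (default
#'   [default_capabilities()]); a statement with a label outside this set is
#'   a validation error.
#' @return data frame of class `capability_tally` with columns `capability`,
#'   `enabler`, `barrier`, `total`.
#' @export
tally_capabilities <- function(statements, user_group, medicine_evaluated,
                               capabilities = default_capabilities()) {
  user_group <- match.arg(user_group, USER_GROUPS)
  medicine_evaluated <- match.arg(medicine_evaluated, MEDICINES)
  statements <- validate_statements(statements, capabilities)
  sel <- statements$user_group == user_group &
    statements$medicine_evaluated == medicine_evaluated
  s <- statements[sel, , drop = FALSE]
  cap <- factor(s$capability, levels = capabilities)
  val <- factor(s$valence, levels = VALENCES)
  tab <- table(cap, val)
  out <- data.frame(capability = capabilities,
                    enabler = as.integer(tab[, "enabler"]),
                    barrier = as.integer(tab[, "barrier"]),
                    stringsAsFactors = FALSE)
  out$total <- out$enabler + out$barrier
  attr(out, "user_group") <- user_group
  attr(out, "medicine_evaluated") <- medicine_evaluated
  class(out) <- c("capability_tally", "data.frame")
  out
}

#' Cross-tabulate capability tallies over all group x medicine cells
#'
#' Produces the four tallies (each user group evaluating each medicine
#' system). Statement counts are conserved: the cell totals sum to the
#' number of input statements.
#'
#' @inheritParams tally_capabilities
#' @return Named list of four `capability_tally` data frames, keyed
#'   `"<user_group>:<medicine_evaluated>"`.
#' @export
compare_groups <- function(statements, capabilities = default_capabilities()) {
  statements <- validate_statements(statements, capabilities)
  cells <- expand.grid(user_group = USER_GROUPS, medicine = MEDICINES,
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    tally_capabilities(statements, cells$user_group[i], cells$medicine[i],
                       capabilities = capabilities)
  })
  names(out) <- paste(cells$user_group, cells$medicine, sep = ":")
  out
}

#' Read perception statements from delimited text
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @param capabilities allowed capability labels used for validation.
#' @return Validated statements data frame.
#' @export
read_perception_statements <- function(path, delim = ",",
                                       capabilities = default_capabilities()) {
  if (!file.exists(path)) stop("input file does not exist: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, quote = "\"",
                           fileEncoding = "UTF-8", comment.char = "")
  validate_statements(raw, capabilities)
}
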