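#' Required sample size for a finite household population
#'
#' Computes the number of households to survey from a finite sampling frame
#' using the finite-population correction
#' \deqn{n = \frac{N_T}{1 + N_T e_p^2}}
#' where \eqn{N_T} is the total number of households and \eqn{e_p} the
#' precision (margin of error) expressed as a fraction. The result is rounded
#' up to the next integer, the conservative sampling convention.
#'
#' The formula carries no explicit z term: the usual narrative pairing with a
#' "95 % confidence level" is a convention of the simplified estimator, not a
#' parameter of it. `precision = 0` is accepted as a limit flag meaning a full
#' census (the formula then reduces to \eqn{N_T}).
#'
#' @param total_households positive integer, the frame size \eqn{N_T}.
#' @param precision fraction in \[0, 1), the precision level \eqn{e_p}
#'   (default 0.05).
#' @return A positive integer, never exceeding `total_households`.
#' @examples
#' required_sample_size(227, 0.05) # 145
#' required_sample_size(1000, 0.05) # 286
#' @export
required_sample_size <- function(total_households, precision = 0.05) {
  if (!is.numeric(total_households) || length(total_households) != 1L ||
      !is.finite(total_households) || total_households < 1 ||
      total_households != floor(total_households)) {
    stop("`total_households` must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(precision) || length(precision) != 1L ||
      !is.finite(precision) || precision < 0 || precision >= 1) {
    stop("`precision` must be a single fraction in [0, 1)", call. = FALSE)
  }
  n <- total_households / (1 + total_households * precision^2)
  # guard against 145.0000000001-style float noise before ceiling
  as.integer(ceiling(n - 1e-9))
}

#' Sampling-frame record
#'
#' Light container bundling the frame size, a free-text confidence note and
#' the precision level; `required_sample_size()` accepts its fields directly.
#'
#' @param total_households positive integer \eqn{N_T}.
#' @param precision fraction in \[0, 1).
#' @param confidence_note free text (narrative only; not used in computation).
#' @return A list of class `sampling_frame`.
#' @export
sampling_frame <- function(total_households, precision = 0.05,
                           confidence_note = "95 % confidence level") {
  out <- list(total_households = total_households, precision = precision,
              confidence_note = confidence_note)
  class(out) <- "sampling_frame"
  # validate eagerly so invalid frames fail at construction
  required_sample_size(total_households, precision)
  out
}

#' @export
print.sampling_frame <- function(x, ...) {
  cat("Sampling frame: N_T =", x$total_households,
      "| e_p =", x$precision, "|", x$confidence_note, "\n")
  cat("Required sample size:",
      required_sample_size(x$total_households, x$precision), "\n")
  invisible(x)
}
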