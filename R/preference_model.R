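# Binary logistic model of herbal-vs-allopathy preference.
#
# Outcome: 1 = prefers herbal (medicinal plants), 0 = prefers allopathy.
# The log-odds are linear in the respondent covariates,
#   logit(P) = ln(p / (1 - p)) = b0 + b1 x1 + ... + bk xk,
# fitted by maximum likelihood via iteratively reweighted least squares
# (IRLS) with step-halving, after screening covariates for multicollinearity
# with variance inflation factors.

#' Variance-inflation-factor screen
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from the least-squares
#' regression of covariate j on all the others (with intercept). Covariates
#' whose VIF exceeds the threshold are removed one at a time from the
#' largest, recomputing all VIFs after each removal — dropping one member of
#' a collinear cluster often rescues the rest. Exactly collinear covariates
#' show infinite VIF and are excluded first.
#'
#' @param covariates data frame (or matrix) of numeric covariates, one
#'   column per covariate; at least two columns and more rows than columns.
#' @param threshold exclusion threshold (default 5).
#' @return List with `kept` (character), `excluded` (data frame of
#'   `covariate` and the `vif` at removal time) and `initial_vif` (named
#'   vector of the pre-screening VIFs).
#' @export
vif_screen <- function(covariates, threshold = 5) {
  x <- as.data.frame(covariates)
  if (ncol(x) < 2L) stop("need at least two covariates", call. = FALSE)
  if (nrow(x) <= ncol(x)) {
    stop("need more records than covariates", call. = FALSE)
  }
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all covariates must be numeric", call. = FALSE)
  }

  vif_one <- function(j, dat) {
    others <- dat[, setdiff(names(dat), j), drop = FALSE]
    fit <- stats::lm(dat[[j]] ~ ., data = others)
    # exact collinearity gives a perfect auxiliary fit; that is the very case
    # we are screening for, so silence summary.lm's note about it
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  all_vifs <- function(dat) {
    vapply(names(dat), vif_one, numeric(1), dat = dat)
  }

  initial <- all_vifs(x)
  excluded <- data.frame(covariate = character(0), vif = numeric(0),
                         stringsAsFactors = FALSE)
  repeat {
    if (ncol(x) < 2L) break
    v <- all_vifs(x)
    if (max(v) <= threshold) break
    worst <- names(v)[which.max(v)]
    excluded <- rbind(excluded,
                      data.frame(covariate = worst, vif = unname(v[worst]),
                                 stringsAsFactors = FALSE))
    x <- x[, setdiff(names(x), worst), drop = FALSE]
  }
  list(kept = names(x), excluded = excluded, initial_vif = initial)
}

#' Kolmogorov–Smirnov distance to a reference distribution
#'
#' The one-sample statistic D = sup_x |F_n(x) - F(x)|, evaluated at the
#' jump points of the empirical CDF (both sides of each jump).
#'
#' @param sample nonempty numeric vector.
#' @param reference vectorized cumulative distribution function, e.g.
#'   `pnorm` or `function(x) punif(x)`.
#' @return D in \[0, 1\].
#' @export
ks_statistic <- function(sample, reference) {
  if (length(sample) == 0L || anyNA(sample)) {
    stop("`sample` must be nonempty without NAs", call. = FALSE)
  }
  x <- sort(sample)
  n <- length(x)
  fx <- reference(x)
  max(abs(seq_len(n) / n - fx), abs(fx - (seq_len(n) - 1) / n))
}

logistic_loglik <- function(y, eta) {
  # numerically stable: -log(1 + exp(-eta)) for y=1, -log(1+exp(eta)) for y=0
  sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression with an intercept, fitted by
#' iteratively reweighted least squares with step-halving (the log
#' likelihood never decreases across iterations). Standard errors come from
#' the inverse observed information at the optimum; Wald z and two-sided
#' normal p-values and odds ratios exp(beta) are reported per coefficient.
#'
#' Complete or quasi-complete separation makes the MLE diverge; it is
#' detected (coefficient norm escaping with a non-vanishing gradient, or a
#' one-class outcome) and raised as an explicit error rather than returned
#' as silently huge estimates. A rank-deficient design raises an error
#' naming the aliased covariate.
#'
#' @param data data frame holding the outcome and covariates.
#' @param outcome name of the 0/1 outcome column (1 = prefers herbal).
#' @param covariates character vector of covariate columns (default: every
#'   other numeric column).
#' @param max_iterations IRLS iteration cap (default 50).
#' @param tolerance convergence tolerance on the maximum absolute
#'   coefficient change (default 1e-8).
#' @return Object of class `logit_fit`: `coefficients` (data frame with
#'   `term`, `estimate`, `std_error`, `z`, `p`, `odds_ratio`, `stars`),
#'   `iterations`, `converged`, `loglik`, `n`.
#' @export
fit_logit <- function(data, outcome = "outcome", covariates = NULL,
                      max_iterations = 50L, tolerance = 1e-8) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  y <- data[[outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be coded 0/1", call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          outcome)
  }
  if (length(covariates) > 0 && !all(covariates %in% names(data))) {
    stop("covariate(s) not found: ",
         paste(setdiff(covariates, names(data)), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("separation: outcome takes a single value; ",
         "both preference classes are required", call. = FALSE)
  }

  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(data[covariates])))
  storage.mode(X) <- "double"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular information matrix; aliased covariate(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  beta <- rep(0, ncol(X))
  ll <- logistic_loglik(y, drop(X %*% beta))
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    iterations <- it
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    delta <- tryCatch(solve(info, score), error = function(e) {
      stop("singular information matrix during IRLS", call. = FALSE)
    })
    # step-halving: never accept a step that lowers the log likelihood
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_cand <- logistic_loglik(y, drop(X %*% cand))
      if (ll_cand >= ll - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    moved <- max(abs(step * delta))
    beta <- beta + step * delta
    ll <- ll_cand
    if (max(abs(beta)) > 1e3 && max(abs(score)) > 1e-4) {
      stop("separation: coefficients diverge (complete or quasi-complete ",
           "separation in the data)", call. = FALSE)
    }
    if (moved < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(beta)) > 10) {
    # the MLE is escaping to infinity: coefficients keep growing without the
    # update ever settling, the signature of (quasi-)complete separation
    stop("separation: coefficients diverge (complete or quasi-complete ",
         "separation in the data)", call. = FALSE)
  }
  if (!converged) {
    warning("IRLS did not converge in ", max_iterations, " iterations",
            call. = FALSE)
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * w, X)
  se <- sqrt(diag(solve(info)))
  z <- wald_z(beta, se)
  p <- 2 * stats::pnorm(-abs(z))
  coef_tab <- data.frame(term = colnames(X), estimate = unname(beta),
                         std_error = unname(se), z = unname(z), p = unname(p),
                         odds_ratio = odds_ratio(unname(beta)),
                         stars = significance_stars(unname(p)),
                         stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab, iterations = iterations,
                 converged = converged, loglik = ll, n = length(y)),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, digits = 6, ...) {
  cat("Binary logistic fit (IRLS), n =", x$n, "\n")
  cat("Converged:", x$converged, "after", x$iterations,
      "iterations; log-likelihood", format(x$loglik, digits = digits), "\n\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$std_error <- round(tab$std_error, digits)
  tab$z <- round(tab$z, 3)
  tab$p <- signif(tab$p, 3)
  tab$odds_ratio <- round(tab$odds_ratio, 3)
  print(tab, row.names = FALSE)
  cat("---\nSignif. codes: '***' 0.001 '**' 0.01 '*' 0.05 '.' 0.1\n")
  invisible(x)
}

#' Wald z statistic
#' @param estimate coefficient estimate(s).
#' @param se standard error(s), strictly positive.
#' @return `estimate / se`.
#' @export
wald_z <- function(estimate, se) {
  if (any(se <= 0)) stop("`se` must be positive", call. = FALSE)
  estimate / se
}

#' Odds ratio from a log-odds coefficient
#' @param estimate finite coefficient(s) on the log-odds scale.
#' @return `exp(estimate)`.
#' @export
odds_ratio <- function(estimate) {
  if (any(!is.finite(estimate))) stop("`estimate` must be finite", call. = FALSE)
  exp(estimate)
}

#' Significance stars
#'
#' The conventional regression-table codes: `***` below 0.001, `**` below
#' 0.01, `*` below 0.05, `.` below 0.1, empty otherwise.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", ""), right = FALSE) |> as.character()
}
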