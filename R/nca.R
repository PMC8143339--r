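# Non-compartmental analysis of drug concentration-time data.

#' Terminal half-life by log-linear regression
#'
#' `ln(2) / lambda_z`, where `lambda_z` is the negative slope of the
#' least-squares line through the log-concentrations of the last `n_terminal`
#' positive observations. With `n_terminal = NULL` the number of terminal
#' points (3 or more) is chosen to maximise the adjusted R-squared of the
#' regression.
#'
#' @param times sampling times (h), strictly increasing.
#' @param concs concentrations (mg/L), nonnegative.
#' @param n_terminal number of terminal points used (default 3).
#' @return terminal half-life (h). Invariant to uniform scaling of `concs`.
#' @export
terminal_half_life <- function(times, concs, n_terminal = 3) {
  if (length(times) != length(concs))
    stop("'times' and 'concs' must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  pos <- concs > 0
  times <- times[pos]; concs <- concs[pos]
  n <- length(times)
  if (n < 3) stop("need >= 3 positive concentrations", call. = FALSE)
  slope_of <- function(k, score = FALSE) {
    idx <- (n - k + 1):n
    f <- lm(log(concs[idx]) ~ times[idx])
    list(lambda = -unname(coef(f)[2]),
         adjr2 = if (score) suppressWarnings(summary(f)$adj.r.squared) else NA)
  }
  if (is.null(n_terminal)) {
    cand <- lapply(3:n, slope_of, score = TRUE)
    best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "adjr2"))]]
  } else {
    if (n_terminal < 3 || n_terminal > n)
      stop("'n_terminal' must be between 3 and the number of positive points",
           call. = FALSE)
    best <- slope_of(n_terminal)
  }
  if (!is.finite(best$lambda) || best$lambda <= 0)
    stop("terminal slope is not negative; no terminal phase identified",
         call. = FALSE)
  log(2) / best$lambda
}

#' Area under the concentration-time curve
#'
#' Linear trapezoid to the last observation; if `lambda_z` is supplied, the
#' extrapolated tail `C_last / lambda_z` is added for the area to infinity.
#'
#' @param times sampling times (h), strictly increasing.
#' @param concs concentrations (mg/L), nonnegative.
#' @param lambda_z optional terminal rate constant (1/h) for extrapolation.
#' @return named vector `c(auc_last, auc_inf)` (mg h / L); `auc_inf` is `NA`
#'   when `lambda_z` is not given.
#' @export
nca_auc <- function(times, concs, lambda_z = NULL) {
  if (length(times) != length(concs))
    stop("'times' and 'concs' must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(concs < 0)) stop("'concs' must be nonnegative", call. = FALSE)
  n <- length(times)
  auc_last <- if (n > 1)
    sum(diff(times) * (concs[-1] + concs[-n]) / 2) else 0
  auc_inf <- NA_real_
  if (!is.null(lambda_z)) {
    .assert_positive(lambda_z, "lambda_z")
    auc_inf <- auc_last + concs[n] / lambda_z
  }
  c(auc_last = auc_last, auc_inf = auc_inf)
}
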