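# Sequential weighted-least-squares naive-pooled estimation: PK first, then
# the cytokine (PD) stage with PK fixed, then the transaminase (disease)
# stage with everything upstream fixed. Destructive sampling gives one
# observation per animal, so all observations enter a single pooled
# objective; there are no per-animal effects.

#' Model predictions for an observation table
#'
#' Simulates each distinct (dose, ConA status) condition once at exactly the
#' observation times and maps every record to its model observable.
#'
#' @param params a [model_parameters()] object.
#' @param data an observation table (see [read_observation_table()]).
#' @param rtol,atol solver tolerances passed to [simulate_group()].
#' @return numeric vector of predictions aligned with `data` rows.
#' @export
predict_observations <- function(params, data, rtol = 1e-8, atol = 1e-10) {
  data <- validate_observation_table(data)
  bad <- setdiff(unique(data$analyte), .observables)
  if (length(bad))
    stop("observations with no matching model observable: ",
         paste(bad, collapse = ", "), call. = FALSE)
  yhat <- numeric(nrow(data))
  key <- paste(data$dose_mg_per_kg, data$cona)
  for (k in unique(key)) {
    rows <- which(key == k)
    dose <- data$dose_mg_per_kg[rows[1]]
    cona <- data$cona[rows[1]]
    tt <- data$time_h[rows]
    if (all(data$analyte[rows] == "GRMS55")) {
      # drug-only condition: the closed form is exact and fast
      yhat[rows] <- pk_concentration(tt, dose, params$pk)
    } else {
      traj <- simulate_group(params, dose = dose, times = unique(tt),
                             cona = cona, rtol = rtol, atol = atol)
      for (an in unique(data$analyte[rows])) {
        r <- rows[data$analyte[rows] == an]
        yhat[r] <- observable(traj, an)[match(data$time_h[r], traj$time)]
      }
    }
  }
  yhat
}

#' Weighted least-squares objective
#'
#' `sum(w * (y - yhat)^2)` with prediction-based weights
#' `w = 1 / max(yhat, eps)^(2 * weight_exponent)`. The default
#' `weight_exponent = 1` gives `1/yhat^2`, i.e. relative (proportional-error)
#' weighting; `0` gives ordinary least squares. `eps` guards zero
#' predictions.
#'
#' @param params a [model_parameters()] object.
#' @param data an observation table.
#' @param weight_exponent weighting exponent (default 1).
#' @param eps floor applied to predictions inside the weights.
#' @return nonnegative scalar; exactly 0 iff predictions equal observations.
#' @export
wls_objective <- function(params, data, weight_exponent = 1, eps = 1e-8) {
  yhat <- predict_observations(params, data)
  sum(((data$value - yhat) / pmax(yhat, eps)^weight_exponent)^2)
}

#' WLS goodness-of-fit information criteria
#'
#' Convention used package-wide for a weighted sum of squares `WSS` from `n`
#' observations and `p` estimated parameters:
#' `AIC = n * log(WSS / n) + 2 p` and `BIC = n * log(WSS / n) + p * log(n)`
#' (additive constants dropped, as usual for least-squares criteria).
#'
#' @param objective final WLS value, >= 0.
#' @param n_obs number of observations; must exceed `n_params`.
#' @param n_params number of estimated parameters, >= 1.
#' @return named vector `c(aic, bic)`.
#' @export
information_criteria <- function(objective, n_obs, n_params) {
  if (!is.numeric(objective) || objective < 0)
    stop("'objective' must be >= 0", call. = FALSE)
  if (n_params < 1 || n_obs <= n_params)
    stop("need n_obs > n_params >= 1", call. = FALSE)
  ll <- n_obs * log(objective / n_obs)
  c(aic = ll + 2 * n_params, bic = ll + n_params * log(n_obs))
}

#' @keywords internal
.make_fit <- function(estimates, cv, objective, n_obs, fixed, converged,
                      message, unidentifiable = character(),
                      hessian = NULL, weight_exponent = 1) {
  p <- length(estimates)
  ic <- if (n_obs > p && objective > 0) information_criteria(objective, n_obs, p)
        else c(aic = NA_real_, bic = NA_real_)
  structure(list(estimates = estimates, cv_percent = cv,
                 objective = objective, aic = unname(ic["aic"]),
                 bic = unname(ic["bic"]), n_obs = n_obs,
                 converged = converged, fixed = fixed,
                 unidentifiable = unidentifiable, message = message,
                 hessian = hessian, weight_exponent = weight_exponent),
            class = "cona_fit")
}

#' @export
print.cona_fit <- function(x, ...) {
  cat(sprintf("WLS fit: %d observations, objective = %.6g, AIC = %.4g, BIC = %.4g\n",
              x$n_obs, x$objective, x$aic, x$bic))
  cat(sprintf("converged: %s (%s)\n", x$converged, x$message))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    cv_percent = round(x$cv_percent, 1))
  print(tab)
  if (length(x$fixed)) cat("fixed:", paste(x$fixed, collapse = ", "), "\n")
  if (length(x$unidentifiable))
    cat("flagged unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

# Core log-scale Levenberg-Marquardt driver. `resid_fn` maps a natural-scale
# named parameter vector to the weighted residual vector; starting values and
# box bounds are on the natural scale.
#' @keywords internal
.wls_fit <- function(resid_fn, init, lower = init / 100, upper = init * 100,
                     maxiter = 200) {
  lp0 <- log(init)
  fn <- function(lp) resid_fn(setNames(exp(lp), names(init)))
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                     ptol = 1e-10)
  fit <- minpack.lm::nls.lm(par = lp0, lower = log(lower), upper = log(upper),
                            fn = fn, control = ctrl)
  est <- setNames(exp(fit$par), names(init))
  n <- length(fn(fit$par))
  p <- length(est)
  # asymptotic CV% from the Gauss-Newton curvature (J'J on the log scale):
  # the log-scale SE is the relative SE of the natural-scale estimate.
  cv <- rep(NA_real_, p)
  s2 <- if (n > p) fit$deviance / (n - p) else NA_real_
  if (is.finite(s2)) {
    cov_log <- try(solve(fit$hessian) * s2, silent = TRUE)
    if (!inherits(cov_log, "try-error")) {
      dg <- diag(cov_log)
      cv[dg >= 0] <- 100 * sqrt(dg[dg >= 0])
    }
  }
  list(estimates = est, cv = setNames(cv, names(init)),
       objective = fit$deviance, n_obs = n,
       converged = fit$info %in% 1:4, message = fit$message,
       hessian = fit$hessian)
}

#' @keywords internal
.subset_analytes <- function(data, analytes, what) {
  data <- validate_observation_table(data)
  data <- data[data$analyte %in% analytes, , drop = FALSE]
  if (!nrow(data)) stop("no ", what, " observations in 'data'", call. = FALSE)
  data
}

#' Fit the pharmacokinetic model
#'
#' Minimises the WLS objective over `(Vd_F, ka, ke)` using the closed-form
#' concentration profile, pooling all dose groups with shared parameters
#' (dose linearity). The two-exponential model is exactly symmetric under
#' swapping `ka` and `ke` (with `Vd_F` rescaled), so both branches are fitted
#' from data-driven starts; when their objectives tie, `terminal_phase`
#' selects the reported branch — `"absorption"` (default) reports the
#' flip-flop solution in which the terminal slope is the absorption rate, the
#' regime of slow intraperitoneal absorption this model describes.
#'
#' @param data observation table restricted to the drug analyte (rows for
#'   other analytes are ignored); needs >= 3 distinct sampling times.
#' @param init optional named starting values `c(Vd_F, ka, ke)`; by default
#'   derived from the data (terminal log-linear slope, observed tmax and
#'   dose-normalised peak).
#' @param weight_exponent WLS weighting exponent (see [wls_objective()]).
#' @param terminal_phase which branch to report on a tie: `"absorption"`
#'   (flip-flop, `ka < ke`) or `"elimination"` (`ka > ke`).
#' @return a `cona_fit` with estimates, CV%, objective, AIC/BIC.
#' @export
fit_pk <- function(data, init = NULL, weight_exponent = 1,
                   terminal_phase = c("absorption", "elimination")) {
  terminal_phase <- match.arg(terminal_phase)
  data <- .subset_analytes(data, "GRMS55", "drug concentration")
  if (length(unique(data$time_h)) < 3)
    stop("PK fit needs >= 3 distinct sampling times", call. = FALSE)
  if (all(data$dose_mg_per_kg == 0))
    stop("PK fit needs at least one dosed group", call. = FALSE)

  resid_fn <- function(th) {
    pk <- pk_parameters(th[["Vd_F"]], th[["ka"]], th[["ke"]])
    yhat <- pk_concentration(data$time_h, 1, pk) * data$dose_mg_per_kg
    (data$value - yhat) / pmax(yhat, 1e-8)^weight_exponent
  }

  if (is.null(init)) init <- .pk_init(data)
  swap <- function(th) c(Vd_F = unname(th[["Vd_F"]] * th[["ke"]] / th[["ka"]]),
                         ka = unname(th[["ke"]]), ke = unname(th[["ka"]]))
  f1 <- .wls_fit(resid_fn, init)
  f2 <- .wls_fit(resid_fn, swap(init))
  pick <- if (abs(f1$objective - f2$objective) >
              1e-6 * (f1$objective + f2$objective + 1e-12)) {
    if (f1$objective < f2$objective) f1 else f2
  } else {
    flip1 <- f1$estimates[["ka"]] < f1$estimates[["ke"]]
    want_flip <- terminal_phase == "absorption"
    if (flip1 == want_flip) f1 else f2
  }
  .make_fit(pick$estimates, pick$cv, pick$objective, pick$n_obs,
            fixed = character(), converged = pick$converged,
            message = pick$message, hessian = pick$hessian,
            weight_exponent = weight_exponent)
}

# Data-driven PK starting values: terminal log-linear slope (3 late points of
# the pooled dose-normalised means), peak time/height of the mean profile,
# and the Bateman tmax relation to recover the faster rate.
#' @keywords internal
.pk_init <- function(data) {
  d <- data[data$dose_mg_per_kg > 0, ]
  cn <- d$value / d$dose_mg_per_kg
  tt <- sort(unique(d$time_h))
  prof <- vapply(tt, function(t) mean(cn[d$time_h == t]), numeric(1))
  pos <- prof > 0
  lz <- tryCatch(log(2) / terminal_half_life(tt[pos], prof[pos],
                                             n_terminal = min(3, sum(pos))),
                 error = function(e) NA_real_)
  if (!is.finite(lz)) lz <- 1
  imax <- which.max(prof)
  tmax <- tt[imax]
  # solve ln(mu/lz)/(mu - lz) = tmax for the faster rate mu
  mu <- tryCatch(uniroot(function(m) log(m / lz) / (m - lz) - tmax,
                         lower = lz * 1.001, upper = lz * 1000,
                         extendInt = "no")$root,
                 error = function(e) 3 * lz)
  cmax_pred <- lz / (lz - mu) * (exp(-mu * tmax) - exp(-lz * tmax))
  V0 <- max(cmax_pred / max(prof[imax], 1e-12), 1e-3)
  c(Vd_F = V0, ka = lz, ke = mu)
}

#' Fit the cytokine (pharmacodynamic) stage
#'
#' With the pharmacokinetic parameters fixed at the PK-stage estimates and
#' the baselines fixed at the healthy-animal means, jointly fits all four
#' cytokine series by WLS over `{tau, kout x4, IC50 x3, S x4, kin_IL10_dis,
#' I_IL10_IFN}` (14 parameters; the maximal inhibition fractions are fixed to
#' 1 and the production rates are derived from the baselines). If the data
#' contain no drug-treated group the IC50s are inoperative: they are dropped
#' from the estimation and flagged unidentifiable, while the stimulation and
#' turnover parameters are still estimated.
#'
#' @param data observation table restricted to the four cytokines (other
#'   analytes ignored).
#' @param fixed_pk a [pk_parameters()] object from the PK stage.
#' @param baselines named vector with `TNFa`, `IFNg`, `IL6`, `IL10` (ng/L).
#' @param init named starting values for the 14 free parameters (names as in
#'   the return value); required.
#' @param weight_exponent WLS weighting exponent.
#' @param conA_time challenge time (h post-dose).
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @return a `cona_fit`; `fixed` lists the non-estimated quantities.
#' @export
fit_pd <- function(data, fixed_pk, baselines, init, weight_exponent = 1,
                   conA_time = 0.5, maxiter = 200) {
  stopifnot(inherits(fixed_pk, "pk_parameters"))
  need <- c("TNFa", "IFNg", "IL6", "IL10")
  if (!all(need %in% names(baselines)))
    stop("baselines must name TNFa, IFNg, IL6, IL10", call. = FALSE)
  data <- .subset_analytes(data, need, "cytokine")

  free <- .free_pd_names
  unident <- character()
  if (all(data$dose_mg_per_kg == 0)) {
    unident <- c("IC50_TNF", "IC50_IFN", "IC50_IL6")
    free <- setdiff(free, unident)
  }
  if (missing(init) || is.null(init))
    stop("'init' starting values are required for the PD fit", call. = FALSE)
  if (!all(free %in% names(init)))
    stop("init must name: ", paste(setdiff(free, names(init)), collapse = ", "),
         call. = FALSE)
  init <- init[free]

  base <- .pd_template(fixed_pk, baselines, conA_time)
  resid_fn <- function(th) {
    pars <- .set_flat(base, th)
    yhat <- predict_observations(pars, data, rtol = 1e-7, atol = 1e-9)
    (data$value - yhat) / pmax(yhat, 1e-8)^weight_exponent
  }
  f <- .wls_fit(resid_fn, init, maxiter = maxiter)
  .make_fit(f$estimates, f$cv, f$objective, f$n_obs,
            fixed = c("Vd_F", "ka", "ke", "Imax_TNF", "Imax_IFN", "Imax_IL6",
                      "R0 (all)", "kin (derived)"),
            converged = f$converged, message = f$message,
            unidentifiable = unident, hessian = f$hessian,
            weight_exponent = weight_exponent)
}

# Template parameter set whose free entries are overwritten by the fitters;
# placeholder values are irrelevant (every free parameter is set before use).
#' @keywords internal
.pd_template <- function(pk, baselines, conA_time = 0.5,
                         disease = NULL) {
  if (is.null(disease))
    disease <- disease_parameters(S_ALT_TNF = 1e-3, S_ALT_IFN = 1e-3,
                                  kout_ALT = 0.1, S_AST_TNF = 1e-3,
                                  S_AST_IFN = 1e-3, kout_AST = 0.1,
                                  R0_ALT = if ("ALT" %in% names(baselines))
                                    baselines[["ALT"]] else 35,
                                  R0_AST = if ("AST" %in% names(baselines))
                                    baselines[["AST"]] else 60)
  model_parameters(
    pk = pk, tau = 0.4,
    tnf = cytokine_parameters("tnf", IC50 = 10, S = 100, kout = 0.2,
                              R0 = baselines[["TNFa"]]),
    ifn = cytokine_parameters("ifn", IC50 = 10, S = 100, kout = 0.2,
                              R0 = baselines[["IFNg"]]),
    il6 = cytokine_parameters("il6", IC50 = 10, S = 100, kout = 0.5,
                              R0 = baselines[["IL6"]]),
    il10 = il10_parameters(S = 1, kout = 1, kin_dis = 100, I_ifn = 1e-4,
                           R0 = baselines[["IL10"]]),
    disease = disease, conA_time = conA_time)
}

#' Fit the disease-progression (transaminase) stage
#'
#' With every upstream parameter fixed (PK and PD stages, baselines, the
#' structural exponents alpha = beta = 1.5), estimates the six transaminase
#' turnover parameters `{S_ALT_TNF, S_ALT_IFN, kout_ALT, S_AST_TNF,
#' S_AST_IFN, kout_AST}` by WLS on the ALT and AST series. If no observation
#' comes from a ConA-challenged group the cytokines stay at baseline, the
#' transaminases are constant, and the stimulation coefficients are flagged
#' unidentifiable.
#'
#' @param data observation table restricted to ALT and AST.
#' @param fixed_params a full [model_parameters()] object carrying the fixed
#'   PK and PD estimates (its disease-stage entries are used only as
#'   structure; baselines `R0_ALT`/`R0_AST` are taken from it).
#' @param init named starting values for the six free parameters; required.
#' @param weight_exponent WLS weighting exponent.
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @return a `cona_fit`.
#' @export
fit_disease <- function(data, fixed_params, init, weight_exponent = 1,
                        maxiter = 200) {
  stopifnot(inherits(fixed_params, "cona_parameters"))
  data <- .subset_analytes(data, c("ALT", "AST"), "transaminase")
  free <- .free_disease_names
  unident <- character()
  if (!any(data$cona)) {
    unident <- c("S_ALT_TNF", "S_ALT_IFN", "S_AST_TNF", "S_AST_IFN")
    free <- setdiff(free, unident)
  }
  if (missing(init) || is.null(init))
    stop("'init' starting values are required for the disease fit", call. = FALSE)
  if (!all(free %in% names(init)))
    stop("init must name: ", paste(setdiff(free, names(init)), collapse = ", "),
         call. = FALSE)
  init <- init[free]

  resid_fn <- function(th) {
    pars <- .set_flat(fixed_params, th)
    yhat <- predict_observations(pars, data, rtol = 1e-7, atol = 1e-9)
    (data$value - yhat) / pmax(yhat, 1e-8)^weight_exponent
  }
  f <- .wls_fit(resid_fn, init, maxiter = maxiter)
  .make_fit(f$estimates, f$cv, f$objective, f$n_obs,
            fixed = c("PK stage", "PD stage", "alpha", "beta", "R0 (all)",
                      "kin (derived)"),
            converged = f$converged, message = f$message,
            unidentifiable = unident, hessian = f$hessian,
            weight_exponent = weight_exponent)
}

#' Asymptotic precision of a converged fit
#'
#' Per-parameter coefficients of variation from the Gauss-Newton
#' approximation of the objective curvature at the optimum:
#' `cov = s^2 (J' J)^-1` with `s^2 = WSS / (n - p)` and `J` the Jacobian of
#' the weighted residuals with respect to the log parameters, whose standard
#' errors are relative standard errors, reported as `CV% = 100 * SE`.
#' Parameters whose curvature is singular get `NA`, not an error.
#'
#' @param fit a `cona_fit` object.
#' @return named vector of CV% for the estimated parameters.
#' @export
estimate_cv <- function(fit) {
  stopifnot(inherits(fit, "cona_fit"))
  fit$cv_percent
}
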