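# Synthetic-study generator. Reproduces the trial design: intraperitoneal
# drug doses at t = 0, intravenous ConA at t = 0.5 h, destructive sampling
# (each animal contributes exactly one time point), serum drug sampled
# 5-120 min post-dose in a separate PK cohort, biomarkers sampled 1-24 h
# post-ConA, plus a healthy-baseline cohort.

#' Study design of the hepatitis trial
#'
#' @param groups data frame with columns `label`, `dose` (mg/kg) and `cona`
#'   (logical), one row per ConA-challenged treatment arm. Defaults to a
#'   vehicle control plus 50 and 100 mg/kg drug arms, all challenged.
#' @param pk_sampling drug sampling times (h post-dose) for the dedicated
#'   unchallenged PK cohort; default 5, 15, 30, 60, 90, 120 minutes.
#' @param pd_sampling biomarker sampling times (h post-ConA); default 1, 2,
#'   4, 8, 24.
#' @param n_pk,n_pd animals per time point in the PK and PD cohorts
#'   (defaults 4 and 5).
#' @param n_healthy healthy-baseline animals (default 4), sampled untreated
#'   and unchallenged.
#' @param analytes observables recorded in the PD cohort.
#' @return an object of class `cona_design`.
#' @export
study_design <- function(groups = data.frame(
                           label = c("control", "GRMS55_50", "GRMS55_100"),
                           dose = c(0, 50, 100),
                           cona = TRUE),
                         pk_sampling = c(5, 15, 30, 60, 90, 120) / 60,
                         pd_sampling = c(1, 2, 4, 8, 24),
                         n_pk = 4, n_pd = 5, n_healthy = 4,
                         analytes = c("GRMS55", "TNFa", "IFNg", "IL6",
                                      "IL10", "ALT", "AST")) {
  stopifnot(all(c("label", "dose", "cona") %in% names(groups)),
            all(groups$dose >= 0), n_pk >= 1, n_pd >= 1, n_healthy >= 0)
  if (any(pk_sampling <= 0) || is.unsorted(pk_sampling, strictly = TRUE))
    stop("'pk_sampling' must be positive and increasing", call. = FALSE)
  if (any(pd_sampling <= 0) || is.unsorted(pd_sampling, strictly = TRUE))
    stop("'pd_sampling' must be positive and increasing", call. = FALSE)
  analytes <- match.arg(analytes, .observables, several.ok = TRUE)
  structure(list(groups = groups, pk_sampling = pk_sampling,
                 pd_sampling = pd_sampling, n_pk = n_pk, n_pd = n_pd,
                 n_healthy = n_healthy, analytes = analytes),
            class = "cona_design")
}

#' Multiplicative log-normal measurement noise
#'
#' Returns `value * exp(sigma * Z - sigma^2 / 2)` with
#' `sigma^2 = log(1 + cv^2)`, i.e. log-normal proportional error whose
#' expectation equals the noiseless value (mean-preserving) and whose
#' coefficient of variation is `cv`. Draws use the current RNG state, so
#' results are reproducible under `set.seed()`.
#'
#' @param value noiseless value(s), > 0.
#' @param cv coefficient of variation as a fraction, >= 0.
#' @return perturbed value(s), strictly positive.
#' @export
apply_proportional_noise <- function(value, cv) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("'value' must be > 0", call. = FALSE)
  if (!is.numeric(cv) || cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  if (cv == 0) return(value)
  sigma <- sqrt(log(1 + cv^2))
  value * exp(sigma * rnorm(length(value)) - sigma^2 / 2)
}

#' Generate a synthetic study dataset
#'
#' Simulates every arm of the design under `params`, evaluates the
#' observables at the design's sampling times and applies multiplicative
#' log-normal noise independently per record. Destructive sampling is
#' encoded explicitly: each animal appears at a single time point (all its
#' analytes measured from the same terminal serum sample), which is why the
#' estimation stage pools naively instead of fitting per-animal effects.
#' Healthy-baseline animals are sampled with no drug and no challenge. Drug
#' records in unexposed arms are exact zeros and bypass the noise model.
#'
#' @param design a [study_design()] object.
#' @param params a [model_parameters()] object.
#' @param noise_cv proportional-error coefficient of variation (default 0.2,
#'   a typical magnitude for serum immunoassay and enzymatic readouts).
#' @param seed optional integer seed for reproducibility.
#' @return observation table: `group`, `animal_id`, `dose_mg_per_kg`,
#'   `time_h` (post-dose), `analyte`, `value`, `unit`, `cona`.
#' @export
generate_study <- function(design, params, noise_cv = 0.2, seed = NULL) {
  stopifnot(inherits(design, "cona_design"),
            inherits(params, "cona_parameters"))
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  units <- c(GRMS55 = "mg/L", TNFa = "ng/L", IFNg = "ng/L", IL6 = "ng/L",
             IL10 = "ng/L", ALT = "U/L", AST = "U/L")
  rows <- list()
  id <- 0L

  add_cohort <- function(label, dose, cona, times, n_per_tp, analytes) {
    traj <- simulate_group(params, dose = dose, times = times, cona = cona)
    pred <- lapply(setNames(analytes, analytes), function(a)
      observable(traj, a)[match(times, traj$time)])
    out <- list()
    for (ti in seq_along(times)) {
      for (k in seq_len(n_per_tp)) {
        id <<- id + 1L
        vals <- vapply(analytes, function(a) pred[[a]][ti], numeric(1))
        noisy <- vals
        pos <- vals > 0
        noisy[pos] <- apply_proportional_noise(vals[pos], noise_cv)
        out[[length(out) + 1L]] <- data.frame(
          group = label, animal_id = sprintf("m%04d", id),
          dose_mg_per_kg = dose, time_h = times[ti], analyte = analytes,
          value = unname(noisy), unit = unname(units[analytes]), cona = cona)
      }
    }
    do.call(rbind, out)
  }

  # dedicated PK cohort: dosed, unchallenged animals, drug analyte only
  for (g in which(design$groups$dose > 0)) {
    rows[[length(rows) + 1L]] <- add_cohort(
      paste0("pk_", design$groups$label[g]), design$groups$dose[g],
      cona = FALSE, times = design$pk_sampling, n_per_tp = design$n_pk,
      analytes = "GRMS55")
  }
  # PD / disease-progression cohorts: sampled post-ConA
  pd_times <- params$conA_time + design$pd_sampling
  for (g in seq_len(nrow(design$groups))) {
    rows[[length(rows) + 1L]] <- add_cohort(
      design$groups$label[g], design$groups$dose[g],
      cona = design$groups$cona[g], times = pd_times, n_per_tp = design$n_pd,
      analytes = design$analytes)
  }
  # healthy-baseline animals
  if (design$n_healthy > 0) {
    biomarkers <- setdiff(design$analytes, "GRMS55")
    if (length(biomarkers))
      rows[[length(rows) + 1L]] <- add_cohort(
        "healthy", 0, cona = FALSE, times = params$conA_time,
        n_per_tp = design$n_healthy, analytes = biomarkers)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  validate_observation_table(tab)
}

#' Healthy-cohort baseline means
#'
#' Averages the healthy-baseline records per analyte, mirroring the
#' convention that baselines are fixed to the mean of healthy animals rather
#' than estimated.
#'
#' @param data an observation table containing a `healthy` group.
#' @return named vector of baseline means by analyte.
#' @export
baseline_means <- function(data) {
  data <- validate_observation_table(data)
  h <- data[data$group == "healthy", ]
  if (!nrow(h)) stop("no 'healthy' group records in 'data'", call. = FALSE)
  vapply(split(h$value, h$analyte), mean, numeric(1))
}
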