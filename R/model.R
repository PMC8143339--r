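# State ordering of the 24-dimensional ODE system. The transit compartments
# are hypothetical precursors: T1 is shared by all pathways; T1a feeds
# TNF-alpha, T1b..T7b IFN-gamma, T1c IL-10 and T1d..T6d IL-6. The drug
# concentration is not a state: C = X_central / Vd_F.

#' Names of the 24 ODE states, in solver order
#'
#' `A_depot` and `X_central` are drug amounts per kg body weight; the
#' `T*` states are dimensionless precursor quantities; `C_*` are cytokine
#' concentrations (ng/L) and `A_ALT`/`A_AST` transaminase activities (U/L).
#'
#' @return character vector of length 24.
#' @export
state_names <- function() {
  c("A_depot", "X_central", "T1", "T1a",
    paste0("T", 1:7, "b"), "T1c", paste0("T", 1:6, "d"),
    "C_TNF", "C_IFN", "C_IL6", "C_IL10", "A_ALT", "A_AST")
}

#' Initial state at the moment of drug dosing
#'
#' The depot holds the nominal dose (per kg, bioavailability folded into
#' Vd/F), the central compartment and all precursor chains are empty, and
#' every biomarker sits at its baseline.
#'
#' @param params a [model_parameters()] object.
#' @param dose drug dose (mg/kg), 0 for vehicle.
#' @return named numeric state vector of length 24.
#' @export
initial_state <- function(params, dose = 0) {
  if (!is.numeric(dose) || dose < 0) stop("'dose' must be >= 0", call. = FALSE)
  setNames(c(dose, 0, rep(0, 16),
             params$tnf$R0, params$ifn$R0, params$il6$R0, params$il10$R0,
             params$disease$R0_ALT, params$disease$R0_AST),
           state_names())
}

#' Closed-form serum drug concentration
#'
#' Bateman solution of the one-compartment first-order absorption model:
#' `C(t) = dose/Vd_F * ka/(ka - ke) * (exp(-ke t) - exp(-ka t))`, with the
#' `t * exp(-k t)` limiting form when `ka` and `ke` coincide. Identical to
#' numerically integrating the depot/central ODE pair. The terminal log-linear
#' slope is `min(ka, ke)`: under flip-flop kinetics (`ka < ke`) the terminal
#' phase reflects absorption, not elimination.
#'
#' @param t time after the dose (h), >= 0; vectorised.
#' @param dose dose (mg/kg), >= 0.
#' @param pk a [pk_parameters()] object.
#' @return serum concentration (mg/L).
#' @export
pk_concentration <- function(t, dose, pk) {
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  if (!is.numeric(dose) || dose < 0) stop("'dose' must be >= 0", call. = FALSE)
  ka <- pk$ka; ke <- pk$ke
  if (abs(ka - ke) < 1e-10 * (ka + ke)) {
    k <- (ka + ke) / 2
    dose / pk$Vd_F * k * t * exp(-k * t)
  } else {
    dose / pk$Vd_F * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
}

#' Right-hand side of the full ODE system
#'
#' Derivatives of the 24 states: drug depot/central pair, shared precursor
#' `T1` (first-order decay with mean transit time `tau`), the three
#' drug-inhibitable transit chains whose first compartments receive `T1`
#' attenuated by the Imax/IC50 inhibition function, the IL-10 precursor
#' (`(T1 - T1c)/tau`), four cytokine turnover equations, and the two
#' transaminase turnover equations driven by the cytokine excesses above
#' baseline. The excesses `(C - R0)` are clamped at zero before the power
#' terms: nonnegativity holds in exact arithmetic, so the clamp only guards
#' against transient solver undershoot. The disease-state IL-10 production
#' term is active when `cona` is `TRUE`; its modulator `F_IL10` is not
#' clamped (its transient negativity produces the observed IL-10 dip) but the
#' total IL-10 production rate is floored at zero.
#'
#' @param t time after the drug dose (h).
#' @param state numeric state vector of length 24 (see [state_names()]).
#' @param params a [model_parameters()] object.
#' @param drug_present if `FALSE`, the inhibition terms are identically zero
#'   (vehicle groups).
#' @param cona whether the ConA challenge has occurred; defaults to
#'   `t >= params$conA_time`. Pass `FALSE` to describe healthy animals at any
#'   time.
#' @return named numeric vector of derivatives, length 24.
#' @export
full_rhs <- function(t, state, params, drug_present = TRUE,
                     cona = t >= params$conA_time) {
  if (length(state) != 24L)
    stop("'state' must have length 24", call. = FALSE)
  bad <- which(!is.finite(state))
  if (length(bad))
    stop(sprintf("non-finite state entries at index: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  tau <- params$tau
  A <- state[1]; X <- state[2]; T1 <- state[3]; T1a <- state[4]
  Tb <- state[5:11]; T1c <- state[12]; Td <- state[13:18]
  C_TNF <- state[19]; C_IFN <- state[20]; C_IL6 <- state[21]
  C_IL10 <- state[22]; A_ALT <- state[23]; A_AST <- state[24]

  C <- X / params$pk$Vd_F
  inh <- function(p) if (drug_present) inhibition_fraction(C, p$IC50, p$Imax) else 0

  d <- numeric(24)
  d[1] <- -params$pk$ka * A
  d[2] <- params$pk$ka * A - params$pk$ke * X
  d[3] <- -T1 / tau
  d[4] <- T1 * (1 - inh(params$tnf)) - T1a / tau
  d[5] <- T1 * (1 - inh(params$ifn)) - Tb[1] / tau
  d[6:11] <- (Tb[1:6] - Tb[2:7]) / tau
  d[12] <- (T1 - T1c) / tau
  d[13] <- T1 * (1 - inh(params$il6)) - Td[1] / tau
  d[14:18] <- (Td[1:5] - Td[2:6]) / tau

  d[19] <- (1 + T1a * params$tnf$S) * kin_from_baseline(params$tnf$R0, params$tnf$kout) -
    params$tnf$kout * C_TNF
  d[20] <- (1 + Tb[7] * params$ifn$S) * kin_from_baseline(params$ifn$R0, params$ifn$kout) -
    params$ifn$kout * C_IFN
  d[21] <- (1 + Td[6] * params$il6$S) * kin_from_baseline(params$il6$R0, params$il6$kout) -
    params$il6$kout * C_IL6

  prod10 <- kin_from_baseline(params$il10$R0, params$il10$kout)
  if (isTRUE(cona)) {
    F_IL10 <- 1 + T1c * params$il10$S - C_IFN * params$il10$I_ifn
    prod10 <- max(prod10 + F_IL10 * params$il10$kin_dis, 0)
  }
  d[22] <- prod10 - params$il10$kout * C_IL10

  ds <- params$disease
  exc_tnf <- max(C_TNF - params$tnf$R0, 0)
  exc_ifn <- max(C_IFN - params$ifn$R0, 0)
  F_ALT <- (1 + exc_tnf^ds$alpha * ds$S_ALT_TNF) * (1 + exc_ifn^ds$beta * ds$S_ALT_IFN)
  F_AST <- (1 + exc_tnf * ds$S_AST_TNF) * (1 + exc_ifn * ds$S_AST_IFN)
  d[23] <- F_ALT * kin_from_baseline(ds$R0_ALT, ds$kout_ALT) - ds$kout_ALT * A_ALT
  d[24] <- F_AST * kin_from_baseline(ds$R0_AST, ds$kout_AST) - ds$kout_AST * A_AST

  setNames(d, state_names())
}

# Parameter vector handed to the compiled right-hand side; order must match
# src/conahep_rhs.c exactly.
#' @keywords internal
.c_parms <- function(params, drug_present, cona_active) {
  c(params$pk$Vd_F, params$pk$ka, params$pk$ke, params$tau,
    params$tnf$Imax, params$tnf$IC50, params$tnf$S, params$tnf$kout, params$tnf$R0,
    params$ifn$Imax, params$ifn$IC50, params$ifn$S, params$ifn$kout, params$ifn$R0,
    params$il6$Imax, params$il6$IC50, params$il6$S, params$il6$kout, params$il6$R0,
    params$il10$S, params$il10$kout, params$il10$kin_dis, params$il10$I_ifn,
    params$il10$R0,
    params$disease$S_ALT_TNF, params$disease$S_ALT_IFN, params$disease$kout_ALT,
    params$disease$R0_ALT, params$disease$alpha,
    params$disease$S_AST_TNF, params$disease$S_AST_IFN, params$disease$kout_AST,
    params$disease$R0_AST, params$disease$beta,
    as.numeric(drug_present), as.numeric(cona_active))
}
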