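#' @keywords internal
.assert_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (!strict && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  unname(x)
}

#' One-compartment pharmacokinetic parameters
#'
#' First-order absorption from the injection site into a central compartment
#' with first-order elimination. Bioavailability is not separately
#' identifiable after extravascular dosing and is folded into the apparent
#' volume `Vd_F`; all drug amounts are expressed per kg body weight.
#'
#' @param Vd_F apparent volume of distribution (L/kg), > 0.
#' @param ka first-order absorption rate constant (1/h), > 0.
#' @param ke first-order elimination rate constant (1/h), > 0. `ka < ke`
#'   (flip-flop kinetics, absorption-limited terminal phase) is permitted.
#' @return an object of class `pk_parameters`.
#' @examples
#' pk_parameters(Vd_F = 1.81, ka = 1.49, ke = 4.59)
#' @export
pk_parameters <- function(Vd_F, ka, ke) {
  structure(list(Vd_F = .assert_positive(Vd_F, "Vd_F"),
                 ka = .assert_positive(ka, "ka"),
                 ke = .assert_positive(ke, "ke")),
            class = "pk_parameters")
}

#' Number of pathway-specific transit compartments per cytokine
#' @keywords internal
.n_transit <- c(tnf = 1L, ifn = 7L, il6 = 6L)

#' Parameters of one inhibitable cytokine pathway
#'
#' Each of TNF-alpha, IFN-gamma and IL-6 is produced by an indirect-response
#' (turnover) model whose production is stimulated by the last compartment of
#' a pathway-specific transit chain (1, 7 and 6 compartments, respectively,
#' after the shared precursor), and whose chain input is inhibited by the drug
#' through an Imax/IC50 function. The zero-order production rate `kin` is never
#' stored: it is always derived from the baseline as `R0 * kout` so that the
#' unperturbed system is at steady state.
#'
#' @param name one of `"tnf"`, `"ifn"`, `"il6"`.
#' @param IC50 drug concentration giving half-maximal inhibition (mg/L).
#' @param S dimensionless linear stimulation coefficient.
#' @param kout first-order loss rate constant (1/h).
#' @param R0 baseline serum concentration (ng/L).
#' @param Imax maximal inhibition fraction in `[0, 1]`; fixed to 1 in the
#'   reference analysis.
#' @return an object of class `cytokine_parameters` with an `n_transit` field.
#' @export
cytokine_parameters <- function(name, IC50, S, kout, R0, Imax = 1) {
  name <- match.arg(name, c("tnf", "ifn", "il6"))
  if (!is.numeric(Imax) || Imax < 0 || Imax > 1)
    stop("'Imax' must lie in [0, 1]", call. = FALSE)
  structure(list(name = name,
                 n_transit = .n_transit[[name]],
                 Imax = Imax,
                 IC50 = .assert_positive(IC50, "IC50"),
                 S = .assert_positive(S, "S"),
                 kout = .assert_positive(kout, "kout"),
                 R0 = .assert_positive(R0, "R0")),
            class = "cytokine_parameters")
}

#' Parameters of the IL-10 pathway
#'
#' IL-10 turnover is not drug-inhibited. After the ConA challenge an
#' additional zero-order production term `kin_dis` switches on, modulated by
#' `F_IL10 = 1 + T1c * S - C_IFN * I_ifn`: the challenge (through a one-step
#' transit chain) stimulates IL-10 synthesis while IFN-gamma linearly
#' inhibits it. `F_IL10` may transiently become negative (this produces the
#' observed post-peak dip); the total production rate is floored at zero so
#' concentrations cannot be driven negative.
#'
#' @param S dimensionless stimulation coefficient of the challenge on IL-10
#'   production.
#' @param kout first-order loss rate constant (1/h).
#' @param kin_dis additional zero-order production rate in disease
#'   (ng/L/h), active from the challenge onwards.
#' @param I_ifn linear inhibitory coefficient of IFN-gamma on IL-10
#'   production (L/ng).
#' @param R0 baseline serum concentration (ng/L).
#' @return an object of class `il10_parameters`.
#' @export
il10_parameters <- function(S, kout, kin_dis, I_ifn, R0) {
  structure(list(S = .assert_positive(S, "S"),
                 kout = .assert_positive(kout, "kout"),
                 kin_dis = .assert_positive(kin_dis, "kin_dis"),
                 I_ifn = .assert_positive(I_ifn, "I_ifn"),
                 R0 = .assert_positive(R0, "R0")),
            class = "il10_parameters")
}

#' Disease-progression (transaminase turnover) parameters
#'
#' ALT and AST are each described by an indirect-response model whose
#' production is stimulated by the excess of TNF-alpha and IFN-gamma above
#' their baselines. For ALT the excesses enter through power functions with
#' fixed exponents `alpha` and `beta`; for AST linear functions suffice.
#' The exponents are structural constants (both 1.5) and are never estimated.
#'
#' @param S_ALT_TNF,S_ALT_IFN stimulation coefficients of ALT production by
#'   the TNF-alpha and IFN-gamma excesses (units (L/ng)^alpha, (L/ng)^beta).
#' @param kout_ALT,kout_AST first-order loss rate constants (1/h).
#' @param S_AST_TNF,S_AST_IFN linear stimulation coefficients of AST
#'   production (L/ng).
#' @param R0_ALT,R0_AST baseline serum activities (U/L).
#' @param alpha,beta fixed power exponents for the TNF-alpha and IFN-gamma
#'   excesses in the ALT stimulation function (default 1.5).
#' @return an object of class `disease_parameters`.
#' @export
disease_parameters <- function(S_ALT_TNF, S_ALT_IFN, kout_ALT,
                               S_AST_TNF, S_AST_IFN, kout_AST,
                               R0_ALT, R0_AST, alpha = 1.5, beta = 1.5) {
  structure(list(S_ALT_TNF = .assert_positive(S_ALT_TNF, "S_ALT_TNF"),
                 S_ALT_IFN = .assert_positive(S_ALT_IFN, "S_ALT_IFN"),
                 kout_ALT = .assert_positive(kout_ALT, "kout_ALT"),
                 S_AST_TNF = .assert_positive(S_AST_TNF, "S_AST_TNF"),
                 S_AST_IFN = .assert_positive(S_AST_IFN, "S_AST_IFN"),
                 kout_AST = .assert_positive(kout_AST, "kout_AST"),
                 R0_ALT = .assert_positive(R0_ALT, "R0_ALT"),
                 R0_AST = .assert_positive(R0_AST, "R0_AST"),
                 alpha = .assert_positive(alpha, "alpha"),
                 beta = .assert_positive(beta, "beta")),
            class = "disease_parameters")
}

#' Full model parameter vector
#'
#' Aggregates the pharmacokinetic, pharmacodynamic and disease-progression
#' parameters together with the shared mean transit time `tau` and the timing
#' of the ConA challenge relative to the drug dose.
#'
#' @param pk a [pk_parameters()] object.
#' @param tau mean transit time of the precursor compartments (h), shared by
#'   all chains.
#' @param tnf,ifn,il6 [cytokine_parameters()] objects for the three
#'   drug-inhibitable pathways.
#' @param il10 an [il10_parameters()] object.
#' @param disease a [disease_parameters()] object.
#' @param conA_time time of the ConA challenge after the drug dose (h),
#'   default 0.5.
#' @return an object of class `cona_parameters`.
#' @seealso [grms55_parameters()] for the packaged reference parameter set.
#' @export
model_parameters <- function(pk, tau, tnf, ifn, il6, il10, disease,
                             conA_time = 0.5) {
  stopifnot(inherits(pk, "pk_parameters"),
            inherits(tnf, "cytokine_parameters"), tnf$name == "tnf",
            inherits(ifn, "cytokine_parameters"), ifn$name == "ifn",
            inherits(il6, "cytokine_parameters"), il6$name == "il6",
            inherits(il10, "il10_parameters"),
            inherits(disease, "disease_parameters"))
  structure(list(pk = pk, tau = .assert_positive(tau, "tau"),
                 tnf = tnf, ifn = ifn, il6 = il6, il10 = il10,
                 disease = disease,
                 conA_time = .assert_positive(conA_time, "conA_time")),
            class = "cona_parameters")
}

#' @export
print.cona_parameters <- function(x, ...) {
  cat("PK/PD/disease-progression parameter set\n")
  cat(sprintf("  PK:  Vd/F = %.4g L/kg, ka = %.4g 1/h, ke = %.4g 1/h%s\n",
              x$pk$Vd_F, x$pk$ka, x$pk$ke,
              if (x$pk$ka < x$pk$ke) "  (flip-flop regime)" else ""))
  cat(sprintf("  tau = %.4g h, ConA challenge at %.3g h post-dose\n",
              x$tau, x$conA_time))
  for (nm in c("tnf", "ifn", "il6")) {
    p <- x[[nm]]
    cat(sprintf("  %s: %d transit cpt, IC50 = %.4g mg/L, S = %.4g, kout = %.4g 1/h, R0 = %.4g ng/L\n",
                toupper(nm), p$n_transit, p$IC50, p$S, p$kout, p$R0))
  }
  cat(sprintf("  IL10: S = %.4g, kout = %.4g 1/h, kin_dis = %.4g ng/L/h, I_ifn = %.4g L/ng, R0 = %.4g ng/L\n",
              x$il10$S, x$il10$kout, x$il10$kin_dis, x$il10$I_ifn, x$il10$R0))
  d <- x$disease
  cat(sprintf("  ALT: S_TNF = %.4g, S_IFN = %.4g, kout = %.4g 1/h, R0 = %.4g U/L (alpha = %g, beta = %g)\n",
              d$S_ALT_TNF, d$S_ALT_IFN, d$kout_ALT, d$R0_ALT, d$alpha, d$beta))
  cat(sprintf("  AST: S_TNF = %.4g, S_IFN = %.4g, kout = %.4g 1/h, R0 = %.4g U/L\n",
              d$S_AST_TNF, d$S_AST_IFN, d$kout_AST, d$R0_AST))
  invisible(x)
}

#' Fractional Imax/IC50 inhibition
#'
#' `Imax * C / (IC50 + C)`: the fraction by which the drug inhibits the input
#' of a cytokine precursor chain. Monotonically nondecreasing in `C`,
#' approaching `Imax` as `C` grows.
#'
#' @param C_drug drug concentration (mg/L), >= 0; vectorised.
#' @param IC50 concentration giving half-maximal inhibition (mg/L), > 0.
#' @param Imax maximal inhibition fraction in `[0, 1]`.
#' @return inhibition fraction in `[0, Imax]`.
#' @examples
#' inhibition_fraction(7.97, IC50 = 7.97)  # 0.5 at C == IC50
#' @export
inhibition_fraction <- function(C_drug, IC50, Imax = 1) {
  if (any(!is.finite(C_drug)) || any(C_drug < 0))
    stop("'C_drug' must be finite and >= 0", call. = FALSE)
  .assert_positive(IC50, "IC50")
  if (!is.numeric(Imax) || Imax < 0 || Imax > 1)
    stop("'Imax' must lie in [0, 1]", call. = FALSE)
  Imax * C_drug / (IC50 + C_drug)
}

#' Zero-order production rate from baseline and loss rate
#'
#' The turnover ODE `dC/dt = kin - kout * C` has steady state `kin / kout`;
#' fixing `kin = R0 * kout` therefore pins the unperturbed steady state at
#' exactly the observed baseline `R0`. Production rates are never estimated or
#' stored: they are always derived this way.
#'
#' @param R0 baseline response (biomarker units), >= 0.
#' @param kout first-order loss rate constant (1/h), > 0.
#' @return zero-order production rate (units/h).
#' @export
kin_from_baseline <- function(R0, kout) {
  if (any(!is.finite(R0)) || any(R0 < 0))
    stop("'R0' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(kout)) || any(kout <= 0))
    stop("'kout' must be > 0", call. = FALSE)
  R0 * kout
}

#' Half-life from a first-order rate constant
#'
#' `ln(2) / k`, used both for the absorption/elimination half-lives of the
#' drug and for biomarker elimination half-lives derived from `kout`.
#'
#' @param k first-order rate constant (1/h), > 0; vectorised.
#' @return half-life (h).
#' @examples
#' half_life_from_rate(1.49) * 60  # absorption half-life in minutes
#' @export
half_life_from_rate <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("'k' must be finite and > 0", call. = FALSE)
  log(2) / k
}

#' Documented default baselines for the synthetic study
#'
#' Absolute healthy-mouse baselines are study-specific inputs and are not part
#' of the published parameter table; these defaults are package assumptions in
#' the physiological range for female BALB/c mice and are used by the
#' synthetic-study generator. All cytokine timing results are provably
#' invariant to them.
#'
#' @return named vector of baselines: cytokines in ng/L, transaminases in U/L.
#' @export
default_baselines <- function() {
  c(TNFa = 10, IFNg = 5, IL6 = 5, IL10 = 20, ALT = 35, AST = 60)
}

#' Reference parameter set of the GRMS-55 hepatitis model
#'
#' Loads the packaged configuration holding the published estimates for the
#' PDE7A/PDE4B inhibitor GRMS-55 in ConA-induced hepatitis (PK: Vd/F 1.81
#' L/kg, ka 1.49 1/h, ke 4.59 1/h; tau 0.405 h; pathway IC50, S and kout
#' values; ALT/AST coefficients with alpha = beta = 1.5), combined with the
#' documented default baselines unless others are supplied.
#'
#' @param baselines named vector with elements TNFa, IFNg, IL6, IL10, ALT,
#'   AST (cytokines ng/L, transaminases U/L).
#' @return a [model_parameters()] object.
#' @export
grms55_parameters <- function(baselines = default_baselines()) {
  path <- system.file("extdata", "grms55_parameters.yaml", package = "conahep",
                      mustWork = TRUE)
  read_parameters(path, baselines = baselines)
}

# ---- internal: flat named-vector view used by the solver and the fitters ----

#' @keywords internal
.free_pd_names <- c("tau",
                    "kout_TNF", "kout_IFN", "kout_IL6", "kout_IL10",
                    "IC50_TNF", "IC50_IFN", "IC50_IL6",
                    "S_TNF", "S_IFN", "S_IL6", "S_IL10",
                    "kin_IL10_dis", "I_IL10_IFN")

#' @keywords internal
.free_disease_names <- c("S_ALT_TNF", "S_ALT_IFN", "kout_ALT",
                         "S_AST_TNF", "S_AST_IFN", "kout_AST")

#' @keywords internal
.get_flat <- function(params) {
  c(Vd_F = params$pk$Vd_F, ka = params$pk$ka, ke = params$pk$ke,
    tau = params$tau,
    IC50_TNF = params$tnf$IC50, S_TNF = params$tnf$S, kout_TNF = params$tnf$kout,
    IC50_IFN = params$ifn$IC50, S_IFN = params$ifn$S, kout_IFN = params$ifn$kout,
    IC50_IL6 = params$il6$IC50, S_IL6 = params$il6$S, kout_IL6 = params$il6$kout,
    S_IL10 = params$il10$S, kout_IL10 = params$il10$kout,
    kin_IL10_dis = params$il10$kin_dis, I_IL10_IFN = params$il10$I_ifn,
    S_ALT_TNF = params$disease$S_ALT_TNF, S_ALT_IFN = params$disease$S_ALT_IFN,
    kout_ALT = params$disease$kout_ALT,
    S_AST_TNF = params$disease$S_AST_TNF, S_AST_IFN = params$disease$S_AST_IFN,
    kout_AST = params$disease$kout_AST)
}

#' Update a parameter set from a flat named vector
#' @keywords internal
.set_flat <- function(params, x) {
  nm <- names(x)
  take <- function(key, old) if (key %in% nm) unname(x[[key]]) else old
  params$pk$Vd_F <- take("Vd_F", params$pk$Vd_F)
  params$pk$ka <- take("ka", params$pk$ka)
  params$pk$ke <- take("ke", params$pk$ke)
  params$tau <- take("tau", params$tau)
  params$tnf$IC50 <- take("IC50_TNF", params$tnf$IC50)
  params$tnf$S <- take("S_TNF", params$tnf$S)
  params$tnf$kout <- take("kout_TNF", params$tnf$kout)
  params$ifn$IC50 <- take("IC50_IFN", params$ifn$IC50)
  params$ifn$S <- take("S_IFN", params$ifn$S)
  params$ifn$kout <- take("kout_IFN", params$ifn$kout)
  params$il6$IC50 <- take("IC50_IL6", params$il6$IC50)
  params$il6$S <- take("S_IL6", params$il6$S)
  params$il6$kout <- take("kout_IL6", params$il6$kout)
  params$il10$S <- take("S_IL10", params$il10$S)
  params$il10$kout <- take("kout_IL10", params$il10$kout)
  params$il10$kin_dis <- take("kin_IL10_dis", params$il10$kin_dis)
  params$il10$I_ifn <- take("I_IL10_IFN", params$il10$I_ifn)
  params$disease$S_ALT_TNF <- take("S_ALT_TNF", params$disease$S_ALT_TNF)
  params$disease$S_ALT_IFN <- take("S_ALT_IFN", params$disease$S_ALT_IFN)
  params$disease$kout_ALT <- take("kout_ALT", params$disease$kout_ALT)
  params$disease$S_AST_TNF <- take("S_AST_TNF", params$disease$S_AST_TNF)
  params$disease$S_AST_IFN <- take("S_AST_IFN", params$disease$S_AST_IFN)
  params$disease$kout_AST <- take("kout_AST", params$disease$kout_AST)
  params
}
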