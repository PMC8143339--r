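# Reference parameter values used throughout the suite (the packaged
# configuration holds the same numbers; tests that exercise recovery use
# these as generating truth).
table1_pk <- c(Vd_F = 1.81, ka = 1.49, ke = 4.59)

table1_pd <- c(tau = 0.405,
               kout_TNF = 0.209, kout_IFN = 0.234, kout_IL6 = 0.531,
               kout_IL10 = 1.841,
               IC50_TNF = 7.97, IC50_IFN = 12.27, IC50_IL6 = 13.40,
               S_TNF = 453.9, S_IFN = 5856, S_IL6 = 10320, S_IL10 = 2.035,
               kin_IL10_dis = 160.8, I_IL10_IFN = 2e-4)

table1_disease <- c(S_ALT_TNF = 0.0072, S_ALT_IFN = 2e-4, kout_ALT = 0.0997,
                    S_AST_TNF = 0.7727, S_AST_IFN = 7e-4, kout_AST = 0.0817)

ref_params <- function(baselines = default_baselines()) {
  grms55_parameters(baselines = baselines)
}

# deterministic alternating perturbation used as fitting start in recovery
# studies (the usual simulation-study convention: start away from truth)
perturbed <- function(truth, up = 1.5, down = 0.7) {
  truth * rep(c(up, down), length.out = length(truth))
}

cytokine_rows <- function(data) {
  data[data$analyte %in% c("TNFa", "IFNg", "IL6", "IL10") &
         data$group != "healthy", ]
}

transaminase_rows <- function(data) {
  data[data$analyte %in% c("ALT", "AST") & data$group != "healthy", ]
}

pk_rows <- function(data) {
  data[data$analyte == "GRMS55" & startsWith(data$group, "pk_"), ]
}
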