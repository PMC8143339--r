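Package: conahep
Title: PK/PD/Disease-Progression Modelling of Concanavalin-A-Induced Hepatitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-mechanistic pharmacokinetic/pharmacodynamic/disease-progression
    model of a dual PDE7A/PDE4B inhibitor in the concanavalin-A (ConA) mouse model
    of autoimmune hepatitis: one-compartment first-order absorption
    pharmacokinetics, transit-compartment cascades driving indirect-response
    turnover of four serum cytokines (TNF-alpha, IFN-gamma, IL-6, IL-10), and
    cytokine-driven turnover of the transaminases ALT and AST. Includes
    event-aware simulation of the ConA challenge, sequential
    weighted-least-squares naive-pooled estimation (PK, then PD, then disease
    progression) with goodness-of-fit metrics, non-compartmental analysis of
    drug concentration data, and a synthetic-study generator reproducing the
    destructive-sampling trial design so that every estimation stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
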