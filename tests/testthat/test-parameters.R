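test_that("inhibition fraction follows the Imax/IC50 form and its bounds", {
  expect_identical(inhibition_fraction(0, IC50 = 7.97), 0)
  expect_equal(inhibition_fraction(7.97, IC50 = 7.97), 0.5)
  expect_equal(inhibition_fraction(3.2, IC50 = 3.2, Imax = 0.8), 0.4)
  # monotone nondecreasing, bounded by Imax, saturating
  for (ic50 in c(0.5, 7.97, 13.4)) {
    C <- sort(runif(50, 0, 100))
    f <- inhibition_fraction(C, IC50 = ic50, Imax = 1)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(inhibition_fraction(1e9, IC50 = ic50), 1, tolerance = 1e-6)
  }
  expect_error(inhibition_fraction(-1, IC50 = 1), "C_drug")
  expect_error(inhibition_fraction(1, IC50 = 0), "IC50")
  expect_error(inhibition_fraction(1, IC50 = 1, Imax = 1.5), "Imax")
})

test_that("production rates derive from baselines and pin the steady state", {
  expect_identical(kin_from_baseline(0, 0.209), 0)
  expect_equal(kin_from_baseline(100, 0.209), 20.9)
  expect_equal(kin_from_baseline(40, 0.0997), 3.988)
  expect_error(kin_from_baseline(10, 0), "kout")
  expect_error(kin_from_baseline(-1, 0.2), "R0")
  # the turnover ODE dC/dt = kin - kout*C is exactly zero at C = R0
  for (i in 1:5) {
    R0 <- runif(1, 1, 100); kout <- runif(1, 0.05, 2)
    expect_equal(kin_from_baseline(R0, kout) - kout * R0, 0)
  }
})

test_that("half-life arithmetic is ln(2)/k", {
  expect_equal(half_life_from_rate(1), log(2))
  expect_equal(half_life_from_rate(c(2, 4)), log(2) / c(2, 4))
  expect_error(half_life_from_rate(0), "k")
  expect_error(half_life_from_rate(-1), "k")
})

test_that("parameter constructors validate their domains", {
  expect_error(pk_parameters(-1, 1, 1), "Vd_F")
  expect_error(pk_parameters(1, 0, 1), "ka")
  # flip-flop (ka < ke) is legal
  expect_s3_class(pk_parameters(1.81, 1.49, 4.59), "pk_parameters")
  expect_error(cytokine_parameters("tnf", IC50 = -1, S = 1, kout = 1, R0 = 1),
               "IC50")
  expect_error(cytokine_parameters("tnf", IC50 = 1, S = 1, kout = 1, R0 = 1,
                                   Imax = 2), "Imax")
  # chain lengths are structural: 1, 7, 6 after the shared precursor
  expect_identical(cytokine_parameters("tnf", 1, 1, 1, 1)$n_transit, 1L)
  expect_identical(cytokine_parameters("ifn", 1, 1, 1, 1)$n_transit, 7L)
  expect_identical(cytokine_parameters("il6", 1, 1, 1, 1)$n_transit, 6L)
  expect_error(il10_parameters(1, 1, -1, 1, 1), "kin_dis")
  expect_error(disease_parameters(1, 1, 0, 1, 1, 1, 1, 1), "kout_ALT")
})

test_that("the packaged reference configuration reproduces the published set", {
  p <- ref_params()
  expect_equal(p$tau, 0.405)
  expect_equal(p$pk$ke, 4.59)
  expect_equal(p$pk$Vd_F, 1.81)
  expect_equal(p$tnf$IC50, 7.97)
  expect_equal(p$ifn$S, 5856)
  expect_equal(p$il10$kout, 1.841)
  expect_equal(p$disease$kout_AST, 0.0817)
  expect_equal(p$disease$alpha, 1.5)
  expect_equal(p$tnf$Imax, 1)
  expect_equal(p$conA_time, 0.5)
})

test_that("the state vector layout is the documented 24-state map", {
  nm <- state_names()
  expect_length(nm, 24L)
  expect_identical(nm[1:4], c("A_depot", "X_central", "T1", "T1a"))
  expect_identical(nm[19:24],
                   c("C_TNF", "C_IFN", "C_IL6", "C_IL10", "A_ALT", "A_AST"))
  y0 <- initial_state(ref_params(), dose = 50)
  expect_equal(unname(y0["A_depot"]), 50)
  expect_equal(unname(y0["C_IL10"]), 20)
  expect_true(all(y0[3:18] == 0))
})
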