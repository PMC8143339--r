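test_that("transit chains reproduce their gamma-shaped closed forms", {
  p <- ref_params()
  traj <- simulate_group(p, dose = 0, t_end = 8, grid_step = 0.01)
  st <- attr(traj, "state")
  s <- traj$time - p$conA_time
  sel <- s >= 0
  chain <- function(n) s[sel]^n / (factorial(n) * p$tau^(n - 1)) *
    exp(-s[sel] / p$tau)
  for (n in 1:7) {
    num <- st[sel, paste0("T", n, "b")]
    ana <- chain(n)
    expect_equal(num[which.max(ana)], max(ana), tolerance = 1e-6)
    expect_equal(num, ana, tolerance = 1e-5)
  }
  expect_equal(st[sel, "T6d"], chain(6), tolerance = 1e-5)
  # IL-10 precursor: input scaled by 1/tau gives (s/tau) exp(-s/tau)
  expect_equal(st[sel, "T1c"], s[sel] / p$tau * exp(-s[sel] / p$tau),
               tolerance = 1e-5)
})

test_that("without a challenge every biomarker is conserved at baseline", {
  p <- ref_params()
  traj <- simulate_group(p, dose = 100, t_end = 48, grid_step = 0.5,
                         cona = FALSE)
  expect_equal(traj$C_TNF, rep(p$tnf$R0, nrow(traj)), tolerance = 1e-8)
  expect_equal(traj$C_IFN, rep(p$ifn$R0, nrow(traj)), tolerance = 1e-8)
  expect_equal(traj$C_IL10, rep(p$il10$R0, nrow(traj)), tolerance = 1e-8)
  expect_equal(traj$A_ALT, rep(p$disease$R0_ALT, nrow(traj)), tolerance = 1e-8)
})

test_that("normalised cytokine dynamics are invariant to the baselines", {
  b1 <- default_baselines()
  b2 <- b1; b2[["TNFa"]] <- 100; b2[["IFNg"]] <- 50
  tr1 <- simulate_group(ref_params(b1), dose = 0, t_end = 12, grid_step = 0.05)
  tr2 <- simulate_group(ref_params(b2), dose = 0, t_end = 12, grid_step = 0.05)
  expect_equal(tr2$C_TNF / 100, tr1$C_TNF / b1[["TNFa"]], tolerance = 1e-8)
  expect_equal(tr2$C_IFN / 50, tr1$C_IFN / b1[["IFNg"]], tolerance = 1e-8)
  # peak times therefore do not move under a global baseline rescaling
  b3 <- b1 * 3
  tr3 <- simulate_group(ref_params(b3), dose = 0, t_end = 12, grid_step = 0.01)
  tr1f <- simulate_group(ref_params(b1), dose = 0, t_end = 12, grid_step = 0.01)
  for (a in c("TNFa", "IFNg", "IL6")) {
    expect_equal(predicted_tmax(tr3, a)$tmax, predicted_tmax(tr1f, a)$tmax,
                 tolerance = 1e-4)
  }
})

test_that("cytokines never fall below baseline and higher doses never raise peaks", {
  p <- ref_params()
  peaks <- sapply(c(0, 50, 100), function(d) {
    tr <- simulate_group(p, dose = d, t_end = 16, grid_step = 0.02)
    expect_true(all(tr$C_TNF >= p$tnf$R0 - 1e-8))
    expect_true(all(tr$C_IFN >= p$ifn$R0 - 1e-8))
    expect_true(all(tr$C_IL6 >= p$il6$R0 - 1e-8))
    c(max(tr$C_TNF), max(tr$C_IFN), max(tr$C_IL6))
  })
  expect_true(all(diff(t(peaks))[, 1] <= 1e-8))  # dose 0 -> 50
  expect_true(all(diff(t(peaks))[, 2] <= 1e-8))  # dose 50 -> 100
})

test_that("the long-horizon state returns to its analytic fixed point", {
  p <- ref_params()
  tr <- simulate_group(p, dose = 0, t_end = 200, grid_step = 0.2)
  n <- nrow(tr)
  expect_equal(tr$C_TNF[n], p$tnf$R0, tolerance = 0.01)
  expect_equal(tr$C_IFN[n], p$ifn$R0, tolerance = 0.01)
  expect_equal(tr$C_IL6[n], p$il6$R0, tolerance = 0.01)
  # IL-10 settles at the elevated disease steady state
  fp <- p$il10$R0 +
    p$il10$kin_dis * (1 - p$il10$I_ifn * p$ifn$R0) / p$il10$kout
  expect_equal(tr$C_IL10[n], fp, tolerance = 1e-4)
})

test_that("the challenge event is a clean restart: T1 jumps, everything else is continuous", {
  p <- ref_params()
  tr <- simulate_group(p, dose = 50, t_end = 2, grid_step = 0.005)
  st <- attr(tr, "state")
  i <- which(tr$time == p$conA_time)
  expect_length(i, 1L)
  expect_equal(unname(st[i, "T1"]), 1)             # the jump
  expect_equal(unname(st[i - 1, "T1"]), 0)         # zero before it
  # biomarkers continuous through the event (still at baseline there)
  expect_equal(unname(st[i, "C_TNF"]), p$tnf$R0, tolerance = 1e-8)
  expect_equal(unname(st[i, "A_AST"]), p$disease$R0_AST, tolerance = 1e-8)
  # drug states unaffected by the event: closed form holds across it
  expect_equal(tr$C_GRMS, pk_concentration(tr$time, 50, p$pk),
               tolerance = 1e-7)
})

test_that("peak refinement is stable under tightened solver tolerances", {
  p <- ref_params()
  t1 <- simulate_group(p, dose = 0, t_end = 10, grid_step = 0.01)
  t2 <- simulate_group(p, dose = 0, t_end = 10, grid_step = 0.01,
                       rtol = 1e-9, atol = 1e-11)
  for (a in c("TNFa", "IFNg", "IL6")) {
    expect_equal(predicted_tmax(t1, a)$tmax, predicted_tmax(t2, a)$tmax,
                 tolerance = 0.01)
  }
})

test_that("a series without an interior peak is flagged, not an error", {
  p <- ref_params()
  tr <- simulate_group(p, dose = 0, t_end = 2.5, grid_step = 0.05)
  res <- predicted_tmax(tr, "ALT")  # still rising at 2.5 h
  expect_false(res$interior)
  res2 <- predicted_tmax(tr, "TNFa")  # peak at ~1.7 h post-challenge: interior
  expect_true(res2$interior)
})

test_that("simulate_group rejects impossible horizons and zero-dose drug states stay zero", {
  p <- ref_params()
  expect_error(simulate_group(p, dose = 0, t_end = 0.4), "t_end")
  expect_error(simulate_group(p, dose = -1), "dose")
  tr <- simulate_group(p, dose = 0, t_end = 5, grid_step = 0.1)
  expect_true(all(tr$C_GRMS == 0))
})
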