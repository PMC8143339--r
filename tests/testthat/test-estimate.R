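test_that("the WLS objective is zero iff predictions equal observations", {
  p <- ref_params()
  des <- study_design()
  dat <- generate_study(des, p, noise_cv = 0, seed = 7)
  dat <- dat[dat$value > 0, ]
  expect_equal(wls_objective(p, dat), 0, tolerance = 1e-10)
  # perturbing one observation by a known amount gives the hand-computed value
  d1 <- dat[dat$analyte == "TNFa", ][1:3, ]
  yhat <- predict_observations(p, d1)
  d1$value <- yhat * c(2, 1, 1)  # residual = yhat on the first record only
  expect_equal(wls_objective(p, d1), 1, tolerance = 1e-8)  # (yhat/yhat)^2
})

test_that("the WLS objective matches independent arithmetic and respects the exponent", {
  pk <- pk_parameters(2, 1, 3)
  d <- data.frame(group = "g", animal_id = paste0("a", 1:3),
                  dose_mg_per_kg = 10, time_h = c(0.25, 0.5, 1),
                  analyte = "GRMS55", value = c(1.0, 1.5, 0.9),
                  unit = "mg/L", cona = FALSE)
  p <- ref_params(); p$pk <- pk
  yhat <- pk_concentration(d$time_h, 10, pk)       # independent closed form
  expect_equal(wls_objective(p, d),
               sum(((d$value - yhat) / yhat)^2), tolerance = 1e-12)
  expect_equal(wls_objective(p, d, weight_exponent = 0),
               sum((d$value - yhat)^2), tolerance = 1e-12)
})

test_that("information criteria follow the fixed least-squares convention", {
  expect_equal(information_criteria(10, 10, 3), c(aic = 6, bic = 3 * log(10)))
  h <- information_criteria(5, 10, 2)
  expect_equal(unname(h["aic"]), 10 * log(0.5) + 4)
  expect_equal(unname(h["bic"]), 10 * log(0.5) + 2 * log(10))
  # a parameter added at unchanged WSS strictly worsens both criteria
  h3 <- information_criteria(5, 10, 3)
  expect_true(all(h3 > h))
  expect_error(information_criteria(5, 2, 2), "n_obs")
  expect_error(information_criteria(-1, 10, 2), "objective")
})

test_that("the PK fit is invariant to dose scale and demands a real design", {
  p <- ref_params()
  tt <- c(5, 15, 30, 60, 90, 120) / 60
  mk <- function(doses, scale = 1) {
    do.call(rbind, lapply(doses, function(D) data.frame(
      group = paste0("pk_", D), animal_id = paste0("d", D, "_", seq_along(tt)),
      dose_mg_per_kg = D * scale, time_h = tt,
      analyte = "GRMS55", value = pk_concentration(tt, D, p$pk) * scale,
      unit = "mg/L", cona = FALSE)))
  }
  f1 <- fit_pk(mk(c(50, 100)))
  f2 <- fit_pk(mk(c(50, 100), scale = 2))  # double doses and concentrations
  expect_equal(f1$estimates[c("ka", "ke")], f2$estimates[c("ka", "ke")],
               tolerance = 1e-6)
  expect_equal(unname(f1$estimates["Vd_F"]), 1.81, tolerance = 1e-4)
  one_time <- mk(50)[1, ]
  expect_error(fit_pk(one_time), "3 distinct")
})

test_that("multi-start PK fits from perturbed inits agree on noiseless data", {
  p <- ref_params()
  tt <- c(5, 15, 30, 60, 90, 120) / 60
  d <- data.frame(group = "pk_50", animal_id = paste0("m", seq_along(tt)),
                  dose_mg_per_kg = 50, time_h = tt,
                  analyte = "GRMS55", value = pk_concentration(tt, 50, p$pk),
                  unit = "mg/L", cona = FALSE)
  set.seed(11)
  ests <- replicate(5, {
    init <- table1_pk * runif(3, 0.5, 1.5)
    fit_pk(d, init = init)$estimates
  })
  spread <- apply(ests, 1, function(x) diff(range(x)) / min(x))
  expect_true(all(spread <= 0.01))
})

test_that("a control-only cytokine dataset flags the IC50s but recovers the rest", {
  p <- ref_params()
  des <- study_design(groups = data.frame(label = "control", dose = 0,
                                          cona = TRUE))
  dat <- generate_study(des, p, noise_cv = 0, seed = 3)
  cyt <- cytokine_rows(dat)
  init <- perturbed(table1_pd)
  f <- fit_pd(cyt, p$pk, default_baselines(), init = init)
  expect_setequal(f$unidentifiable, c("IC50_TNF", "IC50_IFN", "IC50_IL6"))
  expect_false(any(grepl("IC50", names(f$estimates))))
  free <- setdiff(names(table1_pd), f$unidentifiable)
  rel <- abs(f$estimates[free] - table1_pd[free]) / table1_pd[free]
  expect_true(all(rel < 0.01))
})

test_that("the disease stage keeps the structural exponents fixed and flags a flat design", {
  p <- ref_params()
  # no challenged animals: transaminases constant, stimulation unidentifiable
  flat <- data.frame(group = "healthy", animal_id = paste0("h", 1:8),
                     dose_mg_per_kg = 0, time_h = rep(c(1, 2), 4),
                     analyte = rep(c("ALT", "AST"), each = 4),
                     value = rep(c(35, 60), each = 4), unit = "U/L",
                     cona = FALSE)
  f <- fit_disease(flat, p, init = table1_disease)
  expect_setequal(f$unidentifiable,
                  c("S_ALT_TNF", "S_ALT_IFN", "S_AST_TNF", "S_AST_IFN"))
  expect_true(all(c("alpha", "beta") %in% f$fixed))
  expect_false(any(c("alpha", "beta") %in% names(f$estimates)))
})

test_that("refitting from the recovered optimum does not move the estimates", {
  p <- ref_params()
  des <- study_design()
  dat <- generate_study(des, p, noise_cv = 0, seed = 5)
  cyt <- cytokine_rows(dat)
  f1 <- fit_pd(cyt, p$pk, default_baselines(), init = perturbed(table1_pd))
  f2 <- fit_pd(cyt, p$pk, default_baselines(), init = f1$estimates)
  expect_equal(f2$estimates, f1$estimates, tolerance = 1e-6)
})

test_that("precision estimates are near zero on noiseless data and shrink with replication", {
  p <- ref_params()
  tt <- c(5, 15, 30, 60, 90, 120) / 60
  mk <- function(n_rep, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n_rep), function(r) data.frame(
      group = "pk_50", animal_id = sprintf("r%d_%d", r, seq_along(tt)),
      dose_mg_per_kg = 50, time_h = tt, analyte = "GRMS55",
      value = apply_proportional_noise(pk_concentration(tt, 50, p$pk), 0.1),
      unit = "mg/L", cona = FALSE)))
  }
  f0 <- fit_pk(mk(2, 1)); f0$cv_percent
  noiseless <- data.frame(group = "pk_50", animal_id = paste0("m", seq_along(tt)),
                          dose_mg_per_kg = 50, time_h = tt, analyte = "GRMS55",
                          value = pk_concentration(tt, 50, p$pk),
                          unit = "mg/L", cona = FALSE)
  fn <- fit_pk(noiseless)
  expect_true(all(estimate_cv(fn) < 1e-3, na.rm = TRUE))
  # median CV over seeded replicates roughly halves when n quadruples
  cv_small <- sapply(1:6, function(s) median(fit_pk(mk(2, s))$cv_percent))
  cv_large <- sapply(1:6, function(s) median(fit_pk(mk(8, 100 + s))$cv_percent))
  expect_lt(median(cv_large), median(cv_small))
})
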