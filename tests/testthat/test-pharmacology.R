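test_that("viability from optical densities is vehicle-relative and floored", {
  expect_equal(viability_from_od(0.8, 0.1, 0.7), 1.0)
  expect_equal(viability_from_od(0.45, 0.10, 0.70), 0.5)
  expect_equal(viability_from_od(0.05, 0.10, 0.70), 0.0)
  expect_error(viability_from_od(0.5, 0.1, 0), "vehicle mean")
})

test_that("4PL curve hits the exact midpoint at the IC50 and is monotone", {
  for (p in list(c(0, 1, 1, 2.3), c(0.2, 0.9, 2.5, 0.4),
                 c(0.4, 1.1, 0.7, 10))) {
    expect_equal(fourpl(p[4], p[1], p[2], p[3], p[4]),
                 (p[1] + p[2]) / 2)
    x <- 10^seq(-3, 3, length.out = 50)
    y <- fourpl(x, p[1], p[2], p[3], p[4])
    expect_true(all(diff(y) < 0))  # decreasing for hill > 0, top > bottom
  }
})

noise_free_dataset <- function(bottom = 0, top = 1, hill = 1, ic50 = 2.3) {
  doses <- 10^seq(log10(0.01), log10(30), length.out = 8)
  grid <- expand.grid(concentration_uM = doses, experiment = 1:3,
                      replicate = 1:3)
  dose_response("drugX", grid$concentration_uM,
                fourpl(grid$concentration_uM, bottom, top, hill, ic50),
                grid$experiment, grid$replicate)
}

test_that("noise-free 4PL data round-trips through the fit", {
  fit <- fit_4pl(noise_free_dataset())
  expect_true(fit$converged)
  expect_equal(fit$ic50, 2.3, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$hill_slope, 1, tolerance = 1e-6)
  expect_equal(fit$per_experiment_ic50s, rep(2.3, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("refitting a fitted curve's predictions recovers the parameters", {
  sim <- sim_dose_response(seed = 17)
  fit <- fit_4pl(sim$datasets$mono)
  refit <- fit_4pl(noise_free_dataset(fit$bottom, fit$top, fit$hill_slope,
                                      fit$ic50))
  expect_equal(refit$ic50, fit$ic50, tolerance = 1e-6)
  expect_equal(refit$hill_slope, fit$hill_slope, tolerance = 1e-6)
})

test_that("noisy simulated curves recover the IC50 within 15%", {
  sim <- sim_dose_response(
    synth_dose_config(conditions = list(
      mono = list(bottom = 0, top = 1, hill = 1, ic50 = 2.3))),
    seed = 4)
  fit <- fit_4pl(sim$datasets$mono)
  expect_lt(abs(fit$ic50 - 2.3) / 2.3, 0.15)
})

test_that("near-flat curves are flagged IC50-unidentifiable", {
  flat <- noise_free_dataset(bottom = 0.99, top = 1, ic50 = 1)
  fit <- fit_4pl(flat)
  expect_true(fit$ic50_unidentifiable)
})

test_that("fewer than 4 distinct doses is an error", {
  d <- dose_response("x", rep(c(1, 2, 3), 2), rep(0.5, 6), rep(1:2, each = 3))
  expect_error(fit_4pl(d), "at least 4 distinct concentrations")
})

test_that("compare_ic50 reports shift, inhibition and a textbook t-test p", {
  mono <- fake_fit(c(2.3, 2.1, 2.5))
  combo <- fake_fit(c(1.0, 0.9, 1.1), min_mean_response = 0.4)
  res <- compare_ic50(mono, combo)
  expect_equal(res$fold_shift, mean(c(2.3, 2.1, 2.5)) / 1.0, tolerance = 1e-10)
  expect_equal(res$max_inhibition_percent, 60)
  # closed-form equal-variance t on log10 values, df = 4
  x <- log10(c(2.3, 2.1, 2.5)); y <- log10(c(1.0, 0.9, 1.1))
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
})

test_that("identical fits give fold shift 1 and p near 1", {
  a <- fake_fit(c(2.0, 2.2, 1.9))
  res <- compare_ic50(a, fake_fit(c(2.0, 2.2, 1.9)))
  expect_equal(res$fold_shift, 1)
  expect_equal(res$p_value, 1, tolerance = 1e-8)
})

test_that("unidentifiable IC50s suppress the p-value", {
  a <- fake_fit(c(2, 2.1, 2.2)); a$ic50_unidentifiable <- TRUE
  res <- compare_ic50(a, fake_fit(c(1, 1.1, 1.2)))
  expect_true(res$unidentifiable)
  expect_true(is.na(res$p_value))
})

test_that("growth-curve comparison tests each group against the reference", {
  set.seed(31)
  curves <- rbind(
    data.frame(treatment = "NC-siRNA", time_h = 72,
               od = c(1.00, 1.02, 0.98)),
    data.frame(treatment = "A-siRNA", time_h = 72,
               od = c(0.70, 0.69, 0.72)),           # 30% reduction
    data.frame(treatment = "same", time_h = 72,
               od = c(1.00, 1.02, 0.98)),
    data.frame(treatment = "single", time_h = 72, od = 0.9))
  expect_warning(res <- compare_growth_curves(curves), "replicates")
  a <- res[res$treatment == "A-siRNA", ]
  expect_lt(a$p_value, 0.01)
  expect_equal(a$stars, "***")
  expect_gt(res$p_value[res$treatment == "same"], 0.9)
  expect_true(is.na(res$p_value[res$treatment == "single"]))
  expect_error(compare_growth_curves(curves, reference = "missing"),
               "absent")
})
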