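test_that("quantification generator is deterministic given a seed", {
  cfg <- synth_quant_config(n_proteins = 150, n_exclusive_cancer = 8)
  a <- sim_quant_experiment(cfg, seed = 12)
  b <- sim_quant_experiment(cfg, seed = 12)
  expect_identical(a$tables$cancer_a$areas, b$tables$cancer_a$areas)
  expect_identical(a$ground_truth$exclusive_cancer_a,
                   b$ground_truth$exclusive_cancer_a)
  c_ <- sim_quant_experiment(cfg, seed = 13)
  expect_false(identical(a$tables$cancer_a$areas, c_$tables$cancer_a$areas))
  expect_error(sim_quant_experiment(cfg), "seed")
})

test_that("zero dropout leaves no missing cells in any line's table", {
  sim <- sim_quant_experiment(
    synth_quant_config(n_proteins = 200, n_exclusive_cancer = 10,
                       dropout = 0),
    seed = 3)
  for (tbl in sim$tables) expect_false(anyNA(tbl$areas))
  # planted exclusives simply have no rows in the other lines' tables
  expect_false(any(sim$ground_truth$exclusive_cancer_a %in%
                     rownames(sim$tables$control$areas)))
  expect_false(any(sim$ground_truth$exclusive_cancer_a %in%
                     rownames(sim$tables$cancer_b$areas)))
})

test_that("generated tables satisfy the quant-table invariants", {
  sim <- sim_quant_experiment(
    synth_quant_config(n_proteins = 300, n_exclusive_cancer = 12,
                       dropout = 0.2),
    seed = 8)
  for (tbl in sim$tables) {
    expect_s3_class(tbl, "quant_table")
    expect_false(anyDuplicated(rownames(tbl$areas)) > 0)
    expect_true(all(tbl$areas >= 0, na.rm = TRUE))
    expect_true(all(rowSums(!is.na(tbl$areas)) >= 1))
  }
})

test_that("trace mode plants sub-threshold control signal for exclusives", {
  sim <- sim_quant_experiment(
    synth_quant_config(n_proteins = 300, n_exclusive_cancer = 12,
                       dropout = 0, exclusive_control_mode = "trace"),
    seed = 8)
  ctrl <- normalize_table(sim$tables$control)
  excl <- sim$ground_truth$exclusive_cancer_a
  expect_true(all(excl %in% rownames(ctrl$areas)))
  expect_true(all(ctrl$areas[excl, ] < 70))
})

test_that("abundance-dependent dropout hits low-abundance proteins harder", {
  cfg <- synth_quant_config(n_proteins = 1000, n_exclusive_cancer = 0,
                            dropout = list(max = 0.8, midpoint_log = 13,
                                           slope = 1.5))
  sim <- sim_quant_experiment(cfg, seed = 42)
  truth <- sim$ground_truth$true_abundance$control
  names(truth) <- sim$ground_truth$accession
  obs <- rownames(sim$tables$control$areas)
  miss_frac <- rowMeans(is.na(sim$tables$control$areas))
  low <- obs[truth[obs] < exp(12)]
  high <- obs[truth[obs] > exp(14)]
  expect_gt(mean(miss_frac[low]), mean(miss_frac[high]))
})

test_that("log-normal abundance marginal matches the configured model", {
  cfg <- synth_quant_config(n_proteins = 2300, n_exclusive_cancer = 0)
  sim <- sim_quant_experiment(cfg, seed = 14)
  ks <- suppressWarnings(
    ks.test(log(sim$ground_truth$true_abundance$control),
            "pnorm", mean = cfg$abundance_meanlog,
            sd = cfg$abundance_sdlog))
  expect_gt(ks$p.value, 0.01)
})

test_that("end-to-end screen recovers the planted exclusives at zero noise", {
  sim <- sim_quant_experiment(
    synth_quant_config(n_proteins = 500, n_exclusive_cancer = 20,
                       replicate_cv = 0, dropout = 0),
    seed = 2)
  res <- run_pipeline(sim$tables[c("cancer_a", "cancer_b")],
                      sim$tables$control, sim$annotation,
                      screen_config(top_n = 20L))
  expect_setequal(res$candidates$cancer_a$accession,
                  sim$ground_truth$exclusive_cancer_a)
  expect_setequal(res$candidates$cancer_b$accession,
                  sim$ground_truth$exclusive_cancer_b)
})

test_that("TMA generator hits the configured positivity probabilities", {
  cfg <- synth_tma_config(n_benign = 5, n_cancer = 5,
                          positivity_prob_benign = 0,
                          positivity_prob_cancer = 1)
  sim <- sim_tma_cohort(cfg, seed = 1)
  benign <- sim$cases$ihc_score[sim$cases$tissue_class == "normal_benign"]
  cancer <- sim$cases$ihc_score[sim$cases$tissue_class == "carcinoma"]
  expect_true(all(benign == 1))
  expect_true(all(cancer >= 2))

  # binomial check: mean cancer positivity near 0.49 over many seeds
  pos_frac <- vapply(1:200, function(s) {
    cases <- sim_tma_cohort(synth_tma_config(), seed = s)$cases
    carc <- cases[cases$tissue_class == "carcinoma", ]
    mean(carc$ihc_score >= 2, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(pos_frac) - 0.49), 0.03)
})

test_that("planted covariate odds ratios shift the positivity logit", {
  cfg <- synth_tma_config(
    n_cancer = 400,
    covariate_log_or = list(ln_metastasis = c(positive = 2)))
  sim <- sim_tma_cohort(cfg, seed = 6)
  carc <- sim$cases[sim$cases$tissue_class == "carcinoma", ]
  tab <- build_contingency(carc, "ln_metastasis")
  res <- pearson_chi_square(tab)
  expect_lt(res$p_value, 0.001)
})

test_that("dose-response generator is exact at zero noise and seeded", {
  cfg <- synth_dose_config(noise_sd = 0)
  sim <- sim_dose_response(cfg, seed = 5)
  d <- sim$datasets$mono$data
  p <- cfg$conditions$mono
  expect_equal(d$viability,
               fourpl(d$concentration_uM, p$bottom, p$top, p$hill, p$ic50))
  a <- sim_dose_response(seed = 5); b <- sim_dose_response(seed = 5)
  expect_identical(a$datasets$mono$data, b$datasets$mono$data)
})

test_that("planted mono-versus-combo shift is detected", {
  sim <- sim_dose_response(seed = 23)
  cmp <- compare_ic50(fit_4pl(sim$datasets$mono),
                      fit_4pl(sim$datasets$combo))
  expect_gt(cmp$fold_shift, 1.5)
  expect_lt(cmp$p_value, 0.05)
})
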