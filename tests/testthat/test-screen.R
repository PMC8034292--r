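test_that("detection rules apply the presence fraction and control minimum", {
  cfg <- screen_config()
  # cancer rule at the 3/4 = 75% boundary (inclusive)
  expect_true(call_detection(3, 4, "cancer", cfg)$detected)
  expect_false(call_detection(2, 4, "cancer", cfg)$detected)
  # control rule needs >= 3 replicates at the floor
  expect_false(call_detection(2, 4, "control", cfg)$detected)
  expect_true(call_detection(3, 4, "control", cfg)$detected)
})

test_that("annotation table flags membrane terms from a semicolon list", {
  ann <- annotation_table(c("P1", "P2", "P3"),
                          c("Cell Membrane; cytoplasm", "cytoplasm",
                            "endoplasmic reticulum membrane"))
  expect_equal(ann$membrane_associated, c(TRUE, FALSE, TRUE))
})

test_that("filter_membrane retains membrane proteins and reports drops", {
  summ <- data.frame(accession = c("P1", "P2", "P3"),
                     n_replicates_total = 4, n_detected = 4,
                     mean_norm_area = c(100, 200, 300),
                     sd_norm_area = 1, cv_percent = 1)
  ann <- annotation_table(c("P1", "P2"), c("cell membrane", "cytoplasm"))
  expect_warning(out <- filter_membrane(summ, ann), "unannotated")
  expect_equal(out$accession, "P1")
  expect_equal(attr(out, "n_unannotated"), 1)
  expect_equal(attr(out, "n_non_membrane"), 1)
})

test_that("compute_venn partitions sets with disjoint pieces", {
  v <- compute_venn(c("p1", "p2", "p3"), c("p2", "p3", "p4"))
  expect_equal(v$n_common, 2)
  expect_equal(v$n_unique_a, 1)
  expect_equal(v$n_unique_b, 1)
  same <- compute_venn(letters[1:5], letters[1:5])
  expect_equal(same$n_common, 5)
  expect_equal(same$n_unique_a, 0)
  disj <- compute_venn(letters[1:5], LETTERS[1:7])
  expect_equal(c(disj$n_common, disj$n_unique_a, disj$n_unique_b), c(0, 5, 7))
})

test_that("venn partition laws hold on random inputs", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample(sprintf("x%02d", 1:40), sample(5:30, 1))
    b <- sample(sprintf("x%02d", 1:40), sample(5:30, 1))
    v <- compute_venn(a, b)
    expect_length(intersect(v$common, v$unique_a), 0)
    expect_length(intersect(v$common, v$unique_b), 0)
    expect_length(intersect(v$unique_a, v$unique_b), 0)
    expect_setequal(c(v$common, v$unique_a), unique(a))
    expect_setequal(c(v$common, v$unique_b), unique(b))
  }
})

make_summary <- function(accession, values_list, threshold = 70) {
  rows <- lapply(values_list, summarize_protein,
                 detection_threshold = threshold)
  cbind(data.frame(accession = accession, gene = accession,
                   description = accession),
        do.call(rbind, rows))
}

test_that("select_candidates enumerates the screening rules on a toy set", {
  # P1 passes everything; P2 is expressed in control; P3 has CV > ceiling
  cancer <- make_summary(
    c("P1", "P2", "P3"),
    list(c(100, 100, 100, 100), c(500, 500, 500, 500),
         c(100, 300, 900, 2000)))
  control <- make_summary(
    c("P1", "P2", "P3"),
    list(c(10, 10, NA, NA), c(80, 80, 80, NA), c(10, 10, 10, 10)))
  # P2 control n_detected = 3 -> control-detected -> excluded
  ann <- annotation_table(c("P1", "P2", "P3"),
                          rep("plasma membrane", 3))
  out <- select_candidates(cancer, control, ann)
  expect_equal(out$accession, "P1")
  expect_equal(out$rank, 1L)
  expect_gt(summarize_protein(c(100, 300, 900, 2000))$cv_percent, 40)
})

test_that("candidate table is ranked by mean with deterministic tie-break", {
  vals <- list(c(300, 300, 300, 300), c(500, 500, 500, 500),
               c(300, 300, 300, 300))
  cancer <- make_summary(c("B", "A", "C"), vals)
  control <- make_summary(c("B", "A", "C"),
                          lapply(1:3, function(i) c(NA, NA, NA, 10)))
  ann <- annotation_table(c("A", "B", "C"), rep("membrane", 3))
  out <- select_candidates(cancer, control, ann)
  expect_equal(out$accession, c("A", "B", "C"))  # mean desc, then accession
  top1 <- select_candidates(cancer, control, ann,
                            screen_config(top_n = 1))
  expect_equal(top1$accession, "A")
})

test_that("no candidate is ever detected under the control rule", {
  set.seed(5)
  for (i in 1:10) {
    sim <- sim_quant_experiment(
      synth_quant_config(n_proteins = 200, n_exclusive_cancer = 10,
                         dropout = 0.15),
      seed = i)
    ctrl_sum <- summarize_quant_table(normalize_table(sim$tables$control))
    cancer_sum <- summarize_quant_table(normalize_table(sim$tables$cancer_a))
    cand <- select_candidates(cancer_sum, ctrl_sum, sim$annotation)
    ctrl_detected <- cand$accession %in%
      ctrl_sum$accession[ctrl_sum$n_detected >=
                           screen_config()$control_min_detected_reps]
    expect_false(any(ctrl_detected))
  }
})

test_that("tightening any screen threshold never adds candidates", {
  sim <- sim_quant_experiment(
    synth_quant_config(n_proteins = 400, n_exclusive_cancer = 15,
                       dropout = 0.1),
    seed = 99)
  n_cand <- function(cfg) {
    ca <- summarize_quant_table(normalize_table(sim$tables$cancer_a),
                                cfg$detection_threshold)
    co <- summarize_quant_table(normalize_table(sim$tables$control),
                                cfg$detection_threshold)
    attr(select_candidates(ca, co, sim$annotation, cfg), "n_pool")
  }
  theta_counts <- vapply(c(70, 120, 200, 400), function(t)
    n_cand(screen_config(detection_threshold = t, top_n = 1000L)),
    numeric(1))
  expect_true(all(diff(theta_counts) <= 0))
  cv_counts <- vapply(c(60, 40, 25, 10), function(cv)
    n_cand(screen_config(cv_max_percent = cv, top_n = 1000L)), numeric(1))
  expect_true(all(diff(cv_counts) <= 0))
  pf_counts <- vapply(c(0.5, 0.75, 1), function(pf)
    n_cand(screen_config(presence_fraction = pf, top_n = 1000L)), numeric(1))
  expect_true(all(diff(pf_counts) <= 0))
})
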