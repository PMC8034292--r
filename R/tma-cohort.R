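fill_levels <- function(n, counts) {
  v <- rep(names(counts), times = counts)
  c(v, rep(NA_character_, n - length(v)))
}

#' Bundled STEAP4 tissue-microarray example cohort
#'
#' A deterministic case-level reconstruction of the published STEAP4
#' breast-cancer tissue-microarray association cohort: 18 normal/benign and
#' 42 carcinoma cases (one unevaluable core per group), 20 of 41 evaluable
#' carcinomas STEAP4-positive, with clinicopathological covariates (age
#' group, pT status, histology grade, lymph-node metastasis, pathological
#' stage, HER2 status) distributed within the positive and negative groups
#' so that every per-covariate contingency table matches the published
#' counts. Covariates unavailable for a case are `NA`; benign cases carry no
#' tumor covariates.
#'
#' Because only the per-covariate margins are published, covariate columns
#' are assigned independently within each positivity group; the joint
#' distribution across covariates is synthetic, but every 2-way
#' covariate-by-expression table (the quantities the association analysis
#' consumes) is exact.
#'
#' @return data.frame with one row per case: `case_id`, `tissue_class`,
#'   `ihc_score`, `age_group`, `pt_status`, `grade`, `ln_metastasis`,
#'   `stage`, `her2_status`.
#' @export
steap4_tma_cohort <- function() {
  # benign: 17 evaluable all score 1 (negative), one unevaluable core
  benign <- data.frame(
    case_id = sprintf("B%02d", 1:18),
    tissue_class = "normal_benign",
    ihc_score = c(rep(1L, 17), NA_integer_),
    age_group = NA_character_, pt_status = NA_character_,
    grade = NA_character_, ln_metastasis = NA_character_,
    stage = NA_character_, her2_status = NA_character_,
    stringsAsFactors = FALSE)
  # carcinoma: 20 positive (scores 2-4), 21 negative (score 1), one
  # unevaluable core; covariate margins per positivity group
  n_pos <- 20L; n_neg <- 21L
  pos <- data.frame(
    case_id = sprintf("C%02d", 1:n_pos),
    tissue_class = "carcinoma",
    ihc_score = rep(c(2L, 3L, 4L), length.out = n_pos),
    age_group = fill_levels(n_pos, c(">40" = 14, "<=40" = 6)),
    pt_status = fill_levels(n_pos, c(T2 = 15, T3 = 3)),
    grade = fill_levels(n_pos, c("II" = 10, "II~III" = 4, "III" = 4)),
    ln_metastasis = fill_levels(n_pos, c(negative = 7, positive = 13)),
    stage = fill_levels(n_pos, c(IIA = 5, IIB = 9, IIIA = 4)),
    her2_status = fill_levels(n_pos, c(negative = 7, positive = 7)),
    stringsAsFactors = FALSE)
  neg <- data.frame(
    case_id = sprintf("C%02d", (n_pos + 1):(n_pos + n_neg)),
    tissue_class = "carcinoma",
    ihc_score = 1L,
    age_group = fill_levels(n_neg, c(">40" = 10, "<=40" = 11)),
    pt_status = fill_levels(n_neg, c(T2 = 9, T3 = 7)),
    grade = fill_levels(n_neg, c("II~III" = 4, "III" = 8)),
    ln_metastasis = fill_levels(n_neg, c(negative = 13, positive = 7)),
    stage = fill_levels(n_neg, c(IIA = 5, IIB = 11, IIIA = 1)),
    her2_status = fill_levels(n_neg, c(negative = 11, positive = 10)),
    stringsAsFactors = FALSE)
  unevaluable <- data.frame(
    case_id = "C42", tissue_class = "carcinoma", ihc_score = NA_integer_,
    age_group = NA_character_, pt_status = NA_character_,
    grade = NA_character_, ln_metastasis = NA_character_,
    stage = NA_character_, her2_status = NA_character_,
    stringsAsFactors = FALSE)
  out <- rbind(benign, pos, neg, unevaluable)
  rownames(out) <- NULL
  out
}
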